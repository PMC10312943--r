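# Prognostic framework: endpoint coding, Kaplan-Meier / log-rank summaries
# (via the survival package, exposed behind a stable module surface),
# a censored-data recursive-partitioning grouping of categories by greedy
# log-rank splits, the packaged category-to-risk-group mapping, and the
# six-stratum framework crossing risk group with MRD positivity.

STRATUM_LEVELS <- c("Low/MRD-", "Low/MRD+", "Intermediate/MRD-",
                    "Intermediate/MRD+", "High/MRD-", "High/MRD+")

#' Code event-free survival from clinical records
#'
#' EFS events are relapse, death in remission by any cause, and
#' non-response; non-response counts as an event at the date of diagnosis
#' (time 0). Records without any of the three are censored at last
#' follow-up.
#'
#' @param clinical clinical table (see [paml_cohort()]).
#' @return data frame `sample_id`, `time`, `event`, `endpoint = "EFS"`.
#' @export
code_efs <- function(clinical) {
  clinical <- as.data.frame(clinical)
  if (any(clinical$efs_time < 0, na.rm = TRUE)) {
    stop("negative follow-up time", call. = FALSE)
  }
  nr <- !is.na(clinical$non_response) & clinical$non_response
  ev <- nr |
    (!is.na(clinical$relapse) & clinical$relapse) |
    (!is.na(clinical$death_in_remission) & clinical$death_in_remission)
  data.frame(sample_id = clinical$sample_id,
             time = ifelse(nr, 0, clinical$efs_time),
             event = ev, endpoint = "EFS", stringsAsFactors = FALSE)
}

#' Code overall survival from clinical records
#' @param clinical clinical table.
#' @return data frame `sample_id`, `time`, `event`, `endpoint = "OS"`.
#' @export
code_os <- function(clinical) {
  clinical <- as.data.frame(clinical)
  if (any(clinical$os_time < 0, na.rm = TRUE)) {
    stop("negative follow-up time", call. = FALSE)
  }
  data.frame(sample_id = clinical$sample_id, time = clinical$os_time,
             event = clinical$os_event, endpoint = "OS",
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event numeric event/censoring times and logical event
#'   indicators (or a data frame with `time` and `event` as first
#'   argument).
#' @return data frame step function: `time`, `n_risk`, `n_event`, `surv`,
#'   starting at S(0) = 1; the estimate drops only at event times.
#' @export
km_estimate <- function(time, event = NULL) {
  if (is.data.frame(time)) { event <- time$event; time <- time$time }
  if (length(time) == 0) stop("no records", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, fit$time), n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event), surv = c(1, fit$surv))
}

#' Evaluate a Kaplan-Meier step function at a landmark time
#'
#' Right-continuous step lookup; beyond the last observed time the last
#' value is carried forward.
#'
#' @param km data frame from [km_estimate()].
#' @param t landmark time(s).
#' @return survival probability at `t`.
#' @export
km_at <- function(km, t) {
  vapply(t, function(tt) km$surv[max(which(km$time <= tt))], 0)
}

#' Log-rank test across groups
#'
#' Standard log-rank statistic with hypergeometric variance; p-value from a
#' chi-square distribution with (groups - 1) degrees of freedom. With zero
#' events the statistic is 0 and p = 1.
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 distinct values).
#' @return list `statistic`, `df`, `p`.
#' @export
logrank <- function(time, event, group) {
  group <- as.factor(group)
  k <- nlevels(droplevels(group))
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (sum(event) == 0) return(list(statistic = 0, df = k - 1, p = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd$chisq), df = k - 1,
       p = stats::pchisq(sd$chisq, k - 1, lower.tail = FALSE))
}

#' Recursive-partitioning risk grouping for censored event times
#'
#' Greedy binary splits over category-subset indicators: at each node the
#' categories are ordered by their landmark Kaplan-Meier survival and the
#' cut along that order maximizing the two-group log-rank statistic is
#' taken (the standard linear-search trick for categorical splits in
#' survival trees). Growth stops at the minimum leaf size, maximum depth,
#' or when no split reaches `split_alpha`; the grown tree is then pruned
#' back to `target_leaves` by collapsing the weakest splits, and the
#' resulting partition is polished by a local refinement pass (single
#' categories move between groups while the overall log-rank statistic
#' improves -- greedy growth alone can strand a category on the wrong side
#' of an early cut). Leaves are ranked by landmark survival into ordered
#' risk labels (best to worst: Low / Intermediate / High for three
#' leaves).
#'
#' @param time,event survival data.
#' @param category category label per sample.
#' @param min_leaf minimum samples per leaf (default 20).
#' @param max_depth maximum split depth (default 3).
#' @param split_alpha log-rank p-value required to accept a split.
#' @param target_leaves prune the tree back to this many leaves (NULL keeps
#'   the grown tree).
#' @param landmark landmark time in years for ordering (default 5).
#' @return object of class `paml_survtree` with `groups` (data frame
#'   `category`, `leaf`, `risk_label`, `surv_landmark`) and the node list.
#' @export
fit_survival_tree <- function(time, event, category, min_leaf = 20,
                              max_depth = 3, split_alpha = 0.01,
                              target_leaves = 3, landmark = 5) {
  stopifnot(length(time) == length(event), length(time) == length(category))
  category <- as.character(category)
  cat_surv <- function(idx) {
    cats <- sort(unique(category[idx]))
    s <- vapply(cats, function(cc) {
      sel <- idx[category[idx] == cc]
      km_at(km_estimate(time[sel], event[sel]), landmark)
    }, 0)
    s
  }
  nodes <- list()
  new_node <- function(idx, depth, parent) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, children = NULL,
                         dropped = FALSE, idx = idx, depth = depth,
                         categories = sort(unique(category[idx])),
                         n = length(idx), events = sum(event[idx]),
                         surv_landmark = km_at(km_estimate(time[idx],
                                                           event[idx]),
                                               landmark),
                         split_stat = NA_real_, split_left = NULL)
    id
  }
  grow <- function(id) {
    nd <- nodes[[id]]
    if (nd$depth >= max_depth || length(nd$categories) < 2 ||
        nd$n < 2 * min_leaf) return(invisible())
    s <- cat_surv(nd$idx)
    ord <- names(s)[order(-s, names(s))]   # best survival first
    best <- NULL
    for (i in seq_len(length(ord) - 1)) {
      left_cats <- ord[seq_len(i)]
      in_left <- category[nd$idx] %in% left_cats
      if (sum(in_left) < min_leaf || sum(!in_left) < min_leaf) next
      lr <- logrank(time[nd$idx], event[nd$idx], in_left)
      if (is.null(best) || lr$statistic > best$stat) {
        best <- list(stat = lr$statistic, p = lr$p, left = left_cats)
      }
    }
    if (is.null(best) || best$p > split_alpha) return(invisible())
    li <- nd$idx[category[nd$idx] %in% best$left]
    ri <- setdiff(nd$idx, li)
    lid <- new_node(li, nd$depth + 1L, id)
    rid <- new_node(ri, nd$depth + 1L, id)
    nodes[[id]]$children <<- c(lid, rid)
    nodes[[id]]$split_stat <<- best$stat
    nodes[[id]]$split_left <<- best$left
    grow(lid); grow(rid)
    invisible()
  }
  root <- new_node(seq_along(time), 0L, NA_integer_)
  grow(root)
  leaves <- function() {
    Filter(function(nd) !nd$dropped && is.null(nd$children), nodes)
  }
  # prune: repeatedly collapse the weakest split whose children are leaves
  if (!is.null(target_leaves)) {
    repeat {
      lv <- leaves()
      if (length(lv) <= target_leaves) break
      cand <- Filter(function(nd) {
        !nd$dropped && !is.null(nd$children) &&
          all(vapply(nodes[nd$children], function(x)
            is.null(x$children), TRUE))
      }, nodes)
      stats_ <- vapply(cand, `[[`, 0, "split_stat")
      weakest <- cand[[which.min(stats_)]]
      for (ch in weakest$children) nodes[[ch]]$dropped <- TRUE
      nodes[[weakest$id]]$children <- NULL
      nodes[[weakest$id]]$split_stat <- NA_real_
      nodes[[weakest$id]]$split_left <- NULL
    }
  }
  lv <- leaves()
  surv <- vapply(lv, `[[`, 0, "surv_landmark")
  ord <- order(-surv)   # best survival first
  k <- length(lv)
  part <- integer(0)    # category -> group index (1 = best survival)
  for (j in seq_len(k)) {
    cats_j <- lv[[ord[j]]]$categories
    part[cats_j] <- j
  }
  # local refinement: greedy binary growth can strand a category on the
  # wrong side of a cut it can never re-cross; hill-climb on single-category
  # moves, accepting the move that most increases the k-group log-rank
  # statistic of the partition
  if (k > 1) {
    part_stat <- function(p) logrank(time, event, p[category])$statistic
    cur <- part_stat(part)
    for (sweep in 1:20) {
      improved <- FALSE
      for (cc in names(part)) {
        if (sum(part == part[cc]) == 1) next   # keep every group non-empty
        for (g in setdiff(seq_len(k), part[cc])) {
          cand <- part; cand[cc] <- g
          st <- part_stat(cand)
          if (st > cur + 1e-9) {
            part <- cand; cur <- st; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }
  labels <- if (k == 1) "Intermediate" else if (k == 2) c("Low", "High")
            else if (k == 3) c("Low", "Intermediate", "High")
            else paste0("risk_", seq_len(k))
  group_surv <- vapply(seq_len(k), function(j) {
    sel <- category %in% names(part)[part == j]
    km_at(km_estimate(time[sel], event[sel]), landmark)
  }, 0)
  relab <- order(-group_surv)   # re-rank groups after refinement
  groups <- do.call(rbind, lapply(seq_len(k), function(j) {
    cats_j <- sort(names(part)[part == relab[j]])
    data.frame(category = cats_j, leaf = relab[j], risk_label = labels[j],
               surv_landmark = group_surv[relab[j]],
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  structure(list(nodes = nodes, groups = groups, landmark = landmark),
            class = "paml_survtree")
}

#' @export
print.paml_survtree <- function(x, ...) {
  k <- length(unique(x$groups$leaf))
  cat(sprintf("survival tree: %d leaves (landmark %g years)\n", k,
              x$landmark))
  for (lab in unique(x$groups$risk_label)) {
    g <- x$groups[x$groups$risk_label == lab, ]
    cat(sprintf("  %s (S(%g) = %.2f): %s\n", lab, x$landmark,
                g$surv_landmark[1], paste(g$category, collapse = ", ")))
  }
  invisible(x)
}

#' Predict the risk label for categories from a fitted survival tree
#' @param object a `paml_survtree`.
#' @param newdata character vector of categories.
#' @param ... unused.
#' @return character vector of risk labels (`NA` for categories unseen in
#'   training).
#' @export
predict.paml_survtree <- function(object, newdata, ...) {
  idx <- match(as.character(newdata), object$groups$category)
  object$groups$risk_label[idx]
}

#' Combine risk group and MRD status into one of six strata
#'
#' @param risk_group `Low`, `Intermediate`, or `High`.
#' @param mrd_positive logical; `NA` withholds the stratum (logged via
#'   warning).
#' @return character vector of stratum labels (`Low/MRD-` ... `High/MRD+`).
#' @export
assign_strata <- function(risk_group, mrd_positive) {
  if (!all(risk_group %in% RISK_LEVELS)) {
    stop("unknown risk group", call. = FALSE)
  }
  out <- ifelse(is.na(mrd_positive), NA_character_,
                paste0(risk_group, "/MRD", ifelse(mrd_positive, "+", "-")))
  if (any(is.na(mrd_positive))) {
    warning(sprintf("stratum withheld for %d sample(s) with unknown MRD",
                    sum(is.na(mrd_positive))), call. = FALSE)
  }
  out
}

#' Risk-stratify a classified cohort
#'
#' Joins category calls with clinical records, maps categories to risk
#' groups via the packaged mapping, assigns the six MRD-combined strata, and
#' codes the requested survival endpoint.
#'
#' @param calls category-call data frame.
#' @param clinical clinical table.
#' @param ruleset a `paml_ruleset`.
#' @param endpoint `"OS"` or `"EFS"`.
#' @return data frame per sample: `sample_id`, `category`, `risk_group`,
#'   `mrd_positive`, `stratum`, `time`, `event`, `endpoint`.
#' @export
stratify_cohort <- function(calls, clinical, ruleset = default_ruleset(),
                            endpoint = c("OS", "EFS")) {
  endpoint <- match.arg(endpoint)
  rec <- if (endpoint == "OS") code_os(clinical) else code_efs(clinical)
  idx <- match(calls$sample_id, rec$sample_id)
  mrd <- clinical$mrd_positive[match(calls$sample_id, clinical$sample_id)]
  risk <- map_risk_group(calls$category, ruleset)
  data.frame(sample_id = calls$sample_id, category = calls$category,
             risk_group = risk, mrd_positive = mrd,
             stratum = assign_strata(risk, mrd),
             time = rec$time[idx], event = rec$event[idx],
             endpoint = endpoint, stringsAsFactors = FALSE)
}
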