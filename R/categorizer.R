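# Precedence-ordered assignment of each sample to exactly one molecular
# category (or Unclassified). The engine evaluates the declarative ruleset
# tier by tier; tier-3 (expression-gated) rules fire only when no tier-1/2
# driver explains the sample and the expression signature is consistent with
# the category. Two distinct categories firing in the same tier is a ruleset
# defect and is raised as an error, not silently resolved.

# sample ids matched by one rule's trigger, given the cohort's fusion table,
# kept pathogenic mutation table, and ASE/outlier support per sample.
rule_matched_samples <- function(rule, fusions, mutations, ase_ok) {
  hits <- character()
  f <- rule$fusion
  if (!is.null(f)) {
    frames <- if (is.null(f$frames)) "in_frame" else unlist(f$frames)
    genes <- if (!is.null(f$gene_set)) unlist(f$gene_set) else f$gene
    sel <- (fusions$gene_5p %in% genes | fusions$gene_3p %in% genes) &
      fusions$frame %in% frames
    if (!identical(f$partners, "any") && !is.null(f$partners)) {
      partners <- unlist(f$partners)
      other <- ifelse(fusions$gene_5p %in% genes, fusions$gene_3p,
                      fusions$gene_5p)
      sel <- sel & other %in% partners
    }
    hits <- c(hits, fusions$sample_id[sel])
  }
  if (!is.null(rule$fusion_pairs)) {
    for (pair in rule$fusion_pairs) {
      sel <- (fusions$gene_5p == pair[[1]] & fusions$gene_3p == pair[[2]]) |
        (fusions$gene_5p == pair[[2]] & fusions$gene_3p == pair[[1]])
      hits <- c(hits, fusions$sample_id[sel & fusions$frame == "in_frame"])
    }
  }
  if (!is.null(rule$sv_gene)) {
    sel <- fusions$gene_5p == rule$sv_gene | fusions$gene_3p == rule$sv_gene
    hits <- c(hits, fusions$sample_id[sel])
  }
  if (!is.null(rule$mutation)) {
    m <- rule$mutation
    sel <- mutations$gene == m$gene &
      mutations$variant_class %in% unlist(m$classes)
    hits <- c(hits, mutations$sample_id[sel])
  }
  if (!is.null(rule$ase_gene) && nrow(ase_ok) > 0) {
    sel <- ase_ok$gene == rule$ase_gene & ase_ok$ok
    hits <- c(hits, ase_ok$sample_id[sel])
  }
  unique(hits)
}

# per-sample expression-consistency gates for tier-3 categories
consistency_gates <- function(samples, scores) {
  gates <- list(
    amkl = stats::setNames(rep(FALSE, length(samples)), samples),
    hox_any = stats::setNames(rep(FALSE, length(samples)), samples),
    hoxb = stats::setNames(rep(FALSE, length(samples)), samples))
  if (is.null(scores)) return(gates)
  thr <- attr(scores, "thresholds")
  idx <- match(samples, scores$sample_id)
  ok <- !is.na(idx)
  if (!is.null(scores$amkl_score) && !is.null(thr[["amkl_score"]])) {
    gates$amkl[ok] <- scores$amkl_score[idx[ok]] > thr[["amkl_score"]]
  }
  ha <- scores$hoxa_score[idx[ok]] > thr[["hoxa_score"]]
  hb <- scores$hoxb_score[idx[ok]] > thr[["hoxb_score"]]
  gates$hox_any[ok] <- ha | hb
  gates$hoxb[ok] <- !is.na(scores$hox_call[idx[ok]]) &
    scores$hox_call[idx[ok]] == "HOXB_like"
  lapply(gates, function(g) {g[is.na(g)] <- FALSE; g})
}

# Unclassified reason for samples with no firing rule
unclassified_reasons <- function(samples, fusions, mutations, cnvs, ruleset) {
  rare_fus <- ruleset$rare_drivers$fusions
  rare_hit <- character()
  for (pair in rare_fus) {
    sel <- (fusions$gene_5p == pair[[1]] & fusions$gene_3p == pair[[2]]) |
      (fusions$gene_5p == pair[[2]] & fusions$gene_3p == pair[[1]])
    rare_hit <- c(rare_hit, fusions$sample_id[sel])
  }
  rare_hit <- c(rare_hit, mutations$sample_id[
    mutations$gene %in% unlist(ruleset$rare_drivers$mutations)])
  has_lesion <- unique(c(fusions$sample_id, mutations$sample_id,
                         cnvs$sample_id))
  ifelse(samples %in% rare_hit, "rare_recurrent_alteration",
         ifelse(samples %in% has_lesion, "non_defining_alterations_only",
                "no_pathogenic_alteration"))
}

# core engine shared by classify_cohort() and assign_category()
classify_tables <- function(samples, fusions, mutations, cnvs, ase_ok,
                            scores, ruleset) {
  order_names <- ruleset_categories(ruleset)
  rules <- ruleset$categories[order_names]
  tiers <- vapply(rules, `[[`, 0, "tier")
  matched <- matrix(FALSE, length(samples), length(rules),
                    dimnames = list(samples, order_names))
  for (nm in order_names) {
    hit <- rule_matched_samples(rules[[nm]], fusions, mutations, ase_ok)
    matched[samples %in% hit, nm] <- TRUE
  }
  gates <- consistency_gates(samples, scores)
  # tier-3 categories only fire with a consistent expression signature
  for (nm in order_names[tiers == 3]) {
    gate <- gates[[rules[[nm]]$expression_consistency]]
    matched[, nm] <- matched[, nm] & gate[samples]
  }
  category <- rep("Unclassified", length(samples))
  rule_fired <- rep(NA_character_, length(samples))
  trace <- character(length(samples))
  for (i in seq_along(samples)) {
    fired_idx <- NA_integer_
    for (tier in 1:3) {
      in_tier <- which(tiers == tier)
      f <- in_tier[matched[i, in_tier]]
      if (length(f) > 1) {
        stop(sprintf(
          "sample %s: categories %s both fire in tier %d (ruleset defect or conflicting defining lesions)",
          samples[i], paste(order_names[f], collapse = " and "), tier),
          call. = FALSE)
      }
      if (length(f) == 1) { fired_idx <- f; break }
    }
    if (!is.na(fired_idx)) {
      category[i] <- order_names[fired_idx]
      rule_fired[i] <- order_names[fired_idx]
      trace[i] <- paste(order_names[seq_len(fired_idx)], collapse = ";")
    } else {
      trace[i] <- paste(order_names, collapse = ";")
    }
  }
  reason <- rep(NA_character_, length(samples))
  uncl <- category == "Unclassified"
  if (any(uncl)) {
    reason[uncl] <- unclassified_reasons(samples[uncl], fusions, mutations,
                                         cnvs, ruleset)
  }
  data.frame(sample_id = samples, category = category,
             superfamily = assign_superfamily(category, ruleset),
             rule_fired = rule_fired, trace = trace,
             unclassified_reason = reason, stringsAsFactors = FALSE)
}

#' Assign a molecular category to one sample
#'
#' Pure function of the sample's lesions, its signature scores, its ASE
#' results, and the ruleset: the first rule (by tier precedence) whose
#' trigger fires wins; tier-3 rules require a consistent expression
#' signature and no prior driver; samples with no firing rule are
#' Unclassified with a reason.
#'
#' @param lesions a lesion set (see [lesion_set()]): list with `sample_id`
#'   and per-sample `fusions`, `mutations` (already filtered to kept
#'   pathogenic calls), `cnvs` tables.
#' @param scores optional one-row signature-score data frame (with a
#'   `"thresholds"` attribute) for this sample.
#' @param ase optional ASE result table for this sample (columns `gene`,
#'   `ase_supported`, and logical `outlier`).
#' @param ruleset a `paml_ruleset`.
#' @return one-row data frame: `sample_id`, `category`, `superfamily`,
#'   `rule_fired`, `trace`, `unclassified_reason`.
#' @export
assign_category <- function(lesions, scores = NULL, ase = NULL,
                            ruleset = default_ruleset()) {
  ase_ok <- if (is.null(ase) || nrow(ase) == 0) {
    data.frame(sample_id = character(), gene = character(), ok = logical())
  } else {
    data.frame(sample_id = lesions$sample_id, gene = ase$gene,
               ok = !is.na(ase$ase_supported) & ase$ase_supported &
                 !is.na(ase$outlier) & ase$outlier)
  }
  classify_tables(lesions$sample_id, lesions$fusions, lesions$mutations,
                  lesions$cnvs, ase_ok, scores, ruleset)
}

#' Classify every sample of a cohort
#'
#' Full pipeline: RNA post-filters on the mutation table (support, VAF,
#' cohort recurrence), expression summarization and signature scoring when a
#' count matrix is present, paired-mode ASE scoring, then precedence-ordered
#' category assignment, superfamily, and Unclassified characterization.
#'
#' @param cohort a `paml_cohort`.
#' @param ruleset a `paml_ruleset`.
#' @param alpha ASE significance threshold on the median binomial p.
#' @param outlier_z z-score cutoff for outlier expression of ASE-defined
#'   genes.
#' @param whitelist hotspot genes exempt from cohort-recurrence flagging.
#' @return data frame of category calls (one row per sample) with attributes
#'   `"thresholds"` (signature thresholds used), `"ase"` (ASE table), and
#'   `"kept_mutations"` (post-filter pathogenic mutation table).
#' @export
classify_cohort <- function(cohort, ruleset = default_ruleset(),
                            alpha = 0.05, outlier_z = 2.5,
                            whitelist = paml_hotspot_whitelist()) {
  stopifnot(inherits(cohort, "paml_cohort"))
  samples <- cohort$samples
  kept <- kept_pathogenic_mutations(cohort$mutations, length(samples),
                                    whitelist = whitelist)
  scores <- NULL
  outliers <- NULL
  if (!is.null(cohort$counts)) {
    lm <- log2cpm(expressed_gene_filter(cohort$counts))
    scores <- hox_signature_scores(lm)
    outliers <- expression_outliers(lm, z_cutoff = outlier_z)
  }
  ase_tab <- ase_score_cohort(cohort$ase_markers, alpha = alpha)
  if (nrow(ase_tab) > 0) {
    out <- rep(FALSE, nrow(ase_tab))
    if (!is.null(outliers)) {
      idx <- cbind(match(ase_tab$sample_id, rownames(outliers)),
                   match(ase_tab$gene, colnames(outliers)))
      hit <- !is.na(idx[, 1]) & !is.na(idx[, 2])
      out[hit] <- outliers[idx[hit, , drop = FALSE]]
    }
    ase_ok <- data.frame(sample_id = ase_tab$sample_id, gene = ase_tab$gene,
                         ok = !is.na(ase_tab$ase_supported) &
                           ase_tab$ase_supported & out)
  } else {
    ase_ok <- data.frame(sample_id = character(), gene = character(),
                         ok = logical())
  }
  calls <- classify_tables(samples, cohort$fusions, kept, cohort$cnvs,
                           ase_ok, scores, ruleset)
  attr(calls, "thresholds") <- if (is.null(scores)) NULL else attr(scores, "thresholds")
  attr(calls, "ase") <- ase_tab
  attr(calls, "kept_mutations") <- kept
  calls
}

#' Cohort coverage of the defined categories
#'
#' @param calls category-call data frame.
#' @return list: `coverage` (fraction of samples with a defined,
#'   non-Unclassified category), `n`, and a per-category `counts` table.
#' @export
cohort_coverage <- function(calls) {
  if (nrow(calls) == 0) stop("no calls", call. = FALSE)
  counts <- table(calls$category)
  list(coverage = mean(calls$category != "Unclassified"), n = nrow(calls),
       counts = counts)
}

#' Partition Unclassified samples by reason
#'
#' Labels each Unclassified sample as carrying a rare recurrent driver (from
#' the ruleset's rare-driver list), only non-defining pathogenic alterations,
#' or no pathogenic alteration at all.
#'
#' @param cohort a `paml_cohort`.
#' @param calls category-call data frame for the cohort.
#' @param ruleset a `paml_ruleset`.
#' @return data frame `sample_id`, `reason` for the Unclassified samples.
#' @export
characterize_unclassified <- function(cohort, calls,
                                      ruleset = default_ruleset()) {
  uncl <- calls$sample_id[calls$category == "Unclassified"]
  kept <- attr(calls, "kept_mutations")
  if (is.null(kept)) {
    kept <- kept_pathogenic_mutations(cohort$mutations,
                                      length(cohort$samples))
  }
  data.frame(sample_id = uncl,
             reason = unclassified_reasons(uncl, cohort$fusions, kept,
                                           cohort$cnvs, ruleset),
             stringsAsFactors = FALSE)
}
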