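# Pairwise co-occurrence / mutual-exclusivity statistics for binary lesion
# features: exact two-sided Fisher tests with Benjamini-Hochberg adjustment,
# the statistic behind the category-by-mutation association matrices.

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Two-sided p-value by probability-mass ordering: the sum of hypergeometric
#' probabilities over all tables (with the observed margins) whose
#' probability does not exceed the observed table's (with the usual relative
#' slack against floating-point ties). The odds ratio is the sample odds
#' ratio (a*d)/(b*c), `Inf` when b*c = 0 and a*d > 0, and `NaN` for a
#' degenerate 0/0.
#'
#' @param a,b,c,d cell counts: `a` = both features present, `b` = first
#'   only, `c` = second only, `d` = neither. Alternatively pass a 2x2
#'   matrix as `a`.
#' @return list with `p` and `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) { b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1] }
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0)) stop("invalid 2x2 table")
  if (sum(counts) == 0) stop("all-zero 2x2 table", call. = FALSE)
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0L, k - n); hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c)
  list(p = p, odds_ratio = or)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, mapped back to the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Binary lesion-feature matrix for association testing
#'
#' One column per gene (TRUE when the sample carries at least one kept
#' pathogenic call in that gene); FLT3 is split into separate `FLT3-ITD`,
#' `FLT3-TKD`, and `FLT3-other` features, since ITD, TKD and non-TKD
#' mutations distribute differently across categories and are tested
#' separately.
#'
#' @param mutations kept pathogenic mutation table (e.g. from
#'   [kept_pathogenic_mutations()]).
#' @param samples sample universe (matrix rows).
#' @param genes genes to include; default all genes present.
#' @param split_flt3 split FLT3 by variant class (default TRUE).
#' @return logical samples x features matrix.
#' @export
feature_matrix <- function(mutations, samples, genes = NULL,
                           split_flt3 = TRUE) {
  mutations <- as.data.frame(mutations)
  feat <- mutations$gene
  if (split_flt3) {
    is_f <- mutations$gene == "FLT3"
    feat[is_f] <- ifelse(mutations$variant_class[is_f] == "itd", "FLT3-ITD",
                         ifelse(mutations$variant_class[is_f] == "tkd",
                                "FLT3-TKD", "FLT3-other"))
  }
  if (is.null(genes)) {
    cols <- sort(unique(feat))
  } else {
    cols <- genes
    if (split_flt3 && "FLT3" %in% cols) {
      cols <- c(setdiff(cols, "FLT3"), "FLT3-ITD", "FLT3-TKD", "FLT3-other")
    }
  }
  m <- matrix(FALSE, length(samples), length(cols),
              dimnames = list(samples, cols))
  sel <- feat %in% cols & mutations$sample_id %in% samples
  m[cbind(match(mutations$sample_id[sel], samples),
          match(feat[sel], cols))] <- TRUE
  m
}

#' Pairwise co-occurrence / exclusivity association matrix
#'
#' Runs the exact Fisher test on every unordered pair of binary features,
#' adjusts across pairs by Benjamini-Hochberg, and reports the direction
#' (odds ratio > 1 co-occurring, < 1 exclusive) with significance flags at
#' p < 0.05 and q < 0.05. A pair with a zero margin (e.g. a constant
#' feature) is reported with p = 1 and direction `none` so the matrix shape
#' is stable.
#'
#' @param features logical samples x features matrix (>= 2 features).
#' @return data frame with one row per pair: `feature1`, `feature2`, `a`
#'   (joint count), `odds_ratio`, `p`, `q`, `direction`, `sig_p`, `sig_q`.
#' @export
exclusivity_matrix <- function(features) {
  features <- as.matrix(features)
  if (ncol(features) < 2) stop("need >= 2 features", call. = FALSE)
  nm <- colnames(features)
  pairs <- utils::combn(ncol(features), 2)
  rows <- apply(pairs, 2, function(ij) {
    x <- features[, ij[1]]; y <- features[, ij[2]]
    a <- sum(x & y); b <- sum(x & !y); cc <- sum(!x & y); d <- sum(!x & !y)
    degenerate <- (a + b == 0) || (cc + d == 0) || (a + cc == 0) || (b + d == 0)
    if (degenerate) {
      res <- list(p = 1, odds_ratio = NA_real_)
    } else {
      res <- fisher_exact_2x2(a, b, cc, d)
    }
    data.frame(feature1 = nm[ij[1]], feature2 = nm[ij[2]], a = a,
               odds_ratio = res$odds_ratio, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$direction <- ifelse(is.na(out$odds_ratio) | out$odds_ratio == 1, "none",
                          ifelse(out$odds_ratio > 1, "co_occurring",
                                 "exclusive"))
  out$direction[out$p >= 1] <- ifelse(
    is.na(out$odds_ratio[out$p >= 1]), "none", out$direction[out$p >= 1])
  out$sig_p <- out$p < 0.05
  out$sig_q <- out$q < 0.05
  rownames(out) <- NULL
  out
}
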