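# Expression summarization and signature scoring. The expression arm of
# classification needs only summary scores: mean log2 CPM over the HOXA and
# HOXB cluster gene sets (superfamily calls), a megakaryoblastic/erythroid
# (AMKL) marker set and an immature/stem set (tier-3 consistency gates), and
# per-gene outlier z-scores for the ASE-defined categories.

#' Expressed-gene filter
#'
#' A gene is considered expressed when its counts-per-million reach
#' `min_cpm` (default 10) in at least `min_samples` (default 5) samples. For
#' cohorts smaller than `min_samples` the required count scales down to the
#' cohort size (logged via message).
#'
#' @param counts non-negative gene x sample count matrix.
#' @return the filtered matrix.
#' @export
expressed_gene_filter <- function(counts, min_cpm = 10, min_samples = 5) {
  if (is.null(dim(counts)) || ncol(counts) < 1 || nrow(counts) < 1) {
    stop("counts must be a non-empty gene x sample matrix", call. = FALSE)
  }
  need <- min(min_samples, ncol(counts))
  if (need < min_samples) {
    message(sprintf("expressed_gene_filter: cohort has %d samples; requiring CPM >= %g in all %d",
                    ncol(counts), min_cpm, need))
  }
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size", call. = FALSE)
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= need
  counts[keep, , drop = FALSE]
}

#' Log2 counts-per-million with zero floor
#'
#' value = log2(1e6 * count / library_size + 0.5), then floored at 0
#' (negative log2 CPM carries no signal at these depths and is set to 0).
#' The 0.5 pseudo-count matches the common variance-stabilizing convention.
#'
#' @param counts gene x sample count matrix with positive library sizes.
#' @param prior pseudo-count added to CPM before the log (default 0.5).
#' @param floor_zero floor negative values at 0 (default TRUE).
#' @return numeric matrix of the same shape.
#' @export
log2cpm <- function(counts, prior = 0.5, floor_zero = TRUE) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size", call. = FALSE)
  x <- log2(sweep(counts, 2, lib, "/") * 1e6 + prior)
  if (floor_zero) x[x < 0] <- 0
  x
}

#' Top variable genes
#'
#' Ranks genes by the variance of their (log) expression values, breaking
#' ties by symbol order, and returns the top `k`. A deterministic,
#' directly checkable stand-in for loess-fit variance standardization with
#' the same intent: rank genes by variability.
#'
#' @param logmat numeric gene x sample matrix (e.g. from [log2cpm()]).
#' @param k number of genes to return (default 320).
#' @return character vector of `k` gene names, most variable first.
#' @export
top_variable_genes <- function(logmat, k = 320) {
  if (k > nrow(logmat)) {
    stop(sprintf("k = %d exceeds the %d available genes", k, nrow(logmat)),
         call. = FALSE)
  }
  v <- apply(logmat, 1, stats::var)
  ord <- order(-v, rownames(logmat))
  rownames(logmat)[ord][seq_len(k)]
}

#' Packaged signature gene sets
#'
#' HOXA / HOXB cluster genes used for superfamily scoring, plus
#' megakaryoblastic (AMKL) and immature/stem marker sets used as tier-3
#' expression-consistency gates.
#'
#' @return named list of character vectors.
#' @export
paml_signature_sets <- function() {
  list(
    HOXA = c("HOXA3", "HOXA5", "HOXA7", "HOXA9", "HOXA10", "HOXA11"),
    HOXB = c("HOXB2", "HOXB3", "HOXB4", "HOXB5", "HOXB6", "HOXB8", "HOXB9"),
    AMKL = c("ITGA2B", "GP1BA", "GP9", "PF4", "VWF"),
    immature = c("CD34", "CD7", "BAALC", "MN1"))
}

#' Mean-expression signature scores per sample
#'
#' Each score is the mean log2 CPM over the genes of one set that are present
#' in the matrix; a set with no genes present yields `NA` with a warning.
#'
#' @param logmat log2 CPM matrix (genes x samples).
#' @param sets named list of gene sets (default [paml_signature_sets()]).
#' @return data frame: `sample_id` plus one `<set>_score` column per set.
#' @export
score_signatures <- function(logmat, sets = paml_signature_sets()) {
  out <- data.frame(sample_id = colnames(logmat), stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    genes <- intersect(sets[[nm]], rownames(logmat))
    if (length(genes) == 0) {
      warning(sprintf("no genes of set '%s' present in the matrix", nm),
              call. = FALSE)
      out[[paste0(tolower(nm), "_score")]] <- NA_real_
    } else {
      out[[paste0(tolower(nm), "_score")]] <-
        colMeans(logmat[genes, , drop = FALSE])
    }
  }
  out
}

# Two-means threshold: midpoint between the two cluster centers of a score
# vector, deterministic via extreme-value initialization. Degenerate vectors
# (no spread) yield +Inf so that nothing is called high.
twomeans_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) return(Inf)
  km <- stats::kmeans(x, centers = matrix(c(min(x), max(x))))
  mean(km$centers)
}

#' Data-derived thresholds for signature scores
#'
#' For each score column, fits 2-means on the cohort's values and returns the
#' midpoint between the two centers. Recorded alongside calls for
#' reproducibility.
#'
#' @param scores data frame from [score_signatures()].
#' @return named numeric vector of thresholds (one per `*_score` column).
#' @export
signature_thresholds <- function(scores) {
  cols <- grep("_score$", names(scores), value = TRUE)
  vapply(cols, function(cl) twomeans_threshold(scores[[cl]]), 0)
}

#' HOX superfamily signature call per sample
#'
#' Scores samples on the HOXA and HOXB cluster sets and calls
#' `HOXB_like` when both scores exceed their thresholds (combined HOXA+HOXB
#' expression), `HOXA_like` when only the HOXA score does (HOXA-high,
#' HOXB-low), and `neither` otherwise. The call depends only on genes in
#' the two sets.
#'
#' @param logmat log2 CPM matrix.
#' @param sets gene-set list with elements `HOXA` and `HOXB` (further sets
#'   are scored and carried along).
#' @param thresholds optional named thresholds (`hoxa_score`, `hoxb_score`,
#'   ...); derived from the cohort by [signature_thresholds()] when `NULL`.
#' @return data frame of scores plus `hox_call`; thresholds attached as
#'   attribute `"thresholds"`.
#' @export
hox_signature_scores <- function(logmat, sets = paml_signature_sets(),
                                 thresholds = NULL) {
  scores <- score_signatures(logmat, sets)
  if (is.null(thresholds)) thresholds <- signature_thresholds(scores)
  ha <- scores$hoxa_score > thresholds[["hoxa_score"]]
  hb <- scores$hoxb_score > thresholds[["hoxb_score"]]
  ha[is.na(ha)] <- FALSE; hb[is.na(hb)] <- FALSE
  scores$hox_call <- ifelse(ha & hb, "HOXB_like",
                            ifelse(ha, "HOXA_like", "neither"))
  attr(scores, "thresholds") <- thresholds
  scores
}

#' Per-gene outlier expression flags
#'
#' Flags samples whose log2 CPM for a gene exceeds the cohort mean by more
#' than `z_cutoff` standard deviations; used for the outlier-expression arm
#' of the ASE-defined categories.
#'
#' @param logmat log2 CPM matrix.
#' @param genes genes to screen (absent genes yield all-FALSE columns).
#' @param z_cutoff z-score cutoff (default 2.5).
#' @return logical samples x genes matrix.
#' @export
expression_outliers <- function(logmat, genes = c("MECOM", "BCL11B", "MNX1"),
                                z_cutoff = 2.5) {
  out <- matrix(FALSE, ncol(logmat), length(genes),
                dimnames = list(colnames(logmat), genes))
  for (g in intersect(genes, rownames(logmat))) {
    x <- logmat[g, ]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) next
    out[, g] <- (x - mean(x)) / s > z_cutoff
  }
  out
}
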