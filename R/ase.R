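# Allele-specific expression (ASE) scoring for enhancer-hijacking-driven
# categories (MECOM, BCL11B, MNX1). Paired mode tests RNA allelic imbalance
# at DNA-heterozygous SNP markers with an exact binomial test; RNA-only mode
# falls back to a coverage/imbalance rule.

#' Exact two-sided binomial test p-value at p = 0.5
#'
#' Two-sidedness by probability-mass ordering: the p-value is the sum of
#' P(X = j) over all outcomes j whose probability does not exceed that of
#' the observed k (with a small relative slack against floating-point ties,
#' the usual exact-test convention). Symmetric in k and n - k.
#'
#' @param k observed successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @return p-value in (0, 1].
#' @export
binomial_two_sided <- function(k, n) {
  if (length(k) != 1 || length(n) != 1) stop("k and n must be scalars")
  if (is.na(k) || is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must be in [0, n]", call. = FALSE)
  d <- stats::dbinom(0:n, n, 0.5)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

#' Select heterozygous SNP markers eligible for paired ASE testing
#'
#' A marker is eligible when the DNA evidence shows a heterozygous site
#' (coverage >= `min_dna_cov`, DNA VAF in [0.2, 0.8]) that is also observed
#' in the RNA (RNA coverage >= 1).
#'
#' @param markers ASE marker table (see [paml_cohort()]).
#' @param min_dna_cov minimum DNA coverage (default 10).
#' @return the eligible subset (possibly empty).
#' @export
select_het_markers <- function(markers, min_dna_cov = 10) {
  markers <- as.data.frame(markers)
  if (nrow(markers) == 0) return(markers)
  dna_cov <- markers$dna_ref + markers$dna_alt
  dna_vaf <- ifelse(dna_cov > 0, markers$dna_alt / dna_cov, NA_real_)
  rna_cov <- markers$rna_ref + markers$rna_alt
  keep <- !is.na(dna_cov) & dna_cov >= min_dna_cov &
    !is.na(dna_vaf) & dna_vaf >= 0.2 & dna_vaf <= 0.8 & rna_cov >= 1
  markers[keep, , drop = FALSE]
}

#' Paired-mode ASE score for one sample and gene
#'
#' Runs the exact binomial test on each eligible marker's RNA allele counts
#' and summarizes by the median p-value (midpoint-of-two convention for even
#' marker counts). ASE is called supported when the median p falls below
#' `alpha`. With zero eligible markers the result carries
#' `ase_supported = NA`.
#'
#' @param markers eligible markers for one (sample, gene), e.g. from
#'   [select_het_markers()].
#' @param alpha significance threshold on the median p (default 0.05); the
#'   threshold used is recorded in the result.
#' @return list with `mode`, `markers_used`, `per_marker_p`, `median_p`,
#'   `ase_supported`, `alpha`.
#' @export
ase_score_paired <- function(markers, alpha = 0.05) {
  markers <- as.data.frame(markers)
  if (nrow(markers) == 0) {
    return(list(mode = "paired", markers_used = 0L,
                per_marker_p = numeric(), median_p = NA_real_,
                ase_supported = NA, alpha = alpha))
  }
  p <- vapply(seq_len(nrow(markers)), function(i) {
    binomial_two_sided(markers$rna_alt[i],
                       markers$rna_ref[i] + markers$rna_alt[i])
  }, 0)
  med <- stats::median(p)
  list(mode = "paired", markers_used = nrow(markers), per_marker_p = p,
       median_p = med, ase_supported = med < alpha, alpha = alpha)
}

#' RNA-only ASE support rule
#'
#' Without DNA genotypes, ASE is supported when at least one marker has RNA
#' coverage >= `min_rna_cov` and an RNA VAF of at most 0.2 or at least 0.8
#' (allelic imbalance).
#'
#' @param markers marker table for one (sample, gene).
#' @param min_rna_cov minimum RNA coverage (default 10).
#' @return list with `mode`, `markers_used`, `ase_supported`.
#' @export
ase_score_rna_only <- function(markers, min_rna_cov = 10) {
  markers <- as.data.frame(markers)
  if (nrow(markers) == 0) {
    return(list(mode = "rna_only", markers_used = 0L, ase_supported = NA))
  }
  cov <- markers$rna_ref + markers$rna_alt
  vaf <- ifelse(cov > 0, markers$rna_alt / cov, NA_real_)
  hit <- !is.na(vaf) & cov >= min_rna_cov & (vaf <= 0.2 | vaf >= 0.8)
  list(mode = "rna_only", markers_used = nrow(markers),
       ase_supported = any(hit))
}

#' Score ASE for every (sample, gene) pair in a cohort
#'
#' @param ase_markers cohort ASE marker table.
#' @param genes genes to score (default the three ASE-defined category
#'   genes).
#' @param mode `"paired"` (binomial test on DNA-het markers) or
#'   `"rna_only"`.
#' @param alpha paired-mode significance threshold on the median p.
#' @return data frame with one row per (sample, gene) having any markers:
#'   `sample_id`, `gene`, `mode`, `markers_used`, `median_p`,
#'   `ase_supported`.
#' @export
ase_score_cohort <- function(ase_markers, genes = c("MECOM", "BCL11B", "MNX1"),
                             mode = c("paired", "rna_only"), alpha = 0.05) {
  mode <- match.arg(mode)
  ase_markers <- as.data.frame(ase_markers)
  ase_markers <- ase_markers[ase_markers$gene %in% genes, , drop = FALSE]
  if (nrow(ase_markers) == 0) {
    return(data.frame(sample_id = character(), gene = character(),
                      mode = character(), markers_used = integer(),
                      median_p = numeric(), ase_supported = logical(),
                      stringsAsFactors = FALSE))
  }
  groups <- split(ase_markers,
                  list(ase_markers$sample_id, ase_markers$gene), drop = TRUE)
  rows <- lapply(groups, function(g) {
    if (mode == "paired") {
      res <- ase_score_paired(select_het_markers(g), alpha = alpha)
    } else {
      res <- ase_score_rna_only(g)
      res$median_p <- NA_real_
    }
    data.frame(sample_id = g$sample_id[1], gene = g$gene[1], mode = res$mode,
               markers_used = res$markers_used,
               median_p = if (is.null(res$median_p)) NA_real_ else res$median_p,
               ase_supported = res$ase_supported, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$gene), , drop = FALSE]
}
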