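# Post-filters for RNA-based somatic variant calls, cohort-recurrence artifact
# flagging, and mechanical germline-candidate criteria. All boundary
# comparisons are inclusive exactly as printed in the source thresholds:
# supporting reads <= 5 fails, VAF <= 5% fails, population AF <= 0.001 passes.

#' RNA-seq somatic variant support filters
#'
#' Removes a variant when its alt-allele read support is <= `min_alt_reads`
#' (default 5) or its variant allele fraction is <= `min_vaf` (default 0.05).
#' "Supporting reads" means reads carrying the alternative allele.
#'
#' @param mutations mutation table (see [paml_cohort()]); `alt_reads` and
#'   `vaf` must be populated -- a row missing both is an error.
#' @param min_alt_reads alt-read threshold; a variant at the threshold fails.
#' @param min_vaf VAF threshold; a variant at the threshold fails.
#' @return data frame of filter decisions: one row per variant with `kept`
#'   and semicolon-separated `reasons` (`read_support`, `vaf`) for removed
#'   variants.
#' @export
filter_rna_variants <- function(mutations, min_alt_reads = 5, min_vaf = 0.05) {
  mutations <- as.data.frame(mutations)
  if (nrow(mutations) == 0) {
    return(cbind(mutations, kept = logical(), reasons = character()))
  }
  no_vaf <- is.na(mutations$vaf)
  no_reads <- is.na(mutations$alt_reads)
  if (any(no_vaf & no_reads)) {
    stop(sprintf("%d variant(s) with neither VAF nor read counts",
                 sum(no_vaf & no_reads)), call. = FALSE)
  }
  vaf <- ifelse(no_vaf, mutations$alt_reads / mutations$total_reads,
                mutations$vaf)
  fail_reads <- !no_reads & mutations$alt_reads <= min_alt_reads
  fail_vaf <- vaf <= min_vaf
  reasons <- character(nrow(mutations))
  reasons[fail_reads] <- "read_support"
  reasons[fail_vaf] <- ifelse(nzchar(reasons[fail_vaf]), "read_support;vaf",
                              "vaf")
  out <- mutations
  out$kept <- !(fail_reads | fail_vaf)
  out$reasons <- reasons
  out
}

#' Default hotspot/defining-gene whitelist for recurrence flagging
#'
#' Genes whose recurrent identical variants are genuine hotspots rather than
#' artifacts (RAS/FLT3/KIT hotspots and category-defining mutation genes), so
#' the >5% cohort-recurrence rule does not discard them. Replaceable by the
#' user.
#'
#' @return character vector of gene symbols.
#' @export
paml_hotspot_whitelist <- function() {
  c("NRAS", "KRAS", "PTPN11", "BRAF", "HRAS", "FLT3", "KIT", "WT1", "JAK2",
    "NPM1", "CEBPA", "GATA1", "UBTF", "CBFB", "KMT2A", "MLLT1", "H3F3A")
}

#' Flag cohort-recurrent variants as likely germline or artifacts
#'
#' A variant key (gene + protein change) carried by more than
#' `threshold` (default 5%) of cohort cases is flagged; flagged variants are
#' excluded from pathogenic sets downstream but retained in logs. Genes on
#' the whitelist are exempt (recurrent hotspots are expected).
#'
#' @param mutations mutation table.
#' @param n_cases cohort size (> 0).
#' @param threshold recurrence fraction; strictly greater-than comparison.
#' @param whitelist genes exempt from flagging; `character(0)` disables.
#' @return the mutation table with logical column `recurrent_flag`.
#' @export
flag_cohort_recurrent <- function(mutations, n_cases, threshold = 0.05,
                                  whitelist = paml_hotspot_whitelist()) {
  if (n_cases <= 0) stop("n_cases must be positive", call. = FALSE)
  mutations <- as.data.frame(mutations)
  key <- paste(mutations$gene, mutations$protein_change, sep = "|")
  carriers <- tapply(mutations$sample_id, key,
                     function(s) length(unique(s)))
  flagged_keys <- names(carriers)[carriers / n_cases > threshold]
  flag <- key %in% flagged_keys & !(mutations$gene %in% whitelist)
  mutations$recurrent_flag <- flag
  mutations
}

#' Kept pathogenic mutations after both RNA post-filters
#'
#' Convenience pipeline step: applies [filter_rna_variants()] and
#' [flag_cohort_recurrent()], then keeps pathogenic / likely pathogenic
#' calls only.
#'
#' @inheritParams flag_cohort_recurrent
#' @param panel optional gene vector; when given, calls outside the panel are
#'   dropped (RNA-only mode restricts calling to a preselected panel).
#' @return filtered mutation table.
#' @export
kept_pathogenic_mutations <- function(mutations, n_cases,
                                      whitelist = paml_hotspot_whitelist(),
                                      panel = NULL) {
  if (nrow(mutations) == 0) return(mutations)
  dec <- filter_rna_variants(mutations)
  dec <- flag_cohort_recurrent(dec, n_cases, whitelist = whitelist)
  keep <- dec$kept & !dec$recurrent_flag &
    dec$pathogenicity %in% c("pathogenic", "likely_pathogenic")
  if (!is.null(panel)) keep <- keep & dec$gene %in% panel
  out <- dec[keep, , drop = FALSE]
  out$kept <- NULL; out$reasons <- NULL; out$recurrent_flag <- NULL
  rownames(out) <- NULL
  out
}

#' Default RNA-only calling panel
#'
#' Genes to which mutation calling is restricted when only RNA-seq is
#' available: category-defining mutation genes plus recurrently mutated
#' cooperating genes. User-replaceable.
#'
#' @return character vector of gene symbols.
#' @export
paml_panel_genes <- function() {
  unique(c("NPM1", "CEBPA", "UBTF", "CBFB", "KMT2A", "GATA1", "MLLT1",
           "H3F3A", "JAK2", "FLT3", "KIT", "WT1", "ETV6", "RUNX1", "TP53",
           paml_ras_genes(),
           c("GATA2", "EZH2", "TET2", "ASXL1", "RAD21", "SETD2", "BCOR",
             "PHF6", "SMC1A", "STAG2", "SMC3", "CTCF", "IKZF1", "SETD1A",
             "DNMT3A", "IDH1", "IDH2", "SRSF2", "SF3B1", "U2AF1", "ZRSR2",
             "EED", "SUZ12", "KDM6A", "CREBBP", "EP300", "MGA", "MYC",
             "SPI1", "ERG", "CSF3R", "JAK1", "JAK3", "MPL", "SH2B3",
             "KDM5A", "PHF23", "NSD1", "DDX41", "SAMD9", "SAMD9L",
             "ANKRD26", "TERC", "TERT", "GATA3", "PAX5", "IKZF2", "IKZF3",
             "ZEB2", "MYB", "CDK6", "MECOM", "BCL11B", "MNX1", "PRDM16",
             "NKX2-3", "CD96", "LZTR1", "RIT1", "SOS1", "DHX15", "RAD50",
             "ATM", "ATR", "BRCA2", "CHEK2", "FANCA")))
}

#' Mechanical germline-candidate criteria
#'
#' Applies the mechanical curation thresholds to pre-annotated germline
#' candidates: population allele frequency <= 0.001; for SNVs coverage >= 20
#' and VAF in [0.2, 0.8]; for indels coverage >= 15 and >= 3 alt reads.
#' ACMG tier classification is out of scope: a pass means "candidate meets
#' the mechanical criteria" only.
#'
#' @param candidates data frame with `variant_type` (`snv`/`indel`),
#'   `population_af`, `coverage`, `vaf`, `alt_reads`.
#' @return the input with logical `pass` and semicolon-separated
#'   `failed_criteria` columns.
#' @export
curate_germline <- function(candidates) {
  candidates <- as.data.frame(candidates)
  if (any(!candidates$variant_type %in% c("snv", "indel"))) {
    stop("unknown variant_type; must be 'snv' or 'indel'", call. = FALSE)
  }
  fail <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    f <- character()
    if (candidates$population_af[i] > 0.001) f <- c(f, "population_af")
    if (candidates$variant_type[i] == "snv") {
      if (candidates$coverage[i] < 20) f <- c(f, "coverage")
      if (is.na(candidates$vaf[i]) || candidates$vaf[i] < 0.2 ||
          candidates$vaf[i] > 0.8) f <- c(f, "vaf")
    } else {
      if (candidates$coverage[i] < 15) f <- c(f, "coverage")
      if (is.na(candidates$alt_reads[i]) || candidates$alt_reads[i] < 3) {
        f <- c(f, "alt_reads")
      }
    }
    fail[[i]] <- f
  }
  candidates$pass <- lengths(fail) == 0
  candidates$failed_criteria <- vapply(fail, paste, "", collapse = ";")
  candidates
}
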