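# Domain vocabulary: lesion-call tables, clinical records, and the cohort
# container shared by every downstream stage. All coordinates are 0-based
# half-open; converters belong at file boundaries.

FRAME_LEVELS <- c("in_frame", "out_of_frame_Cterm_loss", "sv_other")
VARIANT_CLASSES <- c("snv", "indel", "itd", "ptd", "tkd")
PATHOGENICITY_LEVELS <- c("pathogenic", "likely_pathogenic", "vus", "benign",
                          "unannotated")
COPY_STATES <- c("gain", "loss", "cnloh")
CNV_SCOPES <- c("focal", "broad")
FAB_LEVELS <- c(paste0("M", 0:7), "unknown")
EVIDENCE_LEVELS <- c("rna", "wgs")

#' Canonical gene symbols known to the classifier
#'
#' Symbols referenced by the packaged category ruleset, the RAS-pathway and
#' hotspot lists, and the signature gene sets. Used for case-insensitive
#' symbol normalization; unknown symbols pass through untouched and are
#' treated as non-defining.
#'
#' @return Character vector of canonical symbols.
#' @export
paml_gene_symbols <- function() {
  rs <- default_ruleset()
  unique(c(ruleset_genes(rs), paml_ras_genes(), paml_hotspot_whitelist(),
           unlist(paml_signature_sets(), use.names = FALSE)))
}

#' Normalize gene symbols case-insensitively
#'
#' Matches symbols against [paml_gene_symbols()] ignoring case; symbols with
#' no match are returned unchanged.
#'
#' @param x character vector of gene symbols.
#' @param table canonical symbols to match against.
#' @return character vector of the same length.
#' @export
normalize_gene_symbols <- function(x, table = paml_gene_symbols()) {
  idx <- match(toupper(x), toupper(table))
  out <- x
  out[!is.na(idx)] <- table[idx[!is.na(idx)]]
  out
}

#' RAS-pathway gene list
#'
#' Causative genes of Noonan or Noonan-like syndromes, the definition used
#' for RAS-pathway annotation of AML mutation tables.
#'
#' @return Character vector.
#' @export
paml_ras_genes <- function() {
  c("NRAS", "KRAS", "PTPN11", "NF1", "CBL", "LZTR1", "RIT1", "BRAF",
    "SOS1", "HRAS")
}

empty_fusion_table <- function() {
  data.frame(sample_id = character(), gene_5p = character(),
             gene_3p = character(), frame = character(),
             evidence = character(), stringsAsFactors = FALSE)
}

empty_mutation_table <- function() {
  data.frame(sample_id = character(), gene = character(),
             variant_class = character(), protein_change = character(),
             vaf = numeric(), alt_reads = integer(), total_reads = integer(),
             pathogenicity = character(), stringsAsFactors = FALSE)
}

empty_cnv_table <- function() {
  data.frame(sample_id = character(), chrom = character(), start = integer(),
             end = integer(), copy_state = character(), scope = character(),
             stringsAsFactors = FALSE)
}

empty_ase_table <- function() {
  data.frame(sample_id = character(), gene = character(), position = integer(),
             dna_ref = integer(), dna_alt = integer(), rna_ref = integer(),
             rna_alt = integer(), stringsAsFactors = FALSE)
}

empty_clinical_table <- function() {
  data.frame(sample_id = character(), age_years = numeric(), fab = character(),
             timepoint = character(), mrd_positive = logical(),
             os_time = numeric(), os_event = logical(), efs_time = numeric(),
             relapse = logical(), death_in_remission = logical(),
             non_response = logical(), karyotype_complex = logical(),
             monosomy7 = logical(), stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s table is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df[cols]
}

# Row-level invariant checks. Each validator returns list(kept=, log=) where
# log is a character vector describing dropped rows.
validate_fusions <- function(df) {
  df <- require_columns(df, names(empty_fusion_table()), "fusions")
  bad <- !nzchar(df$gene_5p) | !nzchar(df$gene_3p) | is.na(df$gene_5p) |
    is.na(df$gene_3p) | !(df$frame %in% FRAME_LEVELS) |
    !(df$evidence %in% EVIDENCE_LEVELS)
  log <- if (any(bad)) sprintf("fusions: dropped %d ill-formed row(s)", sum(bad)) else character()
  df$gene_5p <- normalize_gene_symbols(df$gene_5p)
  df$gene_3p <- normalize_gene_symbols(df$gene_3p)
  list(kept = df[!bad, , drop = FALSE], log = log)
}

validate_mutations <- function(df) {
  df <- require_columns(df, names(empty_mutation_table()), "mutations")
  df$vaf <- as.numeric(df$vaf)
  # VAF defaults to alt/total when absent
  no_vaf <- is.na(df$vaf) & !is.na(df$alt_reads) & !is.na(df$total_reads)
  df$vaf[no_vaf] <- df$alt_reads[no_vaf] / df$total_reads[no_vaf]
  bad_counts <- is.na(df$alt_reads) | is.na(df$total_reads) |
    df$alt_reads < 0 | df$total_reads <= 0 | df$alt_reads > df$total_reads
  # consistency within rounding (2 decimals) when both provided
  incons <- !bad_counts & !is.na(df$vaf) &
    abs(df$vaf - df$alt_reads / df$total_reads) > 0.005 + 1e-9
  bad <- bad_counts | incons | is.na(df$vaf) | df$vaf < 0 | df$vaf > 1 |
    !(df$variant_class %in% VARIANT_CLASSES) |
    !(df$pathogenicity %in% PATHOGENICITY_LEVELS)
  log <- character()
  if (any(bad_counts)) log <- c(log, sprintf(
    "mutations: dropped %d row(s) with invalid read counts (e.g. alt_reads > total_reads)",
    sum(bad_counts)))
  if (any(bad & !bad_counts)) log <- c(log, sprintf(
    "mutations: dropped %d row(s) with inconsistent VAF or unknown enum value",
    sum(bad & !bad_counts)))
  df$gene <- normalize_gene_symbols(df$gene)
  list(kept = df[!bad, , drop = FALSE], log = log)
}

validate_cnvs <- function(df) {
  df <- require_columns(df, names(empty_cnv_table()), "cnv")
  bad <- is.na(df$start) | is.na(df$end) | df$start >= df$end |
    !(df$copy_state %in% COPY_STATES) | !(df$scope %in% CNV_SCOPES)
  log <- if (any(bad)) sprintf("cnv: dropped %d ill-formed row(s)", sum(bad)) else character()
  list(kept = df[!bad, , drop = FALSE], log = log)
}

validate_ase_markers <- function(df) {
  df <- require_columns(df, names(empty_ase_table()), "ase_markers")
  cnt <- c("dna_ref", "dna_alt", "rna_ref", "rna_alt")
  neg <- Reduce(`|`, lapply(df[cnt], function(x) !is.na(x) & x < 0))
  no_rna <- is.na(df$rna_ref) | is.na(df$rna_alt)
  bad <- neg | no_rna
  log <- if (any(bad)) sprintf("ase_markers: dropped %d row(s) with negative or missing RNA counts", sum(bad)) else character()
  df$gene <- normalize_gene_symbols(df$gene)
  list(kept = df[!bad, , drop = FALSE], log = log)
}

validate_clinical <- function(df) {
  df <- require_columns(df, names(empty_clinical_table()), "clinical")
  times_bad <- (!is.na(df$os_time) & df$os_time < 0) |
    (!is.na(df$efs_time) & df$efs_time < 0) |
    (!is.na(df$age_years) & df$age_years < 0)
  # at most one of relapse / death in remission / non-response drives EFS
  drivers <- rowSums(cbind(df$relapse, df$death_in_remission,
                           df$non_response), na.rm = TRUE)
  bad <- times_bad | drivers > 1 | !(df$fab %in% FAB_LEVELS)
  log <- if (any(bad)) sprintf("clinical: dropped %d row(s) (negative times, conflicting EFS events, or unknown FAB)", sum(bad)) else character()
  list(kept = df[!bad, , drop = FALSE], log = log)
}

dedupe <- function(df, what) {
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sprintf("%s: deduplicated %d repeated row(s)", what, sum(dup)),
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' Construct a cohort object
#'
#' Bundles the five lesion/clinical tables plus an optional gene-by-sample
#' count matrix into a single validated container. Row-level invariant
#' violations are dropped with a warning and recorded in the parse log;
#' duplicated rows are collapsed. The sample universe is the union of sample
#' ids seen across tables.
#'
#' @param fusions,mutations,cnvs,ase_markers,clinical data frames following
#'   the documented table schemas (see the package vignette).
#' @param counts optional integer matrix, genes x samples.
#' @param truth optional ground-truth data frame (synthetic cohorts).
#' @return An object of class `paml_cohort`: a list with the validated
#'   tables, `samples`, `counts`, `truth`, and a `parse_log` attribute.
#' @export
paml_cohort <- function(fusions = empty_fusion_table(),
                        mutations = empty_mutation_table(),
                        cnvs = empty_cnv_table(),
                        ase_markers = empty_ase_table(),
                        clinical = empty_clinical_table(),
                        counts = NULL, truth = NULL) {
  vf <- validate_fusions(as.data.frame(fusions))
  vm <- validate_mutations(as.data.frame(mutations))
  vc <- validate_cnvs(as.data.frame(cnvs))
  va <- validate_ase_markers(as.data.frame(ase_markers))
  vk <- validate_clinical(as.data.frame(clinical))
  log <- c(vf$log, vm$log, vc$log, va$log, vk$log)
  if (length(log) > 0) warning(paste(log, collapse = "; "), call. = FALSE)
  obj <- list(
    fusions = dedupe(vf$kept, "fusions"),
    mutations = dedupe(vm$kept, "mutations"),
    cnvs = dedupe(vc$kept, "cnv"),
    ase_markers = dedupe(va$kept, "ase_markers"),
    clinical = dedupe(vk$kept, "clinical"),
    counts = counts, truth = truth)
  obj$samples <- sort(unique(c(obj$clinical$sample_id, obj$fusions$sample_id,
                               obj$mutations$sample_id, obj$cnvs$sample_id,
                               obj$ase_markers$sample_id,
                               if (!is.null(counts)) colnames(counts))))
  rownames(obj$fusions) <- NULL; rownames(obj$mutations) <- NULL
  rownames(obj$cnvs) <- NULL; rownames(obj$ase_markers) <- NULL
  rownames(obj$clinical) <- NULL
  attr(obj, "parse_log") <- log
  class(obj) <- "paml_cohort"
  obj
}

#' @export
print.paml_cohort <- function(x, ...) {
  cat(sprintf("paml_cohort: %d samples | %d fusions, %d mutations, %d CNV segments, %d ASE markers\n",
              length(x$samples), nrow(x$fusions), nrow(x$mutations),
              nrow(x$cnvs), nrow(x$ase_markers)))
  if (!is.null(x$counts)) {
    cat(sprintf("  expression: %d genes x %d samples\n", nrow(x$counts),
                ncol(x$counts)))
  }
  invisible(x)
}

#' All lesions called in one sample
#'
#' @param cohort a `paml_cohort`.
#' @param sample_id one sample identifier.
#' @return list with per-sample `fusions`, `mutations`, `cnvs`, `ase_markers`
#'   data frames.
#' @export
lesion_set <- function(cohort, sample_id) {
  stopifnot(inherits(cohort, "paml_cohort"), length(sample_id) == 1)
  list(sample_id = sample_id,
       fusions = cohort$fusions[cohort$fusions$sample_id == sample_id, , drop = FALSE],
       mutations = cohort$mutations[cohort$mutations$sample_id == sample_id, , drop = FALSE],
       cnvs = cohort$cnvs[cohort$cnvs$sample_id == sample_id, , drop = FALSE],
       ase_markers = cohort$ase_markers[cohort$ase_markers$sample_id == sample_id, , drop = FALSE])
}

COHORT_FILES <- c(fusions = "fusions.tsv", mutations = "mutations.tsv",
                  cnvs = "cnv.tsv", ase_markers = "ase_markers.tsv",
                  clinical = "clinical.tsv", counts = "counts.tsv")

read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a cohort from tab-separated tables
#'
#' Reads `fusions.tsv`, `mutations.tsv`, `cnv.tsv`, `ase_markers.tsv`,
#' `clinical.tsv` and optionally `counts.tsv` (gene x sample count matrix,
#' first column `gene`) from a directory, or from explicitly named paths.
#' Missing optional tables yield empty tables; a missing required column is a
#' hard error naming the column. Unknown columns are ignored; ill-formed rows
#' are dropped, logged, and reported with a warning.
#'
#' @param dir directory containing the canonical file names, or `NULL`.
#' @param paths optional named list/vector overriding individual file paths
#'   (`fusions`, `mutations`, `cnvs`, `ase_markers`, `clinical`, `counts`).
#' @return A `paml_cohort`.
#' @export
read_cohort <- function(dir = NULL, paths = list()) {
  get_path <- function(key) {
    if (!is.null(paths[[key]])) return(paths[[key]])
    if (!is.null(dir)) {
      p <- file.path(dir, COHORT_FILES[[key]])
      if (file.exists(p)) return(p)
    }
    NULL
  }
  tabs <- lapply(c("fusions", "mutations", "cnvs", "ase_markers", "clinical"),
                 function(k) {
    p <- get_path(k)
    if (is.null(p)) return(NULL)
    read_tsv_table(p)
  })
  names(tabs) <- c("fusions", "mutations", "cnvs", "ase_markers", "clinical")
  defaults <- list(fusions = empty_fusion_table(),
                   mutations = empty_mutation_table(),
                   cnvs = empty_cnv_table(),
                   ase_markers = empty_ase_table(),
                   clinical = empty_clinical_table())
  for (k in names(defaults)) if (is.null(tabs[[k]])) tabs[[k]] <- defaults[[k]]
  counts <- NULL
  cp <- get_path("counts")
  if (!is.null(cp)) {
    cdf <- read_tsv_table(cp)
    counts <- as.matrix(cdf[, -1, drop = FALSE])
    rownames(counts) <- cdf[[1]]
    storage.mode(counts) <- "double"
  }
  paml_cohort(fusions = tabs$fusions, mutations = tabs$mutations,
              cnvs = tabs$cnvs, ase_markers = tabs$ase_markers,
              clinical = tabs$clinical, counts = counts)
}

canonical_sort <- function(df) {
  if (nrow(df) == 0) return(df)
  df[do.call(order, unname(as.list(df))), , drop = FALSE]
}

write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Write a cohort back to canonical tab-separated tables
#'
#' Rows are sorted canonically so that write/read round trips are
#' byte-identical.
#'
#' @param cohort a `paml_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "paml_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in c("fusions", "mutations", "cnvs", "ase_markers", "clinical")) {
    write_tsv_table(canonical_sort(cohort[[k]]), file.path(dir, COHORT_FILES[[k]]))
  }
  if (!is.null(cohort$counts)) {
    cdf <- data.frame(gene = rownames(cohort$counts), cohort$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_table(cdf, file.path(dir, COHORT_FILES[["counts"]]))
  }
  invisible(dir)
}

CATEGORY_TABLE_COLS <- c("sample_id", "category", "superfamily", "rule_fired",
                         "risk_group", "stratum")

#' Write the per-sample category report
#'
#' Deterministic column order (`sample_id`, `category`, `superfamily`,
#' `rule_fired`, `risk_group`, `stratum`) and rows sorted by sample id. An
#' empty call set produces a header-only file.
#'
#' @param calls data frame of category calls (see [classify_cohort()]); extra
#'   columns are dropped, absent optional columns are written as `NA`.
#' @param path output file.
#' @param cohort optional `paml_cohort`; when given, calls for sample ids not
#'   in the cohort are an error.
#' @return `path`, invisibly.
#' @export
write_category_table <- function(calls, path, cohort = NULL) {
  calls <- as.data.frame(calls)
  if (!is.null(cohort)) {
    unknown <- setdiff(calls$sample_id, cohort$samples)
    if (length(unknown) > 0) {
      stop("category call(s) for unknown sample id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  for (col in CATEGORY_TABLE_COLS) {
    if (is.null(calls[[col]])) calls[[col]] <- rep(NA, nrow(calls))
  }
  out <- calls[order(calls$sample_id), CATEGORY_TABLE_COLS, drop = FALSE]
  write_tsv_table(out, path)
  invisible(path)
}

#' Read back a category report written by [write_category_table()]
#' @param path file path.
#' @return data frame with the canonical report columns.
#' @export
read_category_table <- function(path) {
  read_tsv_table(path)
}

#' Read a gene-by-sample count matrix in MatrixMarket format
#'
#' @param mtx path to the `.mtx` file.
#' @param genes,samples paths to one-column index files (row and column
#'   names, in order).
#' @return dense numeric matrix, genes x samples.
#' @export
read_expression_mtx <- function(mtx, genes, samples) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("reading MatrixMarket files requires the Matrix package")
  }
  m <- as.matrix(Matrix::readMM(mtx))
  rownames(m) <- readLines(genes)
  colnames(m) <- readLines(samples)
  m
}

#' Read mutation calls from a minimal VCF
#'
#' Supports the minimal fields CHROM/POS/REF/ALT plus a per-sample `AD`
#' (allelic depth) FORMAT field; the gene symbol is taken from a `GENE=`
#' INFO key when present. Rows become mutation-table records with VAF and
#' read counts derived from AD; `variant_class` is `snv` for single-base
#' substitutions and `indel` otherwise, and pathogenicity is `unannotated`
#' (annotation is upstream of this package).
#'
#' @param path uncompressed or bgzipped VCF file.
#' @param sample_id sample identifier to assign (single-sample VCF).
#' @return mutation table data frame.
#' @export
read_mutations_vcf <- function(path, sample_id) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF files requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) return(empty_mutation_table())
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  parts <- strsplit(ad, ",", fixed = TRUE)
  ref_n <- as.integer(vapply(parts, `[`, "", 1))
  alt_n <- as.integer(vapply(parts, `[`, "", 2))
  info <- vcfR::extract.info(v, "GENE")
  gene <- ifelse(is.na(info), "unknown", info)
  is_snv <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  data.frame(sample_id = sample_id, gene = normalize_gene_symbols(gene),
             variant_class = ifelse(is_snv, "snv", "indel"),
             protein_change = paste0("g.", fix[, "CHROM"], ":",
                                     fix[, "POS"], fix[, "REF"], ">",
                                     fix[, "ALT"]),
             vaf = round(alt_n / (ref_n + alt_n), 4),
             alt_reads = alt_n, total_reads = ref_n + alt_n,
             pathogenicity = "unannotated", stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read gene sets from a GMT file
#' @param path GMT file (set name, description, then member genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[`, "", 1))
}
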