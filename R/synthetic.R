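# Seeded synthetic-cohort generator. Reproduces the statistical structure
# the analysis assumes -- category prevalences, defining lesions,
# category-conditional cooperating mutations, HOXA/HOXB/AMKL/immature
# signature structure, ASE marker imbalance, MRD, and risk-dependent
# exponential survival -- so that every pipeline stage is testable without
# controlled-access patient data. All randomness flows from the single seed
# passed to generate_cohort(); there is no hidden global state.

#' Load the default generator configuration
#'
#' Reads the packaged `default_cohort.yaml`, whose values are calibrated so
#' that cohort-level expectations match the published frequencies (see the
#' file's comments and the methods vignette).
#'
#' @param path YAML config path (defaults to the packaged file).
#' @return validated config list of class `paml_generator_config`.
#' @export
default_generator_config <- function(path = system.file(
    "extdata", "default_cohort.yaml", package = "pamlcat")) {
  cfg <- yaml::read_yaml(path)
  validate_generator_config(cfg)
  class(cfg) <- "paml_generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  prev <- unlist(cfg$category_prevalence)
  if (any(prev < 0) || any(prev > 1)) stop("prevalences must lie in [0,1]")
  tot <- sum(prev) + cfg$unclassified_fraction
  if (abs(tot - 1) > 1e-9) {
    stop(sprintf("prevalences + unclassified_fraction must sum to 1 (got %.6f)",
                 tot), call. = FALSE)
  }
  if (abs(sum(unlist(cfg$unclassified_split)) - 1) > 1e-6) {
    stop("unclassified_split must sum to 1")
  }
  for (co in cfg$cooperating) {
    pr <- c(co$default, unlist(co$overrides))
    if (any(pr < 0 | pr > 1)) stop("cooperating probabilities must lie in [0,1]")
  }
  if (any(unlist(cfg$hazards) <= 0)) {
    stop("stratum hazards must be strictly positive", call. = FALSE)
  }
  invisible(cfg)
}

# defining-fusion partner repertoires (draw weights)
GEN_PARTNERS <- list(
  "KMT2Ar" = c(MLLT3 = .30, MLLT10 = .25, ELL = .12, MLLT1 = .10,
               AFDN = .08, SEPTIN6 = .05, MLLT6 = .05, EPS15 = .05),
  "NUP98r" = c(NSD1 = .45, KDM5A = .25, HOXA9 = .10, PHF23 = .10,
               DDX10 = .10),
  "KAT6Ar" = c(CREBBP = .80, EP300 = .20),
  "GLISr" = c(CBFA2T3 = .90, PCM1 = .10),
  "APL" = c(PML = .90, TBL1XR1 = .10),
  "MECOM" = c(RPN1 = .70, NRIP1 = .30),
  "BCL11B" = c(CCDC26 = .50, ARID1B = .50),
  "MNX1" = c(ETV6 = .80, CDK6 = .20),
  "HOXr" = c(NIPBL = .60, MYB = .40))

GEN_RARE_FUSIONS <- list(c("RUNX1", "USP42"), c("RUNX1", "EVX1"),
                         c("RUNX1", "ZEB2"), c("MLLT10", "DDX3X"),
                         c("MLLT10", "TEC"), c("MLLT10", "MAP2K2"),
                         c("SET", "NUP214"), c("SFPQ", "ZFP36L2"))

GEN_PROTEIN_CHANGES <- list(
  NRAS = c("p.G12D", "p.G12S", "p.G13D", "p.Q61K", "p.Q61R"),
  KRAS = c("p.G12D", "p.G13D", "p.A146T"),
  PTPN11 = c("p.E76K", "p.A72V", "p.D61Y"),
  NF1 = c("p.R1362*", "p.Q1174fs", "p.R2450*"),
  CBL = c("p.C381R", "p.Y371H"),
  BRAF = c("p.V600E", "p.G469A"),
  FLT3_ITD = "p.ITD(e14)",
  FLT3_TKD = c("p.D835Y", "p.D835V"),
  FLT3_OTHER = c("p.N676K", "p.V592A"),
  WT1 = c("p.S381fs", "p.R462W", "p.A382fs"),
  KIT = c("p.D816V", "p.N822K"),
  NPM1 = c("p.W288Cfs*12", "p.W288Ffs*12", "p.T294_A297del"),
  CEBPA = c("p.H24fs", "p.K313dup"),
  UBTF = "p.E435_K461dup",
  CBFB = "p.N162_G163insGDXY",
  KMT2A_PTD = "p.PTD(e3-e9)",
  GATA1 = c("p.V74fs", "p.L68fs"),
  ETV6 = c("p.R399fs", "p.R105*", "p.W380R"),
  RUNX1 = c("p.R201*", "p.R174Q", "p.S322fs"),
  TP53 = c("p.R248Q", "p.R175H", "p.C176F"),
  MLLT1 = "p.C119>SPAR", H3F3A = "p.K28M", JAK2 = "p.V617F")

GEN_POOL_GENES <- c("GATA2", "EZH2", "TET2", "ASXL1", "RAD21", "SETD2",
                    "BCOR", "PHF6", "SMC1A", "STAG2")

# per-sample probability for one cooperating lesion given generated groups
coop_prob <- function(cfg, key, gen_cat) {
  co <- cfg$cooperating[[key]]
  p <- rep(co$default, length(gen_cat))
  for (nm in names(co$overrides)) p[gen_cat == nm] <- co$overrides[[nm]]
  p[gen_cat == "Unclassified_none"] <- 0   # alteration-free by construction
  p
}

# read-support model for emitted mutations: comfortably clonal so that
# emitted pathogenic calls survive the RNA post-filters
draw_mutation_rows <- function(sample_id, gene, class, changes) {
  m <- length(sample_id)
  if (m == 0) return(empty_mutation_table())
  total <- 50L + stats::rpois(m, 70)
  vaf <- pmin(pmax(stats::rbeta(m, 8, 12), 0.12), 0.90)
  alt <- as.integer(round(vaf * total))
  pc <- if (length(changes) == 1) rep(changes, m) else sample(changes, m, TRUE)
  data.frame(sample_id = sample_id, gene = gene, variant_class = class,
             protein_change = pc, vaf = round(alt / total, 4),
             alt_reads = alt, total_reads = total,
             pathogenicity = sample(c("pathogenic", "likely_pathogenic"), m,
                                    TRUE, c(.7, .3)),
             stringsAsFactors = FALSE)
}

fusion_rows <- function(sample_id, g5, g3, frame, evidence = "rna") {
  m <- length(sample_id)
  if (m == 0) return(empty_fusion_table())
  data.frame(sample_id = sample_id, gene_5p = rep_len(g5, m),
             gene_3p = rep_len(g3, m), frame = rep_len(frame, m),
             evidence = rep_len(evidence, m), stringsAsFactors = FALSE)
}

# signature states implied by a category's superfamily (HOXr additionally
# expresses HOXA cluster genes; the ASE categories overexpress their gene)
category_states <- function(categories, ruleset) {
  sf <- assign_superfamily(ifelse(startsWith(categories, "Unclassified"),
                                  "Unclassified", categories), ruleset)
  data.frame(category = categories,
             hoxa = sf %in% c("HOXA", "HOXB") | categories == "HOXr",
             hoxb = sf == "HOXB",
             amkl = sf == "AMKL_AEL",
             immature = sf == "immature", stringsAsFactors = FALSE)
}

#' Generate ASE markers for one sample and gene
#'
#' DNA counts are heterozygous (allele fraction ~0.5, coverage >= 10); RNA
#' counts are skewed towards one allele (fraction drawn near 0.9) for
#' ASE-positive samples and balanced otherwise. Uses the current RNG state.
#'
#' @param sample_id sample identifier.
#' @param gene gene symbol.
#' @param ase_positive skew the RNA allele fraction (TRUE) or keep it
#'   balanced.
#' @param n_markers number of markers (0 yields an empty table).
#' @param config generator configuration.
#' @return ASE marker data frame.
#' @export
generate_ase_markers <- function(sample_id, gene, ase_positive = TRUE,
                                 n_markers = NULL,
                                 config = default_generator_config()) {
  am <- config$ase_markers
  if (is.null(n_markers)) n_markers <- am$n_markers
  if (n_markers == 0) return(empty_ase_table())
  dna_cov <- am$dna_cov_base + stats::rpois(n_markers, am$dna_cov_lambda)
  dna_alt <- stats::rbinom(n_markers, dna_cov, 0.5)
  rna_cov <- am$rna_cov_base + stats::rpois(n_markers, am$rna_cov_lambda)
  frac <- if (ase_positive) {
    f <- stats::rbeta(n_markers, am$skew_shape1, am$skew_shape2)
    ifelse(stats::runif(n_markers) < 0.5, f, 1 - f)   # either allele
  } else rep(0.5, n_markers)
  rna_alt <- stats::rbinom(n_markers, rna_cov, frac)
  data.frame(sample_id = unname(sample_id), gene = unname(gene),
             position = sort(sample.int(5e4, n_markers)),
             dna_ref = dna_cov - dna_alt, dna_alt = dna_alt,
             rna_ref = rna_cov - rna_alt, rna_alt = rna_alt,
             stringsAsFactors = FALSE)
}

#' Generate survival outcomes and MRD flags for a cohort
#'
#' MRD positivity is drawn per risk group; overall survival times are
#' exponential with the stratum hazard under independent uniform censoring
#' on [0, censor_max]; EFS uses a proportional hazard with non-response
#' (event at time 0) drawn per risk group. Uses the current RNG state.
#'
#' @param risk_group character vector of risk groups per sample.
#' @param config generator configuration.
#' @return data frame: `mrd_positive` (with missingness), `stratum` (from
#'   the drawn MRD before masking), `os_time`, `os_event`, `efs_time`,
#'   `relapse`, `death_in_remission`, `non_response`.
#' @export
generate_survival <- function(risk_group, config = default_generator_config()) {
  n <- length(risk_group)
  mrd <- stats::runif(n) < unlist(config$mrd_prob)[risk_group]
  stratum <- paste0(risk_group, "/MRD", ifelse(mrd, "+", "-"))
  lam <- unlist(config$hazards)[stratum]
  t_os <- stats::rexp(n, lam)
  cens <- stats::runif(n, 0, config$censor_max)
  os_time <- pmin(t_os, cens)
  os_event <- t_os <= cens
  nr <- stats::runif(n) < unlist(config$non_response_prob)[risk_group]
  t_efs <- stats::rexp(n, lam * config$efs_hazard_multiplier)
  efs_event <- t_efs <= cens
  efs_time <- ifelse(nr, 0, pmin(t_efs, cens))
  rel <- !nr & efs_event & stats::runif(n) < config$relapse_share
  dir <- !nr & efs_event & !rel
  mrd_out <- mrd
  mrd_out[stats::runif(n) < config$mrd_missing] <- NA
  data.frame(mrd_positive = mrd_out, stratum = stratum, os_time = os_time,
             os_event = os_event, efs_time = efs_time, relapse = rel,
             death_in_remission = dir, non_response = nr,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic pediatric-AML cohort with ground truth
#'
#' Per sample: draws a molecular category (or an Unclassified subgroup),
#' emits its defining lesion (fusion/SV, tandem duplication, mutation, or
#' ASE markers with imbalanced RNA counts), draws cooperating mutations from
#' category-conditional probabilities, generates signature-consistent
#' expression counts, and draws MRD and survival from the risk-dependent
#' outcome model. Fully reproducible under a fixed seed.
#'
#' @param config generator configuration (see
#'   [default_generator_config()]).
#' @param seed integer seed; the only source of randomness.
#' @param n_samples overrides `config$n_samples` when given.
#' @return a `paml_cohort` whose `truth` element is the ground-truth data
#'   frame (`sample_id`, `true_category`, `unclassified_subtype`,
#'   `true_superfamily`, `true_risk_group`, `true_stratum`).
#' @export
generate_cohort <- function(config = default_generator_config(), seed = 1L,
                            n_samples = NULL) {
  validate_generator_config(config)
  set.seed(seed)
  rs <- default_ruleset()
  n <- if (is.null(n_samples)) config$n_samples else n_samples
  prev <- unlist(config$category_prevalence)
  usplit <- unlist(config$unclassified_split) * config$unclassified_fraction
  labels <- c(names(prev), paste0("Unclassified_", names(usplit)))
  gen_cat <- sample(labels, n, TRUE, c(prev, usplit))
  sample_id <- sprintf("S%04d", seq_len(n))
  is_uncl <- startsWith(gen_cat, "Unclassified")
  true_cat <- ifelse(is_uncl, "Unclassified", gen_cat)

  fus <- list(); mut <- list(); ase <- list(); cnv <- list()
  emit_fus <- function(x) fus[[length(fus) + 1]] <<- x
  emit_mut <- function(x) mut[[length(mut) + 1]] <<- x

  ## -- defining lesions -----------------------------------------------------
  pick <- function(cat) sample_id[gen_cat == cat]
  pair_cats <- list("RUNX1::RUNX1T1" = c("RUNX1", "RUNX1T1"),
                    "CBFB::MYH11" = c("CBFB", "MYH11"),
                    "DEK::NUP214" = c("DEK", "NUP214"),
                    "PICALM::MLLT10" = c("PICALM", "MLLT10"),
                    "RBM15::MRTFA" = c("RBM15", "MRTFA"),
                    "BCR::ABL1" = c("BCR", "ABL1"))
  for (cat in names(pair_cats)) {
    ids <- pick(cat)
    emit_fus(fusion_rows(ids, pair_cats[[cat]][1], pair_cats[[cat]][2],
                         "in_frame"))
  }
  for (cat in c("KMT2Ar", "NUP98r", "KAT6Ar")) {
    ids <- pick(cat)
    pl <- GEN_PARTNERS[[cat]]
    gene <- c(KMT2Ar = "KMT2A", NUP98r = "NUP98", KAT6Ar = "KAT6A")[[cat]]
    emit_fus(fusion_rows(ids, gene, sample(names(pl), length(ids), TRUE, pl),
                         "in_frame"))
  }
  ids <- pick("APL")
  p5 <- sample(names(GEN_PARTNERS$APL), length(ids), TRUE, GEN_PARTNERS$APL)
  emit_fus(fusion_rows(ids, p5, ifelse(p5 == "TBL1XR1", "RARB", "RARA"),
                       "in_frame"))
  ids <- pick("GLISr")
  p5 <- sample(names(GEN_PARTNERS$GLISr), length(ids), TRUE,
               GEN_PARTNERS$GLISr)
  emit_fus(fusion_rows(ids, p5, "GLIS2", "in_frame"))
  ids <- pick("FET::ETS")
  fet <- sample(c("FUS", "EWSR1"), length(ids), TRUE, c(.7, .3))
  ets <- sample(c("ERG", "FEV", "FLI1"), length(ids), TRUE, c(.7, .15, .15))
  emit_fus(fusion_rows(ids, fet, ets, "in_frame"))
  ids <- pick("RUNX1::RUNX1T1-like")
  emit_fus(fusion_rows(ids, "RUNX1",
                       sample(c("CBFA2T3", "CBFA2T2"), length(ids), TRUE,
                              c(.6, .4)), "in_frame"))
  ids <- pick("HOXr")
  hx <- sample(c("HOXA9", "HOXA10", "HOXB8"), length(ids), TRUE,
               c(.4, .3, .3))
  emit_fus(fusion_rows(ids, sample(names(GEN_PARTNERS$HOXr), length(ids),
                                   TRUE, GEN_PARTNERS$HOXr), hx, "sv_other"))
  # ASE-definable categories: SV-evident except an ASE-only fraction
  ase_positive <- stats::setNames(rep(FALSE, n), sample_id)
  for (cat in c("MECOM", "BCL11B", "MNX1")) {
    ids <- pick(cat)
    ase_positive[ids] <- TRUE
    sv <- stats::runif(length(ids)) >= config$ase_only_fraction
    pl <- GEN_PARTNERS[[cat]]
    emit_fus(fusion_rows(ids[sv], sample(names(pl), sum(sv), TRUE, pl), cat,
                         "sv_other", evidence = "wgs"))
  }
  # mutation/TD-defined categories
  ids <- pick("NPM1")
  emit_mut(draw_mutation_rows(ids, "NPM1", "indel", GEN_PROTEIN_CHANGES$NPM1))
  ids <- pick("CEBPA")
  emit_mut(draw_mutation_rows(ids, "CEBPA", "indel",
                              GEN_PROTEIN_CHANGES$CEBPA))
  ids <- pick("UBTF")
  emit_mut(draw_mutation_rows(ids, "UBTF", "itd", GEN_PROTEIN_CHANGES$UBTF))
  ids <- pick("CBFB-GDXY")
  emit_mut(draw_mutation_rows(ids, "CBFB", "indel", GEN_PROTEIN_CHANGES$CBFB))
  ids <- pick("KMT2A-PTD")
  emit_mut(draw_mutation_rows(ids, "KMT2A", "ptd",
                              GEN_PROTEIN_CHANGES$KMT2A_PTD))
  ids <- pick("GATA1")
  gfus <- stats::runif(length(ids)) < config$gata1_fusion_fraction
  emit_fus(fusion_rows(ids[gfus], "MYB", "GATA1", "in_frame"))
  emit_mut(draw_mutation_rows(ids[!gfus], "GATA1", "indel",
                              GEN_PROTEIN_CHANGES$GATA1))
  # Unclassified subgroups
  ids <- pick("Unclassified_rare")
  rfus <- stats::runif(length(ids)) < config$rare_driver_fusion_fraction
  if (any(rfus)) {
    pairs <- GEN_RARE_FUSIONS[sample.int(length(GEN_RARE_FUSIONS), sum(rfus),
                                         TRUE)]
    emit_fus(fusion_rows(ids[rfus], vapply(pairs, `[`, "", 1),
                         vapply(pairs, `[`, "", 2), "in_frame"))
  }
  rmut_gene <- sample(c("MLLT1", "H3F3A", "JAK2"), sum(!rfus), TRUE)
  for (g in unique(rmut_gene)) {
    emit_mut(draw_mutation_rows(ids[!rfus][rmut_gene == g], g,
                                if (g == "MLLT1") "indel" else "snv",
                                GEN_PROTEIN_CHANGES[[g]]))
  }
  ids <- pick("Unclassified_nondef")
  ndg <- sample(c("ETV6", "RUNX1", "TP53"), length(ids), TRUE)
  for (g in unique(ndg)) {
    emit_mut(draw_mutation_rows(ids[ndg == g], g,
                                if (g == "TP53") "snv" else "indel",
                                GEN_PROTEIN_CHANGES[[g]]))
  }

  ## -- cooperating mutations ------------------------------------------------
  coop_spec <- list(
    flt3_itd = list(gene = "FLT3", class = "itd",
                    pc = GEN_PROTEIN_CHANGES$FLT3_ITD),
    flt3_tkd = list(gene = "FLT3", class = "tkd",
                    pc = GEN_PROTEIN_CHANGES$FLT3_TKD),
    flt3_other = list(gene = "FLT3", class = "snv",
                      pc = GEN_PROTEIN_CHANGES$FLT3_OTHER),
    wt1 = list(gene = "WT1", class = "indel", pc = GEN_PROTEIN_CHANGES$WT1),
    kras = list(gene = "KRAS", class = "snv", pc = GEN_PROTEIN_CHANGES$KRAS),
    nras = list(gene = "NRAS", class = "snv", pc = GEN_PROTEIN_CHANGES$NRAS),
    ptpn11 = list(gene = "PTPN11", class = "snv",
                  pc = GEN_PROTEIN_CHANGES$PTPN11),
    nf1 = list(gene = "NF1", class = "indel", pc = GEN_PROTEIN_CHANGES$NF1),
    cbl = list(gene = "CBL", class = "snv", pc = GEN_PROTEIN_CHANGES$CBL),
    braf = list(gene = "BRAF", class = "snv", pc = GEN_PROTEIN_CHANGES$BRAF),
    kit = list(gene = "KIT", class = "snv", pc = GEN_PROTEIN_CHANGES$KIT))
  drawn <- list()
  for (key in names(coop_spec)) {
    hit <- stats::runif(n) < coop_prob(config, key, gen_cat)
    drawn[[coop_spec[[key]]$gene]] <-
      (if (is.null(drawn[[coop_spec[[key]]$gene]])) hit else
        drawn[[coop_spec[[key]]$gene]] | hit)
    sp <- coop_spec[[key]]
    emit_mut(draw_mutation_rows(sample_id[hit], sp$gene, sp$class, sp$pc))
  }
  # second cooperating RAS hit for samples with exactly one RAS-gene mutation
  ras6 <- c("KRAS", "NRAS", "PTPN11", "NF1", "CBL", "BRAF")
  ras_n <- Reduce(`+`, lapply(ras6, function(g) as.integer(drawn[[g]])))
  second <- ras_n == 1 & stats::runif(n) < config$ras_second_hit
  for (i in which(second)) {
    cand <- c("PTPN11", "NF1", "CBL", "BRAF")
    cand <- cand[!vapply(cand, function(g) drawn[[g]][i], TRUE)]
    g <- if (length(cand) == 1) cand else sample(cand, 1)
    sp <- coop_spec[[tolower(g)]]
    emit_mut(draw_mutation_rows(sample_id[i], g, sp$class, sp$pc))
  }
  # pooled epigenetic / transcription-factor drivers
  hit <- stats::runif(n) < coop_prob(config, "other_driver", gen_cat)
  pg <- sample(GEN_POOL_GENES, sum(hit), TRUE)
  for (g in unique(pg)) {
    emit_mut(draw_mutation_rows(sample_id[hit][pg == g], g, "snv",
                                sprintf("p.V%dM", c(101, 215, 388, 472, 560,
                                                    644))))
  }

  ## -- CNVs and clinical ----------------------------------------------------
  cnv_rows <- function(ids, chrom, start, end, state, scope) {
    if (length(ids) == 0) return(empty_cnv_table())
    data.frame(sample_id = ids, chrom = chrom, start = start, end = end,
               copy_state = state, scope = scope, stringsAsFactors = FALSE)
  }
  allowed <- gen_cat != "Unclassified_none"
  g8 <- allowed & stats::runif(n) < config$cnv$chr8_gain
  cnv[[1]] <- cnv_rows(sample_id[g8], "chr8", 0L, 146364022L, "gain",
                       "broad")
  l7 <- allowed & stats::runif(n) < config$cnv$chr7_loss
  cnv[[2]] <- cnv_rows(sample_id[l7], "chr7", 0L, 159138663L, "loss",
                       "broad")
  rb <- allowed & stats::runif(n) < config$cnv$rb1_focal_del
  cnv[[3]] <- cnv_rows(sample_id[rb], "chr13", 48877882L, 49056122L, "loss",
                       "focal")

  states <- category_states(gen_cat, rs)
  risk <- map_risk_group(true_cat, rs)
  surv <- generate_survival(risk, config)
  ck_p <- rep(config$complex_karyotype$default, n)
  for (nm in names(config$complex_karyotype$overrides)) {
    ck_p[gen_cat == nm] <- config$complex_karyotype$overrides[[nm]]
  }
  infant <- states$amkl
  age <- ifelse(infant, stats::rlnorm(n, log(1.5), 0.6),
                stats::rlnorm(n, log(9), 0.55))
  age <- pmin(pmax(age, 0.05), 23.5)
  fab <- ifelse(gen_cat == "APL", "M3",
                ifelse(infant & stats::runif(n) < .7, "M7",
                       sample(c("M0", "M1", "M2", "M4", "M5", "unknown"), n,
                              TRUE)))
  clinical <- data.frame(
    sample_id = sample_id, age_years = round(age, 2), fab = fab,
    timepoint = ifelse(stats::runif(n) < config$relapse_timepoint_fraction,
                       "relapse", "diagnosis"),
    mrd_positive = surv$mrd_positive,
    os_time = round(surv$os_time, 4), os_event = surv$os_event,
    efs_time = round(surv$efs_time, 4), relapse = surv$relapse,
    death_in_remission = surv$death_in_remission,
    non_response = surv$non_response,
    karyotype_complex = stats::runif(n) < ck_p, monosomy7 = l7,
    stringsAsFactors = FALSE)

  ## -- ASE markers ----------------------------------------------------------
  ase_gene <- stats::setNames(rep(NA_character_, n), sample_id)
  for (cat in c("MECOM", "BCL11B", "MNX1")) ase_gene[pick(cat)] <- cat
  neg <- is.na(ase_gene) & allowed &
    stats::runif(n) < config$ase_markers$negative_control_fraction
  ase_gene[neg] <- sample(c("MECOM", "BCL11B", "MNX1"), sum(neg), TRUE)
  for (i in which(!is.na(ase_gene))) {
    ase[[length(ase) + 1]] <- generate_ase_markers(
      sample_id[i], ase_gene[i], ase_positive = ase_positive[i],
      config = config)
  }

  ## -- expression counts ----------------------------------------------------
  ex <- config$expression
  sets <- paml_signature_sets()
  genes <- c(sets$HOXA, sets$HOXB, sets$AMKL, sets$immature,
             "MECOM", "BCL11B", "MNX1",
             sprintf("FILLER%02d", seq_len(ex$n_filler_genes)),
             sprintf("SILENT%02d", seq_len(ex$n_silent_genes)))
  mu <- matrix(0, length(genes), n, dimnames = list(genes, sample_id))
  mu[sets$HOXA, ] <- ex$hox_mean_low
  mu[sets$HOXA, states$hoxa] <- ex$hox_mean_high
  mu[sets$HOXB, ] <- ex$hox_mean_low
  mu[sets$HOXB, states$hoxb] <- ex$hox_mean_high
  mu[sets$AMKL, ] <- ex$amkl_mean_low
  mu[sets$AMKL, states$amkl] <- ex$amkl_mean_high
  mu[sets$immature, ] <- ex$immature_mean_low
  mu[sets$immature, states$immature] <- ex$immature_mean_high
  for (g in c("MECOM", "BCL11B", "MNX1")) {
    mu[g, ] <- ex$ase_mean_base
    mu[g, gen_cat == g] <- ex$ase_mean_outlier
  }
  filler_mu <- stats::rlnorm(ex$n_filler_genes, ex$filler_meanlog,
                             ex$filler_sdlog)
  mu[sprintf("FILLER%02d", seq_len(ex$n_filler_genes)), ] <- filler_mu
  mu[sprintf("SILENT%02d", seq_len(ex$n_silent_genes)), ] <- ex$silent_mean
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / ex$nb_dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))

  truth <- data.frame(
    sample_id = sample_id, true_category = true_cat,
    unclassified_subtype = ifelse(is_uncl, sub("Unclassified_", "", gen_cat),
                                  NA_character_),
    true_superfamily = assign_superfamily(true_cat, rs),
    true_risk_group = risk, true_stratum = surv$stratum,
    stringsAsFactors = FALSE)

  cohort <- paml_cohort(fusions = do.call(rbind, fus),
                        mutations = do.call(rbind, mut),
                        cnvs = do.call(rbind, cnv),
                        ase_markers = if (length(ase)) do.call(rbind, ase)
                                      else empty_ase_table(),
                        clinical = clinical, counts = counts, truth = truth)
  cohort
}
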