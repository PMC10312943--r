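# In-code fixtures: no files, everything built programmatically.

make_fusion <- function(sample_id, gene_5p, gene_3p, frame = "in_frame",
                        evidence = "rna") {
  data.frame(sample_id = sample_id, gene_5p = gene_5p, gene_3p = gene_3p,
             frame = frame, evidence = evidence, stringsAsFactors = FALSE)
}

make_mutation <- function(sample_id, gene, variant_class = "snv",
                          protein_change = "p.A1V", vaf = 0.4,
                          alt_reads = 40L, total_reads = 100L,
                          pathogenicity = "pathogenic") {
  data.frame(sample_id = sample_id, gene = gene,
             variant_class = variant_class, protein_change = protein_change,
             vaf = vaf, alt_reads = as.integer(alt_reads),
             total_reads = as.integer(total_reads),
             pathogenicity = pathogenicity, stringsAsFactors = FALSE)
}

make_clinical <- function(sample_id, age_years = 8, fab = "M2",
                          timepoint = "diagnosis", mrd_positive = FALSE,
                          os_time = 5, os_event = FALSE, efs_time = 5,
                          relapse = FALSE, death_in_remission = FALSE,
                          non_response = FALSE, karyotype_complex = FALSE,
                          monosomy7 = FALSE) {
  data.frame(sample_id = sample_id, age_years = age_years, fab = fab,
             timepoint = timepoint, mrd_positive = mrd_positive,
             os_time = os_time, os_event = os_event, efs_time = efs_time,
             relapse = relapse, death_in_remission = death_in_remission,
             non_response = non_response,
             karyotype_complex = karyotype_complex, monosomy7 = monosomy7,
             stringsAsFactors = FALSE)
}

make_marker <- function(sample_id, gene, position = 100L, dna_ref = 15L,
                        dna_alt = 15L, rna_ref = 15L, rna_alt = 15L) {
  data.frame(sample_id = sample_id, gene = gene, position = position,
             dna_ref = dna_ref, dna_alt = dna_alt, rna_ref = rna_ref,
             rna_alt = rna_alt, stringsAsFactors = FALSE)
}

make_lesions <- function(sample_id = "S1", fusions = NULL, mutations = NULL,
                         cnvs = NULL) {
  empty_f <- make_fusion(character(), character(), character(), character(),
                         character())
  empty_m <- make_mutation(character(), character(), character(),
                           character(), numeric(), integer(), integer(),
                           character())
  list(sample_id = sample_id,
       fusions = if (is.null(fusions)) empty_f else fusions,
       mutations = if (is.null(mutations)) empty_m else mutations,
       cnvs = if (is.null(cnvs)) data.frame(sample_id = character()) else cnvs,
       ase_markers = data.frame(sample_id = character()))
}

# three-sample toy cohort used by the IO tests
toy_cohort <- function() {
  suppressWarnings(paml_cohort(
    fusions = rbind(make_fusion("S1", "KMT2A", "MLLT3"),
                    make_fusion("S2", "RUNX1", "RUNX1T1")),
    mutations = rbind(make_mutation("S1", "NRAS", protein_change = "p.G12D"),
                      make_mutation("S2", "KIT", protein_change = "p.D816V"),
                      make_mutation("S3", "NPM1", "indel", "p.W288Cfs*12"),
                      make_mutation("S3", "FLT3", "itd", "p.ITD(e14)")),
    clinical = rbind(make_clinical("S1"), make_clinical("S2"),
                     make_clinical("S3"))))
}
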