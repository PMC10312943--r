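test_that("a small cohort reads back identically from disk", {
  co <- toy_cohort()
  expect_equal(length(co$samples), 3)
  expect_equal(nrow(co$fusions), 2)
  expect_equal(nrow(co$mutations), 4)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$fusions, canonical_sort(co$fusions),
               ignore_attr = TRUE)
  expect_equal(back$mutations, canonical_sort(co$mutations),
               ignore_attr = TRUE)
  expect_equal(back$clinical, canonical_sort(co$clinical),
               ignore_attr = TRUE)
})

test_that("write/read/write round trips are byte-identical", {
  co <- generate_cohort(seed = 42, n_samples = 40)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(read_cohort(d1), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("invariant-violating rows are rejected and logged", {
  bad <- make_mutation("S1", "NRAS", alt_reads = 120L, total_reads = 100L)
  expect_warning(co <- paml_cohort(mutations = rbind(
    make_mutation("S2", "KRAS"), bad)), "alt_reads > total_reads")
  expect_equal(nrow(co$mutations), 1)
  expect_match(attr(co, "parse_log"), "invalid read counts", all = FALSE)
})

test_that("duplicated lesion rows are deduplicated with a warning", {
  f <- make_fusion("S1", "KMT2A", "MLLT3")
  expect_warning(co <- paml_cohort(fusions = rbind(f, f)), "deduplicated")
  expect_equal(nrow(co$fusions), 1)
})

test_that("a missing required column is a hard error naming the column", {
  dir <- withr::local_tempdir()
  write.table(data.frame(sample_id = "S1", gene_5p = "KMT2A"),
              file.path(dir, "fusions.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(read_cohort(dir), "gene_3p")
})

test_that("VAF is computed from read counts when absent", {
  m <- make_mutation("S1", "WT1", vaf = NA, alt_reads = 30L,
                     total_reads = 120L)
  co <- paml_cohort(mutations = m)
  expect_equal(co$mutations$vaf, 0.25)
})

test_that("gene symbols normalize case-insensitively, unknowns pass through", {
  expect_equal(normalize_gene_symbols(c("kmt2a", "Npm1", "MYNOVELGENE")),
               c("KMT2A", "NPM1", "MYNOVELGENE"))
})

test_that("category table writing is deterministic and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  empty <- data.frame(sample_id = character(), category = character())
  write_category_table(empty, path)
  expect_equal(readLines(path),
               paste(c("sample_id", "category", "superfamily", "rule_fired",
                       "risk_group", "stratum"), collapse = "\t"))
  calls <- data.frame(sample_id = c("S2", "S1"),
                      category = c("NPM1", "KMT2Ar"),
                      superfamily = c("HOXB", "HOXA"),
                      rule_fired = c("NPM1", "KMT2Ar"),
                      risk_group = c("Low", "Intermediate"),
                      stratum = c("Low/MRD-", "Intermediate/MRD+"),
                      stringsAsFactors = FALSE)
  write_category_table(calls, path)
  back <- read_category_table(path)
  expect_equal(back$sample_id, c("S1", "S2"))   # sorted
  expect_equal(back[order(back$sample_id), ],
               calls[order(calls$sample_id), ], ignore_attr = TRUE)
  co <- toy_cohort()
  expect_error(write_category_table(
    data.frame(sample_id = "NOPE", category = "NPM1"), path, cohort = co),
    "unknown sample")
})

test_that("lesion_set extracts exactly one sample's records", {
  co <- toy_cohort()
  ls3 <- lesion_set(co, "S3")
  expect_equal(nrow(ls3$mutations), 2)
  expect_equal(nrow(ls3$fusions), 0)
  expect_setequal(ls3$mutations$gene, c("NPM1", "FLT3"))
})

test_that("minimal VCF mutation calls map onto the mutation table", {
  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("chr1", "115258747", ".", "C", "T", ".", "PASS", "GENE=nras",
          "GT:AD", "0/1:60,40", sep = "\t"),
    paste("chr11", "32417945", ".", "CTT", "C", ".", "PASS", "GENE=WT1",
          "GT:AD", "0/1:80,20", sep = "\t")), vcf)
  m <- read_mutations_vcf(vcf, "S1")
  expect_equal(m$gene, c("NRAS", "WT1"))         # normalized case
  expect_equal(m$variant_class, c("snv", "indel"))
  expect_equal(m$vaf, c(0.4, 0.2))
  expect_equal(m$total_reads, c(100L, 100L))
  co <- paml_cohort(mutations = m)               # valid table rows
  expect_equal(nrow(co$mutations), 2)
})
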