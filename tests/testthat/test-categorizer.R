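test_that("defining fusions win over cooperating mutations", {
  les <- make_lesions("S1",
    fusions = make_fusion("S1", "KMT2A", "MLLT3"),
    mutations = make_mutation("S1", "NRAS", protein_change = "p.G12D"))
  call <- assign_category(les)
  expect_equal(call$category, "KMT2Ar")
  expect_equal(call$superfamily, "HOXA")
  expect_equal(call$rule_fired, "KMT2Ar")
})

test_that("UBTF tandem duplication defines its category despite FLT3/WT1", {
  les <- make_lesions("S1", mutations = rbind(
    make_mutation("S1", "UBTF", "itd", "p.E435_K461dup"),
    make_mutation("S1", "FLT3", "itd", "p.ITD(e14)"),
    make_mutation("S1", "WT1", "indel", "p.S381fs")))
  expect_equal(assign_category(les)$category, "UBTF")
})

test_that("NPM1 indels assign the NPM1 category without a fusion", {
  les <- make_lesions("S1", mutations = make_mutation(
    "S1", "NPM1", "indel", "p.T294_A297del"))   # outside the N-terminus
  expect_equal(assign_category(les)$category, "NPM1")
})

test_that("tier precedence: a KMT2A fusion outranks a GATA1 mutation", {
  les <- make_lesions("S1",
    fusions = make_fusion("S1", "KMT2A", "MLLT10"),
    mutations = make_mutation("S1", "GATA1", "indel", "p.V74fs"))
  expect_equal(assign_category(les)$category, "KMT2Ar")
})

test_that("ASE plus outlier expression defines MECOM without rearrangement", {
  les <- make_lesions("S1")
  ase <- data.frame(gene = "MECOM", ase_supported = TRUE, outlier = TRUE)
  expect_equal(assign_category(les, ase = ase)$category, "MECOM")
  # ASE without outlier expression is insufficient
  ase2 <- data.frame(gene = "MECOM", ase_supported = TRUE, outlier = FALSE)
  expect_equal(assign_category(les, ase = ase2)$category, "Unclassified")
})

test_that("lesion-free samples are Unclassified with the right reason", {
  call <- assign_category(make_lesions("S1"))
  expect_equal(call$category, "Unclassified")
  expect_equal(call$unclassified_reason, "no_pathogenic_alteration")
  expect_true(is.na(call$rule_fired))
})

test_that("two distinct defining fusions in one tier raise a ruleset error", {
  les <- make_lesions("S1", fusions = rbind(
    make_fusion("S1", "KMT2A", "MLLT3"),
    make_fusion("S1", "RUNX1", "RUNX1T1")))
  expect_error(assign_category(les), "KMT2Ar and RUNX1::RUNX1T1")
})

test_that("tier-3 categories require expression consistency", {
  les <- make_lesions("S1", mutations = make_mutation(
    "S1", "KMT2A", "ptd", "p.PTD(e3-e9)"))
  # no expression data -> gate closed -> Unclassified (non-defining lesion)
  call <- assign_category(les)
  expect_equal(call$category, "Unclassified")
  expect_equal(call$unclassified_reason, "non_defining_alterations_only")
  # consistent HOXB-like signature opens the gate
  scores <- data.frame(sample_id = "S1", hoxa_score = 10, hoxb_score = 10,
                       amkl_score = 0, immature_score = 0,
                       hox_call = "HOXB_like")
  attr(scores, "thresholds") <- c(hoxa_score = 5, hoxb_score = 5,
                                  amkl_score = 5, immature_score = 5)
  expect_equal(assign_category(les, scores = scores)$category, "KMT2A-PTD")
})

test_that("superfamily mapping is fixed and total", {
  expect_equal(assign_superfamily("NPM1"), "HOXB")
  expect_equal(assign_superfamily("KAT6Ar"), "HOXA")
  expect_equal(assign_superfamily("Unclassified"), "other")
  expect_equal(assign_superfamily(c("GLISr", "CEBPA", "APL")),
               c("AMKL_AEL", "CEBPA", "APL"))
  expect_error(assign_superfamily("NOT_A_CATEGORY"), "unknown category")
  hoxb <- c("NPM1", "NUP98r", "UBTF", "KMT2A-PTD", "DEK::NUP214")
  expect_true(all(assign_superfamily(hoxb) == "HOXB"))
})

test_that("coverage is a direct tally over calls", {
  calls <- data.frame(sample_id = paste0("S", 1:5),
                      category = c("NPM1", "KMT2Ar", "Unclassified",
                                   "NPM1", "Unclassified"))
  cv <- cohort_coverage(calls)
  expect_equal(cv$coverage, 3 / 5)
  expect_equal(sum(cv$counts), 5)
  expect_equal(unname(cv$counts["NPM1"]), 2)
  all_un <- data.frame(sample_id = "S1", category = "Unclassified")
  expect_equal(cohort_coverage(all_un)$coverage, 0)
})

test_that("Unclassified cases partition into the three reasons", {
  # 30 samples so a singleton ETV6 call stays under the >5% recurrence rule
  co <- suppressWarnings(paml_cohort(
    fusions = make_fusion("U1", "RUNX1", "USP42"),
    mutations = make_mutation("U2", "ETV6", "indel", "p.R399fs"),
    clinical = do.call(rbind, lapply(
      c("U1", "U2", "U3", sprintf("P%02d", 1:27)), make_clinical))))
  calls <- classify_cohort(co)
  expect_true(all(calls$category == "Unclassified"))
  ch <- characterize_unclassified(co, calls)
  expect_equal(ch$reason[ch$sample_id == "U1"], "rare_recurrent_alteration")
  expect_equal(ch$reason[ch$sample_id == "U2"],
               "non_defining_alterations_only")
  expect_equal(ch$reason[ch$sample_id == "U3"], "no_pathogenic_alteration")
})

test_that("classification is deterministic and order-invariant", {
  co <- generate_cohort(seed = 9, n_samples = 150)
  calls1 <- classify_cohort(co)
  # shuffle every table's row order
  set.seed(1)
  co2 <- co
  for (k in c("fusions", "mutations", "cnvs", "ase_markers", "clinical")) {
    co2[[k]] <- co2[[k]][sample.int(nrow(co2[[k]])), , drop = FALSE]
  }
  co2$counts <- co2$counts[, sample.int(ncol(co2$counts))]
  co2$samples <- sample(co2$samples)
  calls2 <- classify_cohort(co2)
  m <- match(calls1$sample_id, calls2$sample_id)
  expect_equal(calls1$category, calls2$category[m])
  calls3 <- classify_cohort(co)
  expect_identical(calls1$category, calls3$category)
})

test_that("adding a non-defining lesion never changes a category", {
  co <- generate_cohort(seed = 10, n_samples = 150)
  calls1 <- classify_cohort(co)
  extra <- make_mutation(co$samples, "NRAS", protein_change = "p.G13D")
  co2 <- suppressWarnings(paml_cohort(
    fusions = co$fusions, mutations = rbind(co$mutations, extra),
    cnvs = co$cnvs, ase_markers = co$ase_markers, clinical = co$clinical,
    counts = co$counts))
  calls2 <- classify_cohort(co2)
  m <- match(calls1$sample_id, calls2$sample_id)
  expect_equal(calls1$category, calls2$category[m])
})
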