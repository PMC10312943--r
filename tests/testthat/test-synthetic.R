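test_that("generation is fully reproducible under a fixed seed", {
  c1 <- generate_cohort(seed = 11, n_samples = 100)
  c2 <- generate_cohort(seed = 11, n_samples = 100)
  expect_identical(c1$fusions, c2$fusions)
  expect_identical(c1$mutations, c2$mutations)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$counts, c2$counts)
  c3 <- generate_cohort(seed = 12, n_samples = 100)
  expect_false(identical(c1$mutations, c3$mutations))
})

test_that("the classifier recovers every planted category", {
  co <- generate_cohort(seed = 5, n_samples = 400)
  calls <- classify_cohort(co)
  tr <- co$truth[match(calls$sample_id, co$truth$sample_id), ]
  expect_equal(calls$category, tr$true_category)
  expect_equal(calls$superfamily, tr$true_superfamily)
  # planted driver-free samples never get a defined category
  none <- tr$sample_id[!is.na(tr$unclassified_subtype) &
                         tr$unclassified_subtype == "none"]
  expect_true(all(calls$category[calls$sample_id %in% none] ==
                    "Unclassified"))
})

test_that("defined-category fraction matches the configured total", {
  co <- generate_cohort(seed = 6)      # default n = 895
  frac <- mean(co$truth$true_category != "Unclassified")
  se <- sqrt(0.914 * 0.086 / 895)
  expect_lt(abs(frac - 0.914), 3 * se)
})

test_that("invalid configurations are rejected", {
  cfg <- default_generator_config()
  bad <- cfg; bad$unclassified_fraction <- 0.5
  expect_error(generate_cohort(bad, seed = 1), "sum to 1")
  bad2 <- cfg; bad2$hazards[["Low/MRD-"]] <- 0
  expect_error(generate_cohort(bad2, seed = 1), "strictly positive")
})

test_that("ASE marker generation gives paired-mode power at skewed fractions", {
  set.seed(33)
  pos <- replicate(20, {
    mk <- generate_ase_markers("P", "MECOM", ase_positive = TRUE)
    ase_score_paired(select_het_markers(mk))$median_p
  })
  expect_true(mean(pos < 0.05) >= 0.95)
  neg <- replicate(20, {
    mk <- generate_ase_markers("P", "MECOM", ase_positive = FALSE)
    ase_score_paired(select_het_markers(mk))$median_p
  })
  expect_true(stats::median(neg) > 0.2)
  expect_equal(nrow(generate_ase_markers("P", "MECOM", n_markers = 0)), 0)
})

test_that("survival generation matches the exponential closed form", {
  set.seed(34)
  cfg <- default_generator_config()
  sv <- generate_survival(rep("Low", 2000), cfg)
  for (st in c("Low/MRD-", "Low/MRD+")) {
    sel <- sv$stratum == st
    km <- km_estimate(sv$os_time[sel], sv$os_event[sel])
    lam <- cfg$hazards[[st]]
    expect_lt(abs(km_at(km, 1) - exp(-lam)), 0.04)
    expect_lt(abs(km_at(km, 5) - exp(-5 * lam)), 0.06)
  }
})

test_that("planted strata order their survival curves", {
  set.seed(35)
  cfg <- default_generator_config()
  risk <- sample(c("Low", "Intermediate", "High"), 3000, TRUE)
  sv <- generate_survival(risk, cfg)
  s5 <- vapply(names(cfg$hazards), function(st) {
    sel <- sv$stratum == st
    km_at(km_estimate(sv$os_time[sel], sv$os_event[sel]), 5)
  }, 0)
  expect_true(all(diff(s5) < 0))   # Low/MRD- best ... High/MRD+ worst
})

test_that("cohort-level lesion frequencies converge to the configuration", {
  co <- generate_cohort(seed = 7)
  n <- length(co$samples)
  prev <- unlist(default_generator_config()$category_prevalence)
  tab <- table(co$truth$true_category)
  for (cat in c("KMT2Ar", "RUNX1::RUNX1T1", "NPM1", "CEBPA")) {
    p <- prev[[cat]]
    got <- as.numeric(tab[cat]) / n
    expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n))
  }
  # conditional cooperating-mutation frequency: FLT3-ITD within HOXB
  km <- kept_pathogenic_mutations(co$mutations, n)
  hoxb <- co$truth$sample_id[co$truth$true_superfamily == "HOXB"]
  itd <- unique(km$sample_id[km$gene == "FLT3" & km$variant_class == "itd"])
  p_itd <- mean(hoxb %in% itd)
  expect_lt(abs(p_itd - 0.45), 3 * sqrt(0.45 * 0.55 / length(hoxb)))
})
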