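test_that("EFS coding: non-response at time 0, relapse/death as events", {
  cl <- rbind(
    make_clinical("S1", non_response = TRUE, efs_time = 3),
    make_clinical("S2", relapse = TRUE, efs_time = 1.2),
    make_clinical("S3", efs_time = 5))
  efs <- code_efs(cl)
  expect_equal(efs$time, c(0, 1.2, 5))
  expect_equal(efs$event, c(TRUE, TRUE, FALSE))
  expect_equal(unique(efs$endpoint), "EFS")
  expect_error(code_efs(make_clinical("S4", efs_time = -1)), "negative")
})

test_that("Kaplan-Meier estimate equals the hand-computed product limit", {
  # 6 records: events at 1, 2, 3, 5; censored at 1.5 and 4
  tm <- c(1, 1.5, 2, 3, 4, 5)
  ev <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  km <- km_estimate(tm, ev)
  expect_equal(km$surv[km$time == 0], 1)
  expect_equal(km_at(km, 1), 5 / 6)
  expect_equal(km_at(km, 2), 5 / 6 * 3 / 4)
  expect_equal(km_at(km, 3), 5 / 6 * 3 / 4 * 2 / 3)
  expect_equal(km_at(km, 5), 0)
  expect_equal(km_at(km, 10), 0)              # carry-forward
  expect_true(all(diff(km$surv) <= 0))        # non-increasing
  # drops only at event times
  expect_equal(km_at(km, 1.7), km_at(km, 1))
  # order-invariant
  o <- c(4, 2, 6, 1, 3, 5)
  expect_equal(km_estimate(tm[o], ev[o]), km)
})

test_that("all-censored data keep survival at one", {
  km <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(km$surv == 1))
  expect_equal(km_at(km_estimate(c(1, 2), c(TRUE, FALSE)), 1), 0.5)
  expect_error(km_estimate(numeric(), logical()), "no records")
})

test_that("log-rank: null on identical groups, powered under separation", {
  tm <- rep(c(1, 2, 3, 4), 2); ev <- rep(c(TRUE, TRUE, FALSE, TRUE), 2)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrank(tm, ev, g)
  expect_equal(lr$statistic, 0, tolerance = 1e-10)
  set.seed(14)
  t1 <- rexp(100, 0.1); t2 <- rexp(100, 1.0)
  cens <- runif(200, 0, 7)
  tt <- pmin(c(t1, t2), cens); ee <- c(t1, t2) <= cens
  lr2 <- logrank(tt, ee, rep(c("lo", "hi"), each = 100))
  expect_lt(lr2$p, 0.001)
  expect_equal(logrank(c(1, 2), c(FALSE, FALSE), c("a", "b"))$p, 1)
})

test_that("log-rank p agrees with a permutation reference", {
  set.seed(15)
  tm <- c(rexp(20, 0.2), rexp(20, 0.5)); gp <- rep(c("a", "b"), each = 20)
  cens <- runif(40, 0, 6)
  tt <- pmin(tm, cens); ee <- tm <= cens
  obs <- logrank(tt, ee, gp)
  perm <- replicate(600, logrank(tt, ee, sample(gp))$statistic)
  p_perm <- (1 + sum(perm >= obs$statistic)) / 601
  se <- sqrt(p_perm * (1 - p_perm) / 600)
  expect_lt(abs(p_perm - obs$p), 3 * se + 0.02)
})

test_that("survival tree recovers planted hazard groups", {
  set.seed(16)
  cats <- sprintf("C%d", 1:9)
  hz <- rep(c(0.05, 0.2, 0.6), each = 3)
  names(hz) <- cats
  n <- 600
  cat_i <- sample(cats, n, TRUE)
  t0 <- rexp(n, hz[cat_i]); cens <- runif(n, 0, 7)
  tt <- pmin(t0, cens); ee <- t0 <= cens
  tree <- fit_survival_tree(tt, ee, cat_i)
  grp <- tree$groups
  expect_equal(sort(unique(grp$risk_label)),
               sort(c("Low", "Intermediate", "High")))
  expect_setequal(grp$category[grp$risk_label == "Low"], c("C1", "C2", "C3"))
  expect_setequal(grp$category[grp$risk_label == "Intermediate"],
                  c("C4", "C5", "C6"))
  expect_setequal(grp$category[grp$risk_label == "High"],
                  c("C7", "C8", "C9"))
  expect_equal(unname(predict(tree, c("C1", "C5", "C9"))),
               c("Low", "Intermediate", "High"))
  # relabeling categories permutes leaves but not the partition
  relab <- c(C1 = "X1", C2 = "X2", C3 = "X3", C4 = "Y1", C5 = "Y2",
             C6 = "Y3", C7 = "Z1", C8 = "Z2", C9 = "Z3")
  tree2 <- fit_survival_tree(tt, ee, unname(relab[cat_i]))
  expect_setequal(tree2$groups$category[tree2$groups$risk_label == "High"],
                  c("Z1", "Z2", "Z3"))
})

test_that("a homogeneous cohort yields a single leaf", {
  set.seed(17)
  t0 <- rexp(100, 0.2); cens <- runif(100, 0, 7)
  tree <- fit_survival_tree(pmin(t0, cens), t0 <= cens,
                            sample(c("A", "B"), 100, TRUE))
  expect_equal(length(unique(tree$groups$leaf)), 1)
  expect_equal(unique(tree$groups$risk_label), "Intermediate")
})

test_that("the packaged risk mapping places the anchor categories", {
  expect_equal(map_risk_group("DEK::NUP214"), "Low")
  expect_equal(map_risk_group("KAT6Ar"), "High")
  expect_equal(map_risk_group("CBFB-GDXY"), "Low")
  expect_equal(map_risk_group(c("RUNX1::RUNX1T1", "CBFB::MYH11", "CEBPA")),
               rep("Low", 3))
  expect_equal(map_risk_group(c("GLISr", "MECOM", "PICALM::MLLT10")),
               rep("High", 3))
  expect_equal(map_risk_group("Unclassified"), "Intermediate")
  expect_error(map_risk_group("NOT_A_CATEGORY"), "unknown category")
})

test_that("the six strata are the full risk-by-MRD cross product", {
  grid <- expand.grid(risk = c("Low", "Intermediate", "High"),
                      mrd = c(FALSE, TRUE), stringsAsFactors = FALSE)
  strata <- assign_strata(grid$risk, grid$mrd)
  expect_equal(length(unique(strata)), 6)
  expect_equal(assign_strata("Low", FALSE), "Low/MRD-")
  expect_warning(s <- assign_strata("High", NA), "unknown MRD")
  expect_true(is.na(s))
  expect_error(assign_strata("Medium", TRUE), "unknown risk group")
})

test_that("stratify_cohort joins calls, MRD, and the endpoint", {
  co <- generate_cohort(seed = 19, n_samples = 120)
  calls <- classify_cohort(co)
  st <- suppressWarnings(stratify_cohort(calls, co$clinical,
                                         endpoint = "OS"))
  expect_equal(nrow(st), 120)
  expect_true(all(st$risk_group %in% c("Low", "Intermediate", "High")))
  known <- !is.na(st$stratum)
  expect_equal(st$stratum[known],
               paste0(st$risk_group[known], "/MRD",
                      ifelse(st$mrd_positive[known], "+", "-")))
  expect_equal(st$time, co$clinical$os_time[
    match(st$sample_id, co$clinical$sample_id)])
})
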