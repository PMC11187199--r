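cfg0 <- sp_config()

test_that("segment validity requires a channel strictly above 1 event/min", {
  expect_true(segment_is_valid(c(a = 2.0, b = 0.1), cfg0))
  expect_false(segment_is_valid(c(a = 0, b = 0), cfg0))
  expect_false(segment_is_valid(c(a = 1.0, b = 0.5), cfg0))
})

test_that("before-removal correlation uses the SOZ-constrained reference", {
  # noiseless power law from an SOZ source channel
  p <- power_law_patient(kappa = -1.5)
  r <- spmap:::segment_rates(p, "seg001")
  expect_equal(rho_before_removal(p, r, cfg0), -1, tolerance = 1e-9)
  # non-SOZ channel holds the top rate; reference must still be in the SOZ
  p2 <- toy_patient(rates = c(5, 4, 20, 2, 1, 0.5))  # c3 (non-SOZ) is max
  r2 <- spmap:::segment_rates(p2, "seg001")
  ref <- select_spatial_reference(r2, mask = spmap:::soz_ids(p2))
  expect_identical(ref, "c1")
  oracle <- build_spatial_system(p2, r2, "c1", cfg0)$rho
  expect_equal(rho_before_removal(p2, r2, cfg0), oracle)
  # 8-channel toy equals direct oracle arithmetic
  ids <- paste0("k", 1:8)
  ch <- data.frame(channel_id = ids, x_mm = c(0, 2, 5, 9, 14, 20, 27, 35),
                   y_mm = 0, z_mm = 0,
                   is_soz = c(TRUE, TRUE, rep(FALSE, 6)),
                   is_resected = FALSE, excluded = FALSE)
  rates <- c(6, 5, 3, 2.5, 1.2, 0.7, 0.3, 0.2)
  p3 <- sp_patient("oct", ch, matrix(rates, ncol = 1, dimnames = list(ids, "s1")))
  r3 <- spmap:::segment_rates(p3, "s1")
  d <- c(2, 5, 9, 14, 20, 27, 35)
  expect_equal(rho_before_removal(p3, r3, cfg0),
               pearson_brute(log(d), log(rates[-1])), tolerance = 1e-12)
})

test_that("after-removal applies the zero-substitution rule", {
  # all non-SOZ rates far below 1/min -> exactly 0
  p <- toy_patient(rates = c(10, 8, 0.2, 0.2, 0.2, 0.2))
  expect_identical(rho_after_removal(p, spmap:::segment_rates(p, "seg001"), cfg0), 0)
  # empty SOZ: removal is a no-op, equals unconstrained before-removal
  p2 <- toy_patient(rates = c(10, 8, 4, 2, 1.5, 0.5))
  p2$channels$is_soz <- FALSE
  r2 <- spmap:::segment_rates(p2, "seg001")
  ref <- select_spatial_reference(r2)
  expect_equal(rho_after_removal(p2, r2, cfg0),
               build_spatial_system(p2, r2, ref, cfg0)$rho)
  # fewer than 3 non-SOZ channels -> undefined flag
  p3 <- toy_patient()
  p3$channels$is_soz <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_true(is.na(rho_after_removal(p3, spmap:::segment_rates(p3, "seg001"), cfg0)))
})

test_that("SOZ removal perturbs an unstructured remainder more than the SOZ system", {
  # non-SOZ rates iid noise: |rho_AR| well below |rho_BR| in expectation
  set.seed(5)
  n_rep <- 200
  diff_sum <- 0
  for (i in 1:n_rep) {
    ids <- paste0("c", 1:12)
    d <- c(0, sort(runif(11, 2, 50)))
    ch <- data.frame(channel_id = ids, x_mm = d, y_mm = 0, z_mm = 0,
                     is_soz = c(TRUE, TRUE, rep(FALSE, 10)),
                     is_resected = FALSE, excluded = FALSE)
    rates <- c(30, 20, exp(rnorm(10, log(2), 0.4)))  # noise floor above validity
    p <- sp_patient("sim", ch, matrix(rates, ncol = 1, dimnames = list(ids, "s1")))
    r <- spmap:::segment_rates(p, "s1")
    diff_sum <- diff_sum + (abs(rho_before_removal(p, r, cfg0)) -
                              abs(rho_after_removal(p, r, cfg0)))
  }
  expect_gt(diff_sum / n_rep, 0.2)
})

test_that("random removal removes at least one channel and keeps exact lines exact", {
  p <- power_law_patient(kappa = -1.5, d = c(1, 2, 4, 8, 16, 32, 64))
  r <- spmap:::segment_rates(p, "seg001")
  # rr_fraction * N_SOZ rounds to 0 -> floor of one removed channel
  cfg_small <- sp_config(rr_fraction = 0.2, rr_iterations = 5)
  set.seed(1)
  expect_equal(rho_random_removal(p, r, cfg_small), -1, tolerance = 1e-9)
  # subsetting an exact line never changes the correlation
  cfg_many <- sp_config(rr_iterations = 50)
  set.seed(2)
  expect_equal(rho_random_removal(p, r, cfg_many), -1, tolerance = 1e-9)
})

test_that("perturbation strength follows the capped log-ratio definition", {
  expect_equal(perturbation_strength(-0.3, -0.3, cfg0), log(2), tolerance = 1e-12)
  # printed example correlations: -0.50 / 0.04 with nu = 1 -> log(13.5)
  expect_equal(perturbation_strength(-0.50, 0.04, cfg0), log(13.5), tolerance = 1e-12)
  # zero-substituted denominator: ratio capped at |br| / 1e-6
  expect_equal(perturbation_strength(-0.5, 0, cfg0), log(1 + 0.5e6), tolerance = 1e-12)
  expect_equal(perturbation_strength(0, 0, cfg0), log(1))
  # monotone in |rho_br| for fixed nonzero rho_ar
  s <- sapply(seq(0.05, 0.95, by = 0.05), function(b)
    perturbation_strength(-b, -0.4, cfg0))
  expect_true(all(diff(s) > 0))
})

test_that("patient-level medians equal hand-computed segment medians", {
  # three segments with hand-set rates; medians computed independently
  ids <- paste0("c", 1:6)
  ch <- data.frame(channel_id = ids, x_mm = c(0, 1, 2, 4, 8, 16), y_mm = 0, z_mm = 0,
                   is_soz = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                   is_resected = FALSE, excluded = FALSE)
  m <- cbind(s1 = c(10, 8, 4, 2, 1.5, 0.5),
             s2 = c(12, 7, 5, 2.5, 1.2, 0.4),
             s3 = c(9, 8.5, 3.5, 2.2, 1.8, 0.6))
  rownames(m) <- ids
  p <- sp_patient("tri", ch, m)
  cfg <- sp_config(rr_iterations = 20, rng_seed = 3)
  res <- patient_perturbation(p, cfg)
  br <- sapply(colnames(m), function(s)
    rho_before_removal(p, spmap:::segment_rates(p, s), cfg))
  ar <- sapply(colnames(m), function(s)
    rho_after_removal(p, spmap:::segment_rates(p, s), cfg))
  expect_equal(res$rho_br, median(br))
  expect_equal(res$rho_ar, median(ar))
  expect_equal(res$strength, perturbation_strength(median(br), median(ar), cfg))
  expect_equal(res$n_valid_segments, 3L)
  # single segment: medians are the segment values
  p1 <- sp_patient("uni", ch, m[, 1, drop = FALSE])
  res1 <- patient_perturbation(p1, cfg)
  expect_equal(res1$rho_br, unname(br[1]))
  # median robustness: replacing one of three segments with an outlier moves
  # the median only to a neighbouring observed value, never to the outlier
  out_med <- median(c(br[1], br[2], 0.9))
  expect_true(out_med %in% c(br[1], br[2]))
})

test_that("threshold selection separates, calls and reports correctly", {
  st <- c(p1 = 2, p2 = 2, p3 = 0.1, p4 = 0.1)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  rep <- choose_threshold(st, lab, n_boot = 50, seed = 1)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  expect_equal(rep$auc, 1)
  expect_identical(unname(rep$calls),
                   c("well_sampled", "well_sampled", "poorly_sampled", "poorly_sampled"))
  # fixed literature-scale threshold: 1.40 is called well, 0.99 poorly
  expect_identical(ifelse(c(1.40, 0.99) >= 1.20, "well_sampled", "poorly_sampled"),
                   c("well_sampled", "poorly_sampled"))
  expect_error(choose_threshold(c(1, 2), c(TRUE, TRUE), n_boot = 10), "both")
})

test_that("random labels give chance-level AUC", {
  set.seed(21)
  st <- runif(60)
  lab <- rep(c(TRUE, FALSE), 30)
  rep <- choose_threshold(st, lab, n_boot = 200, seed = 2)
  expect_gt(rep$auc, 0.3)
  expect_lt(rep$auc, 0.7)
  expect_true(rep$auc_ci[1] <= 0.5 && rep$auc_ci[2] >= 0.4)
})

test_that("Cliff's delta matches exhaustive enumeration", {
  expect_equal(cliffs_delta(c(3, 4), c(1, 2)), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffs_delta(c(1, 3), 2), 0)
  set.seed(13)
  for (i in 1:50) {
    x <- sample(-3:3, sample(1:6, 1), replace = TRUE)
    y <- sample(-3:3, sample(1:6, 1), replace = TRUE)
    ref <- 0
    for (xi in x) for (yj in y) ref <- ref + sign(xi - yj)
    expect_equal(cliffs_delta(x, y), ref / (length(x) * length(y)))
  }
  expect_error(cliffs_delta(numeric(0), 1), "non-empty")
})
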