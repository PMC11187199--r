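# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# a small patient with channels on a line at known distances from "c1"
# and hand-set rates; flags chosen so each framework has work to do
toy_patient <- function(rates = NULL, n_segments = 1) {
  ids <- paste0("c", 1:6)
  coords <- cbind(x_mm = c(0, 1, 2, 4, 8, 16), y_mm = 0, z_mm = 0)
  if (is.null(rates)) rates <- c(10, 8, 4, 2, 1, 0.5)
  m <- matrix(rep(rates, n_segments), ncol = n_segments,
              dimnames = list(ids, sprintf("seg%03d", seq_len(n_segments))))
  ch <- data.frame(channel_id = ids, coords,
                   is_soz = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                   is_resected = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                   excluded = FALSE)
  sp_patient("toy", ch, m)
}

# noiseless exact power-law patient: rates = alpha * d^kappa measured from a
# reference channel at the origin, channels along a line
power_law_patient <- function(alpha = 5, kappa = -1.5,
                              d = c(1, 2, 4, 8, 16, 32), peak = 50) {
  ids <- c("ref", paste0("c", seq_along(d)))
  coords <- cbind(x_mm = c(0, d), y_mm = 0, z_mm = 0)
  rates <- c(peak, alpha * d^kappa)
  m <- matrix(rates, ncol = 1, dimnames = list(ids, "seg001"))
  ch <- data.frame(channel_id = ids, coords,
                   is_soz = c(TRUE, rep(FALSE, length(d))),
                   is_resected = FALSE, excluded = FALSE)
  sp_patient("pl", ch, m)
}

# independent brute-force Pearson correlation (direct summation oracle)
pearson_brute <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# independent brute-force OLS slope/intercept
ols_brute <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - b * mx, slope = b)
}

# small seeded synthetic cohort reused by map/model tests (cached per session)
.test_cohort_cache <- new.env(parent = emptyenv())
test_cohort <- function(n_well = 10, n_poor = 10, seed = 11) {
  key <- paste(n_well, n_poor, seed, sep = "_")
  if (is.null(.test_cohort_cache[[key]])) {
    .test_cohort_cache[[key]] <- generate_cohort(n_well, n_poor,
                                                 sp_config(rng_seed = seed))
  }
  .test_cohort_cache[[key]]
}
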