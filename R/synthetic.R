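#' Synthetic SEEG implantation geometry
#'
#' Generates straight-line depth-electrode trajectories: each electrode aims
#' at a random interior target (within 25 mm of the template origin) from a
#' random direction, with equally spaced contacts running outward from the
#' deepest contact. Bipolar channels are located at the midpoints of
#' consecutive contacts. Uses the current RNG stream.
#'
#' @param n_electrodes Number of electrodes.
#' @param contacts_per_electrode Contacts per electrode.
#' @param spacing_mm Center-to-center contact spacing (mm).
#' @return A data.frame with \code{channel_id}, \code{x_mm}, \code{y_mm},
#'   \code{z_mm} for the bipolar channels (\code{(contacts - 1)} per
#'   electrode).
#' @export
generate_implantation <- function(n_electrodes = 12, contacts_per_electrode = 12,
                                  spacing_mm = 3.5) {
  stopifnot(n_electrodes >= 1, contacts_per_electrode >= 2, spacing_mm > 0)
  out <- vector("list", n_electrodes)
  for (e in seq_len(n_electrodes)) {
    target <- runif_ball(25)
    u <- random_unit()
    contacts <- t(vapply(seq_len(contacts_per_electrode) - 1L,
                         function(j) target + j * spacing_mm * u, numeric(3)))
    mids <- (contacts[-nrow(contacts), , drop = FALSE] +
               contacts[-1, , drop = FALSE]) / 2
    out[[e]] <- data.frame(
      channel_id = sprintf("E%02d-%02d", e, seq_len(nrow(mids))),
      x_mm = mids[, 1], y_mm = mids[, 2], z_mm = mids[, 3],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

runif_ball <- function(radius) {
  random_unit() * radius * stats::runif(1)^(1 / 3)
}

#' Synthetic epileptic-focus scenario
#'
#' Describes the generative ground truth of one synthetic patient: a focal
#' generator whose expected biomarker rate decays as a power law of distance,
#' \eqn{\lambda(d) = \alpha \, \max(d, 1\,mm)^{\kappa}}, optionally
#' accompanied by secondary propagation islands with their own (smaller) rate
#' scales. Per-channel multiplicative log-normal factors model stable
#' channel-to-channel variability of excitability; Poisson counting noise is
#' added per segment.
#'
#' @param kind One of \code{"well_sampled"}, \code{"poorly_sampled_missed"},
#'   \code{"poorly_sampled_propagation"}.
#' @param source Length-3 coordinate (mm) of the primary generator.
#' @param secondary_sources Optional matrix (k x 3) of propagation-island
#'   coordinates.
#' @param alpha Rate scale of the primary source (events/min at 1 mm).
#' @param secondary_alpha Rate scales for the secondary sources.
#' @param kappa Decay exponent (< 0).
#' @param noise_sigma Log-normal sigma of the per-channel factor.
#' @param soz_radius_mm Radius defining ground-truth SOZ membership.
#' @return An object of class \code{sp_scenario}.
#' @export
sp_scenario <- function(kind = c("well_sampled", "poorly_sampled_missed",
                                 "poorly_sampled_propagation"),
                        source, secondary_sources = NULL,
                        alpha = 20, secondary_alpha = NULL,
                        kappa = -1.5, noise_sigma = 0.3, soz_radius_mm = 14) {
  kind <- match.arg(kind)
  stopifnot(kappa < 0, noise_sigma >= 0, alpha > 0, length(source) == 3)
  if (!is.null(secondary_sources)) {
    secondary_sources <- matrix(as.numeric(secondary_sources), ncol = 3)
    if (is.null(secondary_alpha)) secondary_alpha <- rep(alpha / 4, nrow(secondary_sources))
    stopifnot(length(secondary_alpha) == nrow(secondary_sources))
  }
  structure(list(kind = kind, source = as.numeric(source),
                 secondary_sources = secondary_sources,
                 alpha = alpha, secondary_alpha = secondary_alpha,
                 kappa = kappa, noise_sigma = noise_sigma,
                 soz_radius_mm = soz_radius_mm),
            class = "sp_scenario")
}

#' Expected event rates under a scenario
#'
#' The expected rate of a channel is the strongest contribution over all
#' active sources, \eqn{\max_s \alpha_s \max(d_s, 1)^{\kappa}}, with a 1 mm
#' distance floor to avoid divergence at the source.
#'
#' @param coords Channel coordinate matrix (n x 3) with rownames.
#' @param scenario An \code{\link{sp_scenario}}.
#' @return Named vector of expected rates (events/min).
#' @export
expected_rates <- function(coords, scenario) {
  coords <- as.matrix(coords)
  src <- rbind(scenario$source, scenario$secondary_sources)
  alphas <- c(scenario$alpha, scenario$secondary_alpha)
  lam <- rep(0, nrow(coords))
  for (s in seq_len(nrow(src))) {
    d <- pmax(sqrt(rowSums(sweep(coords, 2, src[s, ])^2)), 1)
    lam <- pmax(lam, alphas[s] * d^scenario$kappa)
  }
  stats::setNames(lam, rownames(coords))
}

#' Generate per-segment event rates
#'
#' Draws a shared per-channel log-normal factor (stable across segments, so
#' that segment medians estimate a stable spatial field) and, per segment,
#' Poisson event counts with mean \eqn{\lambda_i \cdot g_i \cdot} minutes.
#' Rates are counts divided by segment duration. Uses the current RNG
#' stream. With \code{segment_minutes = Inf} the Poisson counting noise
#' vanishes and the rate equals its expectation times the channel factor.
#'
#' @inheritParams expected_rates
#' @param n_segments Number of 10-min segments.
#' @param segment_minutes Segment duration in minutes.
#' @return Rate matrix (channels x segments, events/min).
#' @export
generate_rates <- function(coords, scenario, n_segments = 5, segment_minutes = 10) {
  lam <- expected_rates(coords, scenario)
  g <- exp(stats::rnorm(length(lam), 0, scenario$noise_sigma))
  mu <- lam * g
  rates <- matrix(0, nrow = length(lam), ncol = n_segments,
                  dimnames = list(names(lam), sprintf("seg%03d", seq_len(n_segments))))
  for (j in seq_len(n_segments)) {
    rates[, j] <- if (is.infinite(segment_minutes)) mu else
      stats::rpois(length(mu), mu * segment_minutes) / segment_minutes
  }
  rates
}

#' Generate a synthetic SEEG cohort with ground-truth sampling quality
#'
#' Builds seeded synthetic patients in three scenarios. Well-sampled: the
#' generator sits on the implantation (at a randomly chosen channel, jittered)
#' and the measured SOZ is the set of channels within
#' \code{soz_radius_mm} of it (at least 3 by construction). Poorly-sampled
#' missed-focus: the generator lies at least \code{exclusion_mm} from every
#' channel, so the implantation records only its shallow far-field (rescaled
#' so the peak in-implantation rate stays clinically plausible); the measured
#' SOZ is marked around the maximum-rate channel, emulating clinical marking
#' of apparent onset. Poorly-sampled propagation: in addition to the missed
#' generator, two propagation islands 25-50 mm from it coincide with sampled
#' channels and fire at 20-50% of the primary scale. Outcome labels are
#' seizure-free for well-sampled and non-seizure-free otherwise.
#'
#' @param n_well,n_poor Patient counts per class; poor patients alternate
#'   missed-focus and propagation scenarios.
#' @param cfg An \code{\link{sp_config}}; \code{cfg$rng_seed} makes the
#'   cohort reproducible.
#' @param n_electrodes,contacts_per_electrode,spacing_mm Implantation
#'   geometry.
#' @param n_segments,segment_minutes Recording segmentation.
#' @param alpha,kappa,noise_sigma,soz_radius_mm Scenario parameters (see
#'   \code{\link{sp_scenario}}).
#' @param exclusion_mm Minimum distance from the missed generator to any
#'   channel.
#' @param missed_peak_rate Peak expected in-implantation rate (events/min)
#'   for far-source scenarios.
#' @return List of \code{sp_patient} objects, each with a
#'   \code{ground_truth} element (\code{scenario}, \code{kind},
#'   \code{true_soz}).
#' @export
generate_cohort <- function(n_well = 20, n_poor = 20, cfg = sp_config(),
                            n_electrodes = 12, contacts_per_electrode = 12,
                            spacing_mm = 3.5,
                            n_segments = 5, segment_minutes = 10,
                            alpha = 20, kappa = -1.5, noise_sigma = 0.3,
                            soz_radius_mm = 14, exclusion_mm = 25,
                            missed_peak_rate = 6) {
  stopifnot(n_well >= 0, n_poor >= 0)
  kinds <- c(rep("well_sampled", n_well),
             rep(c("poorly_sampled_missed", "poorly_sampled_propagation"),
                 length.out = n_poor))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  patients <- vector("list", length(kinds))
  for (i in seq_along(kinds)) {
    pid <- sprintf("S%03d", i)
    set.seed(derive_seed(cfg$rng_seed, paste0("synth:", pid, ":", kinds[i])))
    patients[[i]] <- generate_patient(
      pid, kinds[i],
      n_electrodes = n_electrodes,
      contacts_per_electrode = contacts_per_electrode,
      spacing_mm = spacing_mm, n_segments = n_segments,
      segment_minutes = segment_minutes, alpha = alpha, kappa = kappa,
      noise_sigma = noise_sigma, soz_radius_mm = soz_radius_mm,
      exclusion_mm = exclusion_mm, missed_peak_rate = missed_peak_rate)
  }
  patients
}

# one synthetic patient under the current RNG stream
generate_patient <- function(patient_id, kind, n_electrodes, contacts_per_electrode,
                             spacing_mm, n_segments, segment_minutes,
                             alpha, kappa, noise_sigma, soz_radius_mm,
                             exclusion_mm, missed_peak_rate) {
  geom <- generate_implantation(n_electrodes, contacts_per_electrode, spacing_mm)
  coords <- as.matrix(geom[, c("x_mm", "y_mm", "z_mm")])
  rownames(coords) <- geom$channel_id

  if (kind == "well_sampled") {
    # the generator sits amid the electrodes (inner half of the channel
    # cloud: an exploration is designed around the suspected focus);
    # guarantee >= 3 SOZ channels
    ctr <- colMeans(coords)
    d_ctr <- sqrt(rowSums(sweep(coords, 2, ctr)^2))
    core <- which(d_ctr <= stats::median(d_ctr))
    for (try in 1:50) {
      src <- coords[sample(core, 1), ] + stats::rnorm(3, 0, 2)
      d <- sqrt(rowSums(sweep(coords, 2, src)^2))
      if (sum(d <= soz_radius_mm) >= 3) break
    }
    scen <- sp_scenario(kind, source = src, alpha = alpha, kappa = kappa,
                        noise_sigma = noise_sigma, soz_radius_mm = soz_radius_mm)
  } else {
    # generator beyond the implantation margin
    ctr <- colMeans(coords)
    for (try in 1:100) {
      src <- ctr + random_unit() * (max(sqrt(rowSums(sweep(coords, 2, ctr)^2))) +
                                      stats::runif(1, exclusion_mm, exclusion_mm + 25))
      d <- sqrt(rowSums(sweep(coords, 2, src)^2))
      if (min(d) >= exclusion_mm) break
    }
    # far-field rescaling keeps the recorded peak clinically plausible
    a_eff <- missed_peak_rate / max(pmax(d, 1)^kappa)
    if (kind == "poorly_sampled_propagation") {
      # two sampled propagation islands 25-50 mm from the generator
      cand <- which(d >= 25 & d <= 50)
      if (length(cand) < 2) cand <- order(abs(d - 37.5))[1:2]
      isl <- coords[sample(cand, 2), , drop = FALSE] +
        matrix(stats::rnorm(6, 0, 2), 2, 3)
      sec_alpha <- stats::runif(2, 0.2, 0.5) * alpha
      scen <- sp_scenario(kind, source = src, secondary_sources = isl,
                          alpha = a_eff, secondary_alpha = sec_alpha,
                          kappa = kappa, noise_sigma = noise_sigma,
                          soz_radius_mm = soz_radius_mm)
    } else {
      scen <- sp_scenario(kind, source = src, alpha = a_eff, kappa = kappa,
                          noise_sigma = noise_sigma, soz_radius_mm = soz_radius_mm)
    }
  }

  rates <- generate_rates(coords, scen, n_segments, segment_minutes)

  # measured SOZ: around the true generator when sampled, otherwise around
  # the apparent (maximum expected rate) channel, as a clinician would mark
  d_src <- sqrt(rowSums(sweep(coords, 2, scen$source)^2))
  true_soz <- rownames(coords)[d_src <= soz_radius_mm]
  if (kind == "well_sampled") {
    soz <- true_soz
  } else {
    lam <- expected_rates(coords, scen)
    apex <- coords[which.max(lam), ]
    d_apex <- sqrt(rowSums(sweep(coords, 2, apex)^2))
    soz <- rownames(coords)[d_apex <= soz_radius_mm]
  }

  channels <- data.frame(
    channel_id = geom$channel_id,
    x_mm = geom$x_mm, y_mm = geom$y_mm, z_mm = geom$z_mm,
    is_soz = geom$channel_id %in% soz,
    is_resected = geom$channel_id %in% soz,
    excluded = FALSE,
    stringsAsFactors = FALSE)

  p <- sp_patient(patient_id, channels, rates,
                  segment_minutes = if (is.infinite(segment_minutes)) 10 else segment_minutes,
                  outcome = if (kind == "well_sampled") "seizure_free" else "non_seizure_free")
  p$ground_truth <- list(scenario = scen, kind = kind, true_soz = true_soz)
  p
}
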