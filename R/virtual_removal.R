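#' Segment validity
#'
#' A 10-min segment enters the analysis only if at least one channel fired
#' more than \code{cfg$min_events_per_min} events per minute (strictly), i.e.
#' the segment contains enough interictal activity to support a spatial
#' system.
#'
#' @param rates Named rate vector for the segment (events/min).
#' @param cfg An \code{\link{sp_config}}.
#' @return Logical scalar.
#' @export
segment_is_valid <- function(rates, cfg = sp_config()) {
  length(rates) > 0 && max(rates) > cfg$min_events_per_min
}

#' Spatial coupling before removal of the SOZ
#'
#' The spatial reference is the maximum-rate channel constrained to the SOZ,
#' and the system is built over all included channels. Constraining the
#' reference to the SOZ guarantees that removing the SOZ perturbs the system.
#'
#' @inheritParams segment_is_valid
#' @param patient An \code{sp_patient}.
#' @return Pearson correlation of the log-log system (\code{NA} if undefined).
#' @export
rho_before_removal <- function(patient, rates, cfg = sp_config()) {
  soz <- soz_ids(patient)
  if (length(soz) == 0) stop("patient ", patient$patient_id, " has no SOZ channels")
  ref <- select_spatial_reference(rates, mask = soz)
  build_spatial_system(patient, rates, ref, cfg)$rho
}

#' Spatial coupling after virtual removal of the SOZ
#'
#' All SOZ channels are deleted, the spatial reference is recomputed as the
#' maximum-rate channel among the remainder, and the correlation is
#' recomputed. If every remaining channel's rate is below
#' \code{cfg$min_events_per_min} the correlation is set to exactly zero:
#' below that rate the system is noise-dominated and produces spurious
#' correlations. With an empty SOZ the call degenerates to an unconstrained
#' before-removal system.
#'
#' @inheritParams rho_before_removal
#' @return Correlation, the zero-substituted value, or \code{NA} when fewer
#'   than 3 non-SOZ channels remain.
#' @export
rho_after_removal <- function(patient, rates, cfg = sp_config()) {
  soz <- soz_ids(patient)
  remaining <- rates[setdiff(names(rates), soz)]
  if (length(remaining) < 3) return(NA_real_)
  if (max(remaining) < cfg$min_events_per_min) return(0)
  ref <- select_spatial_reference(remaining)
  build_spatial_system(patient, remaining, ref, cfg)$rho
}

#' Spatial coupling after random removal of non-SOZ channels
#'
#' Control condition: instead of the SOZ, a random subset of non-SOZ channels
#' of size \code{round(cfg$rr_fraction * N_SOZ)} (at least 1) is removed per
#' iteration, the SOZ-constrained system is recomputed, and the median over
#' \code{cfg$rr_iterations} iterations is returned. If random removal leaves
#' the coupling intact while SOZ removal destroys it, the perturbation is
#' attributable to the SOZ, not to the reduction in channel count.
#'
#' @inheritParams rho_before_removal
#' @return Median correlation over iterations (\code{NA} if never defined).
#' @export
rho_random_removal <- function(patient, rates, cfg = sp_config()) {
  soz <- soz_ids(patient)
  non_soz <- setdiff(names(rates), soz)
  if (length(non_soz) < 1) stop("no removable non-SOZ channels")
  n_rm <- min(max(1L, round(cfg$rr_fraction * length(soz))), length(non_soz))
  ref_mask <- soz
  out <- vapply(seq_len(cfg$rr_iterations), function(i) {
    removed <- sample(non_soz, n_rm)
    kept <- rates[setdiff(names(rates), removed)]
    ref <- select_spatial_reference(kept, mask = ref_mask)
    build_spatial_system(patient, kept, ref, cfg)$rho
  }, numeric(1))
  stats::median(out, na.rm = TRUE)
}

#' Perturbation strength
#'
#' The absolute logarithmic ratio of the median correlation before and after
#' SOZ removal, \eqn{\hat\rho = \log(\nu + |\bar\rho_{BR} / \bar\rho_{AR}|)}.
#' The offset \eqn{\nu > 0} keeps the logarithm defined when the ratio is
#' zero; because the log is monotone, the choice of \eqn{\nu} changes values
#' but never the ranking of patients. When the after-removal correlation is
#' exactly zero (the zero-substitution rule) and the before-removal one is
#' not, the ratio is capped at 1e6 so the strength stays finite.
#'
#' @param rho_br,rho_ar Median correlations before/after removal.
#' @param cfg An \code{\link{sp_config}} (supplies \code{nu}).
#' @return Non-negative perturbation strength (natural-log scale).
#' @export
perturbation_strength <- function(rho_br, rho_ar, cfg = sp_config()) {
  if (is.na(rho_br) || is.na(rho_ar)) return(NA_real_)
  if (rho_ar == 0) {
    ratio <- if (rho_br == 0) 0 else abs(rho_br) / 1e-6
  } else {
    ratio <- abs(rho_br / rho_ar)
  }
  log(cfg$nu + ratio)
}

#' Virtual-removal perturbation analysis of one patient
#'
#' Runs the before-removal, after-removal and random-removal correlations on
#' every valid segment, takes the per-patient median of each, and computes
#' the perturbation strength from the medians.
#'
#' @param patient An \code{sp_patient}.
#' @param cfg An \code{\link{sp_config}}; \code{cfg$rng_seed} seeds the
#'   random-removal stream (one independent stream per patient).
#' @return An object of class \code{sp_perturbation}: per-segment correlation
#'   vectors, their medians \code{rho_br}, \code{rho_ar}, \code{rho_rr}, the
#'   \code{strength}, and \code{n_valid_segments}.
#' @export
patient_perturbation <- function(patient, cfg = sp_config()) {
  segs <- colnames(patient$rates)
  valid <- segs[vapply(segs, function(s) segment_is_valid(segment_rates(patient, s), cfg),
                       logical(1))]
  if (length(valid) == 0) stop("patient ", patient$patient_id, " has no valid segments")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$rng_seed, paste0("rr:", patient$patient_id)))

  br <- ar <- rr <- stats::setNames(numeric(length(valid)), valid)
  for (s in valid) {
    r <- segment_rates(patient, s)
    br[s] <- rho_before_removal(patient, r, cfg)
    ar[s] <- rho_after_removal(patient, r, cfg)
    rr[s] <- rho_random_removal(patient, r, cfg)
  }
  rho_br <- stats::median(br, na.rm = TRUE)
  rho_ar <- stats::median(ar, na.rm = TRUE)
  rho_rr <- stats::median(rr, na.rm = TRUE)
  structure(list(patient_id = patient$patient_id,
                 rho_br_per_segment = br, rho_ar_per_segment = ar,
                 rho_rr_per_segment = rr,
                 rho_br = rho_br, rho_ar = rho_ar, rho_rr = rho_rr,
                 strength = perturbation_strength(rho_br, rho_ar, cfg),
                 n_valid_segments = length(valid)),
            class = "sp_perturbation")
}

#' @export
print.sp_perturbation <- function(x, ...) {
  cat(sprintf("<sp_perturbation> %s: rho_br %.3f, rho_ar %.3f, rho_rr %.3f, strength %.3f (%d segments)\n",
              x$patient_id, x$rho_br, x$rho_ar, x$rho_rr, x$strength,
              x$n_valid_segments))
  invisible(x)
}

#' ROC threshold on the perturbation strength
#'
#' Sweeps every observed strength as a candidate threshold (a patient is
#' called well-sampled when \eqn{\hat\rho \ge} threshold), selects the
#' operating point maximizing Youden's J (sensitivity + specificity - 1,
#' ties resolved toward higher sensitivity), and reports sensitivity,
#' specificity and the AUC with a bootstrap confidence interval.
#'
#' @param strengths Named numeric vector of per-patient perturbation
#'   strengths.
#' @param labels Logical or factor vector: \code{TRUE}/\code{"seizure_free"}
#'   marks the positive (well-sampled surrogate) class.
#' @param n_boot Bootstrap resamples for the AUC confidence interval
#'   (default 1000).
#' @param seed Seed for the bootstrap stream.
#' @return A list of class \code{sp_classification}: \code{threshold},
#'   \code{sensitivity}, \code{specificity}, \code{auc}, \code{auc_ci}
#'   (2.5/97.5 percentiles) and \code{calls} (named character vector,
#'   \code{"well_sampled"} / \code{"poorly_sampled"}).
#' @export
choose_threshold <- function(strengths, labels, n_boot = 1000L, seed = 1L) {
  pos <- if (is.logical(labels)) labels else labels %in% c("seizure_free", "well_sampled", "TRUE")
  if (length(unique(pos)) < 2) stop("both outcome classes must be present")
  cand <- sort(unique(strengths))
  best <- NULL
  for (th in cand) {
    call_pos <- strengths >= th
    tp <- sum(call_pos & pos); fn <- sum(!call_pos & pos)
    tn <- sum(!call_pos & !pos); fp <- sum(call_pos & !pos)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sensitivity)) {
      best <- list(j = j, threshold = th, sensitivity = sens, specificity = spec)
    }
  }
  roc_obj <- pROC::roc(response = pos, predictor = strengths,
                       levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc_obj))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "auc-boot"))
  n <- length(strengths)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(pos[idx])) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = pos[idx], predictor = strengths[idx],
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  }, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  calls <- ifelse(strengths >= best$threshold, "well_sampled", "poorly_sampled")
  names(calls) <- names(strengths)
  structure(list(threshold = best$threshold,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 auc = auc, auc_ci = ci, calls = calls),
            class = "sp_classification")
}

#' @export
print.sp_classification <- function(x, ...) {
  cat(sprintf("<sp_classification> threshold %.3f: sensitivity %.2f, specificity %.2f, AUC %.3f [%.3f, %.3f]\n",
              x$threshold, x$sensitivity, x$specificity, x$auc,
              x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' Cliff's delta effect size
#'
#' Nonparametric effect size: the probability that a value from \code{x}
#' exceeds one from \code{y} minus the converse, computed over all pairs.
#'
#' @param x,y Numeric samples.
#' @return Value in [-1, 1].
#' @examples
#' cliffs_delta(c(3, 4), c(1, 2)) # complete dominance -> 1
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  mean(sign(outer(x, y, "-")))
}

# save/restore the global RNG state so seeded internals do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
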