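#' Run the full spatial-perturbation pipeline on a cohort
#'
#' Orchestrates the complete analysis: per patient, the virtual-removal
#' perturbation (when SOZ flags are present) and the ranked SP map with its
#' quadrant features; across the cohort, the bootstrapped cluster model with
#' per-patient adequacy probabilities and calls, the perturbation-strength
#' ROC threshold (when both outcome classes are present), and channel-sphere
#' volumetrics (when resection flags are present). Per-patient stage errors
#' are collected and reported at the end without aborting the run. All
#' randomness derives from \code{cfg$rng_seed}, so reruns are byte-identical.
#'
#' @param patients List of \code{sp_patient}.
#' @param cfg An \code{\link{sp_config}}.
#' @param out_dir Optional directory; when given, result tables
#'   (\code{patients.tsv}), the cluster model (\code{model.json}), the
#'   classification report (\code{classification.json}) and a run manifest
#'   (\code{manifest.json}) are written there.
#' @return A list of class \code{sp_run}: \code{results} (per-patient
#'   data.frame), \code{perturbations}, \code{ranked}, \code{features},
#'   \code{model}, \code{classification}, \code{volumes}, \code{errors},
#'   \code{manifest}.
#' @export
run_pipeline <- function(patients, cfg = sp_config(), out_dir = NULL) {
  stopifnot(length(patients) >= 1)
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  errors <- list()
  note <- function(pid, stage, e) {
    errors[[length(errors) + 1]] <<- list(patient_id = pid, stage = stage,
                                          message = conditionMessage(e))
    message("  [", pid, "] ", stage, " skipped: ", conditionMessage(e))
    NULL
  }

  message("spatial-perturbation pipeline: ", length(patients), " patients")
  perturbations <- ranked <- vols <- stats::setNames(vector("list", length(ids)), ids)
  features <- list()
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    n_seg <- sum(vapply(colnames(p$rates), function(s)
      segment_is_valid(segment_rates(p, s), cfg), logical(1)))
    message(sprintf("  [%s] %d/%d valid segments, %d excluded channels",
                    p$patient_id, n_seg, ncol(p$rates), sum(p$channels$excluded)))
    if (any(p$channels$is_soz & !p$channels$excluded)) {
      perturbations[[i]] <- tryCatch(patient_perturbation(p, cfg),
                                     error = function(e) note(p$patient_id, "virtual_removal", e))
    } else {
      message("  [", p$patient_id, "] virtual_removal skipped: no SOZ flags")
    }
    ranked[[i]] <- tryCatch(patient_ranked_map(p, cfg),
                            error = function(e) note(p$patient_id, "ranked_map", e))
    if (!is.null(ranked[[i]])) {
      features[[p$patient_id]] <- tryCatch(
        quadrant_features(ranked[[i]]$map, patient_id = p$patient_id),
        error = function(e) note(p$patient_id, "features", e))
    }
    if (any(p$channels$is_resected)) {
      vols[[i]] <- tryCatch(patient_volumes(p, cfg),
                            error = function(e) note(p$patient_id, "volumes", e))
    }
  }

  features <- Filter(Negate(is.null), features)
  model <- NULL
  if (length(features) >= 6) {
    labels <- stats::setNames(vapply(patients, function(p) p$outcome, character(1)),
                              ids)[names(features)]
    model <- tryCatch(
      fit_cluster_model(features, cfg,
                        labels = if (all(is.na(labels) | labels == "unknown")) NULL else labels),
      error = function(e) note("<cohort>", "cluster_model", e))
  }

  strengths <- vapply(perturbations, function(x)
    if (is.null(x)) NA_real_ else x$strength, numeric(1))
  outcomes <- vapply(patients, function(p) p$outcome, character(1))
  classification <- NULL
  has_both <- all(c("seizure_free", "non_seizure_free") %in% outcomes[!is.na(strengths)])
  if (has_both) {
    keep <- !is.na(strengths) & outcomes != "unknown"
    classification <- tryCatch(
      choose_threshold(strengths[keep], outcomes[keep] == "seizure_free",
                       seed = cfg$rng_seed),
      error = function(e) note("<cohort>", "classification", e))
  }

  results <- data.frame(
    patient_id = ids,
    outcome = outcomes,
    n_valid_segments = vapply(perturbations, function(x)
      if (is.null(x)) NA_integer_ else x$n_valid_segments, integer(1)),
    rho_br = vapply(perturbations, function(x)
      if (is.null(x)) NA_real_ else x$rho_br, numeric(1)),
    rho_ar = vapply(perturbations, function(x)
      if (is.null(x)) NA_real_ else x$rho_ar, numeric(1)),
    rho_rr = vapply(perturbations, function(x)
      if (is.null(x)) NA_real_ else x$rho_rr, numeric(1)),
    strength = strengths,
    stringsAsFactors = FALSE)
  if (!is.null(classification)) {
    results$call <- unname(classification$calls[match(ids, names(classification$calls))])
  }
  if (!is.null(model)) {
    results$p_adequate <- vapply(ids, function(pid) {
      f <- features[[pid]]
      if (is.null(f)) NA_real_ else probability_adequate(f, model)
    }, numeric(1))
    results$cluster_call <- vapply(ids, function(pid) {
      f <- features[[pid]]
      if (is.null(f)) NA_character_ else classify_by_cluster(f, model)
    }, character(1))
  }
  results$soz_cm3 <- vapply(vols, function(v)
    if (is.null(v)) NA_real_ else v$soz_cm3, numeric(1))
  results$resected_soz_cm3 <- vapply(vols, function(v)
    if (is.null(v)) NA_real_ else v$resected_soz_cm3, numeric(1))

  manifest <- list(
    package_version = as.character(utils::packageVersion("spmap")),
    rng_seed = cfg$rng_seed,
    n_patients = length(patients),
    config = unclass(cfg),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))

  run <- structure(list(results = results, perturbations = perturbations,
                        ranked = ranked, features = features, model = model,
                        classification = classification, volumes = vols,
                        errors = errors, manifest = manifest),
                   class = "sp_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  if (length(errors) > 0) {
    message(length(errors), " stage error(s) collected; see $errors")
  }
  run
}

# serialize the run products (tables + JSON; manifest timestamp excluded from
# tables so identical seeds give byte-identical results)
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run$results
  num <- vapply(res, is.numeric, logical(1))
  res[num] <- lapply(res[num], function(x) signif(x, 12))
  write_tsv(res, file.path(out_dir, "patients.tsv"))
  if (!is.null(run$model)) {
    jsonlite::write_json(
      list(c1_hat = run$model$c1_hat, c2_hat = run$model$c2_hat,
           t1 = run$model$t1, t2 = run$model$t2,
           features = run$model$features),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$classification)) {
    cl <- run$classification
    jsonlite::write_json(
      list(threshold = cl$threshold, sensitivity = cl$sensitivity,
           specificity = cl$specificity, auc = cl$auc,
           auc_ci = cl$auc_ci, calls = as.list(cl$calls)),
      file.path(out_dir, "classification.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run)
}

#' @export
print.sp_run <- function(x, ...) {
  cat(sprintf("<sp_run> %d patients, %d stage errors\n",
              nrow(x$results), length(x$errors)))
  print(utils::head(x$results, 10))
  invisible(x)
}
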