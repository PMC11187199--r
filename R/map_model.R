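#' Quadrant features of an SP map
#'
#' Splits the SP map image at its row and column midpoints into four
#' quadrants: Q1 top-left, Q2 top-right, Q3 bottom-right, Q4 bottom-left.
#' With this orientation a well-sampled patient's diagonal map loads on Q1
#' and Q3 and leaves Q2/Q4 nearly empty. Each feature is the mean of the
#' strictly positive pixels of its quadrant (0 if the quadrant has none),
#' so sparsity does not dilute the signal. The canonical 3-D feature vector
#' used for clustering is (q1, q2, q4); q3 is returned for completeness.
#'
#' @param map An \code{sp_map}.
#' @param patient_id Optional identifier carried along.
#' @return A list of class \code{sp_features} with \code{q1}..\code{q4} and
#'   \code{patient_id}.
#' @export
quadrant_features <- function(map, patient_id = NULL) {
  img <- map$image
  if (isTRUE(map$degenerate)) stop("degenerate SP map has no quadrant structure")
  rmid <- floor(nrow(img) / 2)
  cmid <- floor(ncol(img) / 2)
  pos_mean <- function(m) {
    v <- m[m > 0]
    if (length(v) == 0) 0 else mean(v)
  }
  structure(list(
    q1 = pos_mean(img[seq_len(rmid), seq_len(cmid), drop = FALSE]),
    q2 = pos_mean(img[seq_len(rmid), (cmid + 1):ncol(img), drop = FALSE]),
    q3 = pos_mean(img[(rmid + 1):nrow(img), (cmid + 1):ncol(img), drop = FALSE]),
    q4 = pos_mean(img[(rmid + 1):nrow(img), seq_len(cmid), drop = FALSE]),
    patient_id = patient_id
  ), class = "sp_features")
}

#' Feature matrix helper
#'
#' Stacks a list of \code{sp_features} into a numeric matrix with columns
#' \code{q1}, \code{q2}, \code{q3}, \code{q4} and rownames from patient ids.
#'
#' @param features List of \code{sp_features}.
#' @return Numeric matrix.
#' @export
feature_matrix <- function(features) {
  m <- t(vapply(features, function(f) c(f$q1, f$q2, f$q3, f$q4), numeric(4)))
  colnames(m) <- c("q1", "q2", "q3", "q4")
  rownames(m) <- vapply(features, function(f)
    if (is.null(f$patient_id)) "" else f$patient_id, character(1))
  m
}

#' Dunn's cluster-validity index
#'
#' Minimum between-cluster (single-linkage) distance divided by the maximum
#' within-cluster diameter. Higher is better: compact, well-separated
#' clusters. Returns \code{Inf} when every cluster has zero diameter.
#'
#' @param points Numeric matrix (rows = observations).
#' @param labels Cluster assignment vector (>= 2 non-empty clusters).
#' @return Positive value, possibly \code{Inf}.
#' @export
dunn_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.vector(labels)
  stopifnot(nrow(points) == length(labels), length(unique(labels)) >= 2)
  d <- as.matrix(stats::dist(points))
  same <- outer(labels, labels, "==")
  diag_mask <- diag(TRUE, nrow(d))
  within <- d[same & !diag_mask]
  between <- d[!same]
  diameter <- if (length(within) == 0) 0 else max(within)
  if (diameter == 0) return(Inf)
  min(between) / diameter
}

#' Select the quadrant feature subset maximizing Dunn's index
#'
#' Enumerates every subset of the four quadrant features of size >= 2, runs
#' 2-means on each subset, and returns the subset with the largest Dunn's
#' index. Ties favour the smaller subset, then lexicographic order. On
#' cohorts where the diagonal structure separates adequately sampled from
#' poorly sampled implantations, the selection lands on \{q1, q2, q4\}.
#'
#' @param features Numeric matrix with columns \code{q1}..\code{q4} (one row
#'   per patient; >= 4 patients) or a list of \code{sp_features}.
#' @param seed Seed for the k-means initializations.
#' @return Character vector of selected feature names.
#' @export
select_feature_subset <- function(features, seed = 1L) {
  if (is.list(features) && !is.matrix(features)) features <- feature_matrix(features)
  stopifnot(nrow(features) >= 4)
  quads <- c("q1", "q2", "q3", "q4")
  subsets <- list()
  for (k in 2:4) {
    cmb <- utils::combn(quads, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  best <- NULL
  for (sub in subsets) {
    x <- features[, sub, drop = FALSE]
    if (nrow(unique(x)) < 2) next
    set.seed(derive_seed(seed, paste(sub, collapse = "+")))
    km <- stats::kmeans(x, centers = 2, nstart = 10)
    di <- dunn_index(x, km$cluster)
    if (is.null(best) || di > best$di + 1e-12) {
      best <- list(di = di, sub = sub)
    }
  }
  if (is.null(best)) stop("degenerate features: no subset admits 2 clusters")
  best$sub
}

#' Fit the bootstrapped cluster model of implantation adequacy
#'
#' Runs \code{cfg$kmeans_bootstrap} iterations of 2-means, each on a random
#' \code{cfg$kmeans_subsample} fraction of patients (stratified by outcome
#' label when labels are available). The two centroids of each iteration are
#' matched to the running estimate by minimal total displacement and
#' averaged. The averaged centroid closer to the origin is \eqn{\hat c_1}
#' (adequate sampling: small off-diagonal quadrant means); the other is
#' \eqn{\hat c_2}. Location-scale Student-t distributions are then fit by
#' maximum likelihood to the within-cluster distances from each centroid,
#' backing the adequacy probability.
#'
#' @param features Numeric matrix of selected features (default columns
#'   \code{q1}, \code{q2}, \code{q4}) or list of \code{sp_features}.
#' @param cfg An \code{\link{sp_config}}.
#' @param labels Optional outcome labels for stratified subsampling.
#' @param columns Feature columns to use when \code{features} carries all
#'   four quadrants.
#' @return An object of class \code{sp_cluster_model}: \code{c1_hat},
#'   \code{c2_hat}, \code{t1}, \code{t2} (each \code{list(m, s, df)}),
#'   \code{features} (column names), \code{assignment}.
#' @export
fit_cluster_model <- function(features, cfg = sp_config(), labels = NULL,
                              columns = c("q1", "q2", "q4")) {
  if (is.list(features) && !is.matrix(features)) features <- feature_matrix(features)
  if (!is.null(colnames(features)) && all(columns %in% colnames(features))) {
    x <- features[, columns, drop = FALSE]
  } else {
    x <- as.matrix(features)
    columns <- colnames(x)
  }
  n <- nrow(x)
  stopifnot(n >= 6)
  if (nrow(unique(x)) < 2) stop("degenerate clustering: all feature points identical")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$rng_seed, "kmeans-boot"))

  n_draw <- max(2L, round(cfg$kmeans_subsample * n))
  draw_idx <- function() {
    if (is.null(labels)) return(sample.int(n, n_draw))
    idx <- unlist(lapply(split(seq_len(n), labels), function(g) {
      sample(g, max(1L, round(cfg$kmeans_subsample * length(g))))
    }), use.names = FALSE)
    idx
  }
  acc <- matrix(0, nrow = 2, ncol = ncol(x))
  n_acc <- 0L
  for (b in seq_len(cfg$kmeans_bootstrap)) {
    idx <- draw_idx()
    xb <- x[idx, , drop = FALSE]
    if (nrow(unique(xb)) < 2) next
    km <- tryCatch(stats::kmeans(xb, centers = 2, nstart = 5),
                   error = function(e) NULL)
    if (is.null(km)) next
    cen <- km$centers
    if (n_acc == 0L) {
      # initial orientation: nearer the origin first
      cen <- cen[order(sqrt(rowSums(cen^2))), , drop = FALSE]
    } else {
      ref <- acc / n_acc
      direct <- sum((cen - ref)^2)
      swapped <- sum((cen[2:1, ] - ref)^2)
      if (swapped < direct) cen <- cen[2:1, , drop = FALSE]
    }
    acc <- acc + cen
    n_acc <- n_acc + 1L
  }
  if (n_acc == 0L) stop("degenerate clustering: no bootstrap iteration succeeded")
  cen <- acc / n_acc
  if (sqrt(sum(cen[2, ]^2)) < sqrt(sum(cen[1, ]^2))) cen <- cen[2:1, , drop = FALSE]
  c1 <- cen[1, ]; c2 <- cen[2, ]

  d1_all <- sqrt(colSums((t(x) - c1)^2))
  d2_all <- sqrt(colSums((t(x) - c2)^2))
  assignment <- ifelse(d1_all <= d2_all, 1L, 2L)
  t1 <- fit_t_location_scale(d1_all[assignment == 1L])
  t2 <- fit_t_location_scale(d2_all[assignment == 2L])

  structure(list(c1_hat = c1, c2_hat = c2, t1 = t1, t2 = t2,
                 features = columns, assignment = assignment,
                 n_bootstrap = n_acc),
            class = "sp_cluster_model")
}

#' @export
print.sp_cluster_model <- function(x, ...) {
  cat("<sp_cluster_model>\n")
  cat("  c1 (adequate): ", paste(sprintf("%.3f", x$c1_hat), collapse = ", "), "\n")
  cat("  c2 (poor):     ", paste(sprintf("%.3f", x$c2_hat), collapse = ", "), "\n")
  cat(sprintf("  t1: m %.3f s %.3f df %.1f | t2: m %.3f s %.3f df %.1f\n",
              x$t1$m, x$t1$s, x$t1$df, x$t2$m, x$t2$s, x$t2$df))
  invisible(x)
}

# ML fit of a location-scale Student-t (df bounded below by 1); falls back to
# a normal (df = Inf) when fewer than 4 distances are available or the
# optimizer fails.
fit_t_location_scale <- function(d) {
  d <- d[is.finite(d)]
  normal_fit <- list(m = mean(d), s = max(stats::sd(d), 1e-8), df = Inf)
  if (length(d) < 4 || stats::sd(d) == 0) return(normal_fit)
  starts <- list(
    list(m = mean(d), s = stats::sd(d), df = 5),
    list(m = stats::median(d), s = stats::sd(d) / 2, df = 4),
    list(m = mean(d), s = stats::mad(d) + 1e-6, df = 10)
  )
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(MASS::fitdistr(d, "t", start = st,
                                      lower = c(-Inf, 1e-8, 1))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      est <- fit$estimate
      return(list(m = unname(est["m"]), s = unname(est["s"]), df = unname(est["df"])))
    }
  }
  normal_fit
}

#' Probability that an implantation adequately sampled the SOZ
#'
#' Combines the distances of a patient's feature vector to the two cluster
#' centroids: \eqn{p_1} is the upper-tail probability of the distance to
#' \eqn{\hat c_1} under its Student-t model (large when the patient sits
#' inside the adequate cluster), \eqn{p_2} the analogue for \eqn{\hat c_2}.
#' The reported probability is \eqn{(p_1 + (1 - p_2)) / 2}, i.e. the average
#' evidence of being in the adequate cluster and not in the poor one.
#'
#' @param f An \code{sp_features} or a numeric vector matching
#'   \code{model$features}.
#' @param model An \code{sp_cluster_model}.
#' @return Probability in [0, 1].
#' @export
probability_adequate <- function(f, model) {
  v <- feature_vector(f, model$features)
  d1 <- sqrt(sum((v - model$c1_hat)^2))
  d2 <- sqrt(sum((v - model$c2_hat)^2))
  p1 <- t_upper_tail(d1, model$t1)
  p2 <- t_upper_tail(d2, model$t2)
  (p1 + (1 - p2)) / 2
}

#' Nearest-centroid adequacy call
#'
#' @inheritParams probability_adequate
#' @return \code{"well_sampled"} or \code{"poorly_sampled"}; ties resolve to
#'   \code{"well_sampled"}.
#' @export
classify_by_cluster <- function(f, model) {
  v <- feature_vector(f, model$features)
  d1 <- sqrt(sum((v - model$c1_hat)^2))
  d2 <- sqrt(sum((v - model$c2_hat)^2))
  if (d1 <= d2) "well_sampled" else "poorly_sampled"
}

feature_vector <- function(f, columns) {
  if (inherits(f, "sp_features")) {
    v <- unlist(f[columns])
  } else {
    v <- as.numeric(f)
    if (!is.null(names(f)) && all(columns %in% names(f))) v <- as.numeric(f[columns])
  }
  if (length(v) != length(columns)) stop("feature vector length mismatch")
  v
}

t_upper_tail <- function(d, tt) {
  if (is.infinite(tt$df)) {
    stats::pnorm((d - tt$m) / tt$s, lower.tail = FALSE)
  } else {
    stats::pt((d - tt$m) / tt$s, df = tt$df, lower.tail = FALSE)
  }
}
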