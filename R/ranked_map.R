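#' Per-channel perturbation strengths (ranked framework)
#'
#' The ranked framework perturbs the spatial system without any knowledge of
#' the SOZ by permuting the spatial reference. The base system is referenced
#' at the unconstrained maximum-rate channel (correlation \eqn{\rho_{ref}}).
#' Each channel then acts as the reference of its own system, with the base
#' reference channel excluded from the point set before computing
#' \eqn{\rho_i}. The perturbation strength of channel i is
#' \eqn{\hat P_i = 1 - (\rho_i - \rho_{ref})}: 1 when the permutation leaves
#' the coupling unchanged, smaller when it weakens it. Undefined
#' \eqn{\rho_i} are treated as 0 before differencing.
#'
#' @param patient An \code{sp_patient}.
#' @param rates Named rate vector for one segment.
#' @param cfg An \code{\link{sp_config}}.
#' @return Named numeric vector of \eqn{\hat P_i} over included channels.
#' @export
channel_perturbation_strengths <- function(patient, rates, cfg = sp_config()) {
  ids <- intersect(included_ids(patient), names(rates))
  if (length(ids) < 4) stop("need at least 4 included channels")
  ref_g <- select_spatial_reference(rates[ids])
  rho_ref <- build_spatial_system(patient, rates, ref_g, cfg)$rho
  if (is.na(rho_ref)) stop("undefined reference correlation")
  p <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    if (id == ref_g) {
      p[id] <- 1
      next
    }
    rho_i <- build_spatial_system(patient, rates, id, cfg, exclude = ref_g)$rho
    if (is.na(rho_i)) rho_i <- 0
    p[id] <- 1 - (rho_i - rho_ref)
  }
  p
}

#' Channel-wise median of per-segment perturbation strengths
#'
#' @param per_segment List of named \eqn{\hat P} vectors (one per valid
#'   segment) over a common channel set.
#' @return Named vector of per-channel medians \eqn{\bar P_i}.
#' @export
median_strengths <- function(per_segment) {
  stopifnot(length(per_segment) >= 1)
  m <- do.call(rbind, per_segment)
  apply(m, 2, stats::median)
}

#' Centroid of the high-perturbation region
#'
#' Channels with \eqn{\bar P} at or above the \code{cfg$centroid_percentile}
#' percentile (linear interpolation) form the high-perturbation region; the
#' centroid is the unweighted mean of their coordinates. It serves as a proxy
#' of the SOZ location. The inclusive cut guarantees a non-empty region even
#' under ties.
#'
#' @param patient An \code{sp_patient}.
#' @param pbar Named vector of per-channel \eqn{\bar P_i}.
#' @param cfg An \code{\link{sp_config}}.
#' @return Length-3 centroid coordinate (mm).
#' @export
perturbation_centroid <- function(patient, pbar, cfg = sp_config()) {
  stopifnot(length(pbar) >= 1)
  q <- stats::quantile(pbar, cfg$centroid_percentile / 100, type = 7, names = FALSE)
  high <- names(pbar)[pbar >= q]
  coords <- channel_coords(patient)[high, , drop = FALSE]
  colMeans(coords)
}

#' Construct the SP map
#'
#' Projects the per-channel perturbation strengths onto a 2-D image: rows are
#' channels ranked by \eqn{\bar P} in descending order (ties by channel id),
#' columns are \code{cfg$map_bins} equal-width distance bins spanning [0, max
#' distance to the perturbation centroid] (half-open bins, last bin closed).
#' Each row of the raw image holds the channel's \eqn{\bar P} in its distance
#' bin and zeros elsewhere. Because that representation is sparse, a single
#' pass of grayscale morphological closing with a 3x3 square structuring
#' element spatially connects nearby activations; a well-sampled implantation
#' then appears as a diagonal band of decreasing intensity from the top-left.
#'
#' @inheritParams perturbation_centroid
#' @param centroid Perturbation centroid from
#'   \code{\link{perturbation_centroid}}.
#' @return An object of class \code{sp_map}: \code{image} (post-morphology),
#'   \code{raw_image}, \code{bin_edges} (mm), \code{row_order} (channel ids),
#'   \code{row_strength}, \code{distance} (mm per row) and \code{degenerate}
#'   (all distances zero).
#' @export
build_sp_map <- function(patient, pbar, centroid, cfg = sp_config()) {
  stopifnot(length(pbar) >= 2)
  coords <- channel_coords(patient)[names(pbar), , drop = FALSE]
  d <- sqrt(rowSums(sweep(coords, 2, centroid)^2))
  ord <- order(-pbar, names(pbar))
  pbar <- pbar[ord]; d <- d[ord]
  dmax <- max(d)
  degenerate <- dmax == 0
  nb <- if (degenerate) 1L else cfg$map_bins
  edges <- if (degenerate) c(0, 0) else seq(0, dmax, length.out = nb + 1)
  bin <- if (degenerate) rep(1L, length(d)) else pmin(findInterval(d, edges), nb)
  raw <- matrix(0, nrow = length(pbar), ncol = nb,
                dimnames = list(names(pbar), NULL))
  raw[cbind(seq_along(pbar), bin)] <- pbar
  img <- if (degenerate || nrow(raw) < 3) raw else {
    m <- EBImage::closing(raw, EBImage::makeBrush(3, shape = "box"))
    matrix(as.numeric(m), nrow = nrow(raw), dimnames = dimnames(raw))
  }
  structure(list(image = img, raw_image = raw, bin_edges = edges,
                 row_order = names(pbar), row_strength = pbar,
                 distance = d, degenerate = degenerate),
            class = "sp_map")
}

#' @export
print.sp_map <- function(x, ...) {
  cat(sprintf("<sp_map> %d channels x %d bins, max distance %.1f mm%s\n",
              nrow(x$image), ncol(x$image), max(x$bin_edges),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Ranked perturbation analysis of one patient
#'
#' Computes per-channel perturbation strengths for every valid segment, their
#' channel-wise medians, the perturbation centroid and the SP map.
#'
#' @param patient An \code{sp_patient}.
#' @param cfg An \code{\link{sp_config}}.
#' @return A list of class \code{sp_ranked}: \code{pbar}, \code{centroid},
#'   \code{map}, and \code{n_valid_segments}.
#' @export
patient_ranked_map <- function(patient, cfg = sp_config()) {
  segs <- colnames(patient$rates)
  valid <- segs[vapply(segs, function(s) segment_is_valid(segment_rates(patient, s), cfg),
                       logical(1))]
  if (length(valid) == 0) stop("patient ", patient$patient_id, " has no valid segments")
  per_seg <- lapply(valid, function(s)
    channel_perturbation_strengths(patient, segment_rates(patient, s), cfg))
  pbar <- median_strengths(per_seg)
  centroid <- perturbation_centroid(patient, pbar, cfg)
  map <- build_sp_map(patient, pbar, centroid, cfg)
  structure(list(patient_id = patient$patient_id, pbar = pbar,
                 centroid = centroid, map = map,
                 n_valid_segments = length(valid)),
            class = "sp_ranked")
}

#' Render an SP map
#'
#' Displays the (morphologically closed) SP map with ranked channels on the
#' vertical axis (strongest on top) and distance to the perturbation centroid
#' on the horizontal axis.
#'
#' @param x An \code{sp_map}.
#' @param main Plot title.
#' @param ... Passed to \code{graphics::image}.
#' @export
plot.sp_map <- function(x, main = "SP map", ...) {
  img <- x$image
  graphics::image(x = seq(0, max(x$bin_edges), length.out = ncol(img) + 1),
                  y = seq_len(nrow(img) + 1) - 0.5,
                  z = t(img[rev(seq_len(nrow(img))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "distance to perturbation centroid (mm)",
                  ylab = "channel rank (ascending strength upward)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}
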