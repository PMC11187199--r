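#' Union volume of channel spheres
#'
#' Inflates each channel of interest by a sphere of
#' \code{cfg$sphere_radius_mm} and numerically estimates the total
#' non-overlapping volume of the union on a regular grid of
#' \code{cfg$grid_resolution_mm} voxels: a voxel counts if its center lies
#' inside any sphere, and overlapping regions count once. The grid is
#' axis-aligned to the bounding box of the centers padded by the radius.
#'
#' @param coordinates Numeric matrix (n x 3) of channel coordinates (mm), or
#'   NULL/empty for volume 0.
#' @param cfg An \code{\link{sp_config}}.
#' @return Volume in cm^3.
#' @examples
#' # single 5 mm sphere ~ (4/3) * pi * 0.5^3 cm^3
#' sphere_union_volume(matrix(c(0, 0, 0), 1, 3))
#' @export
sphere_union_volume <- function(coordinates, cfg = sp_config()) {
  if (is.null(coordinates) || NROW(coordinates) == 0) return(0)
  coordinates <- matrix(as.numeric(coordinates), ncol = 3)
  r <- cfg$sphere_radius_mm
  h <- cfg$grid_resolution_mm
  lo <- apply(coordinates, 2, min) - r
  hi <- apply(coordinates, 2, max) + r
  ax <- lapply(1:3, function(k) seq(lo[k] + h / 2, hi[k], by = h))
  nx <- vapply(ax, length, integer(1))
  inside <- array(FALSE, dim = nx)
  r2 <- r^2
  for (i in seq_len(nrow(coordinates))) {
    ctr <- coordinates[i, ]
    # restrict to the sub-box around this center
    rng <- lapply(1:3, function(k) which(abs(ax[[k]] - ctr[k]) <= r))
    if (any(vapply(rng, length, integer(1)) == 0)) next
    dx2 <- (ax[[1]][rng[[1]]] - ctr[1])^2
    dy2 <- (ax[[2]][rng[[2]]] - ctr[2])^2
    dz2 <- (ax[[3]][rng[[3]]] - ctr[3])^2
    sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
    inside[rng[[1]], rng[[2]], rng[[3]]] <-
      inside[rng[[1]], rng[[2]], rng[[3]]] | sub
  }
  sum(inside) * h^3 / 1000
}

#' Fraction of the SOZ that was resected
#'
#' Region-level set ratio: the number of atlas regions both in the SOZ and in
#' the resection, over the number of SOZ regions. Region labels are an input
#' (projected per contact upstream); this function only performs the set
#' arithmetic.
#'
#' @param soz_regions Character vector of SOZ region labels.
#' @param resected_regions Character vector of resected region labels.
#' @return Fraction in [0, 1]; \code{NA} when the SOZ set is empty (e.g.
#'   palliative cases where no apparent SOZ channel was removed).
#' @export
percent_soz_resected <- function(soz_regions, resected_regions) {
  soz <- unique(soz_regions)
  if (length(soz) == 0) return(NA_real_)
  length(intersect(soz, unique(resected_regions))) / length(soz)
}

#' Incomplete-resection exclusion threshold
#'
#' Given the resected-SOZ volumes of patients marked by an expert as having
#' incomplete resections, returns the upper-quartile volume (default; the
#' percentile is configurable). Patients with resected-SOZ volume below this
#' threshold are excluded from corrected performance reporting, since their
#' poor outcome may reflect a functionally constrained resection rather than
#' poor sampling. Percentiles use linear interpolation.
#'
#' @param volumes Numeric vector of resected-SOZ volumes (cm^3), >= 4 values.
#' @param cfg An \code{\link{sp_config}}.
#' @return Threshold volume in cm^3.
#' @examples
#' incomplete_resection_threshold(c(1, 2, 3, 4)) # 3.25
#' @export
incomplete_resection_threshold <- function(volumes, cfg = sp_config()) {
  if (length(volumes) < 4) stop("need at least 4 volumes to estimate the threshold")
  stats::quantile(volumes, cfg$incomplete_resection_percentile / 100,
                  type = 7, names = FALSE)
}

#' Per-patient volume estimates
#'
#' Computes sphere-union volumes for the SOZ channels, the resected channels,
#' and their intersection.
#'
#' @param patient An \code{sp_patient}.
#' @param cfg An \code{\link{sp_config}}.
#' @return A list of class \code{sp_volumes}: \code{soz_cm3},
#'   \code{resected_cm3}, \code{resected_soz_cm3}.
#' @export
patient_volumes <- function(patient, cfg = sp_config()) {
  ch <- patient$channels
  coords <- channel_coords(patient)
  vol <- function(mask) sphere_union_volume(coords[mask, , drop = FALSE], cfg)
  structure(list(
    patient_id = patient$patient_id,
    soz_cm3 = vol(ch$is_soz),
    resected_cm3 = vol(ch$is_resected),
    resected_soz_cm3 = vol(ch$is_soz & ch$is_resected)
  ), class = "sp_volumes")
}
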