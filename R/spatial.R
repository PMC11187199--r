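#' Bipolar channel midpoint
#'
#' The coordinate of a bipolar channel is the component-wise midpoint of its
#' two contact coordinates (mm, template space).
#'
#' @param contact_a,contact_b Numeric length-3 coordinate vectors (mm).
#' @return Numeric length-3 midpoint.
#' @examples
#' bipolar_midpoint(c(0, 0, 0), c(2, 4, 6))
#' @export
bipolar_midpoint <- function(contact_a, contact_b) {
  if (length(contact_a) != 3 || length(contact_b) != 3 ||
      any(!is.finite(contact_a)) || any(!is.finite(contact_b))) {
    stop("invalid coordinate: both contacts must be finite length-3 vectors")
  }
  (contact_a + contact_b) / 2
}

#' Select the spatial reference channel
#'
#' The spatial reference anchors the distance axis of a spatial system: it is
#' the channel with the maximum event rate, optionally constrained to a subset
#' (the SOZ for the before-removal system, its complement after removal, or
#' all channels for the unconstrained ranked framework). Ties are broken by
#' lexicographic channel id so that reference selection is deterministic.
#'
#' @param rates Named numeric vector of event rates (events/min).
#' @param mask Optional character vector of channel ids to which the argmax is
#'   restricted.
#' @return The reference \code{channel_id}.
#' @export
select_spatial_reference <- function(rates, mask = NULL) {
  if (!is.null(mask)) rates <- rates[intersect(names(rates), mask)]
  rates <- rates[is.finite(rates)]
  if (length(rates) == 0) stop("empty reference candidate set")
  cand <- names(rates)[rates == max(rates)]
  sort(cand)[1]
}

#' Log-log Pearson fit of a power-law spatial system
#'
#' Computes the Pearson correlation between log-distance and log-rate, and
#' the ordinary least-squares line \eqn{y = \tilde\alpha + \kappa x}. The
#' correlation is the goodness of fit of the power-law decay hypothesis. When
#' either variable has zero variance, or fewer than 3 points are supplied, the
#' correlation is undefined and returned as \code{NA} (never NaN arithmetic).
#'
#' @param x,y Numeric vectors (log-distance, log-rate).
#' @return A list with \code{rho}, \code{alpha_tilde} (intercept, natural-log
#'   scale) and \code{kappa} (slope).
#' @export
loglog_pearson_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    return(list(rho = NA_real_, alpha_tilde = NA_real_, kappa = NA_real_, n = n))
  }
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    return(list(rho = NA_real_, alpha_tilde = NA_real_, kappa = NA_real_, n = n))
  }
  rho <- stats::cor(x, y)
  kappa <- stats::cov(x, y) / stats::var(x)
  alpha_tilde <- mean(y) - kappa * mean(x)
  list(rho = rho, alpha_tilde = alpha_tilde, kappa = kappa, n = n)
}

#' Build a spatial system for one segment
#'
#' Couples each included, non-reference channel's log event rate with the log
#' of its Euclidean distance (mm) to the reference channel, and fits the
#' power-law line. The reference channel itself is removed from the point set
#' because its distance is zero and the logarithm is undefined there.
#' Channels with a rate of exactly zero have \code{cfg$rate_floor} added so
#' the logarithm is well defined; non-zero rates are left untouched to
#' preserve their ordering. Natural logarithms are used throughout (the
#' correlation and slope are base-invariant; the intercept is on the
#' natural-log scale).
#'
#' @param patient An \code{sp_patient}.
#' @param rates Named rate vector for one segment (see
#'   \code{\link{select_spatial_reference}}); channels absent from
#'   \code{rates} are ignored.
#' @param reference_id Channel id of the spatial reference.
#' @param cfg An \code{\link{sp_config}}.
#' @param exclude Optional channel ids removed from the point set in addition
#'   to the reference (used by the ranked framework).
#' @return An object of class \code{sp_system}: reference id, the point set
#'   (\code{channel_id}, \code{log_distance}, \code{log_rate}), and the fit
#'   (\code{rho}, \code{alpha_tilde}, \code{kappa}). \code{rho} is \code{NA}
#'   when undefined (fewer than 3 points or zero variance).
#' @export
build_spatial_system <- function(patient, rates, reference_id, cfg = sp_config(),
                                 exclude = character()) {
  coords <- channel_coords(patient)
  if (!reference_id %in% rownames(coords)) stop("unknown reference channel: ", reference_id)
  ids <- setdiff(intersect(included_ids(patient), names(rates)),
                 c(reference_id, exclude))
  ref <- coords[reference_id, ]
  d <- sqrt(rowSums(sweep(coords[ids, , drop = FALSE], 2, ref)^2))
  r <- rates[ids]
  r[r == 0] <- r[r == 0] + cfg$rate_floor
  # coincident channels (zero distance) cannot enter log space
  ok <- d > 0
  pts <- data.frame(channel_id = ids[ok],
                    log_distance = log(d[ok]),
                    log_rate = log(r[ok]),
                    stringsAsFactors = FALSE)
  fit <- loglog_pearson_fit(pts$log_distance, pts$log_rate)
  structure(list(reference_id = reference_id, points = pts,
                 rho = fit$rho, alpha_tilde = fit$alpha_tilde,
                 kappa = fit$kappa),
            class = "sp_system")
}

#' @export
print.sp_system <- function(x, ...) {
  cat(sprintf("<sp_system> ref %s, %d points, rho = %s, kappa = %s\n",
              x$reference_id, nrow(x$points),
              format(x$rho, digits = 3), format(x$kappa, digits = 3)))
  invisible(x)
}
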