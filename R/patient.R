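#' Assemble a patient record
#'
#' Bundles a per-patient channel table with the per-segment event-rate matrix.
#' Channels are bipolar SEEG channels located at the midpoint of their two
#' contacts, in a normalized template space (mm). Excluded channels
#' (white-matter, extra-cerebral, artifactual) are retained but flagged and
#' never enter any spatial system.
#'
#' @param patient_id Character scalar identifier.
#' @param channels \code{data.frame} with columns \code{channel_id},
#'   \code{x_mm}, \code{y_mm}, \code{z_mm}, \code{is_soz}, \code{is_resected},
#'   \code{excluded}. Flags may be logical or 0/1.
#' @param rates Numeric matrix of event rates (events/min), rows named by
#'   \code{channel_id}, one column per recording segment. All rated channels
#'   must exist in \code{channels}.
#' @param segment_minutes Duration of each segment in minutes (default 10).
#' @param outcome One of \code{"seizure_free"}, \code{"non_seizure_free"},
#'   \code{"unknown"}.
#'
#' @return An object of class \code{sp_patient}.
#' @export
sp_patient <- function(patient_id, channels, rates, segment_minutes = 10,
                       outcome = c("unknown", "seizure_free", "non_seizure_free")) {
  outcome <- match.arg(outcome)
  required <- c("channel_id", "x_mm", "y_mm", "z_mm", "is_soz", "is_resected", "excluded")
  missing_cols <- setdiff(required, names(channels))
  if (length(missing_cols) > 0) {
    stop("channel table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  channels <- as.data.frame(channels)[required]
  channels$channel_id <- as.character(channels$channel_id)
  dup <- channels$channel_id[duplicated(channels$channel_id)]
  if (length(dup) > 0) {
    stop("duplicated channel_id in channel table: ", paste(unique(dup), collapse = ", "))
  }
  coords <- as.matrix(channels[, c("x_mm", "y_mm", "z_mm")])
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    bad <- which(apply(coords, 1, function(r) any(!is.finite(r))))
    stop("non-finite coordinates for channel(s): ",
         paste(channels$channel_id[bad], collapse = ", "))
  }
  for (fl in c("is_soz", "is_resected", "excluded")) {
    channels[[fl]] <- as.logical(channels[[fl]])
    if (any(is.na(channels[[fl]]))) stop("flag column ", fl, " contains missing values")
  }
  if (sum(!channels$excluded) < 2) stop("fewer than 2 non-excluded channels")

  rates <- as.matrix(rates)
  if (is.null(rownames(rates))) stop("rates matrix must have channel_id rownames")
  unknown <- setdiff(rownames(rates), channels$channel_id)
  if (length(unknown) > 0) {
    stop("rates refer to unknown channel(s): ", paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and non-negative")
  }
  if (is.null(colnames(rates))) {
    colnames(rates) <- sprintf("seg%03d", seq_len(ncol(rates)))
  }
  # align rate rows to the full channel set; unrated channels get rate 0
  full <- matrix(0, nrow = nrow(channels), ncol = ncol(rates),
                 dimnames = list(channels$channel_id, colnames(rates)))
  full[rownames(rates), ] <- rates

  structure(
    list(patient_id = as.character(patient_id),
         channels = channels,
         rates = full,
         segment_minutes = segment_minutes,
         outcome = outcome),
    class = "sp_patient"
  )
}

#' @export
print.sp_patient <- function(x, ...) {
  cat(sprintf("<sp_patient> %s: %d channels (%d SOZ, %d excluded), %d segments, outcome %s\n",
              x$patient_id, nrow(x$channels), sum(x$channels$is_soz),
              sum(x$channels$excluded), ncol(x$rates), x$outcome))
  invisible(x)
}

# coordinate matrix (rownames = channel_id)
channel_coords <- function(patient) {
  m <- as.matrix(patient$channels[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- patient$channels$channel_id
  m
}

# ids of channels usable in spatial systems
included_ids <- function(patient) {
  patient$channels$channel_id[!patient$channels$excluded]
}

soz_ids <- function(patient) {
  patient$channels$channel_id[patient$channels$is_soz & !patient$channels$excluded]
}

# named rate vector for one segment, restricted to non-excluded channels
segment_rates <- function(patient, segment) {
  r <- patient$rates[, segment]
  r[included_ids(patient)]
}
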