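#' Write patient tables
#'
#' Serializes a patient to the package's on-disk schema: a tab-delimited
#' channel table (\code{channel_id}, \code{x_mm}, \code{y_mm}, \code{z_mm},
#' \code{is_soz}, \code{is_resected}, \code{excluded} with 0/1 flags) and a
#' tab-delimited rate table (rows = channels, one column per segment,
#' events/min at full precision). Both files are locale-independent
#' (\code{.} decimal point) and round-trip through
#' \code{\link{read_patient}}.
#'
#' @param patient An \code{sp_patient}.
#' @param channel_path,rates_path Output file paths.
#' @return Invisibly, the patient.
#' @export
write_patient <- function(patient, channel_path, rates_path) {
  ch <- patient$channels
  for (fl in c("is_soz", "is_resected", "excluded")) ch[[fl]] <- as.integer(ch[[fl]])
  write_tsv(ch, channel_path)
  rt <- data.frame(channel_id = rownames(patient$rates),
                   patient$rates, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(rt, rates_path)
  invisible(patient)
}

#' Read patient tables
#'
#' Reads and validates the channel and rate tables written by
#' \code{\link{write_patient}}. Schema violations (missing columns,
#' duplicated channel ids, non-numeric coordinates, rates for unknown
#' channels) raise errors naming the offending rows.
#'
#' @param channel_path,rates_path Input file paths.
#' @param patient_id Identifier for the assembled patient (default: channel
#'   file name without extension).
#' @param segment_minutes Segment duration in minutes.
#' @param outcome Optional outcome label.
#' @return An \code{sp_patient}.
#' @export
read_patient <- function(channel_path, rates_path,
                         patient_id = sub("\\.[^.]*$", "", basename(channel_path)),
                         segment_minutes = 10, outcome = "unknown") {
  ch <- utils::read.delim(channel_path, stringsAsFactors = FALSE)
  required <- c("channel_id", "x_mm", "y_mm", "z_mm", "is_soz", "is_resected", "excluded")
  missing_cols <- setdiff(required, names(ch))
  if (length(missing_cols) > 0) {
    stop("channel table ", channel_path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (cc in c("x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(ch[[cc]]))
    bad <- which(is.na(v) & !is.na(ch[[cc]]))
    if (length(bad) > 0) {
      stop("non-numeric ", cc, " in channel table row(s): ",
           paste(bad, collapse = ", "))
    }
    ch[[cc]] <- v
  }
  rt <- utils::read.delim(rates_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"channel_id" %in% names(rt)) {
    stop("rates table ", rates_path, " is missing the channel_id column")
  }
  rates <- as.matrix(rt[, setdiff(names(rt), "channel_id"), drop = FALSE])
  rownames(rates) <- as.character(rt$channel_id)
  storage.mode(rates) <- "double"
  sp_patient(patient_id, ch, rates, segment_minutes = segment_minutes,
             outcome = outcome)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     dec = ".")
}

#' Write a synthetic cohort to disk
#'
#' Emits one channel table and one rates table per patient (shared schema
#' with real data) plus a cohort manifest TSV with outcome and ground-truth
#' scenario labels.
#'
#' @param patients List of \code{sp_patient} (e.g. from
#'   \code{\link{generate_cohort}}).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_cohort <- function(patients, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(patients, function(p) {
    write_patient(p,
                  file.path(dir, paste0(p$patient_id, "_channels.tsv")),
                  file.path(dir, paste0(p$patient_id, "_rates.tsv")))
    data.frame(patient_id = p$patient_id, outcome = p$outcome,
               kind = if (is.null(p$ground_truth)) NA_character_ else p$ground_truth$kind,
               stringsAsFactors = FALSE)
  }))
  write_tsv(manifest, file.path(dir, "cohort.tsv"))
  invisible(manifest)
}
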