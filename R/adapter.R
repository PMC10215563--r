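# Adapters for externally deposited datasets whose column layout differs
# from the trial schema. A column-mapping configuration renames external
# columns onto the schema, so the preprocessing and modelling chain can run
# unchanged on third-party exports.

#' Read an external trial time series through a column mapping
#'
#' @param path CSV file path.
#' @param mapping Named character vector: names are trial-schema columns
#'   (see \code{\link{read_trial_csv}}), values the external column names.
#'   Unmapped schema columns are filled with NA; a missing
#'   \code{gaze_valid} mapping derives validity from non-missing gaze
#'   direction samples.
#' @return data.frame in the trial schema.
#' @export
read_external_trial <- function(path, mapping) {
  ext <- utils::read.csv(path, comment.char = "#")
  absent <- setdiff(unname(mapping), names(ext))
  if (length(absent))
    stop("external file ", path, " lacks mapped column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  out <- data.frame(row.names = seq_len(nrow(ext)))
  for (col in trial_columns()) {
    out[[col]] <- if (col %in% names(mapping)) ext[[mapping[[col]]]]
                  else NA_real_
  }
  if (!"gaze_valid" %in% names(mapping))
    out$gaze_valid <- as.integer(!is.na(out$gaze_dir_x))
  if (any(diff(out$time_s) <= 0))
    stop("external trial ", path, ": time must be strictly increasing",
         call. = FALSE)
  out
}

#' Read an external probe-level table through a column mapping
#'
#' Maps an external export onto the probe table used by the condition and
#' appraisal models (\code{participant}, \code{pressure}, \code{feedback},
#' \code{pof}, \code{cof}, \code{anxiety}, optionally \code{block} and
#' \code{trial}).
#'
#' @param path CSV file path.
#' @param mapping Named character vector (names = probe-table columns,
#'   values = external column names).
#' @param levels Optional list recoding condition labels, e.g.
#'   \code{list(pressure = c(H = "high", L = "low"))}.
#' @return Probe-level data.frame.
#' @export
read_external_probes <- function(path, mapping, levels = NULL) {
  ext <- utils::read.csv(path, comment.char = "#")
  absent <- setdiff(unname(mapping), names(ext))
  if (length(absent))
    stop("external file ", path, " lacks mapped column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  out <- data.frame(row.names = seq_len(nrow(ext)))
  for (col in names(mapping)) out[[col]] <- ext[[mapping[[col]]]]
  for (nm in names(levels)) {
    rec <- levels[[nm]]
    out[[nm]] <- unname(rec[as.character(out[[nm]])])
  }
  need <- c("participant", "pressure", "feedback")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stop("probe mapping must provide: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out
}
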