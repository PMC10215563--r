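# Readers and writers for the per-trial 90 Hz time-series files, the session
# manifest and probe table, and the plain-text (YAML) configuration file.
# CSV dialect: comma-separated, header row, UTF-8, '.' decimal; numbers are
# written with enough digits to round-trip exactly. A schema version is
# stamped in a leading comment line.

TRIAL_SCHEMA_VERSION <- "interceptvr_trial v1"

trial_columns <- function() {
  c("time_s",
    "head_x", "head_y", "head_z", "head_qw", "head_qx", "head_qy", "head_qz",
    "ctrl_x", "ctrl_y", "ctrl_z", "ctrl_qw", "ctrl_qx", "ctrl_qy", "ctrl_qz",
    "gaze_origin_x", "gaze_origin_y", "gaze_origin_z",
    "gaze_dir_x", "gaze_dir_y", "gaze_dir_z",
    "ball_x", "ball_y", "ball_z",
    "gaze_valid")
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a trial time-series CSV
#'
#' @param recording data.frame in the trial schema (see
#'   \code{\link{read_trial_csv}}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trial_csv <- function(recording, path) {
  cols <- trial_columns()
  missing <- setdiff(cols, names(recording))
  if (length(missing))
    stop("trial recording is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- recording[cols]
  out <- vapply(cols, function(cn) {
    col <- df[[cn]]
    if (cn == "gaze_valid") as.character(as.integer(col)) else fmt_num(col)
  }, character(nrow(df)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste0("# ", TRIAL_SCHEMA_VERSION),
               paste(cols, collapse = ","),
               apply(out, 1L, paste, collapse = ",")), con)
  invisible(path)
}

#' Read a trial time-series CSV
#'
#' One row per 90 Hz sample: head and controller position (m) and orientation
#' (w,x,y,z quaternion), gaze origin (m) and unit direction vector, ball
#' position (m), and a per-sample gaze validity flag. Samples with
#' \code{gaze_valid == 0} have their gaze direction set to \code{NA} (the
#' missing-data mask used downstream).
#'
#' @param path File path.
#' @return data.frame with the trial columns and attribute
#'   \code{schema_version}.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("no such trial file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  version <- if (startsWith(first, "# ")) sub("^# ", "", first) else NA_character_
  df <- utils::read.csv(path, comment.char = "#")
  missing <- setdiff(trial_columns(), names(df))
  if (length(missing))
    stop("trial file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(diff(df$time_s) <= 0))
    stop("trial file ", path, ": time_s must be strictly increasing",
         call. = FALSE)
  bad <- df$gaze_valid == 0L
  df$gaze_dir_x[bad] <- NA_real_
  df$gaze_dir_y[bad] <- NA_real_
  df$gaze_dir_z[bad] <- NA_real_
  ok <- !bad & !is.na(df$gaze_dir_x)
  norms <- sqrt(df$gaze_dir_x[ok]^2 + df$gaze_dir_y[ok]^2 + df$gaze_dir_z[ok]^2)
  if (length(norms) && any(abs(norms - 1) > 1e-3))
    warning("trial file ", path, ": ", sum(abs(norms - 1) > 1e-3),
            " valid gaze sample(s) deviate from unit norm by > 1e-3")
  attr(df, "schema_version") <- version
  df
}

#' Write a session manifest (trial table and probe table)
#'
#' @param manifest List with data.frames \code{trials} (participant, block,
#'   pressure, feedback, trial, ball_type, feedback_call, probe, hit_truth,
#'   file) and \code{probes} (participant, block, trial, pof, cof, anxiety).
#' @param dir Output directory; writes \code{manifest.csv} and
#'   \code{probes.csv}.
#' @return \code{dir}, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_plain_csv <- function(df, path) {
    out <- vapply(names(df), function(cn) {
      col <- df[[cn]]
      if (is.numeric(col) && !is.integer(col)) fmt_num(col) else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) out <- matrix(out, nrow = 1L)
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(paste0("# ", TRIAL_SCHEMA_VERSION),
                 paste(names(df), collapse = ","),
                 apply(out, 1L, paste, collapse = ",")), con)
  }
  write_plain_csv(manifest$trials, file.path(dir, "manifest.csv"))
  write_plain_csv(manifest$probes, file.path(dir, "probes.csv"))
  invisible(dir)
}

#' Read a session manifest
#'
#' Checks referential integrity: trial indices must be unique within each
#' participant/block, and every probe row must reference an existing trial.
#'
#' @param dir Directory containing \code{manifest.csv} and \code{probes.csv}.
#' @return List with data.frames \code{trials} and \code{probes}.
#' @export
read_manifest <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "manifest.csv"), comment.char = "#")
  probes <- utils::read.csv(file.path(dir, "probes.csv"), comment.char = "#")
  key <- function(d) paste(d$participant, d$block, d$trial)
  if (anyDuplicated(key(trials)))
    stop("manifest: duplicate trial index within a participant/block",
         call. = FALSE)
  dangling <- !(key(probes) %in% key(trials))
  if (any(dangling))
    stop("manifest: probe row(s) reference absent trials: ",
         paste(utils::head(key(probes)[dangling], 5L), collapse = "; "),
         call. = FALSE)
  list(trials = trials, probes = probes)
}

#' Load and validate a configuration file
#'
#' The file is YAML with optional sections \code{physics}, \code{gaze},
#' \code{swing}, \code{selfreport}, \code{preprocess} and \code{session};
#' every key must be an argument of the corresponding configuration
#' constructor (unknown keys are rejected), defaults fill everything not
#' given, and each constructor validates its invariants. An empty file yields
#' the full defaults.
#'
#' @param path Path to a YAML file, or \code{NULL} for defaults.
#' @return List of validated configuration objects: \code{physics},
#'   \code{gaze}, \code{swing}, \code{selfreport}, \code{preprocess},
#'   \code{session}.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  ctors <- list(physics = physics_config, gaze = gaze_config,
                swing = swing_config, selfreport = selfreport_truth,
                preprocess = preprocess_config, session = session_config)
  unknown <- setdiff(names(raw), names(ctors))
  if (length(unknown))
    stop("config: unknown section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (sec in names(ctors)) {
    args <- raw[[sec]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(ctors[[sec]])))
    if (length(bad))
      stop(sprintf("config section `%s`: unknown key(s): %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    out[[sec]] <- do.call(ctors[[sec]], args)
  }
  out
}
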