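#' Construct a force recording
#'
#' A `force_recording` holds one uniformly sampled vertical-force trace from a
#' pressure-sensitive platform together with the session metadata needed for
#' body-weight normalization and longitudinal bookkeeping.
#'
#' @param force Numeric vector of vertical force samples (N), all finite,
#'   length >= 2. Compressive load is positive; small negative sensor noise is
#'   tolerated here and gated out at segmentation.
#' @param sampling_rate Sampling rate in Hz (> 0). The study platform samples
#'   at 50 Hz.
#' @param animal_id Animal identifier.
#' @param limb Limb label, one of `r paste(LIMB_LABELS, collapse = ", ")`.
#' @param day_postop Integer day post-surgery (>= 0). For control animals this
#'   is simply the measurement day.
#' @param body_weight Body weight in kg (> 0).
#' @param session_id Session identifier; defaults to `"<animal>_d<day>"`.
#'
#' @return An object of class `force_recording`.
#' @seealso [read_force_recording()], [detect_stance_phases()]
#' @export
force_recording <- function(force, sampling_rate, animal_id, limb,
                            day_postop, body_weight,
                            session_id = paste0(animal_id, "_d", day_postop)) {
  force <- as.numeric(force)
  if (length(force) < 2L)
    stop_gaitrec("a force recording needs at least 2 samples", "gaitrec_validation")
  if (!all(is.finite(force)))
    stop_gaitrec("all force values must be finite", "gaitrec_validation")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop_gaitrec("sampling_rate must be a single positive number", "gaitrec_validation")
  limb <- as.character(limb)
  if (!limb %in% LIMB_LABELS)
    stop_gaitrec(sprintf("unknown limb label '%s' (expected one of %s)",
                         limb, paste(LIMB_LABELS, collapse = ", ")),
                 "gaitrec_validation")
  if (!is.numeric(body_weight) || body_weight <= 0)
    stop_gaitrec("body_weight must be positive", "gaitrec_validation")
  day_postop <- as.integer(day_postop)
  if (is.na(day_postop) || day_postop < 0L)
    stop_gaitrec("day_postop must be a non-negative integer", "gaitrec_validation")
  structure(
    list(force = force, sampling_rate = sampling_rate,
         animal_id = as.character(animal_id), limb = limb,
         day_postop = day_postop, body_weight = body_weight,
         session_id = as.character(session_id)),
    class = "force_recording")
}

#' @export
print.force_recording <- function(x, ...) {
  cat(sprintf("<force_recording> %s limb %s day %d: %d samples @ %g Hz (%.2f s), BW %.1f kg\n",
              x$animal_id, x$limb, x$day_postop, length(x$force),
              x$sampling_rate, (length(x$force) - 1) / x$sampling_rate,
              x$body_weight))
  invisible(x)
}

#' Read a force recording from a two-column CSV file
#'
#' Reads a platform export with columns `time_s` and `force_N` (header
#' required). The sampling rate is inferred as `1/median(diff(time_s))` and the
#' time grid must be strictly increasing and uniform within 1 % of the median
#' step; otherwise a format error names the first offending row. A file with a
#' single `force_N` column is accepted when `sampling_rate` is supplied (or
#' present in the manifest entry), matching a fixed-rate device.
#'
#' @param path Path to the recording CSV.
#' @param manifest_entry A one-row data frame (or list) with the session
#'   metadata: `animal_id`, `limb`, `day_postop`, `body_weight_kg`,
#'   `session_id`, and optionally `sampling_rate`.
#' @param sampling_rate Fallback sampling rate in Hz used when the file has no
#'   time column; default 50.
#'
#' @return A [force_recording()].
#' @export
read_force_recording <- function(path, manifest_entry, sampling_rate = 50) {
  if (!file.exists(path))
    stop_gaitrec(sprintf("recording file not found: %s", path), "gaitrec_io")
  me <- as.list(manifest_entry)
  if (!is.null(me$body_weight_kg) && me$body_weight_kg <= 0)
    stop_gaitrec("manifest body weight must be positive", "gaitrec_validation")
  dat <- utils::read.csv(path)
  if (!"force_N" %in% names(dat))
    stop_gaitrec(sprintf("%s: expected a 'force_N' column", path), "gaitrec_format")
  if ("time_s" %in% names(dat)) {
    tm <- dat$time_s
    dt <- diff(tm)
    if (any(dt <= 0))
      stop_gaitrec(sprintf("%s: time not strictly increasing at row %d",
                           path, which(dt <= 0)[1] + 1L), "gaitrec_format")
    step <- stats::median(dt)
    bad <- which(abs(dt - step) > 0.01 * step)
    if (length(bad))
      stop_gaitrec(sprintf("%s: irregular time step at row %d (%.6g s vs median %.6g s)",
                           path, bad[1] + 1L, dt[bad[1]], step), "gaitrec_format")
    fs <- 1 / step
  } else {
    fs <- me$sampling_rate %||% sampling_rate
  }
  force_recording(dat$force_N, fs,
                  animal_id = me$animal_id, limb = me$limb,
                  day_postop = me$day_postop, body_weight = me$body_weight_kg,
                  session_id = me$session_id %||%
                    paste0(me$animal_id, "_d", me$day_postop))
}

#' Write a force recording to a two-column CSV file
#'
#' Writes `time_s` (reconstructed from the sampling rate) and `force_N`.
#' Values round-trip through [read_force_recording()] to the printed precision
#' (15 significant digits, i.e. numerically identical in double precision).
#'
#' @param recording A [force_recording()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_force_recording <- function(recording, path) {
  stopifnot(inherits(recording, "force_recording"))
  n <- length(recording$force)
  df <- data.frame(
    time_s = format((seq_len(n) - 1) / recording$sampling_rate, digits = 15,
                    trim = TRUE, scientific = FALSE),
    force_N = format(recording$force, digits = 15, trim = TRUE,
                     scientific = FALSE))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_gaitrec(sprintf("cannot write %s", path), "gaitrec_io")
  invisible(path)
}

#' Read a session manifest (CSV or YAML)
#'
#' A manifest lists one acquisition file per row with columns `file`,
#' `animal_id`, `limb`, `day_postop`, `body_weight_kg`, `session_id`. The
#' combination (animal_id, session_id, limb) must be unique.
#'
#' @param path Manifest path; `.yaml`/`.yml` files are parsed with the yaml
#'   package, anything else as CSV.
#' @return A data frame of manifest entries.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_gaitrec(sprintf("manifest not found: %s", path), "gaitrec_io")
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
    man <- do.call(rbind, lapply(entries, function(e) as.data.frame(e)))
  } else {
    man <- utils::read.csv(path)
  }
  needed <- c("file", "animal_id", "limb", "day_postop", "body_weight_kg")
  missing <- setdiff(needed, names(man))
  if (length(missing))
    stop_gaitrec(paste("manifest lacks columns:", paste(missing, collapse = ", ")),
                 "gaitrec_format")
  if (!"session_id" %in% names(man))
    man$session_id <- paste0(man$animal_id, "_d", man$day_postop)
  key <- paste(man$animal_id, man$session_id, man$limb)
  if (anyDuplicated(key))
    stop_gaitrec("manifest has duplicated (animal_id, session_id, limb) entries",
                 "gaitrec_validation")
  if (any(man$body_weight_kg <= 0))
    stop_gaitrec("manifest body weights must be positive", "gaitrec_validation")
  man
}

#' Write a tidy result table to CSV
#'
#' Writes any homogeneous collection of pipeline records (stance phases, gait
#' parameters, daily summaries, asymmetry records, regression fits) as a CSV
#' with header and a stable column order. Output is deterministic for
#' identical input, so write-read-write is byte-identical.
#'
#' @param records A non-empty data frame (or list of identically named lists).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_tidy_table <- function(records, path) {
  if (is.null(records) || NROW(records) == 0L)
    stop_gaitrec("refusing to write an empty table", "gaitrec_validation")
  if (!is.data.frame(records)) {
    nm <- names(records[[1]])
    if (is.null(nm) || !all(vapply(records, function(r) identical(names(r), nm), logical(1))))
      stop_gaitrec("records are not homogeneous", "gaitrec_validation")
    records <- do.call(rbind, lapply(records, function(r) as.data.frame(r)))
  }
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_gaitrec(sprintf("cannot write %s", path), "gaitrec_io")
  invisible(path)
}

#' Write a simulated cohort to disk in the package's file dialect
#'
#' Emits one recording CSV per acquisition plus a `manifest.csv`, both readable
#' by [read_manifest()] / [read_force_recording()].
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$file <- file.path(dir, sprintf("%s_%s.csv", man$session_id, man$limb))
  for (i in seq_len(nrow(man)))
    write_force_recording(cohort$recordings[[i]], man$file[i])
  path <- file.path(dir, "manifest.csv")
  write_tidy_table(man, path)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the recording CSVs.
#' @return A list with elements `recordings` and `manifest`.
#' @export
read_cohort <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.csv"))
  recs <- lapply(seq_len(nrow(man)), function(i)
    read_force_recording(man$file[i], man[i, ]))
  list(recordings = recs, manifest = man)
}
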