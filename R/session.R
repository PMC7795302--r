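## Session container and the on-disk dialect.
##
## A session directory holds `manifest.txt` (flat key=value, UTF-8) plus one
## delimited trajectory file per exercise with header
## time,p00x,p00y,p00z,...,p20z (64 columns, seconds and meters).

coord_col_names <- function() {
  c("time", paste0(rep(sprintf("p%02d", 0:20), each = 3), c("x", "y", "z")))
}

exercise_file_name <- function(exercise) {
  paste0(gsub(" ", "_", tolower(exercise)), ".csv")
}

#' Exercise recording
#'
#' One exercise's raw trajectories: 21 points of interest (POI) tracked in 3D
#' over time. Times are seconds and strictly increasing (the sensor's sampling
#' is variable-rate); positions are meters in the sensor frame.
#'
#' @param exercise Exercise name (one of [exercise_names()]).
#' @param times Strictly increasing numeric vector, length >= 2.
#' @param positions Numeric array `length(times) x 21 x 3` (or an equivalent
#'   `length(times) x 63` matrix in x,y,z-per-point column order).
#' @return An object of class `hb_recording`.
#' @export
exercise_recording <- function(exercise, times, positions) {
  if (!is_exercise(exercise))
    hb_stop("unknown_exercise", sprintf("unknown exercise name '%s'", exercise))
  times <- as.numeric(times)
  if (length(times) < 2)
    hb_stop("too_few_samples", "a recording needs at least 2 time samples")
  if (any(diff(times) <= 0))
    hb_stop("nonmonotone_times", "timestamps must be strictly increasing")
  if (is.matrix(positions) && ncol(positions) == 63)
    positions <- array(positions, dim = c(nrow(positions), 3, 21)) # temp; fixed below
  if (is.matrix(positions))
    hb_stop("bad_columns", "positions matrix must have 63 columns")
  if (length(dim(positions)) == 3 && dim(positions)[2] == 3 && dim(positions)[3] == 21) {
    ## came from a 63-column matrix laid out (x,y,z) fastest: reorder to n x 21 x 3
    positions <- aperm(positions, c(1, 3, 2))
  }
  if (!identical(dim(positions)[2:3], c(21L, 3L)))
    hb_stop("bad_columns", "positions must be length(times) x 21 x 3")
  if (dim(positions)[1] != length(times))
    hb_stop("bad_columns", "positions and times lengths differ")
  if (!all(is.finite(positions)))
    hb_stop("nonfinite_positions", "positions must be finite")
  dimnames(positions) <- list(NULL, NULL, c("x", "y", "z"))
  structure(list(exercise = exercise, times = times, positions = positions),
            class = "hb_recording")
}

#' @export
print.hb_recording <- function(x, ...) {
  cat(sprintf("<hb_recording> %s: %d samples over %.2f s (21 POI x 3 axes)\n",
              x$exercise, length(x$times), diff(range(x$times))))
  invisible(x)
}

#' Measurement session
#'
#' One measurement session of a patient: up to nine exercise recordings, an
#' optional clinician House-Brackmann grade, and an outlier-exclusion flag.
#' A complete session holds 9 recordings = 567 coordinate curves
#' (3 axes x 21 POI x 9 exercises).
#'
#' @param session_id,patient_id Identifier strings.
#' @param recordings List of [exercise_recording()] objects, at most one per
#'   exercise.
#' @param hb_clinician Optional raw clinician grade (1-6).
#' @param excluded Logical outlier flag (exclusion is a human decision).
#' @param excluded_reason Free-text reason when `excluded`.
#' @return An object of class `hb_session`.
#' @export
session <- function(session_id, patient_id, recordings,
                    hb_clinician = NULL, excluded = FALSE,
                    excluded_reason = "") {
  stopifnot(is.list(recordings))
  exs <- vapply(recordings, function(r) {
    if (!inherits(r, "hb_recording"))
      hb_stop("bad_recording", "recordings must be hb_recording objects")
    r$exercise
  }, character(1))
  if (anyDuplicated(exs))
    hb_stop("duplicate_exercise", "at most one recording per exercise")
  names(recordings) <- exs
  if (!is.null(hb_clinician)) {
    if (!(length(hb_clinician) == 1 && hb_clinician %in% 1:6))
      hb_stop("bad_grade", "hb_clinician must be a single grade in 1..6")
    hb_clinician <- as.integer(hb_clinician)
  }
  structure(list(session_id = as.character(session_id),
                 patient_id = as.character(patient_id),
                 recordings = recordings,
                 hb_clinician = hb_clinician,
                 excluded = isTRUE(excluded),
                 excluded_reason = as.character(excluded_reason)),
            class = "hb_session")
}

#' @rdname session
#' @param x An `hb_session`.
#' @return `n_coordinate_curves()`: the number of coordinate curves the
#'   session exposes (3 x 21 per recording; 567 for a complete session).
#' @export
n_coordinate_curves <- function(x) {
  stopifnot(inherits(x, "hb_session"))
  63L * length(x$recordings)
}

#' @export
print.hb_session <- function(x, ...) {
  cat(sprintf("<hb_session> %s (patient %s): %d recordings, %d coordinate curves\n",
              x$session_id, x$patient_id, length(x$recordings),
              n_coordinate_curves(x)))
  if (!is.null(x$hb_clinician))
    cat(sprintf("  clinician HB grade: %d (adjusted %d)\n",
                x$hb_clinician, adjust_grade(x$hb_clinician)))
  if (x$excluded)
    cat(sprintf("  excluded: %s\n", x$excluded_reason))
  invisible(x)
}

#' Pairwise POI distance curve
#'
#' Euclidean 3D distance between two points of interest at each time sample
#' of a recording; the v(P,Q)(t) building block of every symmetry and
#' intensity indicator.
#'
#' @param rec An [exercise_recording()].
#' @param a,b POI indices in 0-20, `a != b`.
#' @return List with `times` and `values` (meters), class `hb_curve`.
#' @export
distance_curve <- function(rec, a, b) {
  stopifnot(inherits(rec, "hb_recording"))
  if (!(length(a) == 1 && length(b) == 1 && a %in% 0:20 && b %in% 0:20))
    hb_stop("bad_poi_index", "POI indices must be single integers in 0..20")
  if (a == b)
    hb_stop("bad_poi_index", "POI indices must differ")
  d <- rec$positions[, a + 1L, , drop = FALSE] - rec$positions[, b + 1L, , drop = FALSE]
  hb_curve(rec$times, sqrt(rowSums(d * d, dims = 1)))
}

#' Time-indexed scalar curve
#'
#' Lightweight container for a sampled scalar curve (times plus values),
#' used for distance, alignment and indicator curves.
#'
#' @param times,values Equal-length numeric vectors.
#' @return List of class `hb_curve`.
#' @export
hb_curve <- function(times, values) {
  stopifnot(length(times) == length(values))
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "hb_curve")
}

#' @export
print.hb_curve <- function(x, ...) {
  cat(sprintf("<hb_curve> %d samples on [%.3f, %.3f], range [%.4g, %.4g]\n",
              length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

## ---- on-disk dialect ----

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

#' Write a session directory
#'
#' Writes `manifest.txt` plus one 64-column trajectory file per exercise in
#' the package's text dialect (comma-delimited, '.' decimal separator).
#' Registered recordings (see [register_session()]) additionally store their
#' warping-function knots in the manifest.
#'
#' @param x An [session()] object.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(x, path) {
  stopifnot(inherits(x, "hb_session"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) hb_stop("unwritable_path", sprintf("cannot create directory '%s'", path))
  lines <- c(paste0("session_id=", x$session_id),
             paste0("patient_id=", x$patient_id))
  if (!is.null(x$hb_clinician))
    lines <- c(lines, paste0("hb_clinician=", x$hb_clinician))
  lines <- c(lines, paste0("excluded=", tolower(x$excluded)))
  if (nzchar(x$excluded_reason))
    lines <- c(lines, paste0("excluded_reason=", x$excluded_reason))
  if (isTRUE(attr(x, "registered")))
    lines <- c(lines, "registered=true")
  for (ex in names(x$recordings)) {
    rec <- x$recordings[[ex]]
    f <- exercise_file_name(ex)
    lines <- c(lines, sprintf("exercise:%s=%s", ex, f))
    w <- attr(rec, "warping")
    if (!is.null(w))
      lines <- c(lines, sprintf("warp:%s=%s;%s", ex,
                                paste(fmt_num(w$reference_knots), collapse = ","),
                                paste(fmt_num(w$sample_knots), collapse = ",")))
    m <- cbind(rec$times,
               matrix(aperm(rec$positions, c(1, 3, 2)), nrow = length(rec$times)))
    con <- file(file.path(path, f), "w", encoding = "UTF-8")
    writeLines(paste(coord_col_names(), collapse = ","), con)
    writeLines(apply(m, 1, function(r) paste(fmt_num(r), collapse = ",")), con)
    close(con)
  }
  writeLines(lines, file.path(path, "manifest.txt"), useBytes = TRUE)
  invisible(path)
}

parse_manifest <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0))
    hb_stop("bad_manifest", "manifest lines must be key=value")
  keys <- substr(lines, 1, eq - 1)
  vals <- substr(lines, eq + 1, nchar(lines))
  stats::setNames(as.list(vals), keys)
}

#' Read a session directory
#'
#' Inverse of [write_session()]. Distinct error conditions are signalled for a
#' missing manifest (`hbgrade_missing_manifest`), a trajectory file missing
#' (`hbgrade_missing_file`), non-monotone timestamps
#' (`hbgrade_nonmonotone_times`), a wrong column count (`hbgrade_bad_columns`)
#' and an unknown exercise name (`hbgrade_unknown_exercise`).
#'
#' @param path Session directory written by [write_session()].
#' @return An `hb_session`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.txt")
  if (!file.exists(mf))
    hb_stop("missing_manifest", sprintf("no manifest.txt under '%s'", path))
  kv <- parse_manifest(readLines(mf, encoding = "UTF-8"))
  keys <- names(kv)
  ex_keys <- keys[startsWith(keys, "exercise:")]
  recordings <- list()
  for (k in ex_keys) {
    ex <- sub("^exercise:", "", k)
    if (!is_exercise(ex))
      hb_stop("unknown_exercise", sprintf("unknown exercise name '%s' in manifest", ex))
    f <- file.path(path, kv[[k]])
    if (!file.exists(f))
      hb_stop("missing_file", sprintf("trajectory file '%s' not found", kv[[k]]))
    tab <- utils::read.csv(f, header = TRUE, colClasses = "numeric")
    if (ncol(tab) != 64)
      hb_stop("bad_columns",
              sprintf("'%s' has %d columns, expected 64", kv[[k]], ncol(tab)))
    times <- tab[[1]]
    if (any(diff(times) <= 0))
      hb_stop("nonmonotone_times",
              sprintf("timestamps in '%s' are not strictly increasing", kv[[k]]))
    pos <- array(as.matrix(tab[, -1]), dim = c(nrow(tab), 3, 21))
    rec <- exercise_recording(ex, times, aperm(pos, c(1, 3, 2)))
    wk <- kv[[paste0("warp:", ex)]]
    if (!is.null(wk)) {
      parts <- strsplit(wk, ";", fixed = TRUE)[[1]]
      attr(rec, "warping") <- list(
        reference_knots = as.numeric(strsplit(parts[1], ",")[[1]]),
        sample_knots = as.numeric(strsplit(parts[2], ",")[[1]]))
    }
    recordings[[ex]] <- rec
  }
  s <- session(session_id = kv[["session_id"]] %||% basename(path),
               patient_id = kv[["patient_id"]] %||% "",
               recordings = recordings,
               hb_clinician = if (!is.null(kv[["hb_clinician"]]))
                 as.integer(kv[["hb_clinician"]]),
               excluded = identical(kv[["excluded"]], "true"),
               excluded_reason = kv[["excluded_reason"]] %||% "")
  if (identical(kv[["registered"]], "true")) attr(s, "registered") <- TRUE
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
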