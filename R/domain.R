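#' hbgrade: objective House-Brackmann grading from facial landmark kinematics
#'
#' Implements a three-stage procedure for grading mimetic-muscle function
#' after facial-nerve injury from 3D trajectories of 21 tracked facial points:
#' landmark-based curve registration, symmetry/intensity/speed indicator
#' curves, scalar-on-function logistic health scores, and weighted ordinal
#' (cumulative-logit) classification into adjusted House-Brackmann grades.
#'
#' The main entry point is [hb_fit()]; [simulate_cohort()] generates synthetic
#' sessions with known ground truth for validation.
#'
#' @keywords internal
#' @aliases hbgrade-package
"_PACKAGE"

## structured error helper: every named error in the package carries a class
## "hbgrade_<what>" plus "hbgrade_error" so callers can condition on it
hb_stop <- function(what, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("hbgrade_", what), "hbgrade_error", "error")))
}

#' Facial points of interest
#'
#' The 21 tracked facial landmarks (points of interest, POI), indexed 0-20,
#' with their anatomical positions and the depth sensor's internal vertex
#' index (metadata only). Left/right homologue pairs share anatomy across the
#' midsagittal plane.
#'
#' @return A data.frame with columns `index` (0-20), `sensor_index`, and
#'   `anatomical_label`.
#' @export
#' @examples
#' poi_table()
poi_table <- function() {
  data.frame(
    index = 0:20,
    sensor_index = c(1104L, 241L, 210L, 469L, 346L, 222L, 1090L, 731L, 843L,
                     1117L, 803L, 849L, 18L, 8L, 91L, 687L, 19L, 4L, 28L,
                     412L, 933L),
    anatomical_label = c(
      "left eye, bottom", "left eye, top", "left eye, inner corner",
      "left eye, outer corner", "left eyebrow, inner", "left eyebrow, centre",
      "right eye, bottom", "right eye, top", "right eye, inner",
      "right eye, outer", "right eyebrow, inner", "right eyebrow, centre",
      "nose tip", "mouth lower lip, centre-bottom", "mouth, left corner",
      "mouth, right corner", "mouth upper lip, centre-top", "chin, centre",
      "forehead, centre", "left cheek, centre", "right cheek, centre"),
    stringsAsFactors = FALSE
  )
}

## left/right homologue pairs (by POI index)
poi_mirror_pairs <- function() {
  cbind(left  = c(0L, 1L, 2L, 3L, 4L, 5L, 14L, 19L),
        right = c(6L, 7L, 8L, 9L, 10L, 11L, 15L, 20L))
}

#' Exercise catalogue
#'
#' The nine measured facial exercises with the instruction given to the
#' patient. Five of them (Raising, Frowning, Smiling, Baring, Pursing) carry
#' indicator curves; the remaining four are kept in the data model only.
#'
#' @return A data.frame with columns `name`, `instruction` and
#'   `indicator_bearing`.
#' @export
exercise_table <- function() {
  data.frame(
    name = c("Raising", "Frowning", "Closing", "Smiling", "Baring",
             "Pursing", "Blowing", "Closing and Baring", "Raising and Pursing"),
    instruction = c(
      "Raise your eyebrows", "Frown", "Close your eyes tightly",
      "Smile at me", "Bare your teeth", "Purse your lips",
      "Blow out your cheeks",
      "Close your eyes tightly and bare the teeth",
      "Raise your eyebrows and purse the lips"),
    indicator_bearing = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                          FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname exercise_table
#' @export
exercise_names <- function() exercise_table()$name

#' @rdname exercise_table
#' @export
indicator_exercises <- function() {
  tab <- exercise_table()
  tab$name[tab$indicator_bearing]
}

is_exercise <- function(name) name %in% exercise_names()

#' Indicator labels
#'
#' The 14 indicator labels: symmetry, intensity and speed for Raising
#' (`eyebrows.*`), Frowning (`frowning.*`), Smiling (`smiling.*`) and Baring
#' (`teeth.*`), and intensity and speed for Pursing (`lips.*`). Pursing has
#' no symmetry indicator because its motion is measured by a single
#' mouth-corner distance.
#'
#' @return Character vector of the 14 labels, grouped by exercise.
#' @export
indicator_labels <- function() {
  c("eyebrows.symmetry", "eyebrows.intensity", "eyebrows.speed",
    "frowning.symmetry", "frowning.intensity", "frowning.speed",
    "smiling.symmetry",  "smiling.intensity",  "smiling.speed",
    "teeth.symmetry",    "teeth.intensity",    "teeth.speed",
    "lips.intensity",    "lips.speed")
}

## exercise -> indicator-label prefix
exercise_prefix <- function(exercise) {
  switch(exercise,
         Raising = "eyebrows", Frowning = "frowning", Smiling = "smiling",
         Baring = "teeth", Pursing = "lips",
         hb_stop("not_indicator_exercise",
                 sprintf("exercise '%s' carries no indicators", exercise)))
}

#' Adjusted House-Brackmann grades
#'
#' The six-grade House-Brackmann scale is collapsed to the four adjusted
#' grades {1, 2, 3, 6} used for modelling: grade 4 is merged into 3 and
#' grade 5 into 6 (the two merged grades are rare and clinically close to
#' their neighbours).
#'
#' @param raw Integer vector of raw clinician grades in 1-6.
#' @return Integer vector of adjusted grades, each in {1, 2, 3, 6}.
#' @export
#' @examples
#' adjust_grade(1:6)  # 1 2 3 3 6 6
adjust_grade <- function(raw) {
  if (length(raw) == 0 || anyNA(raw) || !all(raw %in% 1:6))
    hb_stop("bad_grade", "raw House-Brackmann grades must be integers in 1..6")
  map <- c(1L, 2L, 3L, 3L, 6L, 6L)
  map[as.integer(raw)]
}

#' @rdname adjust_grade
#' @export
hb_levels <- function() c(1L, 2L, 3L, 6L)
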