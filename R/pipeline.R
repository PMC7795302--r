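## Pipeline orchestration: staged artifacts in one working directory, plus
## JSON (versioned key-value) serialization of the fitted models. This is
## the engine behind the command-line interface in inst/cli/hbgrade.R.

require_artifact <- function(path, what) {
  if (!file.exists(path))
    hb_stop("missing_artifact",
            sprintf("%s not found at '%s'; run the upstream stage first", what, path))
  path
}

write_table_det <- function(df, path) {
  ## deterministic text output: fixed significant digits, no quoting
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Serialize fitted models to JSON
#'
#' Versioned key-value serialization of the stage-2 health-score models and
#' the stage-3 ordinal classifier.
#'
#' @param x An `hb_flr`, an `hb_olr`, or a named list of `hb_flr`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(x, path) {
  ser <- function(m) {
    if (inherits(m, "hb_flr"))
      list(format_version = 1L, type = "flr", label = m$label,
           alpha = m$alpha, coefficients = m$coefficients,
           basis = list(type = m$basis$type, dimension = m$basis$dimension,
                        domain = m$basis$domain, grid = m$basis$grid),
           penalty = m$penalty, transform = m$transform,
           group_sizes = as.list(m$group_sizes), converged = m$converged)
    else if (inherits(m, "hb_olr"))
      list(format_version = 1L, type = "olr",
           levels = m$levels, thresholds = m$thresholds,
           coefficients = as.list(m$coefficients),
           selected_labels = m$selected_labels,
           inclusion_order = m$inclusion_order,
           loglik = m$loglik, aic = m$aic, n = m$n)
    else hb_stop("bad_input", "cannot serialize this object")
  }
  obj <- if (inherits(x, c("hb_flr", "hb_olr"))) ser(x) else lapply(x, ser)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(require_artifact(path, "model file"),
                             simplifyVector = TRUE)
  de <- function(o) {
    if (identical(o$type, "flr")) {
      grid <- as.numeric(o$basis$grid)
      M <- trapezoid_weights(grid) *
        flr_basis(grid, as.integer(o$basis$dimension))
      structure(list(label = o$label, alpha = o$alpha,
                     coefficients = as.numeric(o$coefficients),
                     basis = list(type = o$basis$type,
                                  dimension = as.integer(o$basis$dimension),
                                  domain = as.numeric(o$basis$domain),
                                  grid = grid),
                     quadrature = M, penalty = o$penalty,
                     transform = o$transform,
                     group_sizes = unlist(o$group_sizes),
                     converged = o$converged, separation = FALSE),
                class = "hb_flr")
    } else if (identical(o$type, "olr")) {
      structure(list(levels = as.integer(o$levels),
                     thresholds = as.numeric(o$thresholds),
                     coefficients = unlist(o$coefficients) %||%
                       stats::setNames(numeric(0), character(0)),
                     selected_labels = as.character(o$selected_labels),
                     inclusion_order = as.character(o$inclusion_order),
                     loglik = o$loglik, aic = o$aic, n = o$n,
                     converged = TRUE, weights_used = NULL),
                class = "hb_olr")
    } else hb_stop("bad_input", "unrecognized model record")
  }
  if (!is.null(obj$type)) de(obj) else lapply(obj, de)
}

read_sessions_dir <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "manifest.txt"))]
  if (length(subs) == 0)
    hb_stop("missing_artifact", sprintf("no session directories under '%s'", dir))
  lapply(subs, read_session)
}

indicators_from_table <- function(tab, grades = NULL) {
  ids <- unique(tab$session_id)
  lapply(stats::setNames(ids, ids), function(id) {
    sub <- tab[tab$session_id == id, , drop = FALSE]
    curves <- lapply(split(sub, sub$label), function(d) hb_curve(d$t, d$value))
    structure(list(session_id = id,
                   hb_clinician = if (!is.null(grades)) grades[[id]],
                   curves = curves,
                   absent = setdiff(indicator_labels(), names(curves))),
              class = "hb_indicators")
  })
}

read_grades <- function(dir) {
  gf <- file.path(dir, "grades.csv")
  if (file.exists(gf)) {
    g <- utils::read.csv(gf)
    return(stats::setNames(as.integer(g$hb_clinician), g$session_id))
  }
  sessions <- read_sessions_dir(file.path(dir, "sessions"))
  gr <- vapply(sessions, function(s) s$hb_clinician %||% NA_integer_, integer(1))
  stats::setNames(gr, vapply(sessions, function(s) s$session_id, character(1)))
}

#' Run one pipeline stage
#'
#' Staged command-line-style orchestration over a working directory `dir`:
#' * `simulate`: write `n` synthetic sessions under `dir/sessions/` plus
#'   `grades.csv` and `ground_truth.csv`;
#' * `register`: registered sessions (warping knots in the manifest) under
#'   `dir/registered/`;
#' * `indicators`: `indicators.csv` (long table) and `grades.csv`;
#' * `score`: fit the health-score models (`models_flr.json`) and write
#'   `scores.csv`;
#' * `classify`: stepwise-selected ordinal model (`model_olr.json`) and
#'   `predictions.csv` (session, clinician grade, model grade, four class
#'   probabilities);
#' * `evaluate`: `confusion.csv` and `accuracy.csv`;
#' * `report`: `report.csv`, the per-session case-study table (grades,
#'   probabilities and the selected health scores).
#'
#' Every stage validates its upstream artifacts (a distinct
#' `hbgrade_missing_artifact` error otherwise), writes deterministically for
#' a given seed and configuration, and records a machine-readable
#' `run_manifest.json` (stage, seed, configuration and its hash, inputs,
#' package version).
#'
#' @param mode One of `"simulate"`, `"register"`, `"indicators"`, `"score"`,
#'   `"classify"`, `"evaluate"`, `"report"`.
#' @param dir Working directory holding the staged artifacts.
#' @param config An [hb_config()].
#' @param n Cohort size (simulate only).
#' @param class_mix Grade mix (simulate only).
#' @param seed Seed override (defaults to `config$seed`).
#' @return Invisibly, a character vector of the artifact paths written.
#' @export
run_pipeline <- function(mode = c("simulate", "register", "indicators",
                                  "score", "classify", "evaluate", "report"),
                         dir, config = hb_config(), n = 40L,
                         class_mix = c(58, 21, 23, 20) / 122, seed = NULL) {
  mode <- match.arg(mode)
  seed <- seed %||% config$seed
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  add <- function(p) written <<- c(written, p)

  if (mode == "simulate") {
    coh <- simulate_cohort(n, class_mix, seed = seed)
    sdir <- file.path(dir, "sessions")
    for (s in coh$sessions) add(write_session(s, file.path(sdir, s$session_id)))
    gt <- do.call(rbind, lapply(seq_along(coh$truths), function(i) {
      tr <- coh$truths[[i]]
      p <- tr$params
      data.frame(session_id = coh$sessions[[i]]$session_id,
                 grade = p$grade, affected_side = p$affected_side,
                 asymmetry_attenuation = p$asymmetry_attenuation,
                 intensity_scale = p$intensity_scale,
                 speed_gamma = p$speed_gamma,
                 n_repetitions = p$n_repetitions,
                 sampling_hz = tr$sampling_hz)
    }))
    write_table_det(gt, file.path(dir, "ground_truth.csv"))
    add(file.path(dir, "ground_truth.csv"))
    ids <- vapply(coh$sessions, function(s) s$session_id, character(1))
    write_table_det(data.frame(session_id = ids, hb_clinician = coh$grades),
                    file.path(dir, "grades.csv"))
    add(file.path(dir, "grades.csv"))
  } else if (mode == "register") {
    sessions <- read_sessions_dir(require_artifact(file.path(dir, "sessions"),
                                                   "session directory"))
    rdir <- file.path(dir, "registered")
    for (s in sessions) {
      rs <- tryCatch(register_session(
        s, grid_n = config$grid_n, smooth_window = config$smooth_window,
        threshold = config$threshold, n_points = config$n_points,
        rest_frac = config$rest_frac, repetition = config$repetition),
        hbgrade_error = function(e) {
          warning(sprintf("session %s: %s", s$session_id, conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
      if (is.null(rs)) next
      recs <- lapply(rs$registrations, function(r) r$recording)
      out <- session(s$session_id, s$patient_id, unname(recs),
                     hb_clinician = s$hb_clinician)
      attr(out, "registered") <- TRUE
      add(write_session(out, file.path(rdir, s$session_id)))
    }
  } else if (mode == "indicators") {
    sessions <- read_sessions_dir(require_artifact(file.path(dir, "sessions"),
                                                   "session directory"))
    ci <- cohort_indicators(sessions, config)
    tab <- indicator_table(ci$indicators)
    write_table_det(tab, file.path(dir, "indicators.csv"))
    add(file.path(dir, "indicators.csv"))
    if (!file.exists(file.path(dir, "grades.csv"))) {
      ids <- vapply(sessions, function(s) s$session_id, character(1))
      gr <- vapply(sessions, function(s) s$hb_clinician %||% NA_integer_,
                   integer(1))
      write_table_det(data.frame(session_id = ids, hb_clinician = gr),
                      file.path(dir, "grades.csv"))
      add(file.path(dir, "grades.csv"))
    }
  } else if (mode == "score") {
    tab <- utils::read.csv(require_artifact(file.path(dir, "indicators.csv"),
                                            "indicator table"))
    grades_raw <- read_grades(dir)
    inds <- indicators_from_table(tab, grades_raw)
    adj <- stats::setNames(adjust_grade(grades_raw[names(inds)]), names(inds))
    models <- fit_flr_models(inds, adj, basis_dim = config$basis_dim,
                             penalty = config$penalty,
                             speed_transform = config$speed_transform)
    add(write_model_json(models, file.path(dir, "models_flr.json")))
    scores <- score_dataset(models, inds)
    write_table_det(as.data.frame(scores), file.path(dir, "scores.csv"))
    add(file.path(dir, "scores.csv"))
  } else if (mode == "classify") {
    sc <- utils::read.csv(require_artifact(file.path(dir, "scores.csv"),
                                           "score table"))
    class(sc) <- c("hb_scores", "data.frame")
    grades_raw <- read_grades(dir)
    sm <- score_matrix(sc)
    adj <- adjust_grade(grades_raw[rownames(sm)])
    olr <- if (config$stepwise) stepwise_select(sc, adj)
    else fit_olr(sc, adj)
    add(write_model_json(olr, file.path(dir, "model_olr.json")))
    prob <- predict(olr, sm, type = "prob")
    pred <- grade_from_probabilities(prob)
    out <- data.frame(session_id = rownames(sm),
                      hb_clinician = as.integer(grades_raw[rownames(sm)]),
                      hb_model = pred)
    out[paste0("p_hb", hb_levels())] <- prob
    write_table_det(out, file.path(dir, "predictions.csv"))
    add(file.path(dir, "predictions.csv"))
  } else if (mode == "evaluate") {
    pr <- utils::read.csv(require_artifact(file.path(dir, "predictions.csv"),
                                           "prediction table"))
    cm <- confusion_matrix(adjust_grade(pr$hb_clinician), pr$hb_model)
    cmdf <- as.data.frame.matrix(unclass(cm))
    cmdf <- cbind(hb_clinician = rownames(cmdf), cmdf)
    write_table_det(cmdf, file.path(dir, "confusion.csv"))
    add(file.path(dir, "confusion.csv"))
    acc <- accuracy_report(cm)
    adf <- rbind(acc$per_class[c("class", "n", "correct_pct", "approximate_pct")],
                 data.frame(class = "all", n = acc$n,
                            correct_pct = acc$overall_correct_pct,
                            approximate_pct = acc$overall_approximate_pct))
    write_table_det(adf, file.path(dir, "accuracy.csv"))
    add(file.path(dir, "accuracy.csv"))
  } else if (mode == "report") {
    pr <- utils::read.csv(require_artifact(file.path(dir, "predictions.csv"),
                                           "prediction table"))
    sc <- utils::read.csv(require_artifact(file.path(dir, "scores.csv"),
                                           "score table"))
    olr <- read_model_json(file.path(dir, "model_olr.json"))
    class(sc) <- c("hb_scores", "data.frame")
    sm <- score_matrix(sc)
    sel <- intersect(olr$selected_labels, colnames(sm))
    rep_tab <- cbind(pr, as.data.frame(sm[pr$session_id, sel, drop = FALSE]))
    write_table_det(rep_tab, file.path(dir, "report.csv"))
    add(file.path(dir, "report.csv"))
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(stage = mode, seed = seed,
                   package_version = as.character(utils::packageVersion("hbgrade")),
                   config = unclass(config),
                   config_hash = config_hash(config),
                   artifacts = basename(written))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(written)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                           digits = NA)), tf)
  unname(tools::md5sum(tf))
}
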