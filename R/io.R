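#  File interfaces: maps as plain-text matrices with a JSON sidecar
#  (pixel spacing, slice and state labels), contours as JSON polygon lists
#  in mm coordinates, cohorts and reports as CSV. All round-trips are
#  lossless at full double precision.

sidecar_path <- function(path) paste0(sub("\\.[^.]*$", "", path), ".json")

#' Write / read a perfusion map
#'
#' The map grid is written as a whitespace-separated text matrix (`NA` for
#' background) and its metadata — `pixel_spacing`, `slice`, `state` — as a
#' JSON sidecar next to it (`<stem>.json`). Values survive the round trip
#' bit-exactly (17 significant digits).
#'
#' @param map a [perfusion_map()].
#' @param path destination for the matrix file (e.g. `"rest_mid.txt"`).
#' @return `write_map()` the paths invisibly; `read_map()` a
#'   [perfusion_map()].
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "perfusion_map"))
  txt <- apply(map$values, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(txt, path)
  meta <- list(pixel_spacing = map$spacing, slice = map$slice,
               state = map$state, n_row = nrow(map$values),
               n_col = ncol(map$values))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar_path(path)))
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop_tp("missing JSON sidecar %s", sp, class = "tp_error_format")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (field in c("pixel_spacing", "slice", "state")) {
    if (is.null(meta[[field]])) {
      stop_tp("sidecar %s is missing required field `%s`", sp, field,
              class = "tp_error_format")
    }
  }
  lines <- readLines(path)
  n_col <- length(strsplit(trimws(lines[1]), "\\s+")[[1]])
  vals <- scan(text = paste(lines, collapse = "\n"), what = numeric(),
               na.strings = "NA", quiet = TRUE)
  m <- matrix(vals, ncol = n_col, byrow = TRUE)
  perfusion_map(m, meta$pixel_spacing, slice = meta$slice, state = meta$state)
}

#' Write / read a contour set
#'
#' JSON with `endo` and `epi` vertex lists (mm) and the `rv_insertion`
#' point; validation ([contour_set()]) runs at load, so self-intersecting
#' polygons or an endocardial contour outside the epicardial one are
#' rejected.
#'
#' @param contours a [contour_set()].
#' @param path JSON file path.
#' @return `write_contours()` the path invisibly; `read_contours()` a
#'   [contour_set()].
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  jsonlite::write_json(list(endo = contours$endo, epi = contours$epi,
                            rv_insertion = contours$rv_insertion),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$endo) || is.null(obj$epi)) {
    stop_tp("contour file %s must contain `endo` and `epi` vertex lists",
            path, class = "tp_error_format")
  }
  rv <- obj$rv_insertion
  if (!is.null(rv)) rv <- as.numeric(rv)
  contour_set(as.matrix(obj$endo), as.matrix(obj$epi), rv_insertion = rv)
}

#' Discover a subject's six maps in a directory
#'
#' Follows the filename convention `<state>_<slice>.txt` (e.g.
#' `stress_basal.txt`, `rest_apical.txt`), each with its JSON sidecar, and
#' returns the nested list accepted by [subject_pipeline()]. Contour files
#' `contours_<slice>.json`, when present, are loaded alongside.
#'
#' @param dir subject directory.
#' @return list with `maps` (`$stress`/`$rest` by slice) and `contours`
#'   (by slice; `NULL` entries when absent).
#' @export
read_subject_dir <- function(dir) {
  if (!dir.exists(dir)) stop_tp("subject directory %s does not exist", dir)
  maps <- list(stress = list(), rest = list())
  for (state in c("stress", "rest")) {
    for (sl in c("basal", "mid", "apical")) {
      f <- file.path(dir, sprintf("%s_%s.txt", state, sl))
      if (!file.exists(f)) {
        stop_tp("missing map %s for subject directory %s", basename(f), dir,
                class = "tp_error_format")
      }
      maps[[state]][[sl]] <- read_map(f)
    }
  }
  contours <- lapply(stats::setNames(nm = c("basal", "mid", "apical")),
                     function(sl) {
                       f <- file.path(dir, sprintf("contours_%s.json", sl))
                       if (file.exists(f)) read_contours(f) else NULL
                     })
  list(maps = maps, contours = contours)
}

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param n_subjects simulated cohort size (used when `metrics_csv` is
#'   `NULL`).
#' @param seed master seed: cohort simulation and bootstrap CIs.
#' @param qc_exclude character vector of subject IDs to flag as
#'   quality-control exclusions.
#' @param spec optional [cohort_spec()] override for the simulation.
#' @param metrics_csv optional path to an existing metrics CSV (one row per
#'   subject, [cohort_metrics()]-compatible columns) to analyse instead of
#'   simulating.
#' @param verbose emit stage log lines via `message()`.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, n_subjects = 20, seed = 1,
                       qc_exclude = character(0), spec = NULL,
                       metrics_csv = NULL, verbose = TRUE) {
  structure(list(out_dir = out_dir, n_subjects = n_subjects, seed = seed,
                 qc_exclude = qc_exclude, spec = spec,
                 metrics_csv = metrics_csv, verbose = verbose),
            class = "run_config")
}

#' Run the cohort pipeline end to end
#'
#' Simulate-or-load, derive metrics, apply QC exclusions, build the
#' normative report and write everything (metrics CSV, one CSV per report
#' table, a JSON run summary) under `out_dir`. Deterministic for a fixed
#' seed: repeated runs produce byte-identical CSVs.
#'
#' @param config a [run_config()], or a path to a JSON/YAML file with the
#'   same fields.
#' @return the [build_report()] result, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- do.call(run_config, read_config(config))
  stopifnot(inherits(config, "run_config"))
  log <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  t0 <- Sys.time()
  if (!is.null(config$metrics_csv)) {
    log("stage load: reading metrics from %s", config$metrics_csv)
    cohort <- tibble::as_tibble(utils::read.csv(config$metrics_csv))
    cohort$sex <- factor(cohort$sex, levels = c("female", "male"))
  } else {
    spec <- config$spec %||% cohort_spec(n_subjects = config$n_subjects)
    log("stage simulate: %d subjects (seed %d)", spec$n_subjects, config$seed)
    cohort <- make_cohort(spec, seed = config$seed)
  }
  metrics <- cohort_metrics(cohort)
  metrics$qc_excluded <- metrics$qc_excluded | metrics$subject_id %in% config$qc_exclude
  n_excl <- sum(metrics$qc_excluded)
  if (n_excl > 0) {
    log("stage qc: excluding %d subject(s): %s", n_excl,
        paste(metrics$subject_id[metrics$qc_excluded], collapse = ", "))
  }
  log("stage report: summarizing %d subjects", sum(!metrics$qc_excluded))
  report <- build_report(metrics, boot_seed = config$seed)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  for (nm in names(report$tables)) {
    utils::write.csv(report$tables[[nm]],
                     file.path(config$out_dir, paste0("report_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(n_total = report$n_total, n_excluded = report$n_excluded,
         n_used = report$n_used, seed = config$seed,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    file.path(config$out_dir, "run_summary.json"), auto_unbox = TRUE)
  log("stage done: report written to %s", config$out_dir)
  invisible(report)
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_tp("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
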