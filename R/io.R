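# Dataset and configuration readers/writers.

#' Read a longitudinal dataset from CSV
#'
#' Expects a header with at least `ID`, `TIME`, `DV` (one row per
#' observation).  Rows are grouped by subject and sorted by time; duplicate
#' `(ID, TIME)` pairs and non-numeric `DV` values are rejected with the
#' offending row numbers.
#'
#' @param path CSV file path.
#' @return A tibble with columns `ID`, `TIME`, `DV` (class `sdmem_dataset`).
#' @export
read_dataset <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(c("ID", "TIME", "DV"), names(raw))
  if (length(missing))
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L) {
    warning("dataset has no observation rows")
    out <- tibble::tibble(ID = character(0), TIME = numeric(0),
                          DV = numeric(0))
    class(out) <- c("sdmem_dataset", class(out))
    return(out)
  }
  num <- function(col, nm) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric %s value(s) at data row(s): %s", nm,
                   paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
    v
  }
  ids <- utils::type.convert(raw$ID, as.is = TRUE)
  out <- tibble::tibble(ID = ids, TIME = num("TIME", "TIME"),
                        DV = num("DV", "DV"))
  dup <- duplicated(out[c("ID", "TIME")])
  if (any(dup))
    stop("duplicate (ID, TIME) pair(s) at data row(s): ",
         paste(utils::head(which(dup), 10), collapse = ", "), call. = FALSE)
  out <- dplyr::arrange(out, .data$ID, .data$TIME)
  class(out) <- c("sdmem_dataset", class(out))
  out
}

#' Write a dataset (and simulation truth, if present) to CSV
#'
#' @param dataset A dataset tibble (`ID`, `TIME`, `DV`).
#' @param path Output CSV path; when the dataset carries a `"truth"`
#'   attribute (simulated data), a companion `<path>_truth.csv` is written
#'   with the per-subject random effects and individual parameters.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  readr::write_csv(tibble::as_tibble(dataset)[c("ID", "TIME", "DV")], path)
  truth <- attr(dataset, "truth")
  if (!is.null(truth))
    readr::write_csv(truth, sub("(\\.csv)?$", "_truth.csv", path,
                                ignore.case = TRUE))
  invisible(path)
}

#' Write estimates (or a replicate-study summary) to disk
#'
#' Writes a CSV estimate table plus a JSON metadata record (seeds,
#' convergence, method, package version) sufficient to identify the run.
#' Fixed parameters are marked and carry no RSE, mirroring the dash
#' convention of summary tables for parameters that are not estimated.
#'
#' @param x An `sdmem_fit` or `sdmem_replicate_study`.
#' @param path Output stem: writes `<path>.csv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(x, path) {
  stem <- sub("\\.(csv|json)$", "", path)
  tab <- tidy(x)
  readr::write_csv(tab, paste0(stem, ".csv"))
  meta <- if (inherits(x, "sdmem_fit")) {
    list(type = "fit", method = x$method, objective = x$objective,
         convergence = x$convergence[c("converged", "criterion",
                                       "iterations")],
         fixed = as.list(x$fixed), n_subjects = x$n_subjects,
         n_obs = x$n_obs, h_max = x$h_max,
         package_version = as.character(utils::packageVersion("sdmem")))
  } else {
    list(type = "replicate_study", method = x$method, seed = x$seed,
         n_replicates = x$n_replicates, modes = x$modes,
         n_excluded = as.list(stats::setNames(x$n_excluded$n_excluded,
                                              x$n_excluded$mode)),
         valid = x$valid,
         package_version = as.character(utils::packageVersion("sdmem")))
  }
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read back an estimate table written by [write_estimates()]
#'
#' @param path The stem or `.csv` path.
#' @return A tibble.
#' @export
read_estimates <- function(path) {
  stem <- sub("\\.(csv|json)$", "", path)
  readr::read_csv(paste0(stem, ".csv"), show_col_types = FALSE)
}

#' Read a run configuration (YAML or JSON)
#'
#' A run configuration names a built-in model and collects the estimation
#' method, starting values, fixed-parameter mask, design (observation times,
#' subject count, infusion schedule), seeds and tolerances.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list with class `sdmem_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$model))
    stop("config must name a model", call. = FALSE)
  # validates that the model exists
  invisible(get_model(cfg$model))
  if (!is.null(cfg$design$times) && any(cfg$design$times < 0))
    stop("observation times must be nonnegative", call. = FALSE)
  structure(cfg, class = c("sdmem_config", "list"))
}

#' Build the model, design and start vector from a configuration
#' @param cfg An `sdmem_config`.
#' @return List with `model`, `design`, `start`, `fixed`, `method`, `seed`.
#' @export
materialize_config <- function(cfg) {
  model_args <- cfg$model_args %||% list()
  model <- do.call(get_model, c(list(cfg$model), model_args))
  design <- study_design(
    n_subjects = cfg$design$n_subjects,
    times = cfg$design$times,
    input = cfg$design$input,
    seed = cfg$seed %||% 1L)
  list(model = model, design = design,
       start = unlist(cfg$start), fixed = unlist(cfg$fixed),
       truth = unlist(cfg$truth),
       method = cfg$method %||% "FOCEI", seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
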