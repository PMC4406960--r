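# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a population fit
#'
#' @param x An `sdmem_fit`.
#' @param ... Unused.
#' @return A tibble with one row per population parameter: `parameter`,
#'   `estimate` (natural scale), `rse_pct` (Hessian-based, `NA` if not
#'   computed or not estimated) and `fixed`.
#' @exportS3Method generics::tidy
tidy.sdmem_fit <- function(x, ...) {
  nm <- names(x$theta)
  tibble::tibble(
    parameter = nm,
    estimate = unname(x$theta),
    rse_pct = if (is.null(x$rse)) NA_real_ else unname(x$rse[nm]),
    fixed = nm %in% names(x$fixed))
}

#' One-row summary of a population fit
#'
#' @param x An `sdmem_fit`.
#' @param ... Unused.
#' @return A one-row tibble: objective value, method, convergence
#'   diagnostics, subject/observation counts.
#' @exportS3Method generics::glance
glance.sdmem_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    method = x$method,
    converged = x$convergence$converged,
    criterion = x$convergence$criterion,
    iterations = x$convergence$iterations,
    max_grad = x$convergence$max_grad,
    n_subjects = x$n_subjects,
    n_obs = x$n_obs)
}

#' Tidy a replicate study
#'
#' @param x An `sdmem_replicate_study`.
#' @param ... Unused.
#' @return A tibble with one row per mode and parameter: replicate `mean`,
#'   `sd`, `rse_pct = 100 sd/|mean|`, the `true` value and the number of
#'   converged replicates used.
#' @exportS3Method generics::tidy
tidy.sdmem_replicate_study <- function(x, ...) {
  x$summary |>
    dplyr::mutate(true = unname(x$truth[.data$parameter])) |>
    dplyr::select("mode", "parameter", "true", "mean", "sd", "rse_pct",
                  "n_used")
}

#' One-row summary of a replicate study
#'
#' @param x An `sdmem_replicate_study`.
#' @param ... Unused.
#' @return A one-row tibble with replicate counts, exclusions and validity.
#' @exportS3Method generics::glance
glance.sdmem_replicate_study <- function(x, ...) {
  tibble::tibble(
    n_replicates = x$n_replicates,
    modes = paste(x$modes, collapse = "/"),
    method = x$method,
    n_excluded = sum(x$n_excluded$n_excluded),
    valid = x$valid,
    seed = x$seed)
}
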