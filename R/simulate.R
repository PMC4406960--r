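#' Study design for simulation
#'
#' @param n_subjects Number of subjects.
#' @param times Strictly increasing, nonnegative observation times (min).
#'   Either a single numeric vector shared by all subjects or a list of one
#'   vector per subject.
#' @param input Optional input schedule (see [dynamic_model()]); a single
#'   schedule or a list of one per subject.  `NULL` uses the model's own.
#' @param seed Default seed used when simulating from this design.
#' @return An object of class `study_design`.
#' @examples
#' study_design(20, seq(1, 97, by = 8))
#' @export
study_design <- function(n_subjects, times, input = NULL, seed = 1L) {
  tl <- if (is.list(times)) times else replicate(n_subjects, times,
                                                 simplify = FALSE)
  if (length(tl) != n_subjects)
    stop("need one observation-time vector per subject", call. = FALSE)
  for (tt in tl)
    if (any(tt < 0) || any(diff(tt) <= 0))
      stop("observation times must be nonnegative and strictly increasing",
           call. = FALSE)
  if (!is.null(input) && !is.list(input[[1]]) && !is.function(input))
    input <- replicate(n_subjects, input, simplify = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), times = tl,
                 input = input, seed = as.integer(seed)),
            class = "study_design")
}

design_input <- function(design, model, i) {
  if (is.null(design$input)) return(model$input)
  if (is.list(design$input) && !is.null(design$input$knots))
    return(design$input)
  design$input[[i]]
}

#' Simulate one subject's latent path and observations
#'
#' Integrates the stochastic differential equation by Euler-Maruyama,
#' `x[t+h] = x[t] + f h + Sigma sqrt(h) z`, `z ~ N(0, I)`, on a grid of step
#' `step` refined so that every observation time and input breakpoint falls
#' on the grid.  Observations are `h(x(t_k))` plus measurement noise drawn
#' from the model's measurement covariance.  During simulation the diffusion
#' and a state-dependent measurement covariance are evaluated at the current
#' simulated state (there is no filter estimate to substitute).
#'
#' @param model A [dynamic_model()].
#' @param phi Named individual parameter vector.
#' @param times Observation times, or a [study_design()] whose first
#'   subject's times are used.
#' @param step Euler-Maruyama time increment (min); must be positive.
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param input Optional input schedule overriding the model's.
#' @return A list with `path` (tibble `TIME`, one column per state) and
#'   `obs` (tibble `TIME`, `DV`, `Y_TRUE` the noise-free output).
#' @export
simulate_individual_path <- function(model, phi, times, step = 0.01,
                                     seed = NULL, input = NULL) {
  if (inherits(times, "study_design")) times <- times$times[[1]]
  if (!is.numeric(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(input)) input <- model$input
  x <- as.numeric(model$initial_state(phi))
  n <- model$n_states
  # grid: union of regular step grid, observation times and input knots
  tmax <- max(times)
  grid <- seq(0, tmax, by = step)
  knots <- if (is.list(input) && !is.null(input$knots)) input$knots else numeric(0)
  grid <- sort(unique(c(grid, times, tmax, knots[knots > 0 & knots < tmax])))
  path <- matrix(NA_real_, length(grid), n)
  path[1, ] <- x
  for (g in seq_len(length(grid) - 1L)) {
    t0 <- grid[g]; h <- grid[g + 1L] - t0
    u <- input_value(input, t0)
    f <- as.numeric(model$drift(x, u, t0, phi))
    Sg <- model$diffusion(x, u, t0, phi)
    x <- x + f * h
    if (NCOL(Sg) > 0)
      x <- x + as.numeric(Sg %*% stats::rnorm(NCOL(Sg))) * sqrt(h)
    path[g + 1L, ] <- x
  }
  idx <- match(times, grid)
  y_true <- numeric(length(times)); dv <- numeric(length(times))
  for (k in seq_along(times)) {
    xk <- path[idx[k], ]
    u <- input_value(input, times[k])
    yk <- as.numeric(model$measurement(xk, u, times[k], phi))
    S <- as.matrix(model$measurement_cov(xk, u, times[k], phi))
    e <- as.numeric(chol_psd(S) %*% stats::rnorm(nrow(S)))
    y_true[k] <- yk[1]; dv[k] <- yk[1] + e[1]
  }
  colnames(path) <- model$state_names
  list(path = tibble::as_tibble(as.data.frame(cbind(TIME = grid, path))),
       obs = tibble::tibble(TIME = times, DV = dv, Y_TRUE = y_true))
}

# Cholesky-like factor tolerant of zero (PSD) diagonals
chol_psd <- function(S) {
  S <- as.matrix(S)
  if (all(abs(S) < .Machine$double.eps)) return(S * 0)
  ev <- eigen(S, symmetric = TRUE)
  v <- pmax(ev$values, 0)
  ev$vectors %*% (sqrt(v) * t(ev$vectors))
}

#' Simulate a population dataset
#'
#' Draws random effects `eta_i ~ N(0, U U')` independently per subject, maps
#' them to individual parameters, and simulates each subject independently
#' with [simulate_individual_path()].  The true random effects and
#' individual parameters are retained as the `"truth"` attribute.
#'
#' @param model A [dynamic_model()].
#' @param population A [population_parameters()] object.
#' @param map A [parameter_map()]; defaults to the model's own.
#' @param design A [study_design()].
#' @param step Euler-Maruyama step (min).
#' @param seed Integer seed; defaults to the design's seed.
#' @return A tibble with columns `ID`, `TIME`, `DV` (class `sdmem_dataset`),
#'   with attributes `truth` (tibble of per-subject `eta`/`phi`) and
#'   `paths` (list of latent path tibbles).
#' @examples
#' m <- one_compartment_pk_model()
#' pop <- population_parameters(
#'   theta = c(ka = 0.1, Vm = 0.5, Km = 3, V = 1, s = 0.1, sigma = 0.05),
#'   omega_factor = matrix(c(0.5, 0, 0.1, 0.3), 2, 2))
#' d <- simulate_population_dataset(m, pop, design = study_design(3, c(1, 9, 17)))
#' @export
simulate_population_dataset <- function(model, population, map = model$map,
                                        design, step = 0.01, seed = NULL) {
  stopifnot(inherits(population, "population_parameters"),
            inherits(design, "study_design"))
  if (!all(is.finite(population$theta)) ||
      !all(is.finite(population$omega_factor)))
    stop("population parameters must be finite", call. = FALSE)
  if (is.null(seed)) seed <- design$seed
  set.seed(seed)
  N <- design$n_subjects
  q <- map$n_random
  L <- chol_psd(population$omega)
  eta <- matrix(stats::rnorm(N * q), N, q) %*% t(L)
  rows <- vector("list", N); truth <- vector("list", N); paths <- vector("list", N)
  for (i in seq_len(N)) {
    phi <- map$transform(population$theta, NULL, eta[i, ])
    sim <- simulate_individual_path(model, phi, design$times[[i]], step = step,
                                    seed = NULL,
                                    input = design_input(design, model, i))
    rows[[i]] <- tibble::tibble(ID = i, TIME = sim$obs$TIME, DV = sim$obs$DV)
    truth[[i]] <- tibble::tibble(ID = i,
                                 !!!stats::setNames(as.list(eta[i, ]),
                                                    paste0("eta", seq_len(q))),
                                 !!!as.list(phi))
    paths[[i]] <- sim$path
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  attr(out, "paths") <- paths
  class(out) <- c("sdmem_dataset", class(out))
  out
}

#' Split a dataset into per-subject observation tables
#' @param data A tibble with `ID`, `TIME`, `DV`.
#' @return Named list of per-subject tibbles (`TIME`, `DV`), sorted by time.
#' @keywords internal
split_subjects <- function(data) {
  stopifnot(all(c("ID", "TIME", "DV") %in% names(data)))
  data <- dplyr::arrange(tibble::as_tibble(data)[c("ID", "TIME", "DV")],
                         .data$ID, .data$TIME)
  split(data[c("TIME", "DV")], factor(data$ID, levels = unique(data$ID)))
}
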