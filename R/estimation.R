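# Nested optimization: per-subject (inner) optimization of the a-posteriori
# random-effects likelihood, population-level (outer) BFGS on the
# transformed parameter scale, Hessian-based relative standard errors, and
# the replicate simulation-study driver.

#' Optimize the random effects for one subject
#'
#' Minimizes the negative a-posteriori log-likelihood `-l_i(eta)` by a
#' damped Newton method that uses the (always positive-definite) FOCE
#' information matrix as metric and the exact sensitivity-based gradient,
#' with Armijo backtracking.  Convergence is declared when the gradient
#' infinity-norm falls below `tol` or the relative objective change below
#' `1e-10`.
#'
#' @param data_i Subject observations (`TIME`, `DV`).
#' @param theta Named fixed-effects vector.
#' @param omega Random-effects covariance.
#' @param model A [dynamic_model()].
#' @param map A [parameter_map()].
#' @param eta0 Starting value (warm start); defaults to zero.
#' @param method Which approximate Hessian (`Delta l`) to report:
#'   `"FOCEI"` or `"FOCE"`.
#' @param tol Gradient infinity-norm tolerance.
#' @param max_iter Iteration cap; exceeding it sets `converged = FALSE` and
#'   returns the best iterate.
#' @param P0,h_max,input Passed to the filter.
#' @return A list of class `sdmem_individual_fit`: `eta_star`, `value`
#'   (`-l_i` at the optimum), `gradient`, `hessian` (`Delta l` by the
#'   requested method), `phi_bundle` (phi-block sensitivities at the
#'   optimum), `converged`, `iterations`.
#' @export
inner_optimize <- function(data_i, theta, omega, model, map = model$map,
                           eta0 = NULL, method = c("FOCEI", "FOCE"),
                           tol = 1e-6, max_iter = 100L, P0 = NULL,
                           h_max = 0.1, input = NULL) {
  method <- match.arg(method)
  omega <- as.matrix(omega)
  q <- map$n_random
  if (is.null(eta0)) eta0 <- rep(0, q)
  if (q == 0L) {
    phi <- map$transform(theta, NULL, numeric(0))
    pb <- phi_sensitivities(model, phi, data_i, P0 = P0, h_max = h_max,
                            input = input)
    return(structure(list(
      eta_star = numeric(0), value = nll_data_terms(pb$eps, pb$R),
      gradient = numeric(0), hessian = matrix(0, 0, 0), phi_bundle = pb,
      converged = TRUE, iterations = 0L), class = "sdmem_individual_fit"))
  }
  om_inv <- solve(omega)
  if (nrow(data_i) == 0L) {
    empty <- structure(list(eps = numeric(0), R = numeric(0),
                            deps = matrix(0, 0, q), dR = matrix(0, 0, q),
                            par_names = paste0("eta", seq_len(q))),
                       class = "sdmem_sensitivities")
    return(structure(list(
      eta_star = rep(0, q), value = eta_prior_nll(rep(0, q), omega),
      gradient = rep(0, q), hessian = -om_inv, phi_bundle = empty,
      converged = TRUE, iterations = 0L), class = "sdmem_individual_fit"))
  }
  prior <- function(eta) eta_prior_nll(eta, omega)
  value_at <- function(eta) {
    phi <- map$transform(theta, NULL, eta)
    fr <- tryCatch(filter_eps_R(model, phi, data_i, P0 = P0, h_max = h_max,
                                input = input),
                   error = function(e) NULL)
    if (is.null(fr)) return(Inf)
    v <- nll_data_terms(fr$eps, fr$R) + prior(eta)
    if (!is.finite(v)) Inf else v
  }
  full_at <- function(eta) {
    out <- tryCatch({
      phi <- map$transform(theta, NULL, eta)
      pb <- phi_sensitivities(model, phi, data_i, P0 = P0, h_max = h_max,
                              input = input)
      eb <- chain_bundle(pb, map_d_eta(map, theta, NULL, eta),
                         paste0("eta", seq_len(q)))
      list(phi_bundle = pb, bundle = eb,
           value = nll_data_terms(eb$eps, eb$R) + prior(eta),
           gradient = nll_data_gradient(eb) + as.numeric(om_inv %*% eta))
    }, error = function(e) NULL)
    if (is.null(out) || !is.finite(out$value) ||
        !all(is.finite(out$gradient)))
      return(list(value = Inf))
    out
  }
  eta <- eta0
  cur <- full_at(eta)
  if (!is.finite(cur$value)) { eta <- rep(0, q); cur <- full_at(eta) }
  if (!is.finite(cur$value))
    stop("inner objective is not finite at the starting point", call. = FALSE)
  converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    if (max(abs(cur$gradient)) <= tol) { converged <- TRUE; break }
    iter <- iter + 1L
    info <- t(cur$bundle$deps) %*% (cur$bundle$deps / cur$bundle$R) + om_inv
    dir <- tryCatch(-solve(info, cur$gradient),
                    error = function(e) -cur$gradient)
    slope <- sum(cur$gradient * dir)
    if (slope >= 0) { dir <- -cur$gradient; slope <- -sum(cur$gradient^2) }
    step <- 1; newv <- NULL
    for (ls in seq_len(30L)) {
      cand <- eta + step * dir
      v <- value_at(cand)
      if (v <= cur$value + 1e-4 * step * slope) {
        trial <- full_at(cand)
        if (is.finite(trial$value)) { newv <- trial; break }
      }
      step <- step / 2
    }
    if (is.null(newv)) break
    relchg <- abs(cur$value - newv$value) / (1 + abs(newv$value))
    eta <- cand; cur <- newv
    # objective change at the floating-point floor: no further progress is
    # representable (counts as the relative-change convergence rule)
    if (relchg <= 1e-13 && max(abs(cur$gradient)) <= 1e-4) {
      converged <- TRUE; break
    }
  }
  if (max(abs(cur$gradient)) <= tol) converged <- TRUE
  structure(list(
    eta_star = eta, value = cur$value, gradient = cur$gradient,
    hessian = approx_hessian(cur$bundle, omega, method),
    phi_bundle = cur$phi_bundle, converged = converged, iterations = iter),
    class = "sdmem_individual_fit")
}

# transform helpers between the natural and optimizer scales
to_transformed <- function(nat, scale)
  ifelse(scale[names(nat)] == "log", log(nat), nat)
from_transformed <- function(tr, scale)
  ifelse(scale[names(tr)] == "log", exp(tr), tr)

#' Fit a population model by nested BFGS
#'
#' Maximizes the Laplace-approximated population likelihood
#' ([laplace_population_nll()]) over the population parameters.  Positive
#' parameters (structural, error magnitudes, diagonal covariance-factor
#' entries) are optimized on the log scale; the off-diagonal factor entry is
#' unconstrained.  Each outer iteration warm-starts every subject's inner
#' problem at its previous optimum.  The outer optimizer is BFGS with Armijo
#' backtracking and sensitivity-equation gradients ([outer_gradient()]);
#' convergence is declared at gradient infinity-norm `<= outer_tol` on the
#' transformed scale.
#'
#' @param dataset Data frame with `ID`, `TIME`, `DV`.
#' @param model A [dynamic_model()] with fit metadata.
#' @param map A [parameter_map()].
#' @param start Named starting values for the full population vector
#'   (natural scale).
#' @param method `"FOCEI"` or `"FOCE"`.
#' @param fixed Named vector of parameters to pin (e.g. `c(sigma = 0)` for
#'   an ODE fit); fixed parameters are excluded from optimization.
#' @param rse If `TRUE`, compute Hessian-based relative standard errors at
#'   the optimum via [compute_rse()].
#' @param outer_tol Gradient infinity-norm tolerance (transformed scale).
#' @param max_iter Outer iteration cap.
#' @param P0,h_max,input Passed to the filter.
#' @param trace If `TRUE`, print one line per outer iteration.
#' @return An object of class `sdmem_fit`; see [tidy.sdmem_fit()] and
#'   [glance.sdmem_fit()].
#' @export
fit_population <- function(dataset, model, map = model$map, start,
                           method = c("FOCEI", "FOCE"), fixed = NULL,
                           rse = TRUE, outer_tol = 1e-4, max_iter = 300L,
                           P0 = NULL, h_max = 0.1, input = NULL,
                           trace = FALSE) {
  method <- match.arg(method)
  fs <- model$fit_spec
  all_names <- c(fs$theta_names, fs$omega_names)
  if (!all(all_names %in% c(names(start), names(fixed))))
    stop("start/fixed must cover: ", paste(all_names, collapse = ", "),
         call. = FALSE)
  free <- setdiff(all_names, names(fixed))
  scale <- fs$par_scale
  warm <- new.env(parent = emptyenv())
  assemble <- function(tr) {
    nat <- from_transformed(tr, scale)
    full <- stats::setNames(numeric(length(all_names)), all_names)
    full[free] <- nat[free]
    if (length(fixed)) full[names(fixed)] <- fixed
    full
  }
  n_obj <- 0L; n_grad <- 0L
  objective <- function(tr) {
    n_obj <<- n_obj + 1L
    th <- assemble(tr)
    v <- tryCatch(
      laplace_population_nll(th, dataset, model, map, method = method,
                             P0 = P0, h_max = h_max, input = input,
                             warm = warm),
      error = function(e) Inf)
    as.numeric(v)
  }
  gradient <- function(tr) {
    n_grad <<- n_grad + 1L
    th <- assemble(tr)
    g_nat <- outer_gradient(th, dataset, model, map, method = method,
                            free = free, P0 = P0, h_max = h_max,
                            input = input, warm = warm)
    g_tr <- ifelse(scale[free] == "log", g_nat * th[free], g_nat)
    attr(g_tr, "value") <- attr(g_nat, "value")
    g_tr
  }
  safe_gradient <- function(tr) {
    out <- tryCatch(gradient(tr), error = function(e) NULL)
    if (!is.null(out) &&
        (!all(is.finite(out)) || !is.finite(attr(out, "value"))))
      out <- NULL
    out
  }
  tr <- to_transformed(start[free], scale)
  g <- gradient(tr); f <- attr(g, "value")
  if (!is.finite(f))
    stop("objective is not finite at the starting values", call. = FALSE)
  Hinv <- diag(length(free)) / max(1, sqrt(sum(g^2)))
  trace_rows <- list(
    tibble::tibble(iteration = 0L, objective = f, max_grad = max(abs(g))))
  converged <- FALSE; criterion <- "max_iter"; iter <- 0L
  small_steps <- 0L; reset_tried <- FALSE
  while (iter < max_iter) {
    if (max(abs(g)) <= outer_tol) {
      converged <- TRUE; criterion <- "gtol"; break
    }
    iter <- iter + 1L
    dir <- as.numeric(-Hinv %*% g)
    slope <- sum(g * dir)
    if (!is.finite(slope) || slope >= 0) {
      Hinv <- diag(length(free)) / max(1, sqrt(sum(g^2)))
      dir <- as.numeric(-Hinv %*% g); slope <- sum(g * dir)
    }
    # keep individual transformed-parameter moves bounded per iteration
    if (max(abs(dir)) > 2) {
      dir <- dir * 2 / max(abs(dir)); slope <- sum(g * dir)
    }
    step <- 1; g_new <- NULL
    for (ls in seq_len(30L)) {
      cand <- tr + step * dir
      fv <- objective(cand)
      if (is.finite(fv) && fv <= f + 1e-4 * step * slope) {
        trial <- safe_gradient(cand)
        if (!is.null(trial)) { g_new <- trial; break }
      }
      step <- step / 2
    }
    if (is.null(g_new)) {
      # no acceptable step along the quasi-Newton direction: retry once from
      # a freshly scaled steepest-descent metric, then accept the numerical
      # floor if the gradient is already small
      if (!reset_tried) {
        Hinv <- diag(length(free)) / max(1, sqrt(sum(g^2)))
        reset_tried <- TRUE
        next
      }
      if (max(abs(g)) <= 1e-2) {
        converged <- TRUE; criterion <- "gfloor"
      } else criterion <- "line_search"
      break
    }
    reset_tried <- FALSE
    f_new <- attr(g_new, "value")
    sv <- cand - tr; yv <- as.numeric(g_new - g)
    sy <- sum(sv * yv)
    if (is.finite(sy) && sy > 1e-10 * sqrt(sum(sv^2) * sum(yv^2))) {
      rho <- 1 / sy
      I <- diag(length(free))
      V <- I - rho * outer(sv, yv)
      Hinv <- V %*% Hinv %*% t(V) + rho * outer(sv, sv)
    }
    relchg <- abs(f - f_new) / (1 + abs(f_new))
    tr <- cand; f <- f_new; g <- g_new
    trace_rows[[length(trace_rows) + 1L]] <-
      tibble::tibble(iteration = iter, objective = f, max_grad = max(abs(g)))
    if (trace)
      message(sprintf("iter %3d  obj %.6f  |g|_inf %.3g", iter, f,
                      max(abs(g))))
    if (relchg <= 1e-11) {
      small_steps <- small_steps + 1L
      if (small_steps >= 3L) { converged <- TRUE; criterion <- "ftol"; break }
    } else small_steps <- 0L
  }
  if (!converged && max(abs(g)) <= outer_tol) {
    converged <- TRUE; criterion <- "gtol"
  }
  theta_hat <- assemble(tr)
  final <- laplace_population_nll(theta_hat, dataset, model, map,
                                  method = method, P0 = P0, h_max = h_max,
                                  input = input, warm = warm)
  fit <- structure(list(
    theta = theta_hat, free = free, fixed = fixed, method = method,
    objective = as.numeric(final),
    contributions = attr(final, "contributions"),
    eta_star = attr(final, "eta_star"),
    inner_converged = attr(final, "inner_converged"),
    convergence = list(converged = converged, criterion = criterion,
                       iterations = iter, max_grad = max(abs(g)),
                       n_objective = n_obj, n_gradient = n_grad),
    trace = dplyr::bind_rows(trace_rows),
    model = model, map = map, scale = scale,
    n_subjects = length(unique(dataset$ID)),
    n_obs = nrow(dataset),
    P0 = P0, h_max = h_max, input = input,
    rse = NULL), class = "sdmem_fit")
  if (rse) fit$rse <- compute_rse(fit, dataset, model, map)
  fit
}

#' @export
print.sdmem_fit <- function(x, ...) {
  cat(sprintf("<sdmem_fit> %s, %d subject(s), -2logLik/2 = %.4f, %s\n",
              x$method, x$n_subjects, x$objective,
              if (x$convergence$converged)
                sprintf("converged (%s, %d iterations)",
                        x$convergence$criterion, x$convergence$iterations)
              else "NOT converged"))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Relative standard errors from the outer Hessian
#'
#' Approximates the Hessian of the outer objective at the optimum by central
#' finite differences of the sensitivity-equation gradient on the
#' transformed scale, inverts it, and delta-method-transforms the resulting
#' covariance to the natural scale.  `RSE% = 100 sqrt(diag(H^-1)) / |theta|`.
#'
#' @param fit An `sdmem_fit`.
#' @param dataset,model,map The data and model used for the fit.
#' @param h Finite-difference step on the transformed scale.
#' @return Named RSE% vector over the free parameters (`NA` for fixed
#'   parameters, which are not estimated); attribute `"pd"` is `FALSE` when
#'   the Hessian was not positive definite and a pseudo-inverse was used.
#' @export
compute_rse <- function(fit, dataset = NULL, model = fit$model,
                        map = fit$map, h = 1e-3) {
  if (is.null(dataset))
    stop("compute_rse needs the dataset the model was fitted to",
         call. = FALSE)
  free <- fit$free; scale <- fit$scale
  warm <- new.env(parent = emptyenv())
  gr <- function(tr) {
    nat <- from_transformed(tr, scale)
    th <- fit$theta; th[free] <- nat[free]
    g_nat <- outer_gradient(th, dataset, model, map, method = fit$method,
                            free = free, P0 = fit$P0, h_max = fit$h_max,
                            input = fit$input, warm = warm)
    ifelse(scale[free] == "log", g_nat * th[free], g_nat)
  }
  tr0 <- to_transformed(fit$theta[free], scale)
  p <- length(free)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    tp <- tr0; tp[j] <- tp[j] + h
    tm <- tr0; tm[j] <- tm[j] - h
    H[, j] <- (gr(tp) - gr(tm)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  pd <- all(ev$values > 0)
  if (!pd)
    warning("outer Hessian not positive definite; using pseudo-inverse")
  inv <- ifelse(ev$values > 1e-10 * max(abs(ev$values)), 1 / ev$values, 0)
  cov_tr <- ev$vectors %*% (inv * t(ev$vectors))
  jac <- ifelse(scale[free] == "log", fit$theta[free], 1)
  se_nat <- sqrt(pmax(diag(cov_tr), 0)) * abs(jac)
  rse <- stats::setNames(100 * se_nat / abs(fit$theta[free]), free)
  all_names <- names(fit$theta)
  out <- stats::setNames(rep(NA_real_, length(all_names)), all_names)
  out[free] <- rse
  attr(out, "pd") <- pd
  out
}

#' Replicate simulation study
#'
#' Simulates `n_replicates` population datasets from the true parameters and
#' re-estimates the model on each, in one or both of two modes: `"sde"`
#' (system-noise factor estimated) and `"ode"` (`sigma` fixed at zero).
#' Per-replicate seeds derive from the master seed by a counter, so the
#' whole study is reproducible.  Replicates whose fit does not converge are
#' excluded from the summaries and counted; a study with more than 20%
#' exclusions in any mode is flagged invalid.
#'
#' @param model A [dynamic_model()] with fit metadata.
#' @param truth Named true population vector (fixed effects plus
#'   covariance-factor entries, natural scale).
#' @param start Named starting values for estimation (defaults to `truth`).
#' @param design A [study_design()].
#' @param n_replicates Number of simulated datasets.
#' @param seed Master seed.
#' @param modes Subset of `c("sde", "ode")`.
#' @param method `"FOCEI"` or `"FOCE"`.
#' @param map A [parameter_map()].
#' @param sim_step Euler-Maruyama step for simulation.
#' @param fixed Extra parameters to pin in every fit (in addition to
#'   `sigma = 0` for the ODE mode).
#' @param h_max,outer_tol,max_iter Passed to [fit_population()].
#' @return An object of class `sdmem_replicate_study` with `estimates`
#'   (tibble: replicate, mode, parameter, estimate, converged), `summary`
#'   (tibble: mode, parameter, mean, sd, `rse_pct = 100 sd/mean`,
#'   `n_used`), `n_excluded` per mode and a `valid` flag.
#' @export
replicate_study <- function(model, truth, start = truth, design,
                            n_replicates = 20L, seed = 1L,
                            modes = c("sde", "ode"),
                            method = c("FOCEI", "FOCE"), map = model$map,
                            sim_step = 0.01, fixed = NULL, h_max = 0.1,
                            outer_tol = 1e-4, max_iter = 300L) {
  method <- match.arg(method)
  modes <- match.arg(modes, several.ok = TRUE)
  fs <- model$fit_spec
  U <- omega_factor_from_theta(truth, fs$omega_names)
  pop <- population_parameters(theta_fixed_effects(truth, fs), U)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    dataset <- simulate_population_dataset(model, pop, map, design,
                                           step = sim_step,
                                           seed = seed + r)
    for (mode in modes) {
      fx <- fixed
      st <- start
      if (mode == "ode") {
        fx <- c(fx, c(sigma = 0))
        st <- st[setdiff(names(st), "sigma")]
      }
      fit <- tryCatch(
        fit_population(dataset, model, map, start = st, method = method,
                       fixed = fx, rse = FALSE, outer_tol = outer_tol,
                       max_iter = max_iter, h_max = h_max,
                       input = design$input),
        error = function(e) NULL)
      ok <- !is.null(fit) && fit$convergence$converged
      est <- if (is.null(fit))
        stats::setNames(rep(NA_real_, length(truth)), names(truth))
      else fit$theta[names(truth)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate = r, mode = mode, parameter = names(truth),
        estimate = unname(est[names(truth)]), converged = ok)
    }
  }
  estimates <- dplyr::bind_rows(rows)
  summary <- estimates |>
    dplyr::filter(.data$converged,
                  !(.data$mode == "ode" & .data$parameter == "sigma")) |>
    dplyr::group_by(.data$mode, .data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$estimate),
      sd = if (dplyr::n() > 1L) stats::sd(.data$estimate) else NA_real_,
      n_used = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(rse_pct = 100 * .data$sd / abs(.data$mean))
  n_excluded <- estimates |>
    dplyr::distinct(.data$replicate, .data$mode, .data$converged) |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(n_excluded = sum(!.data$converged), .groups = "drop")
  valid <- all(n_excluded$n_excluded <= 0.2 * n_replicates)
  if (!valid)
    warning("more than 20% of replicates failed to converge; ",
            "study flagged invalid")
  structure(list(estimates = estimates, summary = summary,
                 truth = truth, start = start, n_replicates = n_replicates,
                 seed = seed, modes = modes, method = method,
                 n_excluded = n_excluded, valid = valid),
            class = "sdmem_replicate_study")
}

#' @export
print.sdmem_replicate_study <- function(x, ...) {
  cat(sprintf("<sdmem_replicate_study> %d replicate(s), modes: %s, %s\n",
              x$n_replicates, paste(x$modes, collapse = "/"),
              if (x$valid) "valid" else "INVALID (>20% non-convergence)"))
  print(tidy(x), n = Inf)
  invisible(x)
}
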