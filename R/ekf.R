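#' Filter state
#'
#' A snapshot of the extended Kalman filter: time, state mean and state
#' covariance.
#'
#' @param time Time point.
#' @param mean State mean vector.
#' @param cov State covariance matrix (symmetric positive semidefinite).
#' @return An object of class `ekf_state`.
#' @export
ekf_state <- function(time, mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == length(mean), ncol(cov) == length(mean))
  structure(list(time = time, mean = mean, cov = (cov + t(cov)) / 2),
            class = "ekf_state")
}

# Integration-grid grading shared with the compiled core: the base step
# applies on [0, 10) min, is tripled on [10, 30) and sextupled beyond,
# reflecting the relaxation of the kinetics after the initial transient.
# The grid depends only on time, never on the parameters.
grid_tiers <- c(10, 30)
tier_mult <- function(t) {
  if (t < 10 - 1e-12) 1 else if (t < 30 - 1e-12) 3 else 6
}

# central finite-difference Jacobian of fun(x) (vector -> vector)
jac_fd <- function(fun, x, eps = 1e-6) {
  f0 <- as.numeric(fun(x))
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (as.numeric(fun(xp)) - as.numeric(fun(xm))) / (2 * h)
  }
  J
}

model_drift_jac <- function(model, x, u, t, phi) {
  if (!is.null(model$drift_jac)) return(as.matrix(model$drift_jac(x, u, t, phi)))
  jac_fd(function(z) model$drift(z, u, t, phi), x)
}

model_measurement_jac <- function(model, x, u, t, phi) {
  if (!is.null(model$measurement_jac))
    return(as.matrix(model$measurement_jac(x, u, t, phi)))
  jac_fd(function(z) model$measurement(z, u, t, phi), x)
}

#' Predict the filter state to a later time
#'
#' Propagates the conditional mean and covariance of the state between
#' observations by jointly integrating
#' \deqn{d\hat x/dt = f(\hat x, u, t, \phi)}
#' \deqn{dP/dt = A P + P A^T + \Sigma \Sigma^T}
#' with `A = df/dx` relinearised continuously along the current mean and the
#' diffusion evaluated at the current mean (state-estimate-dependent system
#' noise).  Integration uses classical RK4 on a fixed grid of step at most
#' `h_max`, split at input breakpoints.
#'
#' @param state An [ekf_state()].
#' @param model A [dynamic_model()].
#' @param phi Named individual parameter vector.
#' @param t_next Target time (must be `>= state$time`).
#' @param h_max Maximum integration step (min).
#' @param input Optional input schedule overriding the model's.
#' @param with_transition If `TRUE`, also return the state-transition
#'   Jacobian of the mean propagation (needed by the smoother) and the dense
#'   grid of intermediate states.
#' @return An `ekf_state` at `t_next`; if `with_transition`, a list with
#'   `state`, `transition` and `grid` (list of `ekf_state`s at substeps).
#' @export
ekf_predict <- function(state, model, phi, t_next, h_max = 0.1, input = NULL,
                        with_transition = FALSE) {
  if (t_next < state$time) stop("t_next must be >= state$time", call. = FALSE)
  if (is.null(input)) input <- model$input
  n <- length(state$mean)
  x <- state$mean; P <- state$cov; Phi <- diag(n)
  grid_states <- list()
  if (t_next > state$time) {
    knots <- if (is.list(input) && !is.null(input$knots)) input$knots else numeric(0)
    bnd <- sort(unique(c(state$time, t_next,
                         knots[knots > state$time & knots < t_next],
                         grid_tiers[grid_tiers > state$time &
                                      grid_tiers < t_next])))
    rhs <- function(t, x, P, Phi, u) {
      f <- as.numeric(model$drift(x, u, t, phi))
      A <- model_drift_jac(model, x, u, t, phi)
      Sg <- as.matrix(model$diffusion(x, u, t, phi))
      D <- if (ncol(Sg) > 0) Sg %*% t(Sg) else matrix(0, n, n)
      list(f, A %*% P + P %*% t(A) + D, A %*% Phi)
    }
    for (sgm in seq_len(length(bnd) - 1L)) {
      t0 <- bnd[sgm]; t1 <- bnd[sgm + 1L]
      nstep <- max(1L, ceiling((t1 - t0) / (h_max * tier_mult(t0)) - 1e-12))
      h <- (t1 - t0) / nstep
      u <- input_value(input, (t0 + t1) / 2)
      for (st in seq_len(nstep)) {
        tt <- t0 + (st - 1) * h
        k1 <- rhs(tt, x, P, Phi, u)
        k2 <- rhs(tt + h / 2, x + h / 2 * k1[[1]], P + h / 2 * k1[[2]],
                  Phi + h / 2 * k1[[3]], u)
        k3 <- rhs(tt + h / 2, x + h / 2 * k2[[1]], P + h / 2 * k2[[2]],
                  Phi + h / 2 * k2[[3]], u)
        k4 <- rhs(tt + h, x + h * k3[[1]], P + h * k3[[2]],
                  Phi + h * k3[[3]], u)
        x <- x + h / 6 * (k1[[1]] + 2 * k2[[1]] + 2 * k3[[1]] + k4[[1]])
        P <- P + h / 6 * (k1[[2]] + 2 * k2[[2]] + 2 * k3[[2]] + k4[[2]])
        Phi <- Phi + h / 6 * (k1[[3]] + 2 * k2[[3]] + 2 * k3[[3]] + k4[[3]])
        P <- (P + t(P)) / 2
        if (!all(is.finite(x)) || !all(is.finite(P)))
          stop(sprintf("state prediction diverged near t = %.4g", tt + h),
               call. = FALSE)
        if (with_transition)
          grid_states[[length(grid_states) + 1L]] <-
            ekf_state(tt + h, x, P)
      }
    }
  }
  out <- ekf_state(t_next, x, P)
  if (with_transition) list(state = out, transition = Phi, grid = grid_states)
  else out
}

#' Measurement update of the filter state
#'
#' Applies the linearised Gaussian update at an observation:
#' `C = dh/dx` at the predicted mean, output covariance `R = C P C' + S`,
#' Kalman gain `K = P C' R^-1`, residual `eps = y - h(xhat)`, updated mean
#' `xhat + K eps` and covariance `P - K R K'` (re-symmetrised).
#'
#' @param state Predicted [ekf_state()] at the observation time.
#' @param y Observation vector.
#' @param model A [dynamic_model()].
#' @param phi Named individual parameter vector.
#' @param input Optional input schedule overriding the model's.
#' @return A list with `state` (updated), `residual`, `output_cov`, `gain`
#'   and `ypred`.
#' @export
ekf_update <- function(state, y, model, phi, input = NULL) {
  if (is.null(input)) input <- model$input
  t <- state$time
  u <- input_value(input, t)
  x <- state$mean; P <- state$cov
  C <- model_measurement_jac(model, x, u, t, phi)
  S <- as.matrix(model$measurement_cov(x, u, t, phi))
  R <- C %*% P %*% t(C) + S
  R <- (R + t(R)) / 2
  if (rcond(R) < 1e-14)
    stop("singular output covariance in measurement update", call. = FALSE)
  K <- P %*% t(C) %*% solve(R)
  yhat <- as.numeric(model$measurement(x, u, t, phi))
  eps <- as.numeric(y) - yhat
  xnew <- x + as.numeric(K %*% eps)
  Pnew <- P - K %*% R %*% t(K)
  list(state = ekf_state(t, xnew, Pnew), residual = eps, output_cov = R,
       gain = K, ypred = yhat)
}

#' Run the extended Kalman filter through a subject's observations
#'
#' Alternates [ekf_predict()] and [ekf_update()] from the initial state
#' `(x0(phi), P0)` through all observations, collecting the one-step output
#' predictions, residuals, output covariances, gains, and pre-/post-update
#' states, plus a dense inter-observation prediction grid for plotting.
#'
#' @param model A [dynamic_model()].
#' @param phi Named individual parameter vector.
#' @param data_i Subject observations: a data frame with `TIME` and `DV`
#'   (strictly increasing times).
#' @param P0 Initial state covariance; default zero (the initial state is
#'   known exactly given `phi`, consistent with `x(0) = x0(phi)`).
#' @param h_max Maximum RK4 step (min).
#' @param input Optional input schedule overriding the model's.
#' @param t0 Time at which `x0` applies.
#' @return An object of class `sdmem_filter`.
#' @export
ekf_filter <- function(model, phi, data_i, P0 = NULL, h_max = 0.1,
                       input = NULL, t0 = 0) {
  if (is.null(input)) input <- model$input
  n <- model$n_states
  if (is.null(P0)) P0 <- matrix(0, n, n)
  times <- data_i$TIME
  if (length(times) && any(diff(times) <= 0))
    stop("subject times must be strictly increasing", call. = FALSE)
  y <- as.matrix(data_i$DV)
  x0 <- as.numeric(model$initial_state(phi))
  state <- ekf_state(t0, x0, P0)
  nobs <- length(times)
  pred <- vector("list", nobs); filt <- vector("list", nobs)
  Rs <- vector("list", nobs); Ks <- vector("list", nobs)
  Phis <- vector("list", nobs)
  eps <- matrix(NA_real_, nobs, model$n_output)
  ypred <- matrix(NA_real_, nobs, model$n_output)
  grid <- list(state)
  for (k in seq_len(nobs)) {
    pr <- tryCatch(
      ekf_predict(state, model, phi, times[k], h_max = h_max, input = input,
                  with_transition = TRUE),
      error = function(e)
        stop(sprintf("prediction to observation %d failed: %s", k,
                     conditionMessage(e)), call. = FALSE))
    pred[[k]] <- pr$state
    Phis[[k]] <- pr$transition
    grid <- c(grid, pr$grid)
    up <- tryCatch(
      ekf_update(pr$state, y[k, ], model, phi, input = input),
      error = function(e)
        stop(sprintf("update at observation %d failed: %s", k,
                     conditionMessage(e)), call. = FALSE))
    filt[[k]] <- up$state
    Rs[[k]] <- up$output_cov; Ks[[k]] <- up$gain
    eps[k, ] <- up$residual; ypred[k, ] <- up$ypred
    state <- up$state
  }
  structure(
    list(model = model, phi = phi, times = times, y = y,
         initial = ekf_state(t0, x0, P0),
         pred = pred, filt = filt, transition = Phis,
         eps = eps, R = Rs, gain = Ks, ypred = ypred,
         grid = grid, input = input, h_max = h_max),
    class = "sdmem_filter")
}

#' @export
print.sdmem_filter <- function(x, ...) {
  cat(sprintf("<sdmem_filter> %d observation(s), %d state(s)\n",
              length(x$times), x$model$n_states))
  invisible(x)
}

#' Per-observation filter summaries as a tibble
#'
#' @param x An `sdmem_filter`.
#' @param ... Unused.
#' @return A tibble with one row per observation: time, observed and
#'   predicted output, residual, output variance, predicted and filtered
#'   state means and variances (first output/state component).
#' @exportS3Method generics::tidy
tidy.sdmem_filter <- function(x, ...) {
  nobs <- length(x$times)
  tibble::tibble(
    TIME = x$times,
    DV = x$y[, 1],
    ypred = x$ypred[, 1],
    residual = x$eps[, 1],
    output_var = vapply(x$R, function(r) r[1, 1], numeric(1)),
    state_pred = vapply(x$pred, function(s) s$mean[which_obs_state(x$model)],
                        numeric(1)),
    state_filt = vapply(x$filt, function(s) s$mean[which_obs_state(x$model)],
                        numeric(1)))
}

which_obs_state <- function(model) {
  if (!is.null(model$backend)) {
    if (model$backend$id == 1L) return(2L)
    return(1L)
  }
  1L
}

#' Fixed-interval (Rauch-Tung-Striebel) smoother
#'
#' Backward pass over a completed forward filter trajectory, conditioning
#' each state estimate on *all* of the subject's observations.  The smoothing
#' gain uses the state-transition Jacobian of the mean propagation recorded
#' during filtering; a pseudo-inverse is used for the predicted covariance so
#' that the deterministic limit (zero covariance) is handled exactly: where
#' the prediction carries no uncertainty, no information flows backward and
#' the smoothed state equals the filtered state.
#'
#' @param trajectory An `sdmem_filter` from [ekf_filter()].
#' @return A tibble with one row per observation: `TIME`, smoothed state
#'   means (`xs_<state>`), smoothed state variances (`Ps_<state>`), smoothed
#'   output mean `ys` and output standard deviation `ys_sd` (smoothed state
#'   uncertainty plus measurement covariance).
#' @export
rts_smooth <- function(trajectory) {
  stopifnot(inherits(trajectory, "sdmem_filter"))
  x <- trajectory
  nobs <- length(x$times)
  if (nobs == 0L)
    stop("cannot smooth a trajectory without observations", call. = FALSE)
  n <- x$model$n_states
  xs <- vector("list", nobs); Ps <- vector("list", nobs)
  xs[[nobs]] <- x$filt[[nobs]]$mean
  Ps[[nobs]] <- x$filt[[nobs]]$cov
  for (k in rev(seq_len(nobs - 1L))) {
    Pp <- x$pred[[k + 1L]]$cov
    G <- x$filt[[k]]$cov %*% t(x$transition[[k + 1L]]) %*% pinv_psd(Pp)
    xs[[k]] <- x$filt[[k]]$mean +
      as.numeric(G %*% (xs[[k + 1L]] - x$pred[[k + 1L]]$mean))
    Pk <- x$filt[[k]]$cov +
      G %*% (Ps[[k + 1L]] - Pp) %*% t(G)
    Ps[[k]] <- (Pk + t(Pk)) / 2
  }
  phi <- x$phi; model <- x$model
  ys <- numeric(nobs); ys_sd <- numeric(nobs)
  for (k in seq_len(nobs)) {
    t <- x$times[k]; u <- input_value(x$input, t)
    C <- model_measurement_jac(model, xs[[k]], u, t, phi)
    S <- as.matrix(model$measurement_cov(xs[[k]], u, t, phi))
    ys[k] <- as.numeric(model$measurement(xs[[k]], u, t, phi))[1]
    ys_sd[k] <- sqrt((C %*% Ps[[k]] %*% t(C) + S)[1, 1])
  }
  out <- tibble::tibble(TIME = x$times)
  for (j in seq_len(n)) {
    out[[paste0("xs_", model$state_names[j])]] <-
      vapply(xs, `[`, numeric(1), j)
    out[[paste0("Ps_", model$state_names[j])]] <-
      vapply(Ps, function(P) P[j, j], numeric(1))
  }
  out$ys <- ys
  out$ys_sd <- ys_sd
  attr(out, "mean") <- xs
  attr(out, "cov") <- Ps
  out
}

# eigen pseudo-inverse for symmetric PSD matrices
pinv_psd <- function(P, tol = 1e-12) {
  P <- (P + t(P)) / 2
  ev <- eigen(P, symmetric = TRUE)
  thr <- tol * max(abs(ev$values), 1e-300)
  inv <- ifelse(ev$values > thr, 1 / ev$values, 0)
  ev$vectors %*% (inv * t(ev$vectors))
}

#' Dense prediction grid of a filter trajectory
#'
#' @param x An `sdmem_filter`.
#' @return A tibble with `TIME`, the predicted output mean `ypred` and the
#'   output standard deviation `y_sd` (state uncertainty plus measurement
#'   covariance) along the inter-observation prediction grid, suitable for
#'   plotting uncertainty bands.
#' @export
filter_band <- function(x) {
  stopifnot(inherits(x, "sdmem_filter"))
  model <- x$model; phi <- x$phi
  rows <- lapply(x$grid, function(s) {
    u <- input_value(x$input, s$time)
    C <- model_measurement_jac(model, s$mean, u, s$time, phi)
    S <- as.matrix(model$measurement_cov(s$mean, u, s$time, phi))
    R <- C %*% s$cov %*% t(C) + S
    tibble::tibble(TIME = s$time,
                   ypred = as.numeric(model$measurement(s$mean, u, s$time,
                                                        phi))[1],
                   y_sd = sqrt(R[1, 1]))
  })
  dplyr::bind_rows(rows)
}
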