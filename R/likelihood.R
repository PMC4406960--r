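# Individual a-posteriori likelihood, FOCE/FOCEI Hessian approximations and
# the Laplace-approximated population likelihood.
#
# Scalar-output models are assumed throughout this module (both shipped
# models observe a single concentration); the EKF itself is not so
# restricted.

subject_input <- function(input, model, i) {
  if (is.null(input)) return(model$input)
  if (is.list(input) && !is.null(input$knots)) return(input)
  input[[i]]
}

#' Negative a-posteriori log-likelihood of the random effects
#'
#' Runs the extended Kalman filter at `phi = g(theta, Z, eta)` and returns
#' \deqn{-l_i(\eta) = \frac12 \sum_j \left(\epsilon_j^2/R_j
#'   + \log 2\pi R_j\right) + \frac12 \eta^T \Omega^{-1} \eta
#'   + \frac12 \log|2\pi\Omega|,}
#' the objective of the inner (per-subject) optimization problem.
#'
#' @param eta Random-effects vector.
#' @param data_i Subject observations (`TIME`, `DV`).
#' @param theta Named fixed-effects vector.
#' @param omega Random-effects covariance matrix (positive definite).
#' @param model A [dynamic_model()].
#' @param map A [parameter_map()].
#' @param P0 Initial state covariance (default zero).
#' @param h_max Maximum RK4 step.
#' @param input Optional input schedule override.
#' @return The scalar value of `-l_i(eta)`.
#' @export
individual_nll <- function(eta, data_i, theta, omega, model,
                           map = model$map, P0 = NULL, h_max = 0.1,
                           input = NULL) {
  omega <- as.matrix(omega)
  if (length(eta) > 0L && rcond(omega) < 1e-14)
    stop("omega must be positive definite", call. = FALSE)
  phi <- map$transform(theta, NULL, eta)
  fr <- filter_eps_R(model, phi, data_i, P0 = P0, h_max = h_max,
                     input = input)
  nll_data_terms(fr$eps, fr$R) + eta_prior_nll(eta, omega)
}

eta_prior_nll <- function(eta, omega) {
  if (length(eta) == 0L) return(0)
  0.5 * as.numeric(t(eta) %*% solve(omega, eta)) +
    0.5 * determinant(2 * pi * omega, logarithm = TRUE)$modulus[1]
}

#' FOCE approximation of the inner Hessian
#'
#' First-order conditional estimate of the Hessian of the individual
#' log-likelihood with respect to the random effects, ignoring the
#' dependence of the output covariance on the random effects:
#' \deqn{(\Delta l)_{lk} = -\sum_j \frac{\partial\epsilon_j}{\partial\eta_l}
#'   R_j^{-1} \frac{\partial\epsilon_j}{\partial\eta_k}
#'   - (\Omega^{-1})_{lk}.}
#' Symmetric negative definite by construction.
#'
#' @param bundle Residual/output-variance sensitivities with respect to
#'   `eta`, from [filter_sensitivities()] with `block = "eta"`.
#' @param omega Random-effects covariance.
#' @return The matrix `Delta l`.
#' @export
foce_hessian <- function(bundle, omega) {
  om_inv <- omega_inverse(omega)
  if (nrow(bundle$deps) == 0L) return(-om_inv)
  -(t(bundle$deps) %*% (bundle$deps / bundle$R)) - om_inv
}

omega_inverse <- function(omega) {
  omega <- as.matrix(omega)
  if (nrow(omega) == 0L) return(matrix(0, 0, 0))
  solve(omega)
}

#' FOCEI approximation of the inner Hessian
#'
#' First-order conditional estimate *with interaction*: the second
#' derivative of the inner objective retaining all terms involving the
#' first-order sensitivities of both the residuals and the output
#' covariances (including the
#' `1/2 tr(R^-1 dR/deta_l R^-1 dR/deta_k)` term), while dropping
#' second-order sensitivities.  Reduces exactly to [foce_hessian()] when
#' `dR/deta = 0`.
#'
#' @inheritParams foce_hessian
#' @return The matrix `Delta l`.
#' @export
focei_hessian <- function(bundle, omega) {
  om_inv <- omega_inverse(omega)
  q <- ncol(bundle$deps)
  if (nrow(bundle$deps) == 0L) return(-om_inv)
  with(bundle, {
    H <- t(deps) %*% (deps / R) -
      t(deps) %*% ((eps / R^2) * dR) -
      t(dR) %*% ((eps / R^2) * deps) +
      t(dR) %*% ((eps^2 / R^3) * dR) -
      0.5 * t(dR) %*% ((1 / R^2) * dR)
    -(H + t(H)) / 2 - om_inv
  })
}

approx_hessian <- function(bundle, omega, method = c("FOCEI", "FOCE")) {
  method <- match.arg(method)
  if (method == "FOCE") foce_hessian(bundle, omega)
  else focei_hessian(bundle, omega)
}

#' Laplace-approximated population objective
#'
#' For each subject, maximizes the a-posteriori random-effects likelihood
#' (the inner problem), then accumulates the Laplace approximation of the
#' marginal likelihood:
#' \deqn{-\log L(\theta|Y) \approx \sum_i \left[-l_i(\eta_i^*)
#'   + \frac12 \log\left|\frac{-\Delta l_i(\eta_i^*)}{2\pi}\right|\right],}
#' with `Delta l` the FOCE or FOCEI approximate Hessian.
#'
#' @param theta Full named population parameter vector on the natural scale
#'   (fixed effects plus the covariance-factor entries named in the model's
#'   fit metadata).
#' @param dataset Data frame with `ID`, `TIME`, `DV`.
#' @param model A [dynamic_model()] with fit metadata (`fit_spec`).
#' @param map A [parameter_map()].
#' @param method `"FOCEI"` (interaction terms retained) or `"FOCE"`.
#' @param P0,h_max,input Passed to the filter.
#' @param warm Optional environment carrying per-subject warm starts.
#' @return The scalar negative approximate population log-likelihood, with
#'   attributes `"contributions"` (per subject), `"eta_star"` (matrix) and
#'   `"inner_converged"` (logical per subject).
#' @export
laplace_population_nll <- function(theta, dataset, model, map = model$map,
                                   method = c("FOCEI", "FOCE"), P0 = NULL,
                                   h_max = 0.1, input = NULL, warm = NULL) {
  method <- match.arg(method)
  fs <- model$fit_spec
  omega <- build_omega(omega_factor_from_theta(theta, fs$omega_names))
  th_fe <- theta_fixed_effects(theta, fs)
  subjects <- split_subjects(dataset)
  q <- map$n_random
  contrib <- numeric(length(subjects))
  conv <- logical(length(subjects))
  etas <- matrix(NA_real_, length(subjects), q)
  for (si in seq_along(subjects)) {
    fit_i <- inner_optimize(subjects[[si]], th_fe, omega, model, map,
                            eta0 = warm_eta(warm, si, q), method = method,
                            P0 = P0, h_max = h_max,
                            input = subject_input(input, model, si))
    store_warm(warm, si, fit_i$eta_star)
    nDl <- neg_hessian_floor(fit_i$hessian)
    contrib[si] <- fit_i$value + 0.5 * (nDl$logdet - q * log(2 * pi))
    conv[si] <- fit_i$converged
    etas[si, ] <- fit_i$eta_star
  }
  structure(sum(contrib), contributions = contrib, eta_star = etas,
            inner_converged = conv)
}

warm_eta <- function(warm, si, q) {
  if (is.null(warm)) return(rep(0, q))
  key <- paste0("s", si)
  if (!is.null(warm[[key]])) warm[[key]] else rep(0, q)
}

store_warm <- function(warm, si, eta) {
  if (!is.null(warm)) warm[[paste0("s", si)]] <- eta
  invisible(NULL)
}
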