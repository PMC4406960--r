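# Sensitivity machinery: derivatives of the filter outputs (prediction
# errors and output variances) with respect to individual parameters, random
# effects and population parameters, and the gradients of the inner and
# outer objectives assembled from them.
#
# For the compiled models the phi-sensitivities are the exact derivatives of
# the discretized filter (forward variational RK4 plus exact differentiation
# of the update algebra); for user-declared R models they fall back to
# central finite differences of the generic filter.  Chaining from phi to
# eta or theta uses the parameter map's Jacobian.

#' Filter output sensitivities
#'
#' Computes the per-observation prediction errors `eps`, output variances
#' `R`, and their derivatives with respect to a parameter block: the
#' individual parameters `phi` (default), the random effects `eta`, or the
#' fixed effects `theta` (holding `eta` fixed).  For the `eta`/`theta`
#' blocks, supply `theta`, `eta` and a [parameter_map()]; the chain rule is
#' applied through `phi = g(theta, Z, eta)`.
#'
#' @param model A [dynamic_model()].
#' @param phi Named individual parameters (ignored when `block != "phi"`,
#'   where `phi` is recomputed from the map).
#' @param data_i Subject observations (`TIME`, `DV`).
#' @param block `"phi"`, `"eta"` or `"theta"`.
#' @param theta,eta,map Required for the `eta` and `theta` blocks.
#' @param Z Covariates passed to the map.
#' @param theta_names For `block = "theta"`: which fixed effects to
#'   differentiate with respect to (default: all entering the map).
#' @param P0 Initial state covariance (default zero).
#' @param h_max Maximum RK4 step.
#' @param input Optional input schedule override.
#' @return A list of class `sdmem_sensitivities` with `eps`, `R` (length
#'   `n_obs`), `deps`, `dR` (`n_obs x n_par` matrices) and `par_names`.
#' @export
filter_sensitivities <- function(model, phi = NULL, data_i,
                                 block = c("phi", "eta", "theta"),
                                 theta = NULL, eta = NULL, map = model$map,
                                 Z = NULL, theta_names = NULL, P0 = NULL,
                                 h_max = 0.1, input = NULL) {
  block <- match.arg(block)
  if (block != "phi") {
    stopifnot(!is.null(theta), !is.null(eta), !is.null(map))
    phi <- map$transform(theta, Z, eta)
  }
  base <- phi_sensitivities(model, phi, data_i, P0 = P0, h_max = h_max,
                            input = input)
  if (block == "phi") return(base)
  J <- if (block == "eta") {
    map_d_eta(map, theta, Z, eta)
  } else {
    if (is.null(theta_names)) theta_names <- intersect(names(theta),
                                                       rownames_or_phi(base))
    map_d_theta(map, theta, Z, eta, theta_names)
  }
  chain_bundle(base, J, if (block == "eta") paste0("eta", seq_len(ncol(J)))
               else colnames(J))
}

rownames_or_phi <- function(bundle) bundle$par_names

phi_sensitivities <- function(model, phi, data_i, P0 = NULL, h_max = 0.1,
                              input = NULL) {
  if (has_backend(model)) {
    out <- backend_pass(model, phi, data_i, P0 = P0, h_max = h_max,
                        sens = TRUE, input = input)
    return(structure(list(eps = out$eps, R = out$R, deps = out$deps,
                          dR = out$dR,
                          par_names = model$backend$phi_names),
                     class = "sdmem_sensitivities"))
  }
  # generic path: central finite differences over each phi component
  base <- filter_eps_R(model, phi, data_i, P0 = P0, h_max = h_max,
                       input = input)
  np <- length(phi); nobs <- length(base$eps)
  deps <- matrix(0, nobs, np, dimnames = list(NULL, names(phi)))
  dR <- deps
  for (a in seq_len(np)) {
    h <- 1e-6 * max(1, abs(phi[a]))
    pp <- phi; pp[a] <- phi[a] + h
    pm <- phi; pm[a] <- phi[a] - h
    fp <- filter_eps_R(model, pp, data_i, P0 = P0, h_max = h_max,
                       input = input)
    fm <- filter_eps_R(model, pm, data_i, P0 = P0, h_max = h_max,
                       input = input)
    deps[, a] <- (fp$eps - fm$eps) / (2 * h)
    dR[, a] <- (fp$R - fm$R) / (2 * h)
  }
  structure(list(eps = base$eps, R = base$R, deps = deps, dR = dR,
                 par_names = names(phi)),
            class = "sdmem_sensitivities")
}

chain_bundle <- function(bundle, J, new_names) {
  J <- as.matrix(J)
  structure(list(eps = bundle$eps, R = bundle$R,
                 deps = bundle$deps %*% J, dR = bundle$dR %*% J,
                 par_names = new_names),
            class = "sdmem_sensitivities")
}

# data-part of -l and its exact gradient from a sensitivity bundle
nll_data_terms <- function(eps, R) 0.5 * sum(eps^2 / R + log(2 * pi * R))

nll_data_gradient <- function(bundle) {
  with(bundle, as.numeric(
    t(deps) %*% (eps / R) - 0.5 * t(dR) %*% (eps^2 / R^2) +
      0.5 * t(dR) %*% (1 / R)))
}

#' Gradient of the inner objective
#'
#' Exact gradient of the negative a-posteriori random-effects log-likelihood
#' `-l_i(eta)` with respect to `eta`, assembled from the residuals, output
#' variances and their sensitivities (including the `1/2 tr(R^-1 dR/deta)`
#' terms) plus the prior term `Omega^-1 eta`.
#'
#' @inheritParams individual_nll
#' @param bundle Optional precomputed eta-block [filter_sensitivities()].
#' @return Numeric gradient of length `n_random`.
#' @export
inner_gradient <- function(eta, data_i, theta, omega, model, map = model$map,
                           P0 = NULL, h_max = 0.1, input = NULL,
                           bundle = NULL) {
  if (is.null(bundle))
    bundle <- filter_sensitivities(model, data_i = data_i, block = "eta",
                                   theta = theta, eta = eta, map = map,
                                   P0 = P0, h_max = h_max, input = input)
  if (nrow(bundle$deps) == 0L)
    return(as.numeric(solve(omega, eta)))
  nll_data_gradient(bundle) + as.numeric(solve(omega, eta))
}

#' Gradient of the Laplace population objective
#'
#' Differentiates each subject's Laplace contribution
#' `-[l_i(eta*) - 1/2 log|-Delta l_i(eta*)/(2 pi)|]` with respect to the
#' population parameters, accounting for the implicit dependence of the
#' inner optimum through the first-order condition
#' `d eta*/d theta = -(Delta l)^-1 d2 l/(d eta d theta)`.  First-order
#' pieces come from exact sensitivity propagation; the second-order pieces
#' (`d2 l/(d eta d theta)` and the derivatives of the approximate Hessian
#' inside the log-determinant) are formed by central finite differences of
#' sensitivity-computed first-order quantities, which are smooth functions
#' of the parameters on the fixed integration grid.
#'
#' @param theta Full named population vector (fixed effects and
#'   covariance-factor entries) on the natural scale.
#' @param dataset Dataset (`ID`, `TIME`, `DV`).
#' @param model A [dynamic_model()] with fit metadata.
#' @param map A [parameter_map()].
#' @param method `"FOCEI"` or `"FOCE"`.
#' @param free Names of the components to differentiate with respect to
#'   (default all).
#' @param P0,h_max,input Passed to the filter.
#' @param warm Optional environment carrying per-subject warm starts for the
#'   inner optimizations.
#' @return Named gradient of the negative approximate population
#'   log-likelihood with respect to `theta[free]` (natural scale), with the
#'   objective value as attribute `"value"`.
#' @export
outer_gradient <- function(theta, dataset, model, map = model$map,
                           method = c("FOCEI", "FOCE"), free = names(theta),
                           P0 = NULL, h_max = 0.1, input = NULL,
                           warm = NULL) {
  method <- match.arg(method)
  fs <- model$fit_spec
  omega_names <- intersect(fs$omega_names, names(theta))
  filt_names <- intersect(free, fs$theta_names)
  om_free <- intersect(free, omega_names)
  U <- omega_factor_from_theta(theta, fs$omega_names)
  omega <- build_omega(U)
  subjects <- split_subjects(dataset)
  grad <- stats::setNames(numeric(length(free)), free)
  value <- 0
  q <- map$n_random
  for (si in seq_along(subjects)) {
    data_i <- subjects[[si]]
    inp <- subject_input(input, model, si)
    fit_i <- inner_optimize(data_i, theta_fixed_effects(theta, fs), omega,
                            model, map, eta0 = warm_eta(warm, si, q),
                            method = method, P0 = P0, h_max = h_max,
                            input = inp)
    store_warm(warm, si, fit_i$eta_star)
    eta <- fit_i$eta_star
    th_fe <- theta_fixed_effects(theta, fs)
    nDl <- neg_hessian_floor(fit_i$hessian)
    value <- value + fit_i$value +
      0.5 * (nDl$logdet - q * log(2 * pi))
    nDl_inv <- nDl$inv
    # --- exact first-order part: d(-l)/d theta with eta fixed
    bundle_th <- chain_bundle(fit_i$phi_bundle,
                              map_d_theta(map, th_fe, NULL, eta, filt_names),
                              filt_names)
    g_theta <- stats::setNames(nll_data_gradient(bundle_th), filt_names)
    # prior terms for omega entries
    Om_inv <- if (nrow(omega)) solve(omega) else matrix(0, 0, 0)
    for (wn in om_free) {
      dOm <- d_omega(U, fs$omega_names, wn)
      g_theta[wn] <- 0.5 * (-t(eta) %*% Om_inv %*% dOm %*% Om_inv %*% eta +
                              sum(diag(Om_inv %*% dOm)))
    }
    # --- second-order pieces by central FD of sensitivity-computed
    #     quantities: dDelta/dtheta, d2l/deta dtheta, dDelta/deta
    hstep <- function(v) 1e-4 * max(1, abs(v))
    rows <- list(); tags <- character(0)
    for (tn in filt_names) {
      for (sgn in c(1, -1)) {
        thp <- th_fe; thp[tn] <- thp[tn] + sgn * hstep(thp[tn])
        rows[[length(rows) + 1L]] <- list(theta = thp, eta = eta)
        tags <- c(tags, paste0("t:", tn, ":", sgn))
      }
    }
    for (l in seq_len(q)) {
      for (sgn in c(1, -1)) {
        etp <- eta; etp[l] <- etp[l] + sgn * hstep(etp[l])
        rows[[length(rows) + 1L]] <- list(theta = th_fe, eta = etp)
        tags <- c(tags, paste0("e:", l, ":", sgn))
      }
    }
    evals <- eval_eta_quantities(model, map, data_i, rows, omega,
                                 P0 = P0, h_max = h_max, input = inp,
                                 method = method)
    names(evals) <- tags
    # d Delta l / d eta_l (for the log-determinant term) and the exact
    # Hessian of -l over eta (for the implicit-function term, so that
    # d eta*/d theta follows the stationarity of the *implemented* inner
    # objective, not its FOCE/FOCEI approximation)
    dM_deta_logdet <- numeric(q)
    Hneg <- matrix(0, q, q)   # d2(-l)/deta2, exact to FD accuracy
    for (l in seq_len(q)) {
      hp <- evals[[paste0("e:", l, ":", "1")]]
      hm <- evals[[paste0("e:", l, ":", "-1")]]
      h <- hstep(eta[l])
      dDl <- (hp$Dl - hm$Dl) / (2 * h)
      dM_deta_logdet[l] <- 0.5 * sum(nDl_inv * t(-dDl))
      Hneg[l, ] <- (hp$g - hm$g) / (2 * h)
    }
    Hneg <- (Hneg + t(Hneg)) / 2
    Hneg_inv <- tryCatch({
      ch <- chol(Hneg)
      chol2inv(ch)
    }, error = function(e) nDl_inv)
    # dM/deta total: gradient of -l (about 0 at optimum) + logdet part
    dM_deta <- fit_i$gradient + dM_deta_logdet
    for (tn in filt_names) {
      hp <- evals[[paste0("t:", tn, ":", "1")]]
      hm <- evals[[paste0("t:", tn, ":", "-1")]]
      h <- hstep(th_fe[tn])
      dDl_dth <- (hp$Dl - hm$Dl) / (2 * h)
      d2negl_deta_dth <- (hp$g - hm$g) / (2 * h)
      deta_dth <- -as.numeric(Hneg_inv %*% d2negl_deta_dth)
      grad[tn] <- grad[tn] + g_theta[tn] +
        0.5 * sum(nDl_inv * t(-dDl_dth)) +
        sum(dM_deta * deta_dth)
    }
    # omega entries: analytic (filter does not depend on omega)
    for (wn in om_free) {
      dOm <- d_omega(U, fs$omega_names, wn)
      dOm_inv <- -Om_inv %*% dOm %*% Om_inv
      dDl_dw <- -dOm_inv               # Delta l = ... - Omega^-1
      d2negl_deta_dw <- as.numeric(dOm_inv %*% eta)
      deta_dw <- -as.numeric(Hneg_inv %*% d2negl_deta_dw)
      grad[wn] <- grad[wn] + g_theta[wn] +
        0.5 * sum(nDl_inv * t(-dDl_dw)) +
        sum(dM_deta * deta_dw)
    }
  }
  attr(grad, "value") <- value
  grad
}

# derivative of Omega = U U' with respect to one factor entry
d_omega <- function(U, omega_names, which) {
  dU <- U * 0
  if (length(omega_names) == 1L) dU[1, 1] <- 1
  else switch(which,
              om11 = { dU[1, 1] <- 1 },
              om12 = { dU[1, 2] <- 1 },
              om22 = { dU[2, 2] <- 1 })
  dU %*% t(U) + U %*% t(dU)
}

theta_fixed_effects <- function(theta, fit_spec)
  theta[fit_spec$theta_names]

# Evaluate, for a list of (theta, eta) points, the inner-gradient vector g
# of -l and the approximate Hessian Delta l (by the requested method).
# Uses one batched compiled pass when available.
eval_eta_quantities <- function(model, map, data_i, points, omega, P0, h_max,
                                input, method) {
  q <- map$n_random
  out <- vector("list", length(points))
  if (has_backend(model) && length(points)) {
    phis <- do.call(rbind, lapply(points, function(p)
      backend_phi(model, map$transform(p$theta, NULL, p$eta))[
        seq_along(model$backend$phi_names)]))
    multi <- backend_pass_multi(model, phis, data_i, P0 = P0, h_max = h_max,
                                input = input)
    for (j in seq_along(points)) {
      J <- map_d_eta(map, points[[j]]$theta, NULL, points[[j]]$eta)
      bundle <- structure(list(
        eps = multi$eps[j, ], R = multi$R[j, ],
        deps = matrix(multi$deps[j, , ], ncol = dim(multi$deps)[3]) %*% J,
        dR = matrix(multi$dR[j, , ], ncol = dim(multi$dR)[3]) %*% J,
        par_names = paste0("eta", seq_len(q))),
        class = "sdmem_sensitivities")
      out[[j]] <- list(
        g = nll_data_gradient(bundle) + prior_gradient(omega, points[[j]]$eta),
        Dl = approx_hessian(bundle, omega, method))
    }
  } else {
    for (j in seq_along(points)) {
      p <- points[[j]]
      bundle <- filter_sensitivities(model, data_i = data_i, block = "eta",
                                     theta = p$theta, eta = p$eta, map = map,
                                     P0 = P0, h_max = h_max, input = input)
      out[[j]] <- list(
        g = nll_data_gradient(bundle) + prior_gradient(omega, p$eta),
        Dl = approx_hessian(bundle, omega, method))
    }
  }
  out
}

prior_gradient <- function(omega, eta) {
  if (length(eta) == 0L) return(numeric(0))
  as.numeric(solve(omega, eta))
}

# inverse and log-determinant of -Delta l with an eigenvalue floor
neg_hessian_floor <- function(Dl, floor = 1e-8) {
  if (NROW(Dl) == 0L)
    return(list(logdet = 0, inv = matrix(0, 0, 0), floored = FALSE))
  nDl <- -(Dl + t(Dl)) / 2
  ev <- eigen(nDl, symmetric = TRUE)
  flo <- ev$values < floor
  v <- pmax(ev$values, floor)
  list(logdet = sum(log(v)),
       inv = ev$vectors %*% ((1 / v) * t(ev$vectors)),
       floored = any(flo))
}
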