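#' Declare a structural state-space model
#'
#' A `dynamic_model` bundles the components of a (possibly stochastic)
#' state-space model: the drift `f`, the diffusion matrix `Sigma`, the
#' measurement function `h`, the measurement covariance `S`, the initial
#' state `x0`, and a piecewise-constant input (e.g. an infusion schedule).
#' Setting the diffusion to zero (or `n_wiener = 0`) recovers an ordinary
#' differential-equation model.
#'
#' All functions share the argument convention `(x, u, t, phi)` where `x` is
#' the state vector, `u` the scalar input value at `t`, and `phi` the named
#' vector of individual parameters.  By convention the diffusion receives the
#' filter's current *state estimate*, not the latent state: state-dependent
#' system noise is handled by evaluating `Sigma` along the conditional mean
#' (during simulation, where no filter runs, the simulator substitutes the
#' current simulated state into the same function).
#'
#' @param state_names Character vector of state labels.
#' @param drift Function `(x, u, t, phi)` returning the state derivative.
#' @param diffusion Function `(x, u, t, phi)` returning an
#'   `n_states x n_wiener` matrix; defaults to zero (pure ODE).
#' @param measurement Function `(x, u, t, phi)` returning the output vector.
#' @param measurement_cov Function `(x, u, t, phi)` returning the symmetric
#'   measurement covariance.
#' @param initial_state Function `(phi)` returning the initial state.
#' @param input Piecewise-constant input: either `NULL` (zero input) or a
#'   list with `knots` (K+1 increasing times) and `rates` (K values); the
#'   input is `rates[i]` on `[knots[i], knots[i+1])` and zero outside.
#' @param n_wiener Number of driving Wiener processes (columns of the
#'   diffusion); `0` means no system noise.
#' @param n_output Dimension of the measurement vector.
#' @param drift_jac Optional function `(x, u, t, phi)` returning the Jacobian
#'   of the drift with respect to the state; if omitted it is obtained by
#'   central finite differences.
#' @param measurement_jac Optional Jacobian of the measurement function with
#'   respect to the state.
#'
#' @return An object of class `dynamic_model`.
#' @seealso [one_compartment_pk_model()], [niac_model()]
#' @export
dynamic_model <- function(state_names, drift, diffusion = NULL, measurement,
                          measurement_cov, initial_state, input = NULL,
                          n_wiener = 0L, n_output = 1L,
                          drift_jac = NULL, measurement_jac = NULL) {
  stopifnot(is.character(state_names), length(state_names) >= 1L,
            is.function(drift), is.function(measurement),
            is.function(measurement_cov), is.function(initial_state))
  if (is.null(diffusion)) {
    n_states <- length(state_names)
    diffusion <- function(x, u, t, phi) matrix(0, n_states, 0L)
    n_wiener <- 0L
  }
  if (!is.null(input)) input <- validate_input_schedule(input)
  structure(
    list(state_names = state_names, n_states = length(state_names),
         drift = drift, diffusion = diffusion, measurement = measurement,
         measurement_cov = measurement_cov, initial_state = initial_state,
         input = input, n_wiener = as.integer(n_wiener),
         n_output = as.integer(n_output),
         drift_jac = drift_jac, measurement_jac = measurement_jac,
         backend = NULL),
    class = "dynamic_model")
}

validate_input_schedule <- function(input) {
  if (is.function(input)) return(input)
  stopifnot(is.list(input), !is.null(input$knots), !is.null(input$rates))
  knots <- as.numeric(input$knots); rates <- as.numeric(input$rates)
  if (length(knots) != length(rates) + 1L)
    stop("input schedule needs length(knots) == length(rates) + 1", call. = FALSE)
  if (any(diff(knots) <= 0)) stop("input knots must be increasing", call. = FALSE)
  list(knots = knots, rates = rates)
}

#' Evaluate a piecewise-constant input schedule
#'
#' @param input An input schedule as accepted by [dynamic_model()].
#' @param t Time (vectorised).
#' @return Input value(s) at `t`.
#' @export
input_value <- function(input, t) {
  if (is.null(input)) return(rep(0, length(t)))
  if (is.function(input)) return(vapply(t, input, numeric(1)))
  out <- rep(0, length(t))
  for (i in seq_along(input$rates)) {
    sel <- t >= input$knots[i] & t < input$knots[i + 1]
    out[sel] <- input$rates[i]
  }
  out
}

#' @export
print.dynamic_model <- function(x, ...) {
  cat("<dynamic_model> ", paste(x$state_names, collapse = ", "),
      if (x$n_wiener > 0) sprintf(" | %d Wiener process(es)", x$n_wiener)
      else " | deterministic dynamics",
      if (!is.null(x$backend)) sprintf(" | compiled backend '%s'", x$backend$name),
      "\n", sep = "")
  invisible(x)
}

#' Random-effects covariance from its triangular factor
#'
#' The random-effects covariance is parameterised as `Omega = U U'` with `U`
#' upper triangular, which keeps `Omega` symmetric positive semidefinite for
#' any real entries of `U`.  For the 2x2 case with entries `w11, w12, w22`
#' this is the closed form
#' `[[w11^2 + w12^2, w12 w22], [w12 w22, w22^2]]`.
#'
#' @param omega_factor Square upper-triangular numeric matrix `U`.
#' @return The covariance matrix `U U'`.
#' @examples
#' build_omega(matrix(c(0.5, 0, 0.1, 0.3), 2, 2))
#' @export
build_omega <- function(omega_factor) {
  U <- as.matrix(omega_factor)
  if (nrow(U) != ncol(U)) stop("omega factor must be square", call. = FALSE)
  if (any(abs(U[lower.tri(U)]) > 0))
    stop("omega factor must be upper triangular", call. = FALSE)
  Om <- U %*% t(U)
  (Om + t(Om)) / 2
}

#' Map population parameters and random effects to individual parameters
#'
#' An `parameter_map` holds the transform `phi = g(theta, Z, eta)` linking
#' fixed effects, covariates and random effects to the individual parameter
#' vector, together with the number of random effects per subject.
#'
#' @param transform Function `(theta, Z, eta)` returning the named individual
#'   parameter vector.
#' @param n_random Number of random effects per subject.
#' @param d_eta Optional function `(theta, Z, eta)` returning the Jacobian
#'   `d phi / d eta` (rows follow the transform output); computed by central
#'   finite differences when omitted.
#' @param d_theta Optional function `(theta, Z, eta)` returning the Jacobian
#'   `d phi / d theta` (columns follow `theta`).
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(transform, n_random, d_eta = NULL, d_theta = NULL) {
  stopifnot(is.function(transform), n_random >= 0)
  structure(list(transform = transform, n_random = as.integer(n_random),
                 d_eta = d_eta, d_theta = d_theta),
            class = "parameter_map")
}

map_d_eta <- function(map, theta, Z, eta) {
  if (!is.null(map$d_eta)) return(map$d_eta(theta, Z, eta))
  jac_fd(function(e) map$transform(theta, Z, e), eta)
}

map_d_theta <- function(map, theta, Z, eta, theta_names = names(theta)) {
  if (!is.null(map$d_theta)) {
    J <- map$d_theta(theta, Z, eta)
    return(J[, theta_names, drop = FALSE])
  }
  J <- jac_fd(function(th) map$transform(stats::setNames(th, names(theta)),
                                         Z, eta),
              as.numeric(theta))
  colnames(J) <- names(theta)
  J[, theta_names, drop = FALSE]
}

#' @rdname parameter_map
#' @param map A `parameter_map`.
#' @param theta Named fixed-effects vector.
#' @param Z Covariates for the subject (unused by the built-in models but
#'   carried through the interface).
#' @param eta Random-effects vector of length `n_random`.
#' @export
map_individual_parameters <- function(map, theta, Z = NULL, eta) {
  if (length(eta) != map$n_random)
    stop(sprintf("eta has length %d but the map declares %d random effect(s)",
                 length(eta), map$n_random), call. = FALSE)
  map$transform(theta, Z, eta)
}

# log-normal IIV on ka and Vm; everything else passes through
pk1_parameter_map <- function() {
  nm <- c("ka", "Vm", "Km", "V", "s", "sigma")
  parameter_map(
    transform = function(theta, Z, eta) {
      c(ka = unname(theta[["ka"]] * exp(eta[1])),
        Vm = unname(theta[["Vm"]] * exp(eta[2])),
        Km = unname(theta[["Km"]]), V = unname(theta[["V"]]),
        s = unname(theta[["s"]]), sigma = unname(theta[["sigma"]]))
    },
    n_random = 2L,
    d_eta = function(theta, Z, eta) {
      J <- matrix(0, 6, 2, dimnames = list(nm, NULL))
      J["ka", 1] <- theta[["ka"]] * exp(eta[1])
      J["Vm", 2] <- theta[["Vm"]] * exp(eta[2])
      J
    },
    d_theta = function(theta, Z, eta) {
      J <- diag(6); dimnames(J) <- list(nm, nm)
      J["ka", "ka"] <- exp(eta[1])
      J["Vm", "Vm"] <- exp(eta[2])
      J
    })
}

niac_parameter_map <- function() {
  nm <- c("Vm", "Km", "Vc", "Synt", "s", "sigma")
  parameter_map(
    transform = function(theta, Z, eta) {
      c(Vm = unname(theta[["Vm"]] * exp(eta[1])),
        Km = unname(theta[["Km"]]), Vc = unname(theta[["Vc"]]),
        Synt = unname(theta[["Synt"]]),
        s = unname(theta[["s"]]), sigma = unname(theta[["sigma"]]))
    },
    n_random = 1L,
    d_eta = function(theta, Z, eta) {
      J <- matrix(0, 6, 1, dimnames = list(nm, NULL))
      J["Vm", 1] <- theta[["Vm"]] * exp(eta[1])
      J
    },
    d_theta = function(theta, Z, eta) {
      J <- diag(6); dimnames(J) <- list(nm, nm)
      J["Vm", "Vm"] <- exp(eta[1])
      J
    })
}

#' One-compartment PK model with first-order absorption and
#' Michaelis-Menten elimination
#'
#' The two-state structural model
#' \deqn{dA/dt = -k_a A, \quad A(0) = \mathrm{dose}}
#' \deqn{V\, dC = \left(k_a A - \frac{V_m C}{K_m + C}\right) dt
#'       + \sigma \hat C\, dW, \quad C(0) = 0,}
#' where `A` (mg) is the amount in the GI tract and `C` (mg/L) the plasma
#' concentration.  The system noise is proportional to the filter's estimate
#' of the concentration (`sigma * C-hat`) and enters only the concentration
#' equation, modelling uncertainty in the elimination process; no
#' mass-balance pairing is applied by default.  The measurement is the
#' concentration under additive Gaussian noise, `y = C + e`,
#' `e ~ N(0, s^2)` (set `error = "proportional"` for `e ~ N(0, (s C-hat)^2)`).
#'
#' Individual parameters are `phi = (ka, Vm, Km, V, s, sigma)` with
#' log-normal inter-individual variability on `ka` and `Vm`:
#' `ka_i = ka exp(eta_1)`, `Vm_i = Vm exp(eta_2)`.
#'
#' @param error Residual error model, `"additive"` (default) or
#'   `"proportional"`.
#' @param dose Initial amount in the absorption compartment (mg).
#' @param mass_balance If `TRUE`, the system-noise term is subtracted from
#'   the absorption equation so that total mass is conserved; off by default
#'   (the shipped analyses treat the noise as elimination uncertainty).
#' @return A `dynamic_model` with a compiled estimation backend, a default
#'   [parameter_map()] and fit metadata attached.
#' @examples
#' m <- one_compartment_pk_model()
#' m$drift(c(A = 20, C = 0), 0, 0, c(ka = 0.1, Vm = 0.5, Km = 3, V = 1,
#'                                   s = 0.1, sigma = 0.05))
#' @export
one_compartment_pk_model <- function(error = c("additive", "proportional"),
                                     dose = 20, mass_balance = FALSE) {
  error <- match.arg(error)
  drift <- function(x, u, t, phi) {
    inflow <- phi[["ka"]] * x[1]
    c(-inflow, (inflow - phi[["Vm"]] * x[2] / (phi[["Km"]] + x[2])) / phi[["V"]])
  }
  drift_jac <- function(x, u, t, phi) {
    den <- phi[["Km"]] + x[2]
    matrix(c(-phi[["ka"]], 0,
             phi[["ka"]] / phi[["V"]],
             -phi[["Vm"]] * phi[["Km"]] / (phi[["V"]] * den^2)),
           2, 2, byrow = TRUE)
  }
  diffusion <- if (mass_balance) {
    function(x, u, t, phi)
      matrix(c(-phi[["sigma"]] * x[2] / phi[["V"]],
               phi[["sigma"]] * x[2] / phi[["V"]]), 2, 1)
  } else {
    function(x, u, t, phi)
      matrix(c(0, phi[["sigma"]] * x[2] / phi[["V"]]), 2, 1)
  }
  measurement <- function(x, u, t, phi) x[2]
  measurement_jac <- function(x, u, t, phi) matrix(c(0, 1), 1, 2)
  measurement_cov <- switch(error,
    additive = function(x, u, t, phi) matrix(phi[["s"]]^2, 1, 1),
    proportional = function(x, u, t, phi) matrix((phi[["s"]] * x[2])^2, 1, 1))
  model <- dynamic_model(
    state_names = c("A", "C"),
    drift = drift, diffusion = diffusion,
    measurement = measurement, measurement_cov = measurement_cov,
    initial_state = function(phi) c(A = dose, C = 0),
    n_wiener = 1L, drift_jac = drift_jac, measurement_jac = measurement_jac)
  model$backend <- if (mass_balance) NULL else list(
    name = "one_compartment_abs_mm", id = 1L,
    error_code = if (error == "additive") 0L else 1L,
    phi_names = c("ka", "Vm", "Km", "V", "s", "sigma"),
    extra = c(dose = dose))
  model$map <- pk1_parameter_map()
  model$fit_spec <- list(
    theta_names = c("ka", "Vm", "Km", "V", "s", "sigma"),
    omega_names = c("om11", "om12", "om22"),
    par_scale = c(ka = "log", Vm = "log", Km = "log", V = "log", s = "log",
                  sigma = "log", om11 = "log", om12 = "identity",
                  om22 = "log"))
  model
}

#' Nicotinic-acid (NiAc) disposition model with endogenous synthesis
#'
#' One-state turnover model for plasma NiAc concentration `c` (umol/L) in
#' which NiAc is synthesised endogenously at rate `Synt`, infused at a
#' piecewise-constant rate `u(t)`, and eliminated by a capacity-limited
#' process:
#' \deqn{V_c\, dc = \left(u + Synt - \frac{V_m c}{K_m + c}\right) dt
#'       + \sigma \hat c\, dW,}
#' started at the drug-free steady state
#' \deqn{c(0) = \frac{Synt\, K_m}{V_m - Synt},}
#' which requires `Vm > Synt`.  The residual error is proportional by
#' default (`S = (s c-hat)^2`); the system noise is proportional to the
#' concentration estimate.  Inter-individual variability is log-normal on
#' `Vm` only: `Vm_i = Vm exp(eta)`.
#'
#' @param error Residual error model, `"proportional"` (default) or
#'   `"additive"`.
#' @param infusion Input schedule, a list with `knots` and `rates` as in
#'   [dynamic_model()]; defaults to the 0.67 umol/min/kg over 30 min
#'   infusion (20 umol/kg total).
#' @return A `dynamic_model` with a compiled estimation backend, a default
#'   [parameter_map()] and fit metadata attached.
#' @examples
#' m <- niac_model()
#' m$initial_state(c(Vm = 1.8, Km = 23, Vc = 0.319, Synt = 0.00125,
#'                   s = 0.1, sigma = 0.01))
#' @export
niac_model <- function(error = c("proportional", "additive"),
                       infusion = list(knots = c(0, 30), rates = 0.67)) {
  error <- match.arg(error)
  drift <- function(x, u, t, phi)
    (u + phi[["Synt"]] - phi[["Vm"]] * x[1] / (phi[["Km"]] + x[1])) / phi[["Vc"]]
  drift_jac <- function(x, u, t, phi) {
    den <- phi[["Km"]] + x[1]
    matrix(-phi[["Vm"]] * phi[["Km"]] / (phi[["Vc"]] * den^2), 1, 1)
  }
  diffusion <- function(x, u, t, phi)
    matrix(phi[["sigma"]] * x[1] / phi[["Vc"]], 1, 1)
  measurement_cov <- switch(error,
    additive = function(x, u, t, phi) matrix(phi[["s"]]^2, 1, 1),
    proportional = function(x, u, t, phi) matrix((phi[["s"]] * x[1])^2, 1, 1))
  initial_state <- function(phi) {
    if (phi[["Vm"]] <= phi[["Synt"]])
      stop("NiAc steady-state initial condition requires Vm > Synt",
           call. = FALSE)
    c(c = phi[["Synt"]] * phi[["Km"]] / (phi[["Vm"]] - phi[["Synt"]]))
  }
  model <- dynamic_model(
    state_names = "c",
    drift = drift, diffusion = diffusion,
    measurement = function(x, u, t, phi) x[1],
    measurement_cov = measurement_cov,
    initial_state = initial_state,
    input = infusion, n_wiener = 1L,
    drift_jac = drift_jac,
    measurement_jac = function(x, u, t, phi) matrix(1, 1, 1))
  model$backend <- list(
    name = "niac_disposition", id = 2L,
    error_code = if (error == "proportional") 1L else 0L,
    phi_names = c("Vm", "Km", "Vc", "Synt", "s", "sigma"),
    extra = numeric(0))
  model$map <- niac_parameter_map()
  model$fit_spec <- list(
    theta_names = c("Vm", "Km", "Vc", "Synt", "s", "sigma"),
    omega_names = "om",
    par_scale = c(Vm = "log", Km = "log", Vc = "log", Synt = "log",
                  s = "log", sigma = "log", om = "log"))
  model
}

#' Look up a built-in model by name
#'
#' @param name One of `"one_compartment_abs_mm"` or `"niac_disposition"`.
#' @param ... Passed on to the model constructor.
#' @return A `dynamic_model`.
#' @export
get_model <- function(name, ...) {
  switch(name,
         one_compartment_abs_mm = one_compartment_pk_model(...),
         niac_disposition = niac_model(...),
         stop(sprintf("unknown model '%s'", name), call. = FALSE))
}

#' Population-level parameters
#'
#' Bundles the fixed effects and the upper-triangular factor of the
#' random-effects covariance.
#'
#' @param theta Named fixed-effects vector (structural and error-model
#'   parameters).
#' @param omega_factor Upper-triangular factor `U` of the random-effects
#'   covariance `Omega = U U'`.
#' @return An object of class `population_parameters` with elements `theta`,
#'   `omega_factor` and `omega`.
#' @export
population_parameters <- function(theta, omega_factor) {
  omega <- build_omega(omega_factor)
  structure(list(theta = theta, omega_factor = as.matrix(omega_factor),
                 omega = omega),
            class = "population_parameters")
}

# Assemble U from the named theta entries declared in the model's fit_spec.
omega_factor_from_theta <- function(theta, omega_names) {
  if (length(omega_names) == 0L)
    return(matrix(0, 0, 0))
  if (length(omega_names) == 1L)
    return(matrix(theta[[omega_names]], 1, 1))
  # 2x2 upper-triangular: om11, om12, om22
  matrix(c(theta[["om11"]], 0, theta[["om12"]], theta[["om22"]]), 2, 2)
}
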