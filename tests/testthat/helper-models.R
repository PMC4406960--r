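# Shared fixtures, built in code.

pk_bench_truth <- c(ka = 0.1, Vm = 0.5, Km = 3, V = 1, s = 0.1, sigma = 0.05,
                  om11 = 0.5, om12 = 0.1, om22 = 0.3)
pk_bench_start <- c(ka = 0.2, Vm = 1, Km = 1, V = 2, s = 0.5, sigma = 0.01,
                  om11 = 0.1, om12 = 0, om22 = 0.1)
pk_bench_times <- seq(1, 97, by = 8)

pk_population <- function(theta = pk_bench_truth) {
  population_parameters(
    theta[c("ka", "Vm", "Km", "V", "s", "sigma")],
    matrix(c(theta[["om11"]], 0, theta[["om12"]], theta[["om22"]]), 2, 2))
}

pk_dataset <- function(n_subjects = 3, seed = 7, theta = pk_bench_truth,
                       step = 0.01) {
  simulate_population_dataset(
    one_compartment_pk_model(), pk_population(theta),
    design = study_design(n_subjects, pk_bench_times, seed = seed),
    step = step)
}

# scalar linear SDE dx = -k x dt + sig dW, y = x + e, e ~ N(0, s^2),
# x(0) = x0 -- closed forms exist for everything
linear_model <- function() {
  dynamic_model(
    state_names = "x",
    drift = function(x, u, t, phi) -phi[["k"]] * x[1],
    diffusion = function(x, u, t, phi) matrix(phi[["sig"]], 1, 1),
    measurement = function(x, u, t, phi) x[1],
    measurement_cov = function(x, u, t, phi) matrix(phi[["s"]]^2, 1, 1),
    initial_state = function(phi) phi[["x0"]],
    n_wiener = 1L,
    drift_jac = function(x, u, t, phi) matrix(-phi[["k"]], 1, 1),
    measurement_jac = function(x, u, t, phi) matrix(1, 1, 1))
}

# exact discrete Kalman filter for the linear model above (independent
# oracle: exact discretization Phi = e^{-k dt}, Q = sig^2(1-e^{-2k dt})/(2k))
linear_kf_oracle <- function(phi, times, y, P0 = 0) {
  k <- phi[["k"]]; sig <- phi[["sig"]]; s <- phi[["s"]]
  x <- phi[["x0"]]; P <- P0
  tprev <- 0
  eps <- numeric(length(times)); R <- numeric(length(times))
  xf <- numeric(length(times)); Pf <- numeric(length(times))
  xp <- numeric(length(times)); Pp <- numeric(length(times))
  for (j in seq_along(times)) {
    dt <- times[j] - tprev
    Phi <- exp(-k * dt)
    Q <- if (k == 0) sig^2 * dt else sig^2 * (1 - exp(-2 * k * dt)) / (2 * k)
    x <- Phi * x
    P <- Phi * P * Phi + Q
    xp[j] <- x; Pp[j] <- P
    Rj <- P + s^2
    K <- P / Rj
    eps[j] <- y[j] - x
    x <- x + K * eps[j]
    P <- P - K * Rj * K
    xf[j] <- x; Pf[j] <- P
    R[j] <- Rj
    tprev <- times[j]
  }
  list(eps = eps, R = R, xf = xf, Pf = Pf, xp = xp, Pp = Pp)
}

# one-observation-per-subject Gaussian linear mixed toy
# y_i = mu + eta_i + e_i, eta ~ N(0, om^2), e ~ N(0, s^2);
# the Laplace approximation is exact here.
lmm_toy_model <- function() {
  m <- dynamic_model(
    state_names = "x",
    drift = function(x, u, t, phi) 0,
    measurement = function(x, u, t, phi) x[1],
    measurement_cov = function(x, u, t, phi) matrix(phi[["s"]]^2, 1, 1),
    initial_state = function(phi) phi[["mu"]],
    drift_jac = function(x, u, t, phi) matrix(0, 1, 1),
    measurement_jac = function(x, u, t, phi) matrix(1, 1, 1))
  m$map <- parameter_map(
    transform = function(theta, Z, eta)
      c(mu = unname(theta[["mu"]] + eta[1]), s = unname(theta[["s"]])),
    n_random = 1L)
  m$fit_spec <- list(theta_names = c("mu", "s"), omega_names = "om",
                     par_scale = c(mu = "identity", s = "log", om = "log"))
  m
}

lmm_toy_data <- function(y, times = NULL) {
  if (is.null(times)) times <- seq_along(y)
  tibble::tibble(ID = seq_along(y), TIME = 1, DV = y)
}

# closed-form marginal negative log-likelihood of the toy
lmm_toy_nll <- function(mu, om, s, y) {
  v <- om^2 + s^2
  sum(0.5 * ((y - mu)^2 / v + log(2 * pi * v)))
}

# no-random-effects single-subject constant model y_j = mu + e_j
constant_model <- function() {
  m <- dynamic_model(
    state_names = "x",
    drift = function(x, u, t, phi) 0,
    measurement = function(x, u, t, phi) x[1],
    measurement_cov = function(x, u, t, phi) matrix(phi[["s"]]^2, 1, 1),
    initial_state = function(phi) phi[["mu"]],
    drift_jac = function(x, u, t, phi) matrix(0, 1, 1),
    measurement_jac = function(x, u, t, phi) matrix(1, 1, 1))
  m$map <- parameter_map(
    transform = function(theta, Z, eta)
      c(mu = unname(theta[["mu"]]), s = unname(theta[["s"]])),
    n_random = 0L)
  m$fit_spec <- list(theta_names = c("mu", "s"), omega_names = character(0),
                     par_scale = c(mu = "identity", s = "log"))
  m
}

pk_phi <- function(theta = pk_bench_truth, eta = c(0, 0)) {
  pk1_map <- one_compartment_pk_model()$map
  pk1_map$transform(theta[c("ka", "Vm", "Km", "V", "s", "sigma")], NULL, eta)
}

niac_truth <- c(Vm = 1.35, Km = 13.6, Vc = 0.32, Synt = 0.0018,
                s = 0.241, sigma = 0.033, om = 0.133)

# synthetic NiAc study design: 8 subjects on 0.67 umol/min/kg x 30 min,
# 7 on 0.17 x 300 min (mirrors the analyzed groups)
niac_design <- function(seed = 1L) {
  t1 <- c(5, 10, 20, 30, 40, 50, 65, 80, 100, 130, 160, 200)
  t2 <- c(15, 45, 90, 150, 210, 270, 300, 315, 330, 345, 360, 390)
  study_design(
    15L,
    times = c(replicate(8, t1, simplify = FALSE),
              replicate(7, t2, simplify = FALSE)),
    input = c(replicate(8, list(knots = c(0, 30), rates = 0.67),
                        simplify = FALSE),
              replicate(7, list(knots = c(0, 300), rates = 0.17),
                        simplify = FALSE)),
    seed = seed)
}
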