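test_that("the inner optimum has its closed form on the linear mixed toy", {
  m <- lmm_toy_model()
  theta <- c(mu = 1.5, s = 0.4)
  om <- 0.7
  omega <- matrix(om^2, 1, 1)
  y <- 2.6
  d <- tibble::tibble(TIME = 1, DV = y)
  io <- inner_optimize(d, theta, omega, m, method = "FOCE")
  # posterior mode: eta* = om^2 (y - mu) / (om^2 + s^2)
  expect_equal(io$eta_star, om^2 * (y - 1.5) / (om^2 + 0.4^2),
               tolerance = 1e-7)
  expect_true(io$converged)
  # zero observations: the prior mode, exactly
  io0 <- inner_optimize(tibble::tibble(TIME = numeric(0), DV = numeric(0)),
                        theta, omega, m)
  expect_identical(io0$eta_star, 0)
  expect_identical(io0$iterations, 0L)
  # restarting at the optimum converges immediately
  io2 <- inner_optimize(d, theta, omega, m, eta0 = io$eta_star)
  expect_lte(io2$iterations, 1L)
  expect_equal(io2$eta_star, io$eta_star, tolerance = 1e-8)
})

test_that("a fixed-effects-only fit recovers the Gaussian MLE", {
  set.seed(13)
  m <- constant_model()
  y <- stats::rnorm(20, 5, 0.7)
  d <- tibble::tibble(ID = 1, TIME = seq_along(y), DV = y)
  fit <- fit_population(d, m, start = c(mu = 4, s = 1), rse = FALSE,
                        h_max = 0.5)
  expect_true(fit$convergence$converged)
  expect_equal(fit$theta[["mu"]], mean(y), tolerance = 1e-6)
  expect_equal(fit$theta[["s"]], sqrt(mean((y - mean(y))^2)),
               tolerance = 1e-6)
})

test_that("the population fit recovers the toy parameters and their standard errors", {
  set.seed(8)
  mu <- 2; om <- 0.8; s <- 0.4
  n <- 40
  y <- mu + stats::rnorm(n, 0, om) + stats::rnorm(n, 0, s)
  m <- lmm_toy_model()
  d <- lmm_toy_data(y)
  fit <- fit_population(d, m, start = c(mu = 1, s = 0.6, om = 0.5),
                        method = "FOCEI", rse = FALSE)
  expect_true(fit$convergence$converged)
  # with one observation per subject only mu and the total variance are
  # identified; check them against the closed-form MLE
  v_hat <- fit$theta[["om"]]^2 + fit$theta[["s"]]^2
  expect_equal(fit$theta[["mu"]], mean(y), tolerance = 1e-4)
  expect_equal(v_hat, mean((y - mean(y))^2), tolerance = 1e-3)
  # the objective decreased monotonically across accepted iterations
  expect_true(all(diff(fit$trace$objective) <= 1e-12))
  # RSE of mu matches the closed form 100 sqrt(v/n)/mu within 2%
  rse <- suppressWarnings(compute_rse(fit, d))
  expect_equal(rse[["mu"]],
               100 * sqrt(v_hat / n) / fit$theta[["mu"]],
               tolerance = 0.02)
})

test_that("RSEs shrink like one over the square root of the information", {
  set.seed(30)
  mu <- 2; om <- 0.8; s <- 0.4
  y <- mu + stats::rnorm(16, 0, om) + stats::rnorm(16, 0, s)
  m <- lmm_toy_model()
  d1 <- lmm_toy_data(y)
  d2 <- dplyr::bind_rows(d1, dplyr::mutate(d1, ID = .data$ID + 100))
  fit1 <- fit_population(d1, m, start = c(mu = 1.5, s = 0.5, om = 0.6),
                         rse = FALSE)
  fit2 <- fit_population(d2, m, start = c(mu = 1.5, s = 0.5, om = 0.6),
                         rse = FALSE)
  # with one observation per subject only the total variance is identified,
  # so the (om, s) split is flat and the Hessian is expected to be singular
  r1 <- suppressWarnings(compute_rse(fit1, d1))
  r2 <- suppressWarnings(compute_rse(fit2, d2))
  expect_equal(r2[["mu"]] / r1[["mu"]], 1 / sqrt(2), tolerance = 0.05)
  # a fixed parameter is reported as not estimated
  fit3 <- fit_population(d1, m, start = c(mu = 1.5, om = 0.6),
                         fixed = c(s = 0.4), rse = FALSE)
  r3 <- suppressWarnings(compute_rse(fit3, d1))
  expect_true(is.na(r3[["s"]]))
  expect_false(is.na(r3[["mu"]]))
})

test_that("an ODE-mode fit on near-deterministic data recovers the structure", {
  # data built from the exact ODE flow (not the Euler simulator) so the only
  # perturbation is a tiny additive noise
  m <- one_compartment_pk_model()
  set.seed(55)
  U <- matrix(c(0.5, 0, 0.1, 0.3), 2, 2)
  eta <- matrix(stats::rnorm(16), 8, 2) %*% t(U)
  rows <- lapply(1:8, function(i) {
    phi <- m$map$transform(pk_bench_truth[1:6], NULL, eta[i, ])
    sol <- deSolve::lsoda(y = c(A = 20, C = 0), times = c(0, pk_bench_times),
                          func = function(t, y, p)
                            list(unname(m$drift(y, 0, t, phi))),
                          rtol = 1e-11, atol = 1e-13)
    tibble::tibble(ID = i, TIME = pk_bench_times,
                   DV = sol[-1, "C"] + stats::rnorm(13, 0, 0.002))
  })
  dat <- dplyr::bind_rows(rows)
  start <- c(ka = 0.15, Vm = 0.7, Km = 2, V = 1.5, s = 0.01,
             om11 = 0.3, om12 = 0, om22 = 0.2)
  fit <- fit_population(dat, m, start = start, method = "FOCEI",
                        fixed = c(sigma = 0), rse = FALSE,
                        outer_tol = 1e-3)
  expect_true(fit$convergence$converged)
  # parameters shared across subjects are recovered essentially exactly
  expect_equal(fit$theta[["Km"]], pk_bench_truth[["Km"]], tolerance = 0.01)
  expect_equal(fit$theta[["V"]], pk_bench_truth[["V"]], tolerance = 0.01)
  # parameters carrying inter-individual variability are recovered up to the
  # finite-sample mean of the drawn random effects (the population value
  # estimates the geometric mean of the 8 realised individual parameters)
  expect_equal(fit$theta[["ka"]],
               pk_bench_truth[["ka"]] * exp(mean(eta[, 1])), tolerance = 0.02)
  expect_equal(fit$theta[["Vm"]],
               pk_bench_truth[["Vm"]] * exp(mean(eta[, 2])), tolerance = 0.02)
})

test_that("FOCE and FOCEI coincide without residual interaction", {
  # additive error and sigma = 0 remove all eta-dependence of the output
  # variance, so the two approximations define the same objective
  m <- one_compartment_pk_model()
  th <- pk_bench_truth; th["sigma"] <- 0
  dat <- simulate_population_dataset(
    m, pk_population(th), design = study_design(4, pk_bench_times, seed = 71))
  theta <- c(ka = 0.11, Vm = 0.52, Km = 2.7, V = 1.05, s = 0.12, sigma = 0,
             om11 = 0.45, om12 = 0.08, om22 = 0.28)
  v1 <- laplace_population_nll(theta, dat, m, method = "FOCE")
  v2 <- laplace_population_nll(theta, dat, m, method = "FOCEI")
  expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-10)
  g1 <- outer_gradient(theta, dat, m, method = "FOCE",
                       free = setdiff(names(theta), "sigma"))
  g2 <- outer_gradient(theta, dat, m, method = "FOCEI",
                       free = setdiff(names(theta), "sigma"))
  expect_equal(as.numeric(g1), as.numeric(g2), tolerance = 1e-8)
  # identical objectives imply identical fits; start near the optimum so
  # both runs converge on the gradient criterion rather than at the
  # floating-point floor
  start <- c(ka = 0.1, Vm = 0.5, Km = 3, V = 1, s = 0.12,
             om11 = 0.45, om12 = 0.08, om22 = 0.28)
  fit_foce <- fit_population(dat, m, start = start, method = "FOCE",
                             fixed = c(sigma = 0), rse = FALSE)
  fit_focei <- fit_population(dat, m, start = start, method = "FOCEI",
                              fixed = c(sigma = 0), rse = FALSE)
  expect_lt(max(abs(fit_foce$theta - fit_focei$theta)), 1e-4)
})

test_that("the replicate study is reproducible and summarises correctly", {
  m <- one_compartment_pk_model()
  des <- study_design(3, pk_bench_times)
  st1 <- replicate_study(m, pk_bench_truth, start = pk_bench_truth, design = des,
                         n_replicates = 2, seed = 4, modes = "sde",
                         outer_tol = 1e-2)
  st2 <- replicate_study(m, pk_bench_truth, start = pk_bench_truth, design = des,
                         n_replicates = 2, seed = 4, modes = "sde",
                         outer_tol = 1e-2)
  expect_identical(st1$estimates, st2$estimates)
  expect_true(all(c("mean", "sd", "rse_pct") %in% names(st1$summary)))
  expect_equal(nrow(dplyr::distinct(st1$estimates, .data$replicate)), 2L)
  # a single replicate yields no spread
  st3 <- replicate_study(m, pk_bench_truth, start = pk_bench_truth, design = des,
                         n_replicates = 1, seed = 4, modes = "sde",
                         outer_tol = 1e-2)
  expect_true(all(is.na(st3$summary$sd)))
  # the ODE mode reports no sigma row
  st4 <- replicate_study(m, pk_bench_truth, start = pk_bench_truth, design = des,
                         n_replicates = 1, seed = 4, modes = "ode",
                         outer_tol = 1e-2)
  expect_false("sigma" %in%
                 st4$summary$parameter[st4$summary$mode == "ode"])
})
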