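test_that("prediction solves the mean and covariance ODEs", {
  m <- linear_model()
  phi <- c(k = 1, sig = 0, s = 1, x0 = 1)
  st <- ekf_state(0, 1, matrix(0.5, 1, 1))
  out <- ekf_predict(st, m, phi, 1, h_max = 0.01)
  expect_equal(out$mean, exp(-1), tolerance = 1e-8)
  expect_equal(out$cov[1, 1], 0.5 * exp(-2), tolerance = 1e-8)
  # zero time increment leaves the state untouched
  same <- ekf_predict(st, m, phi, 0)
  expect_equal(same$mean, st$mean)
  expect_equal(same$cov, st$cov)
  # pure diffusion: P grows by sigma^2 * dt exactly
  m0 <- dynamic_model(
    state_names = "x",
    drift = function(x, u, t, phi) 0,
    diffusion = function(x, u, t, phi) matrix(phi[["sig"]], 1, 1),
    measurement = function(x, u, t, phi) x[1],
    measurement_cov = function(x, u, t, phi) matrix(1, 1, 1),
    initial_state = function(phi) 0, n_wiener = 1L,
    drift_jac = function(x, u, t, phi) matrix(0, 1, 1))
  out0 <- ekf_predict(ekf_state(0, 0, matrix(0.2, 1, 1)), m0,
                      c(sig = 0.7), 2.5)
  expect_equal(out0$cov[1, 1], 0.2 + 0.7^2 * 2.5, tolerance = 1e-12)
})

test_that("the measurement update matches the hand-evaluated formulas", {
  m <- linear_model()
  phi <- c(k = 1, sig = 0, s = 1, x0 = 1)
  up <- ekf_update(ekf_state(0, 1, matrix(1, 1, 1)), y = 2, m, phi)
  expect_equal(up$output_cov[1, 1], 2)
  expect_equal(up$gain[1, 1], 0.5)
  expect_equal(up$residual, 1)
  expect_equal(up$state$mean, 1.5)
  expect_equal(up$state$cov[1, 1], 0.5)
  # a certain state learns nothing from data
  up0 <- ekf_update(ekf_state(0, 1, matrix(0, 1, 1)), y = 5, m, phi)
  expect_equal(up0$gain[1, 1], 0)
  expect_equal(up0$state$mean, 1)
  expect_equal(up0$state$cov[1, 1], 0)
  # zero residual leaves the mean fixed but still contracts the covariance
  upz <- ekf_update(ekf_state(0, 1, matrix(1, 1, 1)), y = 1, m, phi)
  expect_equal(upz$residual, 0)
  expect_equal(upz$state$mean, 1)
  expect_equal(upz$state$cov[1, 1], 0.5)
  # S = 0 with P = 0 is singular
  phi0 <- phi; phi0["s"] <- 0
  expect_error(ekf_update(ekf_state(0, 1, matrix(0, 1, 1)), 1, m, phi0),
               "singular")
})

test_that("the filter reproduces an exactly discretized Kalman filter", {
  m <- linear_model()
  phi <- c(k = 0.8, sig = 0.5, s = 0.3, x0 = 2)
  set.seed(14)
  times <- 1:6
  y <- exp(-0.8 * times) * 2 + stats::rnorm(6, 0, 0.4)
  d <- tibble::tibble(TIME = times, DV = y)
  tr <- ekf_filter(m, phi, d, P0 = matrix(0.2, 1, 1), h_max = 0.01)
  kf <- linear_kf_oracle(phi, times, y, P0 = 0.2)
  expect_equal(tr$eps[, 1], kf$eps, tolerance = 1e-8)
  expect_equal(vapply(tr$R, function(r) r[1, 1], numeric(1)), kf$R,
               tolerance = 1e-8)
  expect_equal(vapply(tr$filt, function(s) s$mean, numeric(1)), kf$xf,
               tolerance = 1e-8)
  expect_equal(vapply(tr$filt, function(s) s$cov[1, 1], numeric(1)), kf$Pf,
               tolerance = 1e-8)
})

test_that("without system noise the filter collapses to ODE residuals", {
  m <- one_compartment_pk_model()
  phi <- pk_phi(); phi["sigma"] <- 0
  set.seed(21)
  d <- tibble::tibble(TIME = pk_bench_times,
                      DV = stats::runif(13, 0, 12))
  tr <- ekf_filter(m, phi, d)
  expect_equal(vapply(tr$R, function(r) r[1, 1], numeric(1)),
               rep(0.1^2, 13))
  sol <- deSolve::lsoda(
    y = c(A = 20, C = 0), times = c(0, pk_bench_times),
    func = function(t, y, p) list(unname(m$drift(y, 0, t, phi))),
    rtol = 1e-10, atol = 1e-12)
  expect_equal(tr$eps[, 1], d$DV - sol[-1, "C"], tolerance = 1e-6)
})

test_that("degenerate inputs are handled", {
  m <- linear_model()
  phi <- c(k = 1, sig = 0.2, s = 0.3, x0 = 1)
  tr <- ekf_filter(m, phi, tibble::tibble(TIME = numeric(0),
                                          DV = numeric(0)))
  expect_equal(length(tr$times), 0L)
  expect_equal(tr$initial$mean, 1)
  expect_error(ekf_filter(m, phi, tibble::tibble(TIME = c(2, 1),
                                                 DV = c(1, 2))),
               "strictly increasing")
})

test_that("the state covariance stays symmetric PSD and contracts at updates", {
  m <- one_compartment_pk_model()
  set.seed(33)
  for (rep in 1:5) {
    phi <- pk_phi(eta = stats::rnorm(2, 0, 0.5))
    d <- tibble::tibble(TIME = pk_bench_times,
                        DV = pmax(stats::runif(13, 0, 12), 0.01))
    tr <- ekf_filter(m, phi, d)
    for (k in seq_along(tr$times)) {
      Pp <- tr$pred[[k]]$cov; Pf <- tr$filt[[k]]$cov
      expect_equal(Pp, t(Pp))
      expect_gt(min(eigen(Pf, symmetric = TRUE)$values), -1e-10)
      # information gain: the diagonal never grows across an update
      expect_true(all(diag(Pf) <= diag(Pp) + 1e-12))
    }
  }
})

test_that("likelihood ingredients are invariant to extra prediction grid points", {
  m <- one_compartment_pk_model()
  phi <- pk_phi()
  set.seed(4)
  d <- tibble::tibble(TIME = pk_bench_times, DV = stats::runif(13, 0.5, 12))
  base <- sdmem:::filter_eps_R(m, phi, d)
  # walk the filter manually, inserting prediction-only stops midway
  # through every interval
  st <- ekf_state(0, m$initial_state(phi), matrix(0, 2, 2))
  eps2 <- numeric(13); R2 <- numeric(13)
  tprev <- 0
  for (k in seq_len(13)) {
    mid <- (tprev + d$TIME[k]) / 2
    st <- ekf_predict(st, m, phi, mid)
    st <- ekf_predict(st, m, phi, d$TIME[k])
    up <- ekf_update(st, d$DV[k], m, phi)
    eps2[k] <- up$residual; R2[k] <- up$output_cov[1, 1]
    st <- up$state; tprev <- d$TIME[k]
  }
  expect_lt(max(abs(eps2 - base$eps) / pmax(abs(base$eps), 1)), 1e-8)
  expect_lt(max(abs(R2 - base$R) / base$R), 1e-8)
})

test_that("the compiled and generic filter paths agree", {
  set.seed(60)
  m <- one_compartment_pk_model()
  for (rep in 1:3) {
    phi <- pk_phi(eta = stats::rnorm(2, 0, 0.4))
    d <- tibble::tibble(TIME = pk_bench_times, DV = stats::runif(13, 0.5, 12))
    bp <- sdmem:::backend_pass(m, phi, d)
    tr <- ekf_filter(m, phi, d)
    expect_equal(tr$eps[, 1], bp$eps, tolerance = 1e-10)
    expect_equal(vapply(tr$R, function(r) r[1, 1], numeric(1)), bp$R,
                 tolerance = 1e-10)
  }
  mn <- niac_model()
  phin <- c(Vm = 1.35, Km = 13.6, Vc = 0.32, Synt = 0.0018, s = 0.241,
            sigma = 0.033)
  dn <- tibble::tibble(TIME = c(5, 15, 40, 90, 200),
                       DV = c(20, 35, 8, 0.5, 0.05))
  expect_equal(ekf_filter(mn, phin, dn)$eps[, 1],
               sdmem:::backend_pass(mn, phin, dn)$eps, tolerance = 1e-10)
})

test_that("smoothing conditions on all observations", {
  m <- linear_model()
  phi <- c(k = 0.6, sig = 0.4, s = 0.25, x0 = 1.5)
  # single observation: nothing to smooth
  d1 <- tibble::tibble(TIME = 1, DV = 0.9)
  tr1 <- ekf_filter(m, phi, d1, h_max = 0.01)
  sm1 <- rts_smooth(tr1)
  expect_equal(sm1$xs_x, tr1$filt[[1]]$mean)
  expect_equal(sm1$Ps_x, tr1$filt[[1]]$cov[1, 1])
  # deterministic limit: smoothing returns the ODE solution
  phi0 <- c(k = 0.6, sig = 0, s = 0.25, x0 = 1.5)
  d3 <- tibble::tibble(TIME = 1:3, DV = c(1, 0.4, 0.2))
  sm0 <- rts_smooth(ekf_filter(m, phi0, d3, h_max = 0.01))
  expect_equal(sm0$xs_x, 1.5 * exp(-0.6 * (1:3)), tolerance = 1e-8)
  # joint-Gaussian conditioning oracle on three observations:
  # cov(x_ti, x_tj) = P0 e^{-k(ti+tj)} + sig^2/(2k)(e^{-k|ti-tj|}-e^{-k(ti+tj)})
  P0 <- 0.3
  times <- 1:3
  k <- phi[["k"]]; sig <- phi[["sig"]]; s <- phi[["s"]]
  Cxx <- outer(times, times, function(a, b)
    P0 * exp(-k * (a + b)) +
      sig^2 / (2 * k) * (exp(-k * abs(a - b)) - exp(-k * (a + b))))
  mu <- phi[["x0"]] * exp(-k * times)
  y <- c(1, 0.4, 0.2)
  cond_mean <- mu + Cxx %*% solve(Cxx + diag(s^2, 3), y - mu)
  cond_cov <- Cxx - Cxx %*% solve(Cxx + diag(s^2, 3), Cxx)
  tr <- ekf_filter(m, phi, d3, P0 = matrix(P0, 1, 1), h_max = 0.005)
  sm <- rts_smooth(tr)
  expect_equal(sm$xs_x, as.numeric(cond_mean), tolerance = 1e-6)
  expect_equal(sm$Ps_x, diag(cond_cov), tolerance = 1e-6)
  # smoothed covariances never exceed filtered ones (Loewner order)
  for (j in 1:3)
    expect_lte(sm$Ps_x[j], tr$filt[[j]]$cov[1, 1] + 1e-10)
  # last smoothed state is the last filtered state
  expect_equal(sm$xs_x[3], tr$filt[[3]]$mean)
})

test_that("the output band narrows at observations when system noise is present", {
  m <- one_compartment_pk_model()
  phi <- pk_phi()
  sim <- simulate_individual_path(m, phi, pk_bench_times, seed = 3)
  tr <- ekf_filter(m, phi, sim$obs[, c("TIME", "DV")])
  band <- filter_band(tr)
  # at each observation the output sd immediately after the update is below
  # the predicted sd just before it
  for (k in 2:13) {
    R_pred <- tr$R[[k]][1, 1]
    C <- matrix(c(0, 1), 1, 2)
    R_filt <- (C %*% tr$filt[[k]]$cov %*% t(C))[1, 1] + 0.1^2
    expect_lt(R_filt, R_pred)
  }
  expect_true(all(band$y_sd >= 0.1 - 1e-12))
})
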