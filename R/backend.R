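# Bridge between R model objects and the compiled filter core.
#
# The compiled core implements the same continuous-discrete EKF as
# ekf_filter(), but with the model's drift/diffusion/measurement derivatives
# coded in C++ and forward sensitivities propagated exactly through the
# discrete RK4 + update scheme.  It exists for the two shipped models; any
# other dynamic_model runs through the generic R path.

has_backend <- function(model) !is.null(model$backend)

backend_phi <- function(model, phi) {
  b <- model$backend
  unname(c(phi[b$phi_names], b$extra))
}

backend_input <- function(model, input) {
  if (is.null(input)) input <- model$input
  if (is.null(input)) return(list(knots = numeric(0), rates = numeric(0)))
  if (is.function(input))
    stop("the compiled backend requires a piecewise-constant input schedule",
         call. = FALSE)
  input
}

# One filter pass; sens = TRUE adds d(eps)/dphi, d(R)/dphi in the order of
# backend$phi_names.
backend_pass <- function(model, phi, data_i, P0 = NULL, h_max = 0.1,
                         sens = FALSE, keep_states = FALSE, input = NULL) {
  b <- model$backend
  n <- model$n_states
  if (is.null(P0)) P0 <- matrix(0, n, n)
  inp <- backend_input(model, input)
  out <- .ekf_pass_cpp(b$id, backend_phi(model, phi), data_i$TIME, data_i$DV,
                       inp$knots, inp$rates, as.matrix(P0), h_max, sens,
                       b$error_code, keep_states)
  if (sens) {
    colnames(out$deps) <- b$phi_names
    colnames(out$dR) <- b$phi_names
  }
  out
}

# Batched passes over a matrix of phi vectors (rows); returns eps,R matrices
# (npass x nobs) and deps,dR arrays (npass x nobs x np).
backend_pass_multi <- function(model, phis, data_i, P0 = NULL, h_max = 0.1,
                               input = NULL) {
  b <- model$backend
  n <- model$n_states
  if (is.null(P0)) P0 <- matrix(0, n, n)
  inp <- backend_input(model, input)
  full <- cbind(phis, matrix(rep(b$extra, each = nrow(phis)), nrow(phis)))
  .ekf_pass_multi_cpp(b$id, full, data_i$TIME, data_i$DV, inp$knots,
                      inp$rates, as.matrix(P0), h_max, b$error_code)
}

# Prediction errors and output variances only (scalar output), via the
# fastest available path.
filter_eps_R <- function(model, phi, data_i, P0 = NULL, h_max = 0.1,
                         input = NULL) {
  if (has_backend(model)) {
    out <- backend_pass(model, phi, data_i, P0 = P0, h_max = h_max,
                        input = input)
    return(list(eps = out$eps, R = out$R))
  }
  tr <- ekf_filter(model, phi, data_i, P0 = P0, h_max = h_max, input = input)
  list(eps = as.numeric(tr$eps[, 1]),
       R = vapply(tr$R, function(r) r[1, 1], numeric(1)))
}
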