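# ggplot2 displays for filter trajectories and replicate studies.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a filtered trajectory with its output uncertainty band
#'
#' Shows the one-step predicted output along the dense prediction grid with
#' a band of plus/minus one output standard deviation (state uncertainty
#' plus measurement covariance) and the observations.  With system noise
#' present, the band narrows at each observation (where information is
#' gained) and widens between observations.
#'
#' @param object An `sdmem_filter` from [ekf_filter()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sdmem_filter <- function(object, ...) {
  band <- filter_band(object)
  obs <- tibble::tibble(TIME = object$times, DV = object$y[, 1])
  ggplot2::ggplot(band, ggplot2::aes(x = .data$TIME)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ypred - .data$y_sd,
                                      ymax = .data$ypred + .data$y_sd),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ypred), colour = "steelblue") +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$DV)) +
    ggplot2::labs(x = "Time (min)", y = "Output",
                  title = "One-step prediction with output uncertainty")
}

#' Plot the distribution of replicate estimates
#'
#' Density of the estimated parameters across replicates, by mode, with the
#' true simulation values as vertical lines.
#'
#' @param object An `sdmem_replicate_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sdmem_replicate_study <- function(object, ...) {
  est <- dplyr::filter(object$estimates, .data$converged)
  truth <- tibble::tibble(parameter = names(object$truth),
                          true = unname(object$truth))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate,
                                    colour = .data$mode,
                                    fill = .data$mode)) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::geom_vline(data = truth,
                        ggplot2::aes(xintercept = .data$true),
                        linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Estimate", y = "Density",
                  title = "Replicate estimate distributions")
}

#' Convergence trace of the outer optimization
#'
#' @param fit An `sdmem_fit`.
#' @return A ggplot of objective value versus outer iteration.
#' @export
plot_trace <- function(fit) {
  ggplot2::ggplot(fit$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Outer iteration", y = "Negative log-likelihood",
                  title = "Outer BFGS convergence")
}
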