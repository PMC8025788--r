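#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a chi-square grid-scan fit
#'
#' One row per fitted parameter with its scan-step error bound.
#'
#' @param x A `growth_fit` from [grid_scan_fit()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `error`, `unit`.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kn", "kg_fast", "kg", "r", "n", "v", "dE_coop", "dE_asym"),
    estimate = c(x$kn_hat, x$kg_fast_hat, x$kg_hat, x$r_hat,
                 x$n_hat, x$v_hat, x$dE_coop, x$dE_asym),
    error = c(x$kn_err, x$kg_fast_err, NA, x$r_err, NA, NA, NA, NA),
    unit = c("1/s", "1/s", "1/s", "", "1/(site s)", "sites/s", "kBT", "kBT")
  )
}

#' @rdname tidy.growth_fit
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    chi2_min = x$chi2_min,
    n_grid = x$n_grid,
    M_final = x$M_final,
    ratio_fast_slow = x$ratio_fast_slow,
    on_boundary = x$on_boundary
  )
}

#' Tidy a break-point fit
#'
#' One row per break point with its time, the slopes on either side, the
#' slope change and its classification, and the significance flag.
#'
#' @param x A `breakpoint_fit` from [fit_piecewise_linear()].
#' @param ... Unused.
#' @return A tibble with one row per break.
#' @method tidy breakpoint_fit
#' @export
tidy.breakpoint_fit <- function(x, ...) {
  d <- diff(x$slopes)
  tibble::tibble(
    break_index = seq_len(x$Q),
    t_break = x$t_breaks,
    slope_before = x$slopes[seq_len(x$Q)],
    slope_after = x$slopes[seq_len(x$Q) + 1],
    slope_change = d,
    event = ifelse(d > 0, "nucleation", "collision"),
    significant = x$significant
  )
}

#' @rdname tidy.breakpoint_fit
#' @method glance breakpoint_fit
#' @export
glance.breakpoint_fit <- function(x, ...) {
  tibble::tibble(
    Q = x$Q,
    n_domains = x$n_domains,
    residual = x$residual,
    converged = x$converged
  )
}

#' Tidy solved domain kinetics
#'
#' @param x A `domain_kinetics` from [solve_scenario()].
#' @param ... Unused.
#' @return The per-domain tibble (nucleation time/position, fast and slow
#'   front velocities, asymmetry ratio), or an empty tibble for infeasible
#'   scenarios.
#' @method tidy domain_kinetics
#' @export
tidy.domain_kinetics <- function(x, ...) {
  if (is.null(x$domains)) return(tibble::tibble())
  x$domains
}

#' @rdname tidy.domain_kinetics
#' @method glance domain_kinetics
#' @export
glance.domain_kinetics <- function(x, ...) {
  tibble::tibble(
    n_domains = if (is.null(x$domains)) 0L else nrow(x$domains),
    feasible = x$feasible,
    reason = x$reason,
    closure_error_um = x$closure_error_um
  )
}

#' Plot a coverage curve
#'
#' Contour length against time, with the initial and saturation lengths as
#' reference lines.
#'
#' @param object A `coverage_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coverage_curve
#' @export
autoplot.coverage_curve <- function(object, ...) {
  L0 <- attr(object, "L_initial")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$t_s, y = .data$L_um)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "contour length (um)")
  if (!is.null(L0)) {
    p <- p + ggplot2::geom_hline(yintercept = c(L0, 1.5 * L0),
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot a simulated ensemble mean with its dispersion band
#'
#' @param object A `sim_result` from [simulate_ensemble()].
#' @param ... Unused.
#' @return A ggplot of mean coverage with a +/- SD ribbon.
#' @method autoplot sim_result
#' @export
autoplot.sim_result <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$t_s)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$phi_mean - .data$phi_sd, 0),
                                      ymax = pmin(.data$phi_mean + .data$phi_sd, 1)),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$phi_mean), colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "coverage fraction")
}

#' Plot a break-point fit over the data
#'
#' @param object A `breakpoint_fit`.
#' @param ... Unused.
#' @return A ggplot of the trace, the piecewise-linear fit and the break
#'   times.
#' @method autoplot breakpoint_fit
#' @export
autoplot.breakpoint_fit <- function(object, ...) {
  dat <- object$fitted
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data[[object$value]]),
                        size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$t_breaks, linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = object$value)
}

#' Plot the experimental mean against the best-fit model mean
#'
#' @param object A `growth_fit` from [grid_scan_fit()].
#' @param ... Unused.
#' @return A ggplot comparing aligned experimental mean coverage (with its
#'   standard-error ribbon) and the fitted model mean.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  em <- object$exp_mean
  spec <- object$spec
  n_out <- ceiling(max(em$t_s) / spec$dt)
  res <- sim_ensemble_cpp(object$kn_hat, object$kg_fast_hat, object$r_hat,
                          spec$dt, n_out, as.integer(max(spec$M_schedule[1], 1000)),
                          2L, spec$align_phi, 4L * n_out)
  model <- tibble::tibble(t_s = seq(0, by = spec$dt, length.out = n_out + 1),
                          phi = res$phi_mean)
  ggplot2::ggplot(em, ggplot2::aes(x = .data$t_s)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$phi_mean - .data$se,
                                      ymax = .data$phi_mean + .data$se),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$phi_mean)) +
    ggplot2::geom_line(data = model, ggplot2::aes(y = .data$phi),
                       colour = "firebrick") +
    ggplot2::labs(x = "time since alignment (s)", y = "coverage fraction")
}
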