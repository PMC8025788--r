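#' Integrated free-DNA exposure up to each nucleation event
#'
#' The probability of a new nucleation in `(t, t + dt)` is proportional to
#' the undecorated length, `n * L_free(t) dt`. Integrating from protein
#' addition `t0` to the N-th nucleation time gives `N = n * B_N` with
#' `B_N = int_{t0}^{t_N} L_free dt`, so the B_N statistics of an ensemble of
#' experiments estimate the nucleation rate density n.
#'
#' @param curves A list of coverage curves (tibbles with `t_s`, `Lfree_um`).
#' @param nucleation_times A list (same length) of increasing nucleation
#'   times per experiment, s.
#' @param t0 Protein-addition time, s (scalar or per-experiment vector;
#'   default: first sample of each curve).
#' @return A tibble with columns `experiment`, `N`, `B_N` (um s),
#'   trapezoidal integration of `L_free` with linear interpolation at the
#'   integration limits.
#' @export
compute_bn <- function(curves, nucleation_times, t0 = NULL) {
  if (length(curves) != length(nucleation_times)) {
    abort("`curves` and `nucleation_times` must have the same length.")
  }
  purrr::map_dfr(seq_along(curves), function(i) {
    cur <- curves[[i]]
    tn <- sort(nucleation_times[[i]])
    start <- if (is.null(t0)) cur$t_s[1] else if (length(t0) == 1) t0 else t0[i]
    if (any(tn < start)) abort("nucleation time before protein addition t0.")
    tibble::tibble(
      experiment = i,
      N = seq_along(tn),
      B_N = vapply(tn, function(tt) trapz_between(cur$t_s, cur$Lfree_um, start, tt),
                   numeric(1))
    )
  })
}

# trapezoidal integral of y(t) between a and b with interpolated endpoints
trapz_between <- function(t, y, a, b) {
  if (b <= a) return(0)
  ya <- stats::approx(t, y, xout = a, rule = 2)$y
  yb <- stats::approx(t, y, xout = b, rule = 2)$y
  inside <- t > a & t < b
  tt <- c(a, t[inside], b)
  yy <- c(ya, y[inside], yb)
  sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
}

#' Estimate the nucleation rate density from B_N statistics
#'
#' Averages `B_N` across experiments at each nucleation index N and fits
#' the straight line `B_bar_N ~ N`; the slope is `1/n_bar`. When several
#' experiments contribute to each N the fit is weighted by the inverse
#' variance of the per-N means and the slope's standard error follows from
#' those known variances (a residual-based error from the two or three
#' averaged points would have almost no degrees of freedom); with a single
#' experiment per N it falls back to ordinary least squares. The standard
#' error of `n_bar` follows by propagating the slope's.
#'
#' @param records A tibble from [compute_bn()] (columns `N`, `B_N`).
#' @return A list with `n_hat` (1/(um s); multiply by the site spacing in
#'   um to get 1/(site s)), `se`, `slope`, `slope_se`, `fit` (the `lm`),
#'   and `means` (tibble `N`, `B_bar`, `se`, `n_obs`).
#' @export
fit_nucleation_density <- function(records) {
  means <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(records), .data$N),
                            B_bar = mean(.data$B_N),
                            se = stats::sd(.data$B_N) / sqrt(dplyr::n()),
                            n_obs = dplyr::n(),
                            .groups = "drop")
  if (nrow(means) < 2) abort("need B_N values at two or more distinct N.")
  weighted <- all(means$n_obs >= 2) && all(means$se > 0)
  if (weighted) {
    w <- 1 / means$se^2
    fit <- stats::lm(B_bar ~ N, data = means, weights = w)
    slope <- coef(fit)[["N"]]
    # slope error from the known per-point variances, not the residual
    Nw <- sum(w * means$N) / sum(w)
    slope_se <- sqrt(1 / sum(w * (means$N - Nw)^2))
  } else {
    fit <- stats::lm(B_bar ~ N, data = means)
    slope <- coef(fit)[["N"]]
    # summary.lm warns on exact (zero-residual) data; that is a legitimate
    # input here and simply yields a zero standard error
    slope_se <- suppressWarnings(summary(fit)$coefficients["N", "Std. Error"])
  }
  list(
    n_hat = 1 / slope,
    se = slope_se / slope^2,
    slope = slope,
    slope_se = slope_se,
    fit = fit,
    means = means
  )
}

#' Chi-square distance between experimental and model mean coverage
#'
#' `chi2 = sum_t (phi_exp - phi_mod)^2 / (se_exp^2 + se_mod^2)`, with both
#' standard errors entering (the model mean is itself a Monte-Carlo
#' estimate). Grid points with zero combined variance are regularized with
#' a variance floor of 1e-12.
#'
#' @param exp_mean A tibble with `t_s`, `phi_mean`, `se` (experimental
#'   ensemble mean on the comparison grid).
#' @param model A `sim_result` or tibble with `t_s`, `phi_mean`, `se`;
#'   linearly interpolated onto the experimental grid if needed.
#' @return The chi-square value (one number).
#' @export
chi2_objective <- function(exp_mean, model) {
  ms <- if (inherits(model, "sim_result")) model$summary else tibble::as_tibble(model)
  if (!isTRUE(all.equal(ms$t_s, exp_mean$t_s))) {
    mu <- stats::approx(ms$t_s, ms$phi_mean, xout = exp_mean$t_s, rule = 2)$y
    se_m <- stats::approx(ms$t_s, ms$se, xout = exp_mean$t_s, rule = 2)$y
  } else {
    mu <- ms$phi_mean
    se_m <- ms$se
  }
  v <- pmax(exp_mean$se^2 + se_m^2, 1e-12)
  sum((exp_mean$phi_mean - mu)^2 / v)
}

#' Align coverage curves at a threshold crossing and average them
#'
#' Places t = 0 where the (lightly smoothed) coverage first reaches
#' `align_phi`, interpolates every curve onto a common grid, and returns
#' the per-time mean, between-trace SD and standard error. This is the
#' experimental side of the chi-square comparison; the model ensemble is
#' aligned by the same rule.
#'
#' @param curves List of coverage curves (tibbles with `t_s`, `phi`).
#' @param dt_out Output grid spacing, s.
#' @param align_phi Coverage threshold defining t = 0. `align_phi = 0`
#'   aligns at the first nucleation instead (the sample before coverage
#'   first becomes positive) — usable when the curves are noise-free model
#'   output or the nucleation times are otherwise known.
#' @param smooth_k Moving-average window (samples) used only to locate the
#'   crossing on noisy curves.
#' @param trim_phi Truncate the comparison grid shortly after the ensemble
#'   mean first reaches this coverage (default 0.995): past saturation the
#'   between-trace variance carries no kinetic information.
#' @return A tibble `t_s`, `phi_mean`, `phi_sd`, `se`, `n` spanning from 0
#'   to the shortest aligned trace (or the trimmed saturation time).
#' @export
align_and_average <- function(curves, dt_out = 5, align_phi = 0.05,
                              smooth_k = 5, trim_phi = 0.995) {
  aligned <- purrr::map(curves, function(cur) {
    phi <- cur$phi
    if (align_phi <= 0) {
      idx <- max(which(phi > 1e-9)[1] - 1L, 1L)
    } else {
      sm <- if (smooth_k > 1) {
        as.numeric(stats::filter(phi, rep(1 / smooth_k, smooth_k), sides = 2))
      } else phi
      sm[is.na(sm)] <- phi[is.na(sm)]
      idx <- which(sm >= align_phi)[1]
    }
    if (is.na(idx)) abort("a curve never reaches the alignment threshold.")
    tibble::tibble(t_s = cur$t_s - cur$t_s[idx], phi = phi)
  })
  t_end <- min(vapply(aligned, function(a) max(a$t_s), numeric(1)))
  grid <- seq(0, t_end, by = dt_out)
  mat <- vapply(aligned, function(a) {
    stats::approx(a$t_s, a$phi, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  n <- length(curves)
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  out <- tibble::tibble(t_s = grid, phi_mean = mu, phi_sd = sdv,
                        se = sdv / sqrt(n), n = n)
  sat <- which(mu >= trim_phi)[1]
  if (!is.na(sat)) out <- out[seq_len(min(nrow(out), sat + 2L)), ]
  out
}

#' Scan specification for the chi-square grid fit
#'
#' @param kn Grid of nucleation rates, 1/s (log-spaced recommended).
#' @param kg_fast Grid of fast-front growth rates, 1/s.
#' @param r Grid of asymmetry ratios in `(0, 1]` (linear, e.g. step 0.05).
#' @param M_schedule Ensemble sizes of the zoom stages; each stage
#'   re-evaluates the points whose previous-stage chi-square was within
#'   `threshold_frac` of the stage minimum.
#' @param threshold_frac Relative chi-square band kept between stages
#'   (default 0.10, matching the ~10 percent accuracy of the coarse stage).
#' @param dt Simulation step, s.
#' @param dt_out Comparison grid spacing, s.
#' @param align_phi Alignment threshold for both experiment and model.
#' @param condition_complete Condition each model run on reaching full
#'   coverage within the comparison window (default `TRUE`), mirroring the
#'   selection of complete experimental traces before averaging.
#' @return A list of class `scan_spec`.
#' @export
scan_spec <- function(kn, kg_fast, r,
                      M_schedule = c(1e3, 1e4, 1e5),
                      threshold_frac = 0.10, dt = 0.5, dt_out = 5,
                      align_phi = 0.05, condition_complete = TRUE) {
  structure(list(kn = sort(kn), kg_fast = sort(kg_fast), r = sort(r),
                 M_schedule = M_schedule, threshold_frac = threshold_frac,
                 dt = dt, dt_out = dt_out, align_phi = align_phi,
                 condition_complete = condition_complete),
            class = "scan_spec")
}

#' Fit nucleation, growth and asymmetry rates by iterative chi-square scan
#'
#' Compares the experimental ensemble-mean coverage (aligned at a small
#' coverage threshold) with the Monte-Carlo model mean over a grid in
#' `(kn, kg_fast, r)`. Gradient-based optimisers stall on the Monte-Carlo
#' noise of the chi-square surface, so the minimum is located by an
#' iterative scan: a coarse map of the full grid at the first ensemble
#' size, then re-evaluation of the sub-threshold region at each larger
#' ensemble size. The reported parameter errors are the local grid steps
#' (upper bounds).
#'
#' @param curves List of experimental coverage curves (tibbles with `t_s`,
#'   `phi`).
#' @param spec A [scan_spec()].
#' @param n_sites Mean binding-site count of the constructs, used for the
#'   microscopic conversions and energies.
#' @return An object of class `growth_fit`: list with `kn_hat`,
#'   `kg_fast_hat`, `r_hat`, `kg_hat`, step-sized errors, `chi2_min`,
#'   `n_grid` (comparison points), derived `rates` ([rate_params()]),
#'   `dE_coop`, `dE_asym`, `ratio_fast_slow`, `on_boundary` flag, the full
#'   `scan` table and the aligned `exp_mean`.
#' @export
grid_scan_fit <- function(curves, spec, n_sites = NULL) {
  exp_mean <- align_and_average(curves, dt_out = spec$dt_out,
                                align_phi = spec$align_phi)
  n_out <- ceiling(max(exp_mean$t_s) / spec$dt)
  grid <- tidyr::expand_grid(kn = spec$kn, kg_fast = spec$kg_fast, r = spec$r)
  cell_seed <- sample.int(.Machine$integer.max - 1L, 1)
  eval_chi2 <- function(g, M) {
    purrr::pmap_dbl(g, function(kn, kg_fast, r, ...) {
      # margin past the alignment crossing; crossing sits ~align_phi/((1+r) kg')
      # after the first nucleation
      margin <- ceiling(4 * spec$align_phi / ((1 + r) * kg_fast) / spec$dt) + 200L
      # common random numbers across grid cells: the Monte-Carlo error of the
      # chi-square surface varies smoothly in the parameters, so the argmin
      # is not scrambled by cell-to-cell noise
      set.seed(cell_seed)
      origin <- if (spec$align_phi <= 0) 1L else 2L
      res <- sim_ensemble_cpp(kn, kg_fast, r, spec$dt, n_out, as.integer(M),
                              origin, spec$align_phi, n_out + margin,
                              if (isTRUE(spec$condition_complete)) n_out else 0L)
      model <- tibble::tibble(
        t_s = seq(0, by = spec$dt, length.out = n_out + 1),
        phi_mean = res$phi_mean,
        se = res$phi_sd / sqrt(M)
      )
      chi2_objective(exp_mean, model)
    })
  }
  scan <- NULL
  active <- grid
  for (si in seq_along(spec$M_schedule)) {
    M <- spec$M_schedule[si]
    chi2 <- eval_chi2(active, M)
    stage_tbl <- dplyr::mutate(active, chi2 = chi2, M = M, stage = si)
    scan <- dplyr::bind_rows(scan, stage_tbl)
    keep <- chi2 <= min(chi2) * (1 + spec$threshold_frac)
    # never narrow below the best 20 cells: at coarse M the chi-square noise
    # can exceed the 10 percent band
    if (sum(keep) < 20 && length(chi2) > 20) {
      keep <- rank(chi2, ties.method = "first") <= 20
    }
    active <- active[keep, , drop = FALSE]
  }
  final_stage <- dplyr::filter(scan, .data$stage == max(.data$stage))
  best <- final_stage[which.min(final_stage$chi2), ]
  step_of <- function(grid_vals, at) {
    if (length(grid_vals) < 2) return(NA_real_)
    i <- which.min(abs(grid_vals - at))
    if (i == length(grid_vals)) grid_vals[i] - grid_vals[i - 1]
    else grid_vals[i + 1] - grid_vals[i]
  }
  on_boundary <- best$kn %in% range(spec$kn) |
    best$kg_fast %in% range(spec$kg_fast) | best$r == max(spec$r) |
    best$r == min(spec$r)
  if (on_boundary) {
    warn("chi-square minimum lies on the scan boundary; widen the ranges.")
  }
  rates <- rate_params(kn = best$kn, kg_fast = best$kg_fast, r = best$r,
                       n_sites = n_sites)
  structure(
    list(
      kn_hat = best$kn, kg_fast_hat = best$kg_fast, r_hat = best$r,
      kg_hat = rates$kg,
      kn_err = step_of(spec$kn, best$kn),
      kg_fast_err = step_of(spec$kg_fast, best$kg_fast),
      r_err = step_of(spec$r, best$r),
      chi2_min = best$chi2,
      M_final = best$M,
      n_grid = nrow(exp_mean),
      rates = rates,
      n_hat = rates$n, v_hat = rates$v,
      dE_coop = if (!is.null(n_sites)) energy_coop(rates) else NA_real_,
      dE_asym = energy_asym(best$r),
      ratio_fast_slow = 1 / best$r,
      on_boundary = on_boundary,
      scan = tibble::as_tibble(scan),
      exp_mean = exp_mean,
      spec = spec
    ),
    class = "growth_fit"
  )
}
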