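#' Block-average a coverage curve
#'
#' Averages every `n` consecutive samples of a curve (time and value
#' columns), placing each average at the midpoint of its block. Raw traces
#' sampled at kHz rates are typically averaged down this way (blocks of
#' order 2000 points) before break-point fitting; traces already at an
#' effective 1-10 Hz need little or none.
#'
#' @param curve A data frame with a `t_s` column.
#' @param n Block size in samples.
#' @return A tibble of the same columns, one row per block.
#' @export
block_average <- function(curve, n) {
  if (n <= 1) return(tibble::as_tibble(curve))
  grp <- (seq_len(nrow(curve)) - 1L) %/% n
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(curve), .block = grp),
    dplyr::across(dplyr::where(is.numeric), mean),
    .groups = "drop"
  )[, names(curve), drop = FALSE]
}

#' Fit a continuous piecewise-linear function to a length trace
#'
#' Decomposes the measured contour-length kinetics into linear segments
#' separated by break points (nucleation and collision events). Starting
#' from user- or seed-supplied break times, each break is iteratively
#' refitted by continuous two-segment least squares on the window spanned by
#' its neighbouring breaks, until break times shift by less than one sample
#' interval (or 20 iterations). The final model is a globally continuous
#' piecewise-linear least-squares fit with the refined breaks.
#'
#' A break is flagged non-significant (degenerate) when the two-segment fit
#' on its window does not improve on a single line by an F-test at
#' `alpha` — the threshold replaces by-eye classification and is tunable.
#'
#' @param curve A `coverage_curve` (or data frame with `t_s` and the value
#'   column).
#' @param init_breaks Numeric vector of initial break times, s (at least 1).
#' @param value Column to fit; default `"L_um"`.
#' @param smooth_n Block-average window applied before fitting (samples);
#'   default 1 (none; generated traces are already at effective rate).
#' @param alpha Significance level of the per-break F-test (default 0.01).
#' @param max_iter Maximum refinement sweeps (default 20).
#' @return An object of class `breakpoint_fit`: list with `t_breaks`,
#'   `slopes` (length `Q + 1`, one per segment including before the first
#'   and after the last break), `Q`, `n_domains` (`(Q - 1) / 2`),
#'   `residual` (sum of squared residuals), `significant` (per break),
#'   `converged`, and `fitted` (tibble `t_s`, value, `fit`).
#' @export
fit_piecewise_linear <- function(curve, init_breaks, value = "L_um",
                                 smooth_n = 1, alpha = 0.01, max_iter = 20) {
  dat <- block_average(tibble::as_tibble(curve)[, c("t_s", value)], smooth_n)
  t <- dat$t_s
  y <- dat[[value]]
  if (length(init_breaks) < 1) abort("supply at least one initial break time.")
  breaks <- sort(as.numeric(init_breaks))
  if (any(breaks <= t[1]) || any(breaks >= t[length(t)])) {
    abort("initial breaks must lie strictly inside the time range.")
  }
  step <- stats::median(diff(t))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    old <- breaks
    for (j in seq_along(breaks)) {
      lo <- if (j == 1) t[1] else breaks[j - 1]
      hi <- if (j == length(breaks)) t[length(t)] else breaks[j + 1]
      breaks[j] <- refit_one_break(t, y, lo, hi, breaks[j])
    }
    breaks <- sort(breaks)
    if (max(abs(breaks - old)) < step) { converged <- TRUE; break }
  }
  # polish: coordinate descent on the global continuous-fit residual, which
  # shares information across segments instead of relying on local windows
  for (it in seq_len(max_iter)) {
    old <- breaks
    for (j in seq_along(breaks)) {
      lo <- if (j == 1) t[1] else breaks[j - 1]
      hi <- if (j == length(breaks)) t[length(t)] else breaks[j + 1]
      obj <- function(b) pwl_fit(t, y, sort(replace(breaks, j, b)))$sse
      opt <- stats::optimize(obj, c(lo + step, hi - step),
                             tol = 1e-8 * (hi - lo) + 1e-9)
      if (opt$objective < obj(breaks[j])) breaks[j] <- opt$minimum
    }
    breaks <- sort(breaks)
    if (max(abs(breaks - old)) < 0.05 * step) break
  }
  fit <- pwl_fit(t, y, breaks)
  sig <- vapply(seq_along(breaks), function(j) {
    lo <- if (j == 1) t[1] else breaks[j - 1]
    hi <- if (j == length(breaks)) t[length(t)] else breaks[j + 1]
    break_significant(t, y, lo, hi, breaks[j], alpha)
  }, logical(1))
  if (!converged) {
    warn("break refinement did not converge; returning best iterate.")
  }
  fitted_tbl <- tibble::tibble(t_s = t, y = y, fit = fit$fitted)
  names(fitted_tbl)[2] <- value
  structure(
    list(
      t_breaks = breaks,
      slopes = fit$slopes,
      Q = length(breaks),
      n_domains = (length(breaks) - 1) / 2,
      residual = fit$sse,
      significant = sig,
      converged = converged,
      fitted = fitted_tbl,
      value = value
    ),
    class = "breakpoint_fit"
  )
}

# hinge basis for a continuous piecewise-linear least-squares fit
pwl_design <- function(t, breaks) {
  X <- cbind(1, t)
  for (b in breaks) X <- cbind(X, pmax(t - b, 0))
  X
}

pwl_fit <- function(t, y, breaks) {
  X <- pwl_design(t, breaks)
  cf <- stats::lm.fit(X, y)$coefficients
  cf[is.na(cf)] <- 0
  fitted <- drop(X %*% cf)
  list(
    coef = cf,
    # slope of segment k = base slope + sum of the first k-1 hinge terms
    slopes = unname(cumsum(cf[-1])),
    fitted = fitted,
    sse = sum((y - fitted)^2)
  )
}

# best two-segment break position within (lo, hi): coarse scan over sample
# times then continuous refinement
refit_one_break <- function(t, y, lo, hi, cur) {
  idx <- which(t > lo & t < hi)
  if (length(idx) < 5) return(cur)
  tt <- t[idx]; yy <- y[idx]
  cand <- tt[seq(2, length(tt) - 1)]
  # coarse scan over at most 80 candidate times, then continuous refinement
  if (length(cand) > 80) cand <- cand[unique(round(seq(1, length(cand), length.out = 80)))]
  sse <- vapply(cand, function(b) pwl_fit(tt, yy, b)$sse, numeric(1))
  k <- which.min(sse)
  lo2 <- cand[max(1, k - 1)]; hi2 <- cand[min(length(cand), k + 1)]
  if (hi2 > lo2) {
    opt <- stats::optimize(function(b) pwl_fit(tt, yy, b)$sse, c(lo2, hi2),
                           tol = 1e-8 * (hi - lo) + 1e-9)
    if (opt$objective <= sse[k]) return(opt$minimum)
  }
  cand[k]
}

break_significant <- function(t, y, lo, hi, b, alpha) {
  idx <- which(t > lo & t < hi)
  if (length(idx) < 5) return(FALSE)
  tt <- t[idx]; yy <- y[idx]
  sse2 <- pwl_fit(tt, yy, b)$sse
  cf1 <- stats::lm.fit(cbind(1, tt), yy)$coefficients
  sse1 <- sum((yy - drop(cbind(1, tt) %*% cf1))^2)
  df2 <- length(idx) - 3
  if (df2 <= 0 || sse2 <= 0) return(TRUE)
  Fstat <- (sse1 - sse2) / (sse2 / df2)
  stats::pf(Fstat, 1, df2, lower.tail = FALSE) < alpha
}

#' Enumerate collision scenarios consistent with a break-point fit
#'
#' Break points are classified by the sign of the slope change: an increase
#' marks a nucleation, a decrease a collision (two domain fronts meeting, or
#' a front reaching an end of the molecule). For a complete trace with `Q`
#' breaks there are `N_t = (Q-1)/2` domains and `N_t + 1` collision events
#' closing the `N_t + 1` gaps of the final configuration (two ends plus
#' `N_t - 1` inter-domain gaps). Every spatial ordering of the domains and
#' every chronological assignment of collision breaks to gaps that respects
#' nucleation order (a gap can only close once all adjacent domains exist)
#' is a candidate scenario; unphysical ones are weeded out by
#' [solve_scenario()] (negative front velocities) and replay.
#'
#' Mirror-image scenarios (reversed spatial order) are both enumerated; they
#' solve to the same front-velocity sets because the trace cannot identify
#' absolute orientation.
#'
#' @param fit A [fit_piecewise_linear()] result.
#' @return A list of scenarios (class `scenario`), each a list with
#'   `order` (spatial order of domains, by nucleation index), `events`
#'   (tibble: break index, time, type, gap label) and `n_domains`. Empty
#'   (with attribute `reason`) when the slope pattern admits no consistent
#'   assignment.
#' @export
enumerate_scenarios <- function(fit) {
  Q <- fit$Q
  d_slope <- diff(fit$slopes)    # slope change at each break
  nuc_breaks <- which(d_slope > 0)
  coll_breaks <- which(d_slope < 0)
  N <- length(nuc_breaks)
  fail <- function(reason) structure(list(), reason = reason)
  if (N == 0) return(fail("no slope increases: no nucleation events"))
  if (nuc_breaks[1] != 1) return(fail("first break must be a nucleation"))
  if (length(coll_breaks) != N + 1) {
    return(fail(sprintf(
      "incomplete trace: %d collision breaks for %d domains (need %d)",
      length(coll_breaks), N, N + 1)))
  }
  orders <- perms(N)
  out <- list()
  for (oi in seq_len(nrow(orders))) {
    ord <- orders[oi, ]
    # gap g = 0..N: g=0 left end (adjacent ord[1]); g=k between ord[k], ord[k+1];
    # g=N right end (adjacent ord[N])
    gap_min_break <- vapply(0:N, function(g) {
      adj <- if (g == 0) ord[1] else if (g == N) ord[N] else c(ord[g], ord[g + 1])
      max(nuc_breaks[adj])
    }, numeric(1))
    for (ai in seq_len(nrow(orders_gaps <- perms(N + 1)))) {
      gaps <- orders_gaps[ai, ] - 1L  # gap assigned to each collision break
      if (any(coll_breaks <= gap_min_break[gaps + 1L])) next
      lab <- vapply(gaps, function(g) {
        if (g == 0) "end_left"
        else if (g == N) "end_right"
        else sprintf("between_%d_%d", ord[g], ord[g + 1])
      }, character(1))
      events <- tibble::tibble(
        break_index = seq_len(Q),
        t = fit$t_breaks,
        type = ifelse(d_slope > 0, "nucleation", "collision"),
        gap = NA_integer_,
        gap_label = NA_character_,
        domain = NA_integer_
      )
      events$domain[nuc_breaks] <- seq_len(N)
      events$gap[coll_breaks] <- gaps
      events$gap_label[coll_breaks] <- lab
      out[[length(out) + 1]] <- structure(
        list(order = ord, events = events, n_domains = N),
        class = "scenario"
      )
    }
  }
  out
}

perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Solve one scenario for per-domain front velocities and positions
#'
#' In naked-contour units, each segment's length slope equals half the sum
#' of the active front velocities (covering `dx` of naked contour adds
#' `dx/2` to the total length because decorated contour is 1.5x longer).
#' With one equation per inter-break segment and two fronts per domain the
#' system is square; it is solved exactly, and the nucleation positions
#' follow from accumulated front displacements (the leftmost domain's
#' left-front travel fixes its position; each inter-domain meeting point
#' chains the next one).
#'
#' A scenario is infeasible when any solved velocity is negative (negative
#' front velocity means disassembly, negligible with ATPgammaS) or when its
#' replay puts a nucleation inside already-covered DNA.
#'
#' @param scenario A scenario from [enumerate_scenarios()].
#' @param fit The [fit_piecewise_linear()] result it came from.
#' @param geom The construct's [filament_geometry()].
#' @return An object of class `domain_kinetics`: list with `domains`
#'   (tibble: `domain`, `t_nuc`, `x_um`, `x_frac`, `v_fast_um_s`,
#'   `v_slow_um_s`, `v_fast_sites_s`, `v_slow_sites_s`, `r`), `fronts`
#'   (tibble with per-front velocities, stop breaks and travels),
#'   `feasible`, `reason`, `closure_error_um`, and the originating
#'   `scenario`. Returns with `feasible = FALSE` rather than erroring on
#'   unphysical solutions; a singular system gives `feasible = NA`
#'   (ambiguous).
#' @export
solve_scenario <- function(scenario, fit, geom) {
  ev <- scenario$events
  N <- scenario$n_domains
  ord <- scenario$order
  Q <- fit$Q
  nuc_break <- ev$break_index[ev$type == "nucleation"]
  # front f = (domain d, side L/R): close break from the gap assignment
  pos_in_order <- match(seq_len(N), ord)  # spatial rank of each domain
  coll <- ev[ev$type == "collision", ]
  gap_close_break <- setNames(coll$break_index, coll$gap) # names: gap id
  close_break <- matrix(NA_integer_, N, 2,
                        dimnames = list(NULL, c("L", "R")))
  for (d in seq_len(N)) {
    k <- pos_in_order[d]
    close_break[d, "L"] <- gap_close_break[[as.character(k - 1)]]
    close_break[d, "R"] <- gap_close_break[[as.character(k)]]
  }
  # segment j spans (t_j, t_{j+1}); slope index j+1 in fit$slopes
  segs <- seq_len(Q - 1)
  fronts <- expand.grid(domain = seq_len(N), side = c("L", "R"),
                        stringsAsFactors = FALSE)
  A <- matrix(0, length(segs), nrow(fronts))
  for (j in segs) {
    for (f in seq_len(nrow(fronts))) {
      d <- fronts$domain[f]
      cb <- close_break[d, fronts$side[f]]
      if (nuc_break[d] <= j && cb > j) A[j, f] <- 1
    }
  }
  rhs <- 2 * fit$slopes[segs + 1]
  v <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(v)) {
    return(new_domain_kinetics(NULL, NULL, scenario, NA, "singular system (ambiguous scenario)", NA_real_))
  }
  fronts$v_um_s <- v
  fronts$close_break <- close_break[cbind(fronts$domain, match(fronts$side, c("L", "R")))]
  fronts$t_stop <- fit$t_breaks[fronts$close_break]
  fronts$t_nuc <- fit$t_breaks[nuc_break[fronts$domain]]
  fronts$travel_um <- fronts$v_um_s * (fronts$t_stop - fronts$t_nuc)
  if (any(v < -1e-9)) {
    return(new_domain_kinetics(NULL, tibble::as_tibble(fronts), scenario, FALSE,
                               "negative front velocity (would require disassembly)", NA_real_))
  }
  # positions by chaining travels along the spatial order
  v_mat <- matrix(fronts$v_um_s, N, 2)      # columns: L, R
  travel <- matrix(fronts$travel_um, N, 2)
  x <- numeric(N)
  x[ord[1]] <- travel[ord[1], 1]
  if (N > 1) {
    for (k in 2:N) {
      x[ord[k]] <- x[ord[k - 1]] + travel[ord[k - 1], 2] + travel[ord[k], 1]
    }
  }
  closure <- abs(x[ord[N]] + travel[ord[N], 2] - geom$L_initial)
  vf <- pmax(v_mat[, 1], v_mat[, 2])
  vs <- pmin(v_mat[, 1], v_mat[, 2])
  per_um <- 1 / geom$site_length_um  # sites per um of naked contour
  domains <- tibble::tibble(
    domain = seq_len(N),
    t_nuc = fit$t_breaks[nuc_break],
    x_um = x,
    x_frac = x / geom$L_initial,
    v_left_um_s = v_mat[, 1],
    v_right_um_s = v_mat[, 2],
    v_fast_um_s = vf,
    v_slow_um_s = vs,
    v_fast_sites_s = vf * per_um,
    v_slow_sites_s = vs * per_um,
    r = ifelse(vf > 0, vs / vf, NA_real_)
  )
  kin <- new_domain_kinetics(domains, tibble::as_tibble(fronts), scenario,
                             TRUE, "ok", closure)
  # physicality of positions: replay must accept every nucleation
  ok <- tryCatch({
    reconstruct_length(kin, geom, dt = max(min(diff(fit$fitted$t_s)) / 2, 1e-3),
                       t_end = max(fit$fitted$t_s))
    TRUE
  }, error = function(e) FALSE)
  if (!ok || any(x < -1e-6) || any(x > geom$L_initial + 1e-6)) {
    kin$feasible <- FALSE
    kin$reason <- "nucleation position outside the open region"
  }
  kin
}

new_domain_kinetics <- function(domains, fronts, scenario, feasible, reason,
                                closure) {
  structure(
    list(domains = domains, fronts = fronts, scenario = scenario,
         feasible = feasible, reason = reason, closure_error_um = closure),
    class = "domain_kinetics"
  )
}

#' Forward-simulate the length trace implied by solved domain kinetics
#'
#' Deterministically replays the nucleation list of a `domain_kinetics`
#' (times, positions, per-front velocities) with the front-propagation
#' engine and maps coverage back to total contour length,
#' `L(t) = L(0) (1 + phi/2)`. Used to score competing scenarios by their
#' reconstruction residual against the measured trace.
#'
#' @param kinetics A `domain_kinetics` from [solve_scenario()] (uses its
#'   per-side velocities), or a tibble with columns `t_nuc`, `x_frac` (or
#'   `x_um`) and per-side velocities `v_left_um_s`, `v_right_um_s` (um of
#'   naked contour per second; fraction/s columns `v_left`, `v_right` are
#'   also accepted).
#' @param geom The construct's [filament_geometry()].
#' @param dt Engine time step, s.
#' @param t_end End of the reconstructed trace, s.
#' @return A `coverage_curve` tibble (`t_s`, `L_um`, `phi`, `Lfree_um`).
#' @export
reconstruct_length <- function(kinetics, geom, dt = 0.5, t_end = NULL) {
  dom <- if (inherits(kinetics, "domain_kinetics")) kinetics$domains else
    tibble::as_tibble(kinetics)
  L0 <- geom$L_initial
  if (is.null(dom) || nrow(dom) == 0) {
    if (is.null(t_end)) t_end <- dt
    t_s <- seq(0, t_end, by = dt)
    return(coverage_curve(t_s, rep(L0, length(t_s)), geom))
  }
  x_frac <- if ("x_frac" %in% names(dom)) dom$x_frac else dom$x_um / L0
  vl <- if ("v_left" %in% names(dom)) dom$v_left else dom$v_left_um_s / L0
  vr <- if ("v_right" %in% names(dom)) dom$v_right else dom$v_right_um_s / L0
  if (is.null(t_end)) {
    t_end <- max(dom$t_nuc) + 2 / min(pmax(c(vl, vr), 1e-12))
  }
  ord <- order(dom$t_nuc)
  res <- sim_forced_cpp(dt, ceiling(t_end / dt),
                        dom$t_nuc[ord], x_frac[ord],
                        as.numeric(vl[ord]), as.numeric(vr[ord]),
                        rep(0L, length(ord)))
  t_s <- seq(0, by = dt, length.out = length(res$phi))
  coverage_curve(t_s, L0 * (1 + res$phi / 2), geom)
}

#' Fit, enumerate, solve and rank all decomposition scenarios of a trace
#'
#' Convenience pipeline: [fit_piecewise_linear()] then
#' [enumerate_scenarios()], [solve_scenario()] on each, and ranking of the
#' feasible solutions by the residual of their reconstructed `L(t)` against
#' the measured curve. Several feasible scenarios are common for multi-domain
#' traces; the residual ranking is a heuristic and all feasible solutions are
#' returned.
#'
#' @inheritParams fit_piecewise_linear
#' @param geom The construct's [filament_geometry()].
#' @return A list with `fit`, `scenarios`, `solutions` (all, feasible or
#'   not) and `ranking` (tibble: scenario index, feasibility, reconstruction
#'   residual, ordered best first).
#' @export
decompose_curve <- function(curve, init_breaks, geom, value = "L_um",
                            smooth_n = 1, alpha = 0.01) {
  fit <- fit_piecewise_linear(curve, init_breaks, value = value,
                              smooth_n = smooth_n, alpha = alpha)
  scen <- enumerate_scenarios(fit)
  sols <- lapply(scen, solve_scenario, fit = fit, geom = geom)
  resid <- vapply(seq_along(sols), function(i) {
    if (!isTRUE(sols[[i]]$feasible)) return(NA_real_)
    rec <- reconstruct_length(sols[[i]], geom,
                              dt = stats::median(diff(curve$t_s)),
                              t_end = max(curve$t_s))
    L_hat <- stats::approx(rec$t_s, rec$L_um, xout = curve$t_s, rule = 2)$y
    sum((L_hat - curve$L_um)^2)
  }, numeric(1))
  ranking <- tibble::tibble(
    scenario = seq_along(sols),
    feasible = vapply(sols, function(s) isTRUE(s$feasible), logical(1)),
    residual = resid
  )
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$feasible), .data$residual)
  list(fit = fit, scenarios = scen, solutions = sols, ranking = ranking)
}
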