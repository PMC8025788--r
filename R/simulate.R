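#' Configuration for the few-nuclei Monte-Carlo simulation
#'
#' The stochastic model lives on a normalized substrate `[0, 1]` (positions
#' are fractions of the naked contour). Per time step `dt`, a nucleation
#' occurs with probability `kn (1 - phi) dt` at a uniform point of the
#' undecorated set; each existing domain advances its fast front by
#' `kg_fast * dt` and its slow front by `r * kg_fast * dt` (in substrate
#' fraction), the fast side having been chosen at random at nucleation.
#' Fronts stop at the substrate ends and at collisions with neighbouring
#' domains. A run ends when the molecule is fully covered (with `r = 0` full
#' coverage can take arbitrarily long; `t_max` caps the run).
#'
#' @param rates A [rate_params()] object (uses `kn`, `kg_fast`, `r`).
#' @param dt Time step, s (default 0.5; results should be insensitive to
#'   halving it).
#' @param t_max Maximum simulated time, s.
#' @param time_origin `"protein_addition"` (t = 0 when protein is added),
#'   `"first_nucleation"` (t = 0 at the first nucleation event) or
#'   `"phi_threshold"` (t = 0 when phi first reaches `align_phi`).
#' @param M Ensemble size for [simulate_ensemble()].
#' @param align_phi Coverage threshold used when
#'   `time_origin = "phi_threshold"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(rates, dt = 0.5, t_max = 12000,
                       time_origin = c("protein_addition", "first_nucleation",
                                       "phi_threshold"),
                       M = 1000, align_phi = 0.05) {
  if (!inherits(rates, "rate_params")) abort("`rates` must be a rate_params object.")
  if (dt <= 0) abort("`dt` must be positive.")
  structure(
    list(rates = rates, dt = dt, t_max = t_max,
         time_origin = match.arg(time_origin), M = M, align_phi = align_phi),
    class = "sim_config"
  )
}

origin_code <- function(time_origin) {
  match(time_origin, c("protein_addition", "first_nucleation", "phi_threshold")) - 1L
}

#' Simulate one nucleation-and-growth trajectory
#'
#' Runs a single stochastic realization of the few-nuclei model and returns
#' the coverage trajectory together with the exact ground truth: nucleation
#' times, positions, fast-side choices, per-front velocities, and the
#' collision log (domain-domain merges and end absorptions, with collision
#' times interpolated within the step).
#'
#' Uses R's global RNG stream: call `set.seed()` for reproducibility.
#'
#' @param config A [sim_config()].
#' @return A list with elements `trajectory` (tibble `t_s`, `phi`),
#'   `nucleations` (tibble: `domain`, `t`, `x`, `fast_side`, `v_left`,
#'   `v_right`, velocities in fraction/s), and `collisions` (tibble).
#' @export
simulate_once <- function(config) {
  rt <- config$rates
  n_steps <- ceiling(config$t_max / config$dt)
  res <- sim_once_cpp(rt$kn, rt$kg_fast, rt$r, config$dt, n_steps,
                      config$time_origin != "protein_addition")
  list(
    trajectory = tibble::tibble(
      t_s = seq(0, by = config$dt, length.out = length(res$phi)),
      phi = res$phi
    ),
    nucleations = tibble::as_tibble(res$nucleations),
    collisions = tibble::as_tibble(res$collisions)
  )
}

#' Ensemble mean and dispersion of the simulated coverage
#'
#' Runs `M` independent replicates of the few-nuclei model on a common time
#' grid and returns the ensemble mean `phi_mean(t)`, the between-run
#' standard deviation `phi_sd(t)` and the standard error
#' `se = phi_sd / sqrt(M)`. Trajectories are aligned according to
#' `config$time_origin` before averaging (for slow-nucleation comparisons
#' t = 0 is placed at the first nucleation event).
#'
#' @param config A [sim_config()] with `M >= 2`.
#' @return An object of class `sim_result`: a list with `summary` (tibble
#'   `t_s`, `phi_mean`, `phi_sd`, `se`), `M` and the `config`.
#' @export
simulate_ensemble <- function(config) {
  if (config$M < 2) abort("`M` must be at least 2.")
  rt <- config$rates
  n_out <- ceiling(config$t_max / config$dt)
  # allow room past the alignment origin for late first nucleations
  max_steps <- if (config$time_origin == "protein_addition") n_out else
    n_out + ceiling(2 / max(rt$r, 0.05) / rt$kg_fast / config$dt)
  res <- sim_ensemble_cpp(rt$kn, rt$kg_fast, rt$r, config$dt, n_out,
                          config$M, origin_code(config$time_origin),
                          config$align_phi, max_steps)
  structure(
    list(
      summary = tibble::tibble(
        t_s = seq(0, by = config$dt, length.out = n_out + 1),
        phi_mean = res$phi_mean,
        phi_sd = res$phi_sd,
        se = res$phi_sd / sqrt(config$M)
      ),
      M = config$M,
      config = config
    ),
    class = "sim_result"
  )
}

#' Deterministic replay of a prescribed nucleation scenario
#'
#' Propagates fronts for a given list of nucleation events — no randomness.
#' Used as ground truth by the synthetic-data generator, as the forward
#' model for scenario scoring, and as the oracle for decomposition round
#' trips. Velocities default to the configured `kg_fast` / `r * kg_fast`
#' split given each event's `fast_side`, but per-domain `v_fast` / `v_slow`
#' columns (fraction/s) may be supplied for heterogeneous ground truths.
#'
#' @param config A [sim_config()] (supplies rates, `dt`, `t_max`).
#' @param nucleations A data frame with columns `t` (increasing, s), `x`
#'   (position fraction) and `fast_side` (`"left"`/`"right"` or 0/1);
#'   optional `v_fast`, `v_slow` in fraction/s, or explicit per-side
#'   `v_left`, `v_right` columns (fraction/s), which take precedence.
#' @return A list with `trajectory` (tibble `t_s`, `phi`) and `collisions`.
#' @export
forced_scenario <- function(config, nucleations) {
  nuc <- tibble::as_tibble(nucleations)
  if (nrow(nuc) > 0 && any(diff(nuc$t) < 0)) {
    abort("nucleation times must be non-decreasing.")
  }
  fs <- nuc$fast_side
  if (is.character(fs)) fs <- match(fs, c("left", "right")) - 1L
  rt <- config$rates
  v_fast <- if ("v_fast" %in% names(nuc)) nuc$v_fast else rep(rt$kg_fast, nrow(nuc))
  v_slow <- if ("v_slow" %in% names(nuc)) nuc$v_slow else rep(rt$r * rt$kg_fast, nrow(nuc))
  if (all(c("v_left", "v_right") %in% names(nuc))) {
    v_left <- nuc$v_left
    v_right <- nuc$v_right
  } else {
    v_left <- ifelse(fs == 0L, v_fast, v_slow)
    v_right <- ifelse(fs == 0L, v_slow, v_fast)
  }
  n_steps <- ceiling(config$t_max / config$dt)
  res <- sim_forced_cpp(config$dt, n_steps, nuc$t, nuc$x,
                        as.numeric(v_left), as.numeric(v_right),
                        as.integer(fs))
  list(
    trajectory = tibble::tibble(
      t_s = seq(0, by = config$dt, length.out = length(res$phi)),
      phi = res$phi
    ),
    collisions = tibble::as_tibble(res$collisions)
  )
}
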