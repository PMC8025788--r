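#' Specification of a synthetic force-clamp experiment ensemble
#'
#' Generates ground-truth experiments emulating lambda-DNA-scale constructs
#' held at a 0.8 pN clamp while RecA assembles: naked contour lengths drawn
#' uniformly from 10-17 um (non-specific tethering gives variable lengths;
#' the mean corresponds to roughly 11,800 binding sites), few-nuclei
#' nucleation-and-growth kinetics at the default rates
#' `kn = 1.05e-3 1/s`, `kg_fast = 5.27e-4 1/s`, `r = 0.10`, a clamp force
#' wandering within +/-0.1 pN of 0.8 pN, additive Gaussian position noise,
#' and an effective sampling rate of a few Hz.
#'
#' @param n_experiments Number of constructs to generate.
#' @param rates A [rate_params()] object (defaults above).
#' @param L_range Range of naked contour lengths, um.
#' @param force_pN Clamp set point, pN.
#' @param force_jitter_pN Clamp band half-width, pN (slow random walk,
#'   clipped; the clamp is re-adjusted whenever it drifts to the band edge).
#' @param noise_sd_um SD of additive Gaussian noise on the trap-anchor
#'   distance, um.
#' @param sample_rate_hz Effective sampling rate, Hz.
#' @param t_max Trace duration cap, s.
#' @param dt_sim Simulation step of the underlying kinetics, s.
#' @param wlc A [wlc_params()] object.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_experiments = 5,
                       rates = rate_params(kn = 1.05e-3, kg_fast = 5.27e-4,
                                           r = 0.10),
                       L_range = c(10, 17),
                       force_pN = 0.8, force_jitter_pN = 0.1,
                       noise_sd_um = 0.05, sample_rate_hz = 1,
                       t_max = 12000, dt_sim = 0.5,
                       wlc = wlc_params()) {
  structure(
    list(n_experiments = n_experiments, rates = rates, L_range = L_range,
         force_pN = force_pN, force_jitter_pN = force_jitter_pN,
         noise_sd_um = noise_sd_um, sample_rate_hz = sample_rate_hz,
         t_max = t_max, dt_sim = dt_sim, wlc = wlc),
    class = "synth_spec"
  )
}

#' Generate one synthetic force-clamp experiment with ground truth
#'
#' Forward model: a stochastic few-nuclei trajectory gives phi(t); the
#' contour length follows as `L(t) = L(0) (1 + phi/2)`; the trap-anchor
#' distance is composed segment-wise from the large-force worm-like-chain
#' extension of the naked and decorated parts at the jittered clamp force;
#' Gaussian measurement noise is added on the distance. The exact domain
#' kinetics (nucleation times, positions, per-front velocities, collision
#' log) is returned alongside, so every later pipeline stage can be checked
#' against truth.
#'
#' Uses R's global RNG: call `set.seed()` first for reproducibility.
#'
#' @param spec A [synth_spec()].
#' @return A list with `trace` (tibble `t_s`, `F_pN`, `y_um`), `curve` (the
#'   noise-free `coverage_curve`), `geom`, `nucleations`, `collisions` and
#'   `trajectory` (the simulation-step phi).
#' @export
make_experiment <- function(spec) {
  L0 <- runif(1, spec$L_range[1], spec$L_range[2])
  geom <- filament_geometry(L0)
  cfg <- sim_config(spec$rates, dt = spec$dt_sim, t_max = spec$t_max,
                    time_origin = "protein_addition")
  sim <- simulate_once(cfg)
  dt_samp <- 1 / spec$sample_rate_hz
  t_s <- seq(0, spec$t_max, by = dt_samp)
  phi <- stats::approx(sim$trajectory$t_s, sim$trajectory$phi, xout = t_s,
                       rule = 2)$y
  L <- L0 * (1 + phi / 2)
  # clamp force: bounded random walk around the set point, re-centred at the
  # band edges the way the operator re-adjusts the clamp
  F_step <- spec$force_jitter_pN / 10
  steps <- rnorm(length(t_s), 0, F_step)
  dF <- numeric(length(t_s))
  drift <- 0
  for (i in seq_along(steps)) {
    drift <- drift + steps[i]
    if (abs(drift) > spec$force_jitter_pN) drift <- 0  # clamp re-adjusted
    dF[i] <- drift
  }
  F_pN <- spec$force_pN + dF
  LR <- 3 * (L - L0)
  z <- filament_extension(LR, F_pN, geom, spec$wlc)
  y <- z + rnorm(length(z), 0, spec$noise_sd_um)
  list(
    trace = tibble::tibble(t_s = t_s, F_pN = F_pN, y_um = y),
    curve = coverage_curve(t_s, L, geom),
    geom = geom,
    nucleations = sim$nucleations,
    collisions = sim$collisions,
    trajectory = sim$trajectory
  )
}

#' Generate an ensemble of synthetic experiments
#'
#' Draws `spec$n_experiments` independent experiments with per-experiment
#' sub-seeds derived from `seed`, so the ensemble is reproducible and each
#' experiment can be regenerated in isolation. Optionally writes the traces,
#' ground truth and a manifest to `dir`.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer master seed.
#' @param dir Optional output directory; if given, writes per-experiment
#'   trace TSVs, ground-truth JSON and `manifest.json` with file checksums.
#' @param complete_only Keep only experiments whose coverage reaches
#'   saturation within the trace (the selection applied to real data before
#'   ensemble averaging); further sub-seeds are drawn until
#'   `n_experiments` complete traces are collected (at most 5x as many
#'   tries).
#' @return A list of experiments (see [make_experiment()]), invisibly
#'   carrying the manifest as attribute `manifest` when written.
#' @export
make_ensemble <- function(spec, seed, dir = NULL, complete_only = FALSE) {
  n_try <- if (complete_only) 5L * spec$n_experiments else spec$n_experiments
  sub_seeds <- derive_seeds(seed, n_try)
  exps <- list()
  used <- integer(0)
  for (s in sub_seeds) {
    if (length(exps) >= spec$n_experiments) break
    set.seed(s)
    e <- make_experiment(spec)
    if (complete_only && max(e$trajectory$phi) < 0.999) next
    exps[[length(exps) + 1]] <- e
    used <- c(used, s)
  }
  if (length(exps) < spec$n_experiments) {
    warn("fewer complete experiments than requested; returning what was found.")
  }
  sub_seeds <- used
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- purrr::imap_chr(exps, function(e, i) {
      f <- file.path(dir, sprintf("experiment_%02d.tsv", i))
      write_trace(e$trace, f)
      jf <- file.path(dir, sprintf("experiment_%02d_truth.json", i))
      jsonlite::write_json(
        list(L_initial = e$geom$L_initial,
             n_sites = e$geom$n_sites,
             seed = sub_seeds[i],
             nucleations = e$nucleations),
        jf, auto_unbox = TRUE, digits = NA
      )
      f
    })
    manifest <- tibble::tibble(
      file = basename(c(files, sub("\\.tsv$", "_truth.json", files))),
      md5 = tools::md5sum(c(files, sub("\\.tsv$", "_truth.json", files)))
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    attr(exps, "manifest") <- manifest
  }
  exps
}

# independent per-experiment seeds below 2^31 derived from one master seed
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
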