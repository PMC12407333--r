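#' FUCCI reporter intensities along the cycle
#'
#' Piecewise-linear model of the two FUCCI reporters: hCdt1-mCherry is high
#' throughout G1 and decays linearly over the first 30% of S; hGeminin-
#' mCitrine is absent in G1, rises linearly across S, and stays high through
#' G2 and M. Early S is therefore double positive, reproducing the three
#' flow-cytometry gates (mCherry+ = G1, double positive = early S,
#' mCitrine+ = S/G2/M).
#'
#' @param tau Numeric vector of cycle positions in hours.
#' @param cycle A [cycle_params()] object.
#' @param scale Peak intensity in arbitrary fluorescence units.
#' @param cherry_decay_frac Fraction of S over which mCherry decays to zero.
#' @return A tibble with columns `fucci_cherry` and `fucci_citrine`.
#' @export
fucci_intensity <- function(tau, cycle, scale = 1000,
                            cherry_decay_frac = 0.3) {
  stopifnot(inherits(cycle, "cycle_params"))
  s_start <- cycle$t_g1
  s_end <- cycle$t_g1 + cycle$t_s
  decay_end <- s_start + cherry_decay_frac * cycle$t_s
  cherry <- if_else(
    tau < s_start, 1,
    if_else(tau < decay_end, 1 - (tau - s_start) / (decay_end - s_start), 0)
  )
  citrine <- if_else(
    tau < s_start, 0,
    if_else(tau < s_end, (tau - s_start) / cycle$t_s, 1)
  )
  tibble(fucci_cherry = scale * cherry, fucci_citrine = scale * citrine)
}

# Inverse-CDF sampler for cycle positions. For an exponentially growing
# culture the age density is proportional to 2^(-tau/total): young cells are
# over-represented because every division creates two of them.
sample_tau <- function(n, cycle) {
  u <- runif(n)
  switch(cycle$age_distribution,
    "uniform" = u * cycle$total,
    "exponential-growth" = -cycle$total * log2(1 - u / 2),
    abort(paste0("Unknown age distribution: ", cycle$age_distribution))
  )
}

#' Simulate an asynchronous proliferating cell population
#'
#' Samples `n` cycle positions from the configured age distribution and
#' evaluates, for each cell, the DNA-content schedule, the periodic
#' steady-state amount of every mark, and the FUCCI reporter intensities.
#' Cell-to-cell variation enters only through the sampled cycle position;
#' measurement noise is added downstream (by the image renderer), so the
#' records carry exact ground truth.
#'
#' @param cycle A [cycle_params()] object.
#' @param kinetics A list of [mark_kinetics()] objects (may be empty).
#' @param n Number of cells (>= 1).
#' @param seed Integer seed; two runs with the same seed are identical.
#' @param tau Optional numeric vector of cycle positions to use instead of
#'   sampling (recycled/truncated to length `n`); useful for tests.
#' @return A tibble of cell records: `cell_id`, `tau`, `phase`, `dna`,
#'   one `mark_<name>` column per mark, `fucci_cherry`, `fucci_citrine`.
#' @examples
#' cyc <- cycle_params(10, 8, 4, 1)
#' cells <- simulate_population(cyc, list(mark_kinetics("H3K27me3", 0.05)),
#'                              n = 100, seed = 1)
#' @export
simulate_population <- function(cycle, kinetics = list(), n, seed,
                                tau = NULL) {
  stopifnot(inherits(cycle, "cycle_params"))
  if (n < 1) abort("`n` must be >= 1.")
  if (is.null(tau)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    tau <- sample_tau(n, cycle)
  } else {
    tau <- rep_len(tau, n)
  }
  out <- tibble(
    cell_id = seq_len(n),
    tau = tau,
    phase = cycle_phase(tau, cycle),
    dna = dna_content(tau, cycle)
  )
  for (kin in kinetics) {
    traj <- steady_state_mark(cycle, kin)
    m0 <- attr(traj, "m0")
    out[[paste0("mark_", kin$mark_name)]] <-
      mark_at_tau(tau, m0, kin$k_restore, kin$rho_target, cycle)
  }
  dplyr::bind_cols(out, fucci_intensity(tau, cycle))
}

# Save/restore global RNG state so exported simulators honour their explicit
# seed without disturbing the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
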