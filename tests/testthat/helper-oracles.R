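# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Dense RK4 integration of dM/dt = k * (rho * c(t) - M) with symmetric
# halving at division, iterated to the periodic steady state. Used as the
# numerical oracle for the analytic-propagation solver at a 10x finer step.
rk4_steady_mark <- function(cycle, k, rho, n_steps = 5120L, n_cycles = 400L,
                            tol = 1e-10) {
  h <- cycle$total / n_steps
  tgrid <- seq(0, cycle$total, length.out = n_steps + 1L)
  cfun <- function(t) dna_content(pmin(t, cycle$total - 1e-12), cycle)
  f <- function(t, m) k * (rho * cfun(t) - m)
  m0 <- rho
  for (cyc_i in seq_len(n_cycles)) {
    m <- numeric(n_steps + 1L)
    m[1] <- m0
    for (i in seq_len(n_steps)) {
      t <- tgrid[i]
      k1 <- f(t, m[i])
      k2 <- f(t + h / 2, m[i] + h / 2 * k1)
      k3 <- f(t + h / 2, m[i] + h / 2 * k2)
      k4 <- f(t + h, m[i] + h * k3)
      m[i + 1] <- m[i] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    m0_new <- m[n_steps + 1L] / 2
    if (abs(m0_new - m0) < tol) {
      m0 <- m0_new
      break
    }
    m0 <- m0_new
  }
  list(tau = tgrid[-(n_steps + 1L)], mark = m[-(n_steps + 1L)],
       density = m[-(n_steps + 1L)] /
         (rho * dna_content(tgrid[-(n_steps + 1L)], cycle)))
}

# Exhaustive enumeration of all monotone warping paths (steps right, down,
# diagonal) from (1,1) to (n,m); the minimum path cost is the DTW distance.
brute_force_dtw <- function(a, b) {
  n <- length(a)
  m <- length(b)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n) rec(i + 1L, j, acc)
    if (j < m) rec(i, j + 1L, acc)
    if (i < n && j < m) rec(i + 1L, j + 1L, acc)
    invisible()
  }
  rec(1L, 1L, 0)
  best
}

# Standard slow/fast mark kinetics used throughout: rates are absolute
# (per hour) so that conditions with different G1 lengths share the same
# restoration chemistry.
slow_kin <- function() mark_kinetics("H3K27me3", 1 / 23)
fast_kin <- function() mark_kinetics("H3K4me3", 50 / 23)

reference_cycle <- function(t_g1 = 10) cycle_params(t_g1, 8, 4, 1)

# Imaging fixtures, cached within a test session because several tests share
# them. run_seg_fixture stops after measurement (works at any n);
# run_imaging_fixture runs the full staging pipeline (needs a few hundred
# nuclei).
.pipeline_cache <- new.env(parent = emptyenv())

run_seg_fixture <- function(seed, t_g1 = 10, n = 20) {
  key <- paste("seg", seed, t_g1, n, sep = "_")
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  cyc <- reference_cycle(t_g1)
  cells <- simulate_population(cyc, list(slow_kin(), fast_kin()),
                               n = n, seed = seed)
  img <- render_image(cells, cycle = cyc, seed = seed + 1000L)
  corrected <- lapply(img$channels, function(ch) {
    rolling_ball_subtract(correct_illumination(ch), radius = 20)
  })
  mask <- segment_nuclei(corrected$dna)
  meas <- measure_nuclei(mask, corrected)
  mt <- match_truth(mask, img$truth_mask)
  meas <- dplyr::left_join(meas, mt, by = "label")
  meas <- dplyr::left_join(meas, img$truth_table,
                           by = c(truth_label = "label"),
                           suffix = c("", ".truth"))
  out <- list(cycle = cyc, cells = cells, img = img, mask = mask,
              meas = meas, match = mt)
  .pipeline_cache[[key]] <- out
  out
}

run_imaging_fixture <- function(seed, t_g1 = 10, n = 200, min_cells = 20L) {
  key <- paste("full", seed, t_g1, n, min_cells, sep = "_")
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  cyc <- reference_cycle(t_g1)
  cells <- simulate_population(cyc, list(slow_kin(), fast_kin()),
                               n = n, seed = seed)
  img <- render_image(cells, cycle = cyc, seed = seed + 1000L)
  res <- stage_image_pipeline(img$channels, min_cells = min_cells)
  mt <- match_truth(res$mask, img$truth_mask)
  meas <- dplyr::left_join(res$measurements, mt, by = "label")
  meas <- dplyr::left_join(meas, img$truth_table,
                           by = c(truth_label = "label"),
                           suffix = c("", ".truth"))
  out <- list(cycle = cyc, cells = cells, img = img, res = res, meas = meas)
  .pipeline_cache[[key]] <- out
  out
}

truth_group <- function(phase) {
  ifelse(phase == "G1", "G1", ifelse(phase == "S", "S", "G2M"))
}
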