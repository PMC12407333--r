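#' Cell-cycle phase durations
#'
#' Bundles the four phase durations (hours) plus population-sampling options
#' into a validated parameter object used by the simulator and the kinetic
#' model. The DNA-content schedule implied by these durations is 1 genome
#' equivalent throughout G1, a linear 1 -> 2 ramp across S, and 2 throughout
#' G2 and M.
#'
#' @param t_g1,t_s,t_g2,t_m Phase durations in hours; each must be >= 0, at
#'   most one may be zero, and the total must be positive.
#' @param age_distribution How cycle positions are sampled across a
#'   population: `"uniform"` (every position equally likely) or
#'   `"exponential-growth"` (density proportional to `2^(-tau/total)`, the
#'   age structure of an exponentially growing culture, which over-represents
#'   young cells).
#'
#' @return An object of class `cycle_params`: a list with the four durations,
#'   `total`, and `age_distribution`.
#' @examples
#' cycle_params(t_g1 = 10, t_s = 8, t_g2 = 4, t_m = 1)
#' @export
cycle_params <- function(t_g1, t_s, t_g2, t_m,
                         age_distribution = c("uniform", "exponential-growth")) {
  durs <- c(t_g1 = t_g1, t_s = t_s, t_g2 = t_g2, t_m = t_m)
  if (any(!is.finite(durs)) || any(durs < 0)) {
    abort("All phase durations must be finite and >= 0.")
  }
  if (sum(durs == 0) > 1) {
    abort("At most one phase duration may be zero.")
  }
  total <- sum(durs)
  if (total <= 0) abort("Total cycle length must be positive.")
  structure(
    list(t_g1 = t_g1, t_s = t_s, t_g2 = t_g2, t_m = t_m, total = total,
         age_distribution = match.arg(age_distribution)),
    class = "cycle_params"
  )
}

#' Histone-mark restoration kinetics
#'
#' Parameters of the first-order restoration model: after dilution by DNA
#' replication and cell division, a mark is deposited toward its target
#' density at rate `k_restore`. A "fast" mark (`k_restore * total >> 1`,
#' e.g. H3K4me3-like) tracks DNA content closely; a "slow" mark
#' (`k_restore * total ~ 1`, e.g. H3K27me3-like) lags replication, so its
#' density peaks in late G1 and dips after S.
#'
#' @param mark_name Character label for the mark.
#' @param k_restore Restoration rate per hour (>= 0, finite).
#' @param rho_target Target mark density per genome equivalent (> 0).
#' @return An object of class `mark_kinetics`.
#' @examples
#' mark_kinetics("H3K27me3", k_restore = 0.05, rho_target = 1)
#' @export
mark_kinetics <- function(mark_name, k_restore, rho_target = 1) {
  if (!is.finite(k_restore) || k_restore < 0) {
    abort("`k_restore` must be finite and >= 0.")
  }
  if (!is.finite(rho_target) || rho_target <= 0) {
    abort("`rho_target` must be finite and > 0.")
  }
  structure(
    list(mark_name = as.character(mark_name), k_restore = k_restore,
         rho_target = rho_target),
    class = "mark_kinetics"
  )
}

#' DNA content along the cycle
#'
#' Evaluates the DNA-content schedule c(tau): 1 genome equivalent in G1,
#' linear 1 -> 2 across S, 2 in G2 and M.
#'
#' @param tau Numeric vector of cycle positions in hours, in `[0, total)`.
#' @param cycle A [cycle_params()] object.
#' @return Numeric vector of DNA content in genome equivalents.
#' @export
dna_content <- function(tau, cycle) {
  stopifnot(inherits(cycle, "cycle_params"))
  s_start <- cycle$t_g1
  s_end <- cycle$t_g1 + cycle$t_s
  out <- rep(1, length(tau))
  in_s <- tau >= s_start & tau < s_end
  out[in_s] <- 1 + (tau[in_s] - s_start) / cycle$t_s
  out[tau >= s_end] <- 2
  out
}

#' Phase label along the cycle
#'
#' @param tau Numeric vector of cycle positions in hours.
#' @param cycle A [cycle_params()] object.
#' @return Factor with levels G1, S, G2, M.
#' @export
cycle_phase <- function(tau, cycle) {
  stopifnot(inherits(cycle, "cycle_params"))
  b <- cumsum(c(cycle$t_g1, cycle$t_s, cycle$t_g2))
  ph <- if_else(tau < b[1], "G1",
                if_else(tau < b[2], "S",
                        if_else(tau < b[3], "G2", "M")))
  factor(ph, levels = c("G1", "S", "G2", "M"))
}

# Propagate M through one interval where c(t) is constant (value cc) for
# duration d under dM/dt = k (rho * cc - M). Exact solution.
propagate_const <- function(m0, k, rho, cc, d) {
  if (k == 0) return(m0)
  rho * cc + (m0 - rho * cc) * exp(-k * d)
}

# Propagate M across the S phase where c(t) = 1 + s * (t - t0), s = 1/t_s.
# Exact solution of the linear ODE with linear forcing: the particular
# solution is rho * c(t) - rho * s / k.
propagate_s <- function(m0, k, rho, t_s, dt) {
  if (k == 0) return(m0)
  s <- 1 / t_s
  p0 <- rho * 1 - rho * s / k
  pt <- rho * (1 + s * dt) - rho * s / k
  pt + (m0 - p0) * exp(-k * dt)
}

# Evaluate M(tau) for a vector of tau given M at cycle start.
mark_at_tau <- function(tau, m0, k, rho, cycle) {
  s_start <- cycle$t_g1
  s_end <- cycle$t_g1 + cycle$t_s
  m_s_start <- propagate_const(m0, k, rho, 1, s_start)
  m_s_end <- propagate_s(m_s_start, k, rho, cycle$t_s, cycle$t_s)
  out <- numeric(length(tau))
  g1 <- tau < s_start
  s <- tau >= s_start & tau < s_end
  g2m <- tau >= s_end
  out[g1] <- propagate_const(m0, k, rho, 1, tau[g1])
  out[s] <- propagate_s(m_s_start, k, rho, cycle$t_s, tau[s] - s_start)
  out[g2m] <- propagate_const(m_s_end, k, rho, 2, tau[g2m] - s_end)
  out
}

#' Periodic steady-state mark trajectory over one cell cycle
#'
#' Solves the dilution-restoration model `dM/dt = k_restore * (rho_target *
#' c(tau) - M)` with `c(tau)` the DNA-content schedule, subject to the
#' division condition `M(0) = M(total) / 2` (the mark, like the DNA, is
#' split symmetrically between daughters). The periodic solution is found by
#' iterating whole cycles from an initial guess until successive cycle-start
#' amounts differ by less than `tol`. Within each cycle the linear ODE is
#' propagated analytically segment by segment.
#'
#' The returned density `r(tau) = M(tau) / (rho_target * c(tau))` is the
#' mark-per-DNA profile that an imaging experiment measures after
#' normalizing integrated mark intensity to DNA content.
#'
#' @param cycle A [cycle_params()] object.
#' @param kin A [mark_kinetics()] object.
#' @param tol Convergence tolerance on the cycle-start amount (> 0).
#' @param n_grid Number of evaluation points across the cycle.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return A tibble of class `mark_trajectory` with columns `tau`, `phase`,
#'   `dna`, `mark`, and `density`, plus attributes `mark_name`, `m0`, and
#'   `iterations`.
#' @examples
#' cyc <- cycle_params(10, 8, 4, 1)
#' slow <- steady_state_mark(cyc, mark_kinetics("H3K27me3", 1 / 23))
#' slow$tau[which.max(slow$density)] # late G1
#' @export
steady_state_mark <- function(cycle, kin, tol = 1e-8, n_grid = 512L,
                              max_iter = 200L) {
  stopifnot(inherits(cycle, "cycle_params"), inherits(kin, "mark_kinetics"))
  if (!is.finite(tol) || tol <= 0) abort("`tol` must be > 0.")
  k <- kin$k_restore
  rho <- kin$rho_target
  m0 <- rho # start from fully restored density at 2N
  it <- 0L
  repeat {
    it <- it + 1L
    m_end <- mark_at_tau(cycle$total, m0, k, rho, cycle)
    m0_new <- m_end / 2
    if (abs(m0_new - m0) < tol) {
      m0 <- m0_new
      break
    }
    m0 <- m0_new
    if (it >= max_iter) {
      abort("steady_state_mark did not converge within `max_iter` cycles.")
    }
  }
  tau <- seq(0, cycle$total, length.out = n_grid + 1L)
  tau <- tau[-length(tau)]
  m <- mark_at_tau(tau, m0, k, rho, cycle)
  dna <- dna_content(tau, cycle)
  out <- tibble(
    tau = tau,
    phase = cycle_phase(tau, cycle),
    dna = dna,
    mark = m,
    density = m / (rho * dna)
  )
  structure(out, class = c("mark_trajectory", class(out)),
            mark_name = kin$mark_name, m0 = m0, iterations = it)
}

#' @export
autoplot.mark_trajectory <- function(object, ...) {
  df <- pivot_longer(as_tibble(object)[, c("tau", "mark", "density")],
                     c("mark", "density"),
                     names_to = "quantity", values_to = "value")
  ggplot(df, aes(x = .data$tau, y = .data$value)) +
    geom_line() +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "cycle position (h)", y = NULL,
         title = attr(object, "mark_name")) +
    theme_minimal()
}
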