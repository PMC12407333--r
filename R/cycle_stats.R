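#' Simulate a propidium-iodide DNA-content histogram
#'
#' Draws `n` cells from the stated phase fractions, samples DNA-content
#' fluorescence as a Gaussian at the 2N position (G1), a Gaussian at twice
#' that position (G2/M), or a uniform spread between the two (S phase) with
#' measurement noise proportional to position, and bins the result on a fixed
#' grid.
#'
#' @param fractions Numeric `c(g1, s, g2m)`, nonnegative, summing to 1
#'   within 1e-6.
#' @param n Number of cells (0 gives an empty histogram).
#' @param cv Relative width of the 2N peak.
#' @param seed Integer seed.
#' @param mu_2n Channel position of the 2N peak.
#' @param n_bins Number of histogram bins.
#' @return Tibble with `bin_center` and `count`.
#' @export
simulate_pi_histogram <- function(fractions, n, cv = 0.05, seed = 1,
                                  mu_2n = 50, n_bins = 256L) {
  if (length(fractions) != 3 || any(fractions < 0)) {
    abort("`fractions` must be three nonnegative numbers.")
  }
  if (abs(sum(fractions) - 1) > 1e-6) {
    abort("`fractions` must sum to 1 within 1e-6.")
  }
  breaks <- seq(0, 3 * mu_2n, length.out = n_bins + 1L)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  if (n == 0) return(tibble(bin_center = centers, count = 0L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  phase <- sample(c("g1", "s", "g2m"), n, replace = TRUE, prob = fractions)
  x <- numeric(n)
  ng1 <- sum(phase == "g1"); ns <- sum(phase == "s"); ng2 <- sum(phase == "g2m")
  x[phase == "g1"] <- rnorm(ng1, mu_2n, cv * mu_2n)
  x[phase == "g2m"] <- rnorm(ng2, 2 * mu_2n, 2 * cv * mu_2n)
  if (ns > 0) {
    pos <- runif(ns, mu_2n, 2 * mu_2n)
    x[phase == "s"] <- rnorm(ns, pos, cv * pos)
  }
  x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)])
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                  nbins = n_bins)
  tibble(bin_center = centers, count = cnt)
}

# model densities for the PI mixture fit
.pi_model <- function(centers, mu, cv, w) {
  sig1 <- cv * mu
  sig2 <- 2 * cv * mu
  sig_s <- 1.5 * cv * mu
  g1 <- dnorm(centers, mu, sig1)
  g2 <- dnorm(centers, 2 * mu, sig2)
  s <- (pnorm((centers - mu) / sig_s) - pnorm((centers - 2 * mu) / sig_s)) / mu
  w[1] * g1 + w[2] * s + w[3] * g2
}

#' Fit phase fractions to a DNA-content histogram
#'
#' Deconvolves a propidium-iodide histogram into a G1 Gaussian at the 2N
#' position, a G2/M Gaussian constrained near twice that position, and an
#' S-phase component modelled as a uniform density between the two peaks
#' convolved with the measurement width. Parameters (2N position, relative
#' width, mixing weights) are fitted by least squares with `optim`
#' (L-BFGS-B); mixing weights are parameterized by softmax so fractions are
#' always a valid composition.
#'
#' @param histogram Tibble with `bin_center` and `count`.
#' @return Object of class `pi_fit`: list with `fractions`
#'   (named g1/s/g2m), `mu_2n`, `cv`, `rss`, `converged`, `fitted`
#'   (tibble of bin-wise fitted counts), `histogram`.
#' @export
fit_pi_histogram <- function(histogram) {
  stopifnot(is.data.frame(histogram),
            all(c("bin_center", "count") %in% names(histogram)))
  centers <- histogram$bin_center
  counts <- histogram$count
  total <- sum(counts)
  if (total <= 0) abort("Histogram is empty.")
  bw <- mean(diff(centers))
  mu0 <- centers[which.max(counts)]
  softmax <- function(v) { e <- exp(v - max(v)); e / sum(e) }
  obj <- function(p) {
    mu <- p[1]; cv <- p[2]; w <- softmax(c(p[3], p[4], 0))
    pred <- total * bw * .pi_model(centers, mu, cv, w)
    sum((pred - counts)^2)
  }
  fit <- optim(c(mu0, 0.05, 0, 0), obj, method = "L-BFGS-B",
               lower = c(mu0 * 0.7, 0.005, -12, -12),
               upper = c(mu0 * 1.3, 0.25, 12, 12))
  w <- softmax(c(fit$par[3], fit$par[4], 0))
  if (w[3] < 1e-4) {
    warn("G2/M fraction is ~0; histogram may be unimodal.")
  }
  fitted <- total * bw * .pi_model(centers, fit$par[1], fit$par[2], w)
  structure(
    list(fractions = setNames(w, c("g1", "s", "g2m")),
         mu_2n = fit$par[1], cv = fit$par[2], rss = fit$value,
         converged = fit$convergence == 0,
         fitted = tibble(bin_center = centers, count = counts,
                         fitted = fitted),
         histogram = histogram),
    class = "pi_fit"
  )
}

#' @export
tidy.pi_fit <- function(x, ...) {
  tibble(phase = c("G1", "S", "G2M"), fraction = as.numeric(x$fractions))
}

#' @export
glance.pi_fit <- function(x, ...) {
  tibble(mu_2n = x$mu_2n, cv = x$cv, rss = x$rss, converged = x$converged)
}

#' @export
print.pi_fit <- function(x, ...) {
  cat("PI histogram fit\n")
  cat(sprintf("  2N position: %.2f  (cv %.3f)\n", x$mu_2n, x$cv))
  cat(sprintf("  fractions: G1 %.3f  S %.3f  G2/M %.3f\n",
              x$fractions[1], x$fractions[2], x$fractions[3]))
  invisible(x)
}

#' @export
autoplot.pi_fit <- function(object, ...) {
  ggplot(object$fitted, aes(x = .data$bin_center)) +
    geom_col(aes(y = .data$count), fill = "grey80") +
    geom_line(aes(y = .data$fitted), colour = "red") +
    labs(x = "DNA content (channel)", y = "cells") +
    theme_minimal()
}

#' Gate cells by FUCCI reporter intensities
#'
#' mCherry-positive / mCitrine-negative cells are G1; double positives are
#' early S; mCherry-negative / mCitrine-positive cells are S/G2/M; double
#' negatives are unclassified.
#'
#' @param cells Tibble with `fucci_cherry` and `fucci_citrine` columns.
#' @param cherry_threshold,citrine_threshold Positivity thresholds (> 0).
#' @return `cells` with an added `fucci_gate` factor
#'   (G1, early-S, S-G2-M, unclassified).
#' @export
gate_fucci <- function(cells, cherry_threshold, citrine_threshold) {
  stopifnot(is.data.frame(cells),
            all(c("fucci_cherry", "fucci_citrine") %in% names(cells)))
  if (cherry_threshold <= 0 || citrine_threshold <= 0) {
    abort("Thresholds must be > 0.")
  }
  ch <- cells$fucci_cherry >= cherry_threshold
  ci <- cells$fucci_citrine >= citrine_threshold
  gate <- case_when(
    ch & !ci ~ "G1",
    ch & ci ~ "early-S",
    !ch & ci ~ "S-G2-M",
    TRUE ~ "unclassified"
  )
  cells$fucci_gate <- factor(gate,
                             levels = c("G1", "early-S", "S-G2-M",
                                        "unclassified"))
  cells
}

#' Cell doubling time from two counts
#'
#' `Td = dt * ln(2) / ln(n1 / n0)`. Equal counts give `Inf` with a warning;
#' negative growth gives a negative value flagged by a warning.
#'
#' @param n0,n1 Cell counts (> 0).
#' @param dt Elapsed time in hours (> 0).
#' @return Doubling time in hours.
#' @examples
#' doubling_time(1000, 2000, 24) # 24
#' @export
doubling_time <- function(n0, n1, dt) {
  if (n0 <= 0 || n1 <= 0) abort("Counts must be positive.")
  if (dt <= 0) abort("`dt` must be positive.")
  if (n1 == n0) {
    warn("No growth between observations; doubling time is infinite.")
    return(Inf)
  }
  td <- dt * log(2) / log(n1 / n0)
  if (td < 0) warn("Population shrank; returning a negative doubling time.")
  td
}

#' Absolute phase durations from doubling time and phase fractions
#'
#' Each phase duration is the doubling time multiplied by the corresponding
#' phase fraction, so durations sum exactly to the doubling time.
#'
#' @param td Doubling time in hours (> 0).
#' @param fractions Numeric `c(g1, s, g2m)` summing to 1 within 1e-6, or a
#'   [fit_pi_histogram()] object.
#' @return Tibble with `phase` and `hours`.
#' @export
phase_durations <- function(td, fractions) {
  if (inherits(fractions, "pi_fit")) fractions <- fractions$fractions
  fractions <- as.numeric(fractions)
  if (td <= 0) abort("`td` must be positive.")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-6) {
    abort("`fractions` must be three nonnegative numbers summing to 1.")
  }
  tibble(phase = c("G1", "S", "G2M"), hours = td * fractions)
}
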