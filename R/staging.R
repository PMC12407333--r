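STAGE_LEVELS <- c("G1M", "G1L", "SE", "SML", "G2EM", "G2L", "excluded")

#' Order nuclei along a one-dimensional cell-cycle coordinate
#'
#' Min-max scales the selected features to `[0, 1]`, reduces them to a single
#' coordinate by projecting onto the leading principal axis (the best single
#' line segment through the point cloud — a two-anchor-node reduction), and
#' orients the axis so the coordinate correlates positively with integrated
#' DNA intensity. The returned coordinate is rescaled to `[0, 1]`.
#'
#' Min-max scaling makes the ordering invariant to per-feature rescaling;
#' zero-range features are dropped with a message.
#'
#' @param meas Tibble from [measure_nuclei()] (>= 10 rows).
#' @param features Character vector of feature columns (>= 2 usable).
#' @return `meas` with an added `ordering` column in `[0, 1]`.
#' @export
order_cells <- function(meas, features = c("dna", "area")) {
  stopifnot(is.data.frame(meas))
  if (nrow(meas) < 10) abort("Need at least 10 nuclei to order.")
  missing <- setdiff(features, names(meas))
  if (length(missing)) {
    abort(paste0("Missing feature columns: ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(meas[, features, drop = FALSE])
  rng <- apply(X, 2, function(v) diff(range(v)))
  degenerate <- rng <= 0 | !is.finite(rng)
  if (any(degenerate)) {
    inform(paste0("Dropping zero-range feature(s): ",
                  paste(features[degenerate], collapse = ", ")))
    X <- X[, !degenerate, drop = FALSE]
  }
  if (ncol(X) == 0) abort("All features are degenerate.")
  Xs <- apply(X, 2, function(v) (v - min(v)) / diff(range(v)))
  if (ncol(Xs) == 1) {
    coord <- Xs[, 1]
  } else {
    coord <- prcomp(Xs, center = TRUE, scale. = FALSE)$x[, 1]
  }
  if (!"dna" %in% names(meas)) abort("`meas` must contain a `dna` column.")
  if (cor(coord, meas$dna) < 0) coord <- -coord
  meas$ordering <- (coord - min(coord)) / diff(range(coord))
  meas
}

# Locate the 2N and 4N modes of the integrated-DNA distribution. Returns
# c(m2, m4) or aborts when the distribution is effectively unimodal.
find_dna_modes <- function(dna) {
  d <- density(dna, n = 512)
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1
  if (length(pk) < 2) abort("DNA-intensity distribution is unimodal; cannot stage.")
  # among all peak pairs with roughly a 2x spacing, pick the most massive
  cand <- expand.grid(i = pk, j = pk)
  cand <- cand[d$x[cand$j] / d$x[cand$i] > 1.6 &
                 d$x[cand$j] / d$x[cand$i] < 2.6, , drop = FALSE]
  if (nrow(cand) == 0) abort("No DNA peak pair with ~2x spacing; cannot stage.")
  mass <- y[cand$i] + y[cand$j]
  best <- cand[which.max(mass), ]
  c(m2 = d$x[best$i], m4 = d$x[best$j])
}

#' Assign six cell-cycle stages along the ordering
#'
#' Locates the 2N and 4N modes of integrated DNA intensity, then walks the
#' nuclei in order of the 1-D coordinate: the 2N plateau is G1, the rising
#' flank is S, and the 4N plateau is G2/M. Within regions the ordering is
#' split into the analysis stages: the first G1 tercile (early G1) is
#' excluded, the remaining terciles are G1M and G1L; S is split at its
#' midpoint into SE and SML; the G2/M region is split at two-thirds into G2EM
#' and G2L. When FUCCI columns are supplied with gate thresholds, the gate
#' overrides the DNA-based region (mCherry+/mCitrine- cells can never be
#' assigned to S or G2 stages).
#'
#' @param meas Tibble from [order_cells()] (must contain `ordering`, `dna`).
#' @param flank_frac Fraction of the 2N-4N intensity span used to call the
#'   plateau boundaries (default 0.15).
#' @param smooth_k Running-mean window (odd) used to smooth DNA along the
#'   ordering before boundary detection.
#' @param fucci_thresholds Optional `c(cherry, citrine)` positivity
#'   thresholds; requires `fucci_cherry`/`fucci_citrine` columns.
#' @return `meas` with added columns `region` (G1/S/G2M) and `stage`.
#' @export
assign_stages <- function(meas, flank_frac = 0.15, smooth_k = 15L,
                          fucci_thresholds = NULL) {
  stopifnot(is.data.frame(meas))
  if (!all(c("ordering", "dna") %in% names(meas))) {
    abort("`meas` must contain `ordering` and `dna` (run order_cells first).")
  }
  modes <- find_dna_modes(meas$dna)
  m2 <- modes[["m2"]]; m4 <- modes[["m4"]]
  ord <- order(meas$ordering)
  dna_sorted <- meas$dna[ord]
  k <- min(smooth_k, nrow(meas) - (1 - nrow(meas) %% 2))
  if (k %% 2 == 0) k <- k - 1
  sm <- as.numeric(stats::filter(dna_sorted, rep(1 / k, k), sides = 2))
  # pad the ends of the running mean
  half <- (k - 1) / 2
  if (half > 0) {
    sm[seq_len(half)] <- mean(dna_sorted[seq_len(k)])
    nn <- length(sm)
    sm[(nn - half + 1):nn] <- mean(dna_sorted[(nn - k + 1):nn])
  }
  lo <- m2 + flank_frac * (m4 - m2)
  hi <- m4 - flank_frac * (m4 - m2)
  i_lo <- which(sm > lo)[1]
  i_hi <- which(sm > hi)[1]
  # Extrapolate the flank crossings back to the plateau values: the smoothed
  # DNA rises roughly linearly through S, so the true plateau exits sit
  # (lo - m2) / slope before the lo crossing and (m4 - hi) / slope after the
  # hi crossing.
  if (!is.na(i_lo) && !is.na(i_hi) && i_hi > i_lo) {
    slope <- (hi - lo) / (i_hi - i_lo)
    s_start <- max(1, round(i_lo - (lo - m2) / slope))
    s_end <- min(length(sm) + 1, round(i_hi + (m4 - hi) / slope))
  } else {
    s_start <- if (is.na(i_lo)) length(sm) + 1 else i_lo
    s_end <- if (is.na(i_hi)) length(sm) + 1 else i_hi
  }
  region_sorted <- rep("G1", length(sm))
  if (s_start <= length(sm)) {
    region_sorted[s_start:length(sm)] <- "S"
  }
  if (s_end <= length(sm)) region_sorted[s_end:length(sm)] <- "G2M"
  region <- character(nrow(meas))
  region[ord] <- region_sorted

  if (!is.null(fucci_thresholds)) {
    if (!all(c("fucci_cherry", "fucci_citrine") %in% names(meas))) {
      abort("FUCCI thresholds supplied but FUCCI columns are missing.")
    }
    gates <- gate_fucci(meas, cherry_threshold = fucci_thresholds[1],
                        citrine_threshold = fucci_thresholds[2])$fucci_gate
    region[gates == "G1"] <- "G1"
    region[gates == "early-S" & region == "G2M"] <- "S"
    region[gates == "S-G2-M" & region == "G1"] <- "S"
  }

  # substage by position within each region's ordering span
  stage <- rep("excluded", nrow(meas))
  split_region <- function(which_region, breaks, labels) {
    idx <- which(region == which_region)
    if (!length(idx)) return()
    o <- meas$ordering[idx]
    q <- rank(o, ties.method = "first") / length(o)
    lab <- as.character(cut(q, breaks = breaks, labels = labels,
                            include.lowest = TRUE))
    stage[idx] <<- lab
  }
  split_region("G1", c(0, 1 / 3, 2 / 3, 1), c("excluded", "G1M", "G1L"))
  split_region("S", c(0, 0.5, 1), c("SE", "SML"))
  split_region("G2M", c(0, 2 / 3, 1), c("G2EM", "G2L"))

  meas$region <- factor(region, levels = c("G1", "S", "G2M"))
  meas$stage <- factor(stage, levels = STAGE_LEVELS)
  meas
}

#' Per-stage DNA-normalized mark profile
#'
#' Summarises staged nuclei into the six-stage profile: per-stage cell count,
#' mean integrated mark, mean integrated DNA, mean per-cell mark/DNA ratio,
#' and the ratio normalized by its across-stage mean (so profiles from
#' different conditions compare shape, not absolute staining). The AUC is the
#' trapezoidal integral of the normalized ratio over stage index.
#'
#' @param staged Tibble from [assign_stages()].
#' @param mark Name of the mark (column `mark_<mark>` must exist).
#' @param min_cells Minimum cells per stage; under-filled stages are flagged
#'   (`ok = FALSE`) and excluded from the normalization and the AUC. At least
#'   4 stages must pass.
#' @return Tibble of class `stage_profile`: `stage`, `n`, `mean_mark`,
#'   `mean_dna`, `mean_ratio`, `norm_ratio`, `ok`; attributes `mark`,
#'   `auc` (normalized ratio) and `auc_raw` (raw ratio).
#' @export
stage_profile <- function(staged, mark, min_cells = 20L) {
  col <- paste0("mark_", mark)
  if (!col %in% names(staged)) abort(paste0("Missing column ", col, "."))
  keep <- staged$stage != "excluded" & !is.na(staged$stage)
  df <- staged[keep, , drop = FALSE]
  df$ratio <- df[[col]] / df$dna
  prof <- df |>
    group_by(stage = .data$stage) |>
    summarise(n = dplyr::n(),
              mean_mark = mean(.data[[col]]),
              mean_dna = mean(.data$dna),
              mean_ratio = mean(.data$ratio),
              .groups = "drop")
  all_stages <- tibble(stage = factor(setdiff(STAGE_LEVELS, "excluded"),
                                      levels = STAGE_LEVELS))
  prof <- left_join(all_stages, prof, by = "stage")
  prof$n[is.na(prof$n)] <- 0L
  prof$ok <- prof$n >= min_cells
  if (sum(prof$ok) < 4) {
    abort("Fewer than 4 stages reach `min_cells`; profile not computed.")
  }
  ref <- mean(prof$mean_ratio[prof$ok])
  prof$norm_ratio <- prof$mean_ratio / ref
  auc <- .trapz_unit(prof$norm_ratio[prof$ok])
  auc_raw <- .trapz_unit(prof$mean_ratio[prof$ok])
  structure(prof, class = c("stage_profile", class(prof)),
            mark = mark, auc = auc, auc_raw = auc_raw)
}

.trapz_unit <- function(y) {
  y <- y[!is.na(y)]
  if (length(y) < 2) return(NA_real_)
  sum((y[-1] + y[-length(y)]) / 2)
}

#' Area under a stage profile
#'
#' Trapezoidal integral of the (normalized or raw) mark/DNA ratio over stage
#' index with unit spacing.
#'
#' @param profile A [stage_profile()] object.
#' @param normalized Integrate the mean-normalized ratio (default) or the raw
#'   ratio.
#' @return A scalar.
#' @export
profile_auc <- function(profile, normalized = TRUE) {
  stopifnot(inherits(profile, "stage_profile"))
  y <- if (normalized) profile$norm_ratio else profile$mean_ratio
  y <- y[profile$ok]
  if (sum(!is.na(y)) < 2) abort("Need >= 2 stages with values.")
  .trapz_unit(y)
}

#' Compare two stage profiles on their common support
#'
#' Two conditions with different phase durations retain different stages
#' (a short G1 may leave its G1 stages under `min_cells`), so raw AUCs are
#' not comparable. This helper restricts both profiles to the stages retained
#' in both, renormalizes each mark/DNA ratio by its mean over that common
#' support, and reports the shape summaries on equal footing.
#'
#' @param a,b [stage_profile()] objects for the same mark.
#' @return One-row tibble: `n_common`, `auc_a`, `auc_b`, `range_a`,
#'   `range_b`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "stage_profile"), inherits(b, "stage_profile"))
  common <- intersect(as.character(a$stage[a$ok]), as.character(b$stage[b$ok]))
  if (length(common) < 2) abort("Fewer than 2 common stages.")
  ra <- a$mean_ratio[match(common, as.character(a$stage))]
  rb <- b$mean_ratio[match(common, as.character(b$stage))]
  ra <- ra / mean(ra)
  rb <- rb / mean(rb)
  tibble(n_common = length(common),
         auc_a = .trapz_unit(ra), auc_b = .trapz_unit(rb),
         range_a = diff(range(ra)), range_b = diff(range(rb)))
}

#' @export
tidy.stage_profile <- function(x, ...) {
  as_tibble(x)[, c("stage", "n", "mean_mark", "mean_dna", "mean_ratio",
                   "norm_ratio", "ok")]
}

#' @export
glance.stage_profile <- function(x, ...) {
  tibble(mark = attr(x, "mark"),
         n_stages = sum(x$ok),
         n_cells = sum(x$n),
         auc = attr(x, "auc"),
         auc_raw = attr(x, "auc_raw"),
         ratio_range = diff(range(x$norm_ratio[x$ok])))
}

#' @export
autoplot.stage_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df[df$ok, ], aes(x = .data$stage, y = .data$norm_ratio, group = 1)) +
    geom_line() + geom_point() +
    labs(x = "cell-cycle stage", y = "mark / DNA (normalized)",
         title = attr(object, "mark")) +
    theme_minimal()
}
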