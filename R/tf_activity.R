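#' Construct a TF target set
#'
#' @param tf TF name.
#' @param up,down Character vectors of up- and downregulated target genes;
#'   they must be disjoint and not both empty.
#' @return Object of class `target_set`.
#' @export
target_set <- function(tf, up = character(), down = character()) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down))) abort("`up` and `down` must be disjoint.")
  if (length(up) + length(down) == 0) abort("Target set is empty.")
  structure(list(tf = as.character(tf), up = up, down = down),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set> %s: %d up, %d down\n",
              x$tf, length(x$up), length(x$down)))
  invisible(x)
}

#' Derive a TF target set from a perturbation contrast
#'
#' Compares baseline and factor-overexpression expression (e.g. MEFs vs MEFs
#' with KLF4 alone): genes up by more than `fc_threshold` log2 units are the
#' up targets, genes down by more are the down targets.
#'
#' @param contrast Tibble with columns `gene`, `base`, `perturbed`
#'   (mean log2 expression on a matched gene universe).
#' @param tf TF name for the resulting set.
#' @param fc_threshold Log2 fold-change threshold, default 1.
#' @return A [target_set()].
#' @export
derive_target_set <- function(contrast, tf, fc_threshold = 1) {
  need <- c("gene", "base", "perturbed")
  if (!all(need %in% names(contrast))) {
    abort("`contrast` needs columns gene, base, perturbed.")
  }
  if (anyDuplicated(contrast$gene)) abort("Duplicate gene IDs in contrast.")
  d <- contrast$perturbed - contrast$base
  up <- contrast$gene[d > fc_threshold]
  down <- contrast$gene[-d > fc_threshold]
  if (length(up) + length(down) == 0) {
    return(structure(list(tf = tf, up = character(), down = character()),
                     class = "target_set"))
  }
  target_set(tf, up, down)
}

#' TF activity score of one expression vector
#'
#' Mean log2 expression over the TF's upregulated targets minus the mean over
#' its downregulated targets; an empty side contributes 0. Means (not sums)
#' make the score invariant to target-set size. Genes absent from the vector
#' are ignored; if no target gene is present the score is `NA`.
#'
#' @param expr Named numeric vector of log2 expression.
#' @param ts A [target_set()].
#' @return Scalar score in log2 units (NA if no target present).
#' @examples
#' activity_score(c(g1 = 2, g2 = 4, g3 = 1), target_set("X", c("g1", "g2"), "g3"))
#' @export
activity_score <- function(expr, ts) {
  stopifnot(inherits(ts, "target_set"), !is.null(names(expr)))
  up <- intersect(ts$up, names(expr))
  down <- intersect(ts$down, names(expr))
  if (length(up) + length(down) == 0) return(NA_real_)
  up_m <- if (length(up)) mean(expr[up]) else 0
  down_m <- if (length(down)) mean(expr[down]) else 0
  up_m - down_m
}

# per-cell scores on a wide cell matrix (meta columns + gene columns)
.cell_scores <- function(cells, ts) {
  genes <- setdiff(names(cells),
                   c("cell_id", "pseudotime", "route", "system"))
  up <- intersect(ts$up, genes)
  down <- intersect(ts$down, genes)
  if (length(up) + length(down) == 0) {
    abort("No target gene present in the cell matrix.")
  }
  up_m <- if (length(up)) {
    rowMeans(as.matrix(cells[, up, drop = FALSE]))
  } else 0
  down_m <- if (length(down)) {
    rowMeans(as.matrix(cells[, down, drop = FALSE]))
  } else 0
  up_m - down_m
}

#' TF activity along pseudotime
#'
#' Scores every cell with [activity_score()] semantics, bins cells into
#' equal-occupancy pseudotime bins, and summarises the score per bin
#' (optionally per route). Equal-occupancy bins are used because pseudotime
#' density in single-cell data is uneven. Cells on the non-reprogramming
#' route can be excluded first.
#'
#' @param cells Wide tibble: metadata columns `cell_id`, `pseudotime`, and
#'   optionally `route` and `system`, plus one column per gene (log2).
#' @param ts A [target_set()].
#' @param n_bins Number of pseudotime bins (>= 2).
#' @param by_route Also group by the `route` column.
#' @param exclude_nr Drop cells with `route == "NR"` before binning.
#' @return Tibble with `bin`, (optionally `route`,) `pseudotime` (bin mean),
#'   `mean`, `sd`, `n`, and `low_n` (TRUE when a bin holds < 3 cells).
#' @export
activity_trajectory <- function(cells, ts, n_bins = 10L, by_route = FALSE,
                                exclude_nr = FALSE) {
  stopifnot(is.data.frame(cells), "pseudotime" %in% names(cells))
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  if (exclude_nr) {
    if (!"route" %in% names(cells)) abort("No `route` column to filter on.")
    cells <- cells[cells$route != "NR", , drop = FALSE]
  }
  cells$._score <- .cell_scores(cells, ts)
  cells$bin <- dplyr::ntile(cells$pseudotime, n_bins)
  grp <- if (by_route) c("bin", "route") else "bin"
  out <- cells |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(pseudotime = mean(.data$pseudotime),
              mean = mean(.data$._score),
              sd = sd(.data$._score),
              n = dplyr::n(), .groups = "drop") |>
    mutate(low_n = .data$n < 3)
  if (any(out$low_n)) warn("Some pseudotime bins hold fewer than 3 cells.")
  out
}

#' Classify genes into ChIP-target and non-target groups
#'
#' Genes with higher day-2 mean expression in system A than system B (by more
#' than `fc_threshold` log2 units) are split into Group T (ChIP targets of
#' the enhanced factors) and Group NT (non-targets); all remaining genes are
#' Control. The three groups partition the universe.
#'
#' @param day2 Tibble with columns `gene`, `expr_a`, `expr_b` (mean log2).
#' @param chip_targets Character vector of target genes (may be empty).
#' @param fc_threshold Log2 threshold for "higher", default 0.
#' @return Tibble with `gene` and `group` (factor T/NT/Control).
#' @export
classify_groups <- function(day2, chip_targets, fc_threshold = 0) {
  need <- c("gene", "expr_a", "expr_b")
  if (!all(need %in% names(day2))) {
    abort("`day2` needs columns gene, expr_a, expr_b.")
  }
  if (anyDuplicated(day2$gene)) abort("Duplicate gene IDs.")
  higher <- day2$expr_a - day2$expr_b > fc_threshold
  grp <- case_when(
    higher & day2$gene %in% chip_targets ~ "T",
    higher ~ "NT",
    TRUE ~ "Control"
  )
  tibble(gene = day2$gene, group = factor(grp, levels = c("T", "NT", "Control")))
}

# round half-up to `digits` decimals (matches the printed-percentage style)
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Fraction of genes per group with higher expression
#'
#' For each gene group, counts the flagged genes and reports the percentage
#' `100 * n_higher / n_total` rounded half-up to two decimals (the convention
#' behind printed values such as 20.04% = 335/1672).
#'
#' @param flags Tibble with columns `gene` and `higher` (logical).
#' @param groups Tibble with columns `gene` and `group`, covering all flagged
#'   genes.
#' @return Tibble with `group`, `n_higher`, `n_total`, `percentage`
#'   (NA for empty groups).
#' @export
group_fraction_higher <- function(flags, groups) {
  stopifnot(all(c("gene", "higher") %in% names(flags)),
            all(c("gene", "group") %in% names(groups)))
  if (!all(flags$gene %in% groups$gene)) {
    abort("`groups` must cover every flagged gene.")
  }
  df <- left_join(groups, flags, by = "gene")
  df$higher[is.na(df$higher)] <- FALSE
  df |>
    group_by(group = .data$group, .drop = FALSE) |>
    summarise(n_higher = sum(.data$higher), n_total = dplyr::n(),
              .groups = "drop") |>
    mutate(percentage = if_else(
      .data$n_total > 0,
      round_half_up(100 * .data$n_higher / .data$n_total, 2),
      NA_real_))
}

#' Reprogramming-favorability call for differentially expressed genes
#'
#' A gene with higher expression in the enhanced system favors reprogramming
#' when ESCs express it above the day-2 baseline (its induction points toward
#' the pluripotent state); a lower-expressed gene favors reprogramming when
#' ESCs express it below baseline. The pre-iPSC vs ESC contrast is reported
#' as a supporting annotation.
#'
#' @param genes Tibble with columns `gene`, `direction` (`"higher"` or
#'   `"lower"` in the enhanced system), `day2` (baseline-system day-2 mean),
#'   `ESC`, and optionally `pre_iPSC` and `MEF` means (log2).
#' @param threshold Log2 margin for a non-neutral call, default 0.
#' @return `genes` with added `call` (favors/disfavors/neutral) and, when
#'   `pre_iPSC` is present, `pre_ipsc_below_esc`.
#' @export
favorability_call <- function(genes, threshold = 0) {
  need <- c("gene", "direction", "day2", "ESC")
  if (!all(need %in% names(genes))) {
    abort("`genes` needs columns gene, direction, day2, ESC.")
  }
  if (any(!is.finite(genes$ESC))) abort("Missing ESC values.")
  d <- genes$ESC - genes$day2
  call <- case_when(
    abs(d) <= threshold ~ "neutral",
    genes$direction == "higher" & d > threshold ~ "favors",
    genes$direction == "higher" ~ "disfavors",
    genes$direction == "lower" & d < -threshold ~ "favors",
    TRUE ~ "disfavors"
  )
  genes$call <- factor(call, levels = c("favors", "disfavors", "neutral"))
  if ("pre_iPSC" %in% names(genes)) {
    genes$pre_ipsc_below_esc <- genes$pre_iPSC < genes$ESC
  }
  genes
}
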