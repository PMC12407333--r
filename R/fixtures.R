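#' Simulate four-state expression with planted barrier classes
#'
#' Generates a gene x (MEF, pre_iPSC, iPSC, ESC) log2 matrix containing
#' `n_per_class` genes of each barrier class plus `n_none` unstructured
#' genes. Each planted gene has a baseline drawn per gene and the class
#' pattern applied at the stated effect size before adding Gaussian noise.
#'
#' @param n_per_class Genes per planted class.
#' @param n_none Genes with no planted structure.
#' @param effect Planted effect size in log2 units (default 3).
#' @param noise_sd Gaussian noise SD in log2 units.
#' @param seed Integer seed.
#' @return List with `expr` (tibble gene, MEF, pre_iPSC, iPSC, ESC) and
#'   `truth` (tibble gene, class).
#' @export
simulate_state_expression <- function(n_per_class = 50L, n_none = 200L,
                                      effect = 3, noise_sd = 0, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (effect > 0 && noise_sd > 0 && effect < noise_sd) {
    warn("Planted effect size is below the noise floor; recovery will fail.")
  }
  classes <- c("over_up", "insufficient_up", "over_down", "insufficient_down")
  n_total <- 4L * n_per_class + n_none
  gene <- sprintf("g%05d", seq_len(n_total))
  truth <- c(rep(classes, each = n_per_class), rep("none", n_none))
  base <- runif(n_total, 4, 8)
  m <- matrix(base, n_total, 4)
  colnames(m) <- c("MEF", "pre_iPSC", "iPSC", "ESC")
  idx <- function(cl) which(truth == cl)
  m[idx("over_up"), "pre_iPSC"] <- base[idx("over_up")] + effect
  m[idx("insufficient_up"), c("iPSC", "ESC")] <-
    base[idx("insufficient_up")] + effect
  m[idx("over_down"), "pre_iPSC"] <- base[idx("over_down")] - effect
  m[idx("insufficient_down"), c("MEF", "pre_iPSC")] <-
    base[idx("insufficient_down")] + effect
  if (noise_sd > 0) m <- m + matrix(rnorm(length(m), 0, noise_sd), nrow(m))
  list(
    expr = as_tibble(cbind(tibble(gene = gene), as.data.frame(m))),
    truth = tibble(gene = gene, class = truth)
  )
}

#' Simulate two-system single-cell matrices with planted TF-target effects
#'
#' Builds per-cell log2 expression for two reprogramming systems over a
#' shared pseudotime grid. Each TF receives `n_up` upregulated and `n_down`
#' downregulated target genes whose expression changes linearly with
#' pseudotime at the planted slope (positive for up targets, negative for
#' down targets); slopes can differ between systems and between the
#' reprogramming and non-reprogramming (NR) routes. Remaining genes are flat
#' noise.
#'
#' @param n_cells Cells per system.
#' @param tfs Character vector of TF names.
#' @param n_up,n_down Target genes per TF and direction.
#' @param n_background Untargeted genes.
#' @param slope Planted expression change per unit pseudotime (log2).
#' @param slope_b Slope multiplier for system B (default 1.5: enhanced
#'   activity).
#' @param nr_frac Fraction of cells assigned to the NR route.
#' @param nr_slope_factor Slope multiplier on the NR route (applied to the
#'   last TF in `tfs`, mimicking a KLF4-driven NR branch).
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return List with `cells_a`, `cells_b` (wide tibbles: cell_id, pseudotime,
#'   route, system, gene columns) and `target_sets` (named list of
#'   [target_set()]).
#' @export
simulate_pseudotime_cells <- function(n_cells = 300L,
                                      tfs = c("OCT4", "SOX2", "KLF4"),
                                      n_up = 20L, n_down = 20L,
                                      n_background = 100L,
                                      slope = 2, slope_b = 1.5,
                                      nr_frac = 0.2, nr_slope_factor = 2,
                                      noise_sd = 0.3, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  target_sets <- list()
  gene_names <- character()
  for (tf in tfs) {
    up <- sprintf("%s_up_%02d", tf, seq_len(n_up))
    down <- sprintf("%s_dn_%02d", tf, seq_len(n_down))
    target_sets[[tf]] <- target_set(tf, up, down)
    gene_names <- c(gene_names, up, down)
  }
  bg <- sprintf("bg_%03d", seq_len(n_background))
  gene_names <- c(gene_names, bg)

  make_system <- function(sys, slope_mult) {
    pt <- sort(runif(n_cells))
    route <- sample(c("reprogramming", "NR"), n_cells, TRUE,
                    prob = c(1 - nr_frac, nr_frac))
    m <- matrix(rnorm(n_cells * length(gene_names), 5, noise_sd),
                n_cells, length(gene_names))
    colnames(m) <- gene_names
    nr_tf <- tfs[length(tfs)]
    for (tf in tfs) {
      s <- slope * slope_mult
      route_mult <- rep(1, n_cells)
      if (tf == nr_tf) {
        # the NR-route branch responds more strongly to the last factor
        route_mult[route == "NR"] <- nr_slope_factor
      }
      ts <- target_sets[[tf]]
      m[, ts$up] <- m[, ts$up] + s * route_mult * pt
      m[, ts$down] <- m[, ts$down] - s * route_mult * pt
    }
    bind_cols(
      tibble(cell_id = sprintf("%s_c%04d", sys, seq_len(n_cells)),
             pseudotime = pt, route = route, system = sys),
      as_tibble(as.data.frame(m))
    )
  }
  list(
    cells_a = make_system("A", 1),
    cells_b = make_system("B", slope_b),
    target_sets = target_sets
  )
}

#' Simulate paired expression trajectories with controlled similarity
#'
#' Emits, for each gene, a binned trajectory in two systems: a shared smooth
#' base shape plus a per-gene divergence term of controlled magnitude, so the
#' expected DTW distance and trend correlation between the pair are tunable.
#'
#' @param n_genes Number of genes.
#' @param n_bins Bins per trajectory (>= 3).
#' @param divergence Per-gene divergence scale; genes are assigned
#'   alternating low (similar pair) and `divergence` (dissimilar) scales when
#'   `n_dissimilar > 0`.
#' @param n_dissimilar Number of genes given the large divergence.
#' @param amplitude Base trajectory amplitude (log2 units).
#' @param noise_sd Additive noise SD per bin.
#' @param seed Integer seed.
#' @return List with `traj_a`, `traj_b` (tibbles gene, bin_1..bin_k) and
#'   `truth` (tibble gene, dissimilar).
#' @export
simulate_trajectory_pairs <- function(n_genes = 60L, n_bins = 20L,
                                      divergence = 3, n_dissimilar = 15L,
                                      amplitude = 4, noise_sd = 0.2,
                                      seed = 1) {
  stopifnot(n_bins >= 3, n_dissimilar <= n_genes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  t <- seq(0, 1, length.out = n_bins)
  genes <- sprintf("traj%03d", seq_len(n_genes))
  dissimilar <- c(rep(TRUE, n_dissimilar), rep(FALSE, n_genes - n_dissimilar))
  make <- function(g) {
    phase <- runif(1, 0, pi)
    base <- amplitude * sin(pi * t + phase) + 6
    div <- if (dissimilar[g]) divergence else 0
    shift <- div * cos(2 * pi * t + runif(1, 0, pi))
    a <- base + rnorm(n_bins, 0, noise_sd)
    b <- base + shift + rnorm(n_bins, 0, noise_sd)
    list(a = a, b = b)
  }
  pairs <- lapply(seq_len(n_genes), make)
  to_tbl <- function(which) {
    m <- do.call(rbind, lapply(pairs, `[[`, which))
    colnames(m) <- sprintf("bin_%d", seq_len(n_bins))
    bind_cols(tibble(gene = genes), as_tibble(as.data.frame(m)))
  }
  list(traj_a = to_tbl("a"), traj_b = to_tbl("b"),
       truth = tibble(gene = genes, dissimilar = dissimilar))
}

#' Generate the full expression fixture bundle
#'
#' Convenience wrapper producing the three expression-side fixtures with one
#' seed: the four-state barrier matrix, the two-system pseudotime matrices
#' with planted TF-target effects, and the paired trajectory sets.
#'
#' @param config Optional list overriding defaults of the three generators
#'   (`states`, `cells`, `trajectories` sublists of arguments).
#' @param seed Integer seed.
#' @return List with `states`, `cells`, `trajectories`.
#' @export
make_expression_fixture <- function(config = list(), seed = 1) {
  states <- do.call(simulate_state_expression,
                    c(config$states, list(seed = seed)))
  cells <- do.call(simulate_pseudotime_cells,
                   c(config$cells, list(seed = seed + 1)))
  traj <- do.call(simulate_trajectory_pairs,
                  c(config$trajectories, list(seed = seed + 2)))
  list(states = states, cells = cells, trajectories = traj)
}
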