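#' Count colonies in a plate image
#'
#' Reproduces the classic threshold/size particle rule: the image is rescaled
#' to the 8-bit range `[0, 255]` (min-max), binarized at the threshold,
#' labelled with 8-connected components, and components with area at or above
#' `min_size` pixels are counted.
#'
#' @param img Numeric matrix (single channel).
#' @param threshold Threshold as a fraction of the 8-bit range, default
#'   `60/255`.
#' @param min_size Minimum particle area in pixels, default 550.
#' @param connectivity 4 or 8 (default 8, the usual particle-analysis
#'   behavior).
#' @return Integer colony count (blank image gives 0).
#' @export
count_colonies <- function(img, threshold = 60 / 255, min_size = 550,
                           connectivity = 8L) {
  stopifnot(is.matrix(img))
  rng <- range(img)
  if (diff(rng) == 0) return(0L)
  img8 <- (img - rng[1]) / diff(rng) * 255
  mask <- img8 >= threshold * 255
  if (!any(mask)) return(0L)
  lab <- .label_components(mask, as.integer(connectivity))
  areas <- tabulate(lab[lab > 0])
  sum(areas >= min_size)
}

#' Normalize colony counts to the negative control
#'
#' Reprogramming efficiency per gene = mean colony count across replicates
#' divided by the control's mean count.
#'
#' @param counts Long tibble with columns `gene` and `count` (one row per
#'   replicate well).
#' @param control Gene ID of the negative control (default `"siNC"`), which
#'   must be present with a positive mean count.
#' @return Tibble with `gene`, `mean_count`, `n_rep`, `efficiency`.
#' @export
normalize_counts <- function(counts, control = "siNC") {
  stopifnot(is.data.frame(counts),
            all(c("gene", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("Counts must be >= 0.")
  ctrl <- counts$count[counts$gene == control]
  if (length(ctrl) == 0) abort("Control gene not found.")
  ctrl_mean <- mean(ctrl)
  if (ctrl_mean <= 0) abort("Control mean count must be > 0.")
  counts |>
    group_by(gene = .data$gene) |>
    summarise(mean_count = mean(.data$count), n_rep = dplyr::n(),
              .groups = "drop") |>
    mutate(efficiency = .data$mean_count / ctrl_mean)
}

#' Two-class hit classification of a screen
#'
#' Class 1: knockdown inhibits reprogramming (efficiency below `1 - delta`)
#' and the gene is upregulated during reprogramming — candidate positive
#' drivers. Class 2: knockdown promotes reprogramming (efficiency above
#' `1 + delta`) and the gene is downregulated — candidate brakes. All other
#' records are `none`; the classes are mutually exclusive by construction.
#' Class-1 genes that are also higher-expressed in the enhanced system are
#' additionally flagged (`enhanced_candidate`).
#'
#' @param screen Tibble with columns `gene`, `efficiency`, `trend`
#'   (`up`/`down`/`flat`), and optionally `diff_flag`
#'   (`higher`/`lower`/`ns` in the enhanced-vs-baseline comparison).
#' @param delta Effect threshold on normalized efficiency, default 0.3.
#' @return `screen` with added `hit_class` (class1/class2/none) and
#'   `enhanced_candidate` columns.
#' @export
classify_hits <- function(screen, delta = 0.3) {
  need <- c("gene", "efficiency", "trend")
  if (!all(need %in% names(screen))) {
    abort("`screen` needs columns gene, efficiency, trend.")
  }
  if (any(is.na(screen$trend))) abort("Missing expression trend.")
  cls <- case_when(
    screen$efficiency < 1 - delta & screen$trend == "up" ~ "class1",
    screen$efficiency > 1 + delta & screen$trend == "down" ~ "class2",
    TRUE ~ "none"
  )
  screen$hit_class <- factor(cls, levels = c("class1", "class2", "none"))
  screen$enhanced_candidate <- if ("diff_flag" %in% names(screen)) {
    screen$hit_class == "class1" & screen$diff_flag == "higher"
  } else {
    NA
  }
  screen
}

#' Stage-restricted efficiency matrix with consistency scores
#'
#' Given per-gene normalized efficiencies for the whole-stage treatment and
#' for single-stage (early/mid/late) treatments, computes per gene the
#' fraction of single-stage treatments whose direction of effect (above or
#' below control) agrees with the whole-stage direction.
#'
#' @param efficiencies Tibble with columns `gene`, `stage` (one of `whole`,
#'   `early`, `mid`, `late`), `efficiency`.
#' @return Wide tibble (gene, whole, early, mid, late, consistency);
#'   consistency is NA (flagged) when no single-stage column is available.
#' @export
stage_matrix <- function(efficiencies) {
  stopifnot(is.data.frame(efficiencies),
            all(c("gene", "stage", "efficiency") %in% names(efficiencies)))
  if (!"whole" %in% efficiencies$stage) {
    abort("The whole-stage column is required.")
  }
  wide <- pivot_wider(efficiencies, names_from = "stage",
                      values_from = "efficiency")
  single <- intersect(c("early", "mid", "late"), names(wide))
  wide$consistency <- vapply(seq_len(nrow(wide)), function(i) {
    w <- sign(wide$whole[i] - 1)
    vals <- unlist(wide[i, single])
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0 || w == 0) return(NA_real_)
    mean(sign(vals - 1) == w)
  }, numeric(1))
  if (any(is.na(wide$consistency))) {
    warn("Consistency undefined for some genes (no single-stage data).")
  }
  wide
}

#' Simulate a colony-plate image
#'
#' Draws bright disks of the given pixel area on a dim background with mild
#' Gaussian noise; ground truth is the number of disks at or above the size
#' filter.
#'
#' @param n_colonies Number of colonies.
#' @param shape Image dimensions.
#' @param colony_area Area per colony in pixels (scalar or vector).
#' @param intensity Colony intensity; background is `background`.
#' @param background Background level.
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return List with `image` (matrix) and `truth` (tibble of centers/areas).
#' @export
simulate_colony_plate <- function(n_colonies, shape = c(512L, 512L),
                                  colony_area = 600, intensity = 200,
                                  background = 10, noise_sd = 2, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  img <- matrix(background, nr, nc)
  area <- rep_len(colony_area, max(n_colonies, 1))
  radius <- sqrt(area / pi)
  truth <- list()
  if (n_colonies > 0) {
    rmax <- ceiling(max(radius))
    spacing <- 2 * (rmax + 3)
    gr <- seq(rmax + 4, nr - rmax - 4, by = spacing)
    gc <- seq(rmax + 4, nc - rmax - 4, by = spacing)
    slots <- expand.grid(row = gr, col = gc)
    if (nrow(slots) < n_colonies) abort("Too many colonies for the plate.")
    pick <- slots[sample.int(nrow(slots), n_colonies), , drop = FALSE]
    for (i in seq_len(n_colonies)) {
      r <- radius[i]
      rr <- seq(-ceiling(r), ceiling(r))
      g <- expand.grid(dr = rr, dc = rr)
      g <- g[g$dr^2 + g$dc^2 <= r^2, ]
      img[cbind(pick$row[i] + g$dr, pick$col[i] + g$dc)] <- intensity
      truth[[i]] <- tibble(colony = i, row = pick$row[i], col = pick$col[i],
                           area = nrow(g))
    }
  }
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  }
  list(image = pmax(img, 0), truth = bind_rows(truth))
}

#' Simulate an siRNA screen with planted hits
#'
#' Generates replicate colony counts for a gene panel (default 112 genes, the
#' size of the KEGG cell-cycle pathway panel) with Poisson count noise, a
#' control at efficiency 1, planted class-1 hits (knockdown inhibits, trend
#' up) and class-2 hits (knockdown promotes, trend down).
#'
#' @param n_genes Panel size (default 112).
#' @param n_class1,n_class2 Planted hit counts.
#' @param reps Replicates per gene.
#' @param control_mean Mean control colony count. The default 120 keeps the
#'   Poisson noise of a null gene's normalized efficiency (sd about
#'   `sqrt(2 / (reps * control_mean))`) a 4-sigma margin away from the 0.3
#'   hit threshold, so planted effects dominate counting noise.
#' @param eff_class1,eff_class2 Planted normalized efficiencies.
#' @param seed Integer seed.
#' @return List with `counts` (long tibble incl. the `siNC` control),
#'   `trends` (tibble gene/trend/diff_flag), and `truth` (tibble
#'   gene/hit_class).
#' @export
simulate_screen <- function(n_genes = 112L, n_class1 = 10L, n_class2 = 5L,
                            reps = 3L, control_mean = 120,
                            eff_class1 = 0.4, eff_class2 = 1.7, seed = 1) {
  stopifnot(n_class1 + n_class2 <= n_genes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  truth <- rep("none", n_genes)
  truth[seq_len(n_class1)] <- "class1"
  truth[n_class1 + seq_len(n_class2)] <- "class2"
  eff <- ifelse(truth == "class1", eff_class1,
                ifelse(truth == "class2", eff_class2, 1))
  trend <- ifelse(truth == "class1", "up",
                  ifelse(truth == "class2", "down",
                         sample(c("up", "down", "flat"), n_genes, TRUE)))
  diff_flag <- ifelse(truth == "class1",
                      sample(c("higher", "ns"), n_genes, TRUE),
                      sample(c("higher", "lower", "ns"), n_genes, TRUE))
  counts <- bind_rows(
    tibble(gene = rep(genes, each = reps),
           count = rpois(n_genes * reps, rep(eff * control_mean, each = reps))),
    tibble(gene = "siNC", count = rpois(reps, control_mean))
  )
  list(counts = counts,
       trends = tibble(gene = genes, trend = trend, diff_flag = diff_flag),
       truth = tibble(gene = genes, hit_class = truth))
}
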