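#' Render a multi-channel nucleus image from simulated cells
#'
#' Paints one elliptical nucleus per cell record onto a DNA channel and one
#' channel per mark, then corrupts the field with an additive low-order
#' polynomial illumination gradient and Poisson-Gaussian noise, mimicking a
#' wide-field fluorescence acquisition. Per-nucleus integrated signal in each
#' channel is proportional to the generating quantity (DNA content or mark
#' amount), so segmentation + integrated-intensity measurement can recover
#' the truth. Nucleus area grows linearly with cycle position, as nuclei do
#' between divisions.
#'
#' Placement uses a jittered grid with spacing `2 * (r_max + 2)`, which
#' guarantees non-overlap; if the grid cannot hold all nuclei the call fails.
#'
#' @param cells Tibble of cell records from [simulate_population()].
#' @param shape Image dimensions `c(rows, cols)` in pixels.
#' @param brightness Integrated DNA-channel counts per genome equivalent.
#'   Mark channels use the same constant per unit mark amount.
#' @param r0 Base nucleus radius (pixels) at cycle start; radius grows as
#'   `sqrt(1 + tau/total)` so area is linear in cycle position.
#' @param cycle The [cycle_params()] used to generate `cells` (for `total`).
#' @param illumination Polynomial coefficients of the additive background
#'   `b0 + b1*x + b2*y + b3*x*y + b4*x^2 + b5*y^2` with x, y in `[0, 1]`;
#'   units are counts.
#' @param gain Photons per count for Poisson shot noise; `0` disables it.
#' @param read_sd Gaussian read-noise standard deviation in counts.
#' @param seed Integer seed controlling placement and noise.
#' @param quantize Round to integers and clip to the 16-bit range.
#' @return A list of class `image_fixture`: `channels` (named list of
#'   matrices: `dna` plus one per mark), `truth_mask` (integer label matrix,
#'   labels 1..N), `truth_table` (cells plus `label`, `row`, `col`,
#'   `radius`), and `illumination_field`.
#' @export
render_image <- function(cells, shape = c(512L, 512L), brightness = 2e5,
                         r0 = 6, cycle = NULL,
                         illumination = c(100, 80, 60, 0, 0, 0),
                         gain = 1, read_sd = 2, seed = 1,
                         quantize = TRUE) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1)
  n <- nrow(cells)
  nr <- shape[1]; nc <- shape[2]
  total <- if (!is.null(cycle)) cycle$total else max(cells$tau) * 1.01
  radius <- r0 * sqrt(1 + cells$tau / total)
  r_max <- ceiling(max(radius))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # jittered-grid placement: guaranteed non-overlapping
  spacing <- 2 * (r_max + 2)
  margin <- r_max + 2
  gr <- seq(margin + 1, nr - margin, by = spacing)
  gc <- seq(margin + 1, nc - margin, by = spacing)
  slots <- expand.grid(row = gr, col = gc)
  if (nrow(slots) < n) {
    abort(sprintf(
      "Cannot place %d nuclei of radius %d in a %dx%d image without overlap.",
      n, r_max, nr, nc))
  }
  idx <- sample.int(nrow(slots), n)
  centers <- slots[idx, , drop = FALSE]
  jit <- 2
  centers$row <- centers$row + round(runif(n, -jit, jit))
  centers$col <- centers$col + round(runif(n, -jit, jit))

  mark_cols <- grep("^mark_", names(cells), value = TRUE)
  chan_names <- c("dna", sub("^mark_", "", mark_cols))
  channels <- setNames(lapply(chan_names, function(x) matrix(0, nr, nc)),
                       chan_names)
  truth_mask <- matrix(0L, nr, nc)

  for (i in seq_len(n)) {
    a <- radius[i]
    b <- radius[i] * runif(1, 0.8, 1)
    theta <- runif(1, 0, pi)
    rr <- seq(-ceiling(a), ceiling(a))
    box_r <- centers$row[i] + rr
    box_c <- centers$col[i] + rr
    gridm <- expand.grid(r = box_r, c = box_c)
    dx <- gridm$r - centers$row[i]
    dy <- gridm$c - centers$col[i]
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    px <- gridm[inside, , drop = FALSE]
    area <- nrow(px)
    lin <- cbind(px$r, px$c)
    truth_mask[lin] <- i
    channels$dna[lin] <- channels$dna[lin] + brightness * cells$dna[i] / area
    for (mcol in mark_cols) {
      cn <- sub("^mark_", "", mcol)
      channels[[cn]][lin] <- channels[[cn]][lin] +
        brightness * cells[[mcol]][i] / area
    }
  }

  # additive polynomial illumination on the unit square
  x <- matrix(rep((seq_len(nc) - 1) / (nc - 1), each = nr), nr, nc)
  y <- matrix(rep((seq_len(nr) - 1) / (nr - 1), nc), nr, nc)
  il <- illumination
  field <- il[1] + il[2] * x + il[3] * y + il[4] * x * y +
    il[5] * x^2 + il[6] * y^2

  for (cn in names(channels)) {
    img <- channels[[cn]] + field
    if (gain > 0) img <- rpois(length(img), pmax(img, 0) / gain) * gain
    if (read_sd > 0) img <- img + rnorm(length(img), 0, read_sd)
    img <- matrix(img, nr, nc)
    if (quantize) img <- pmin(pmax(round(img), 0), 65535)
    channels[[cn]] <- img
  }

  truth <- cells
  truth$label <- seq_len(n)
  truth$row <- centers$row
  truth$col <- centers$col
  truth$radius <- radius

  structure(
    list(channels = channels, truth_mask = truth_mask,
         truth_table = as_tibble(truth), illumination_field = field),
    class = "image_fixture"
  )
}
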