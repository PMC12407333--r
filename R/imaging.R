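#' Correct uneven illumination by block-minimum polynomial fitting
#'
#' Divides the image into blocks, takes the minimum pixel intensity of each
#' block as a local background estimate (the minimum is robust to sparse
#' bright nuclei), fits a 2-D polynomial surface to the block minima by least
#' squares, subtracts the fitted surface, and clips at zero.
#'
#' @param img Numeric matrix.
#' @param block_size Block edge length in pixels (>= 8).
#' @param poly_order Polynomial order of the fitted surface (1..4).
#' @return Corrected numeric matrix of the same shape, with the fitted
#'   surface attached as attribute `"background"`.
#' @export
correct_illumination <- function(img, block_size = 64L, poly_order = 2L) {
  stopifnot(is.matrix(img))
  if (block_size < 8) abort("`block_size` must be >= 8.")
  if (!poly_order %in% 1:4) abort("`poly_order` must be in 1..4.")
  nr <- nrow(img); nc <- ncol(img)
  if (nr < block_size || nc < block_size) {
    abort("Image is smaller than a single block.")
  }
  rb <- unique(c(seq(1, nr, by = block_size), nr + 1))
  cb <- unique(c(seq(1, nc, by = block_size), nc + 1))
  mins <- list()
  k <- 0
  for (i in seq_len(length(rb) - 1)) {
    for (j in seq_len(length(cb) - 1)) {
      k <- k + 1
      block <- img[rb[i]:(rb[i + 1] - 1), cb[j]:(cb[j + 1] - 1)]
      # anchor the estimate at the location of the minimum, not the block
      # center: on a tilted background the block minimum sits at the block
      # edge, and fitting it at the center would bias the surface low
      idx <- which.min(block)
      mins[[k]] <- c(
        r = rb[i] + ((idx - 1) %% nrow(block)),
        c = cb[j] + ((idx - 1) %/% nrow(block)),
        v = block[idx]
      )
    }
  }
  pts <- do.call(rbind, mins)
  # scale coordinates to [0,1] for a well-conditioned design matrix
  design <- function(r, c) {
    x <- (c - 1) / (nc - 1)
    y <- (r - 1) / (nr - 1)
    cols <- list(rep(1, length(x)))
    for (d in seq_len(poly_order)) {
      for (px in 0:d) {
        cols[[length(cols) + 1]] <- x^px * y^(d - px)
      }
    }
    do.call(cbind, cols)
  }
  X <- design(pts[, "r"], pts[, "c"])
  beta <- qr.coef(qr(X), pts[, "v"])
  beta[is.na(beta)] <- 0
  full_r <- matrix(rep(seq_len(nr), nc), nr, nc)
  full_c <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  bg <- matrix(design(as.vector(full_r), as.vector(full_c)) %*% beta, nr, nc)
  out <- pmax(img - bg, 0)
  attr(out, "background") <- bg
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background by grayscale morphology with a ball
#' structuring element of the given radius (non-flat erosion then dilation —
#' the classic "rolling ball" of image-processing practice), subtracts it,
#' and clips at zero. Features narrower than the ball survive; slowly varying
#' background is removed.
#'
#' For speed, the morphology can run on a block-mean downsampled copy with a
#' proportionally smaller ball, the estimated background being bilinearly
#' upsampled afterwards (the standard shrink optimization of rolling-ball
#' implementations). The default shrink factor keeps the effective ball
#' radius near 10 pixels.
#'
#' @param img Numeric matrix.
#' @param radius Ball radius in pixels (>= 1, less than the image extent).
#' @param shrink Integer downsampling factor; `NULL` picks
#'   `max(1, floor(radius / 10))`.
#' @return Corrected matrix with the background as attribute `"background"`.
#' @export
rolling_ball_subtract <- function(img, radius = 25, shrink = NULL) {
  stopifnot(is.matrix(img))
  if (radius < 1) abort("`radius` must be >= 1.")
  if (2 * radius + 1 > min(dim(img))) {
    abort("`radius` exceeds the image extent.")
  }
  shrink <- shrink %||% max(1L, floor(radius / 10))
  if (shrink > 1) {
    small <- .block_reduce(img, shrink)
    bg_small <- .rolling_ball_background(small, radius / shrink)
    bg <- .bilinear_upsample(bg_small, nrow(img), ncol(img), shrink)
  } else {
    bg <- .rolling_ball_background(img, radius)
  }
  out <- pmax(img - bg, 0)
  attr(out, "background") <- bg
  out
}

# block-min reduction by integer factor (min, not mean, so sparse bright
# objects cannot lift the background estimate)
.block_reduce <- function(img, f) {
  nr <- floor(nrow(img) / f) * f
  nc <- floor(ncol(img) / f) * f
  x <- img[seq_len(nr), seq_len(nc)]
  a <- array(x, dim = c(f, nr / f, f, nc / f))
  apply(a, c(2, 4), min)
}

# bilinear upsampling of a reduced grid back to the full frame; grid points
# sit at block centers
.bilinear_upsample <- function(small, nr, nc, f) {
  sr <- nrow(small); sc <- ncol(small)
  # source coordinates of each output pixel on the small grid
  rr <- pmin(pmax((seq_len(nr) - 0.5) / f + 0.5, 1), sr)
  cc <- pmin(pmax((seq_len(nc) - 0.5) / f + 0.5, 1), sc)
  r0 <- pmin(floor(rr), sr - 1); r1 <- r0 + 1; wr <- rr - r0
  c0 <- pmin(floor(cc), sc - 1); c1 <- c0 + 1; wc <- cc - c0
  if (sr == 1) { r0 <- r1 <- rep(1, nr); wr <- rep(0, nr) }
  if (sc == 1) { c0 <- c1 <- rep(1, nc); wc <- rep(0, nc) }
  top <- small[r0, c0, drop = FALSE] * (1 - wr) + small[r1, c0, drop = FALSE] * wr
  bot <- small[r0, c1, drop = FALSE] * (1 - wr) + small[r1, c1, drop = FALSE] * wr
  top * rep(1 - wc, each = nr) + bot * rep(wc, each = nr)
}

#' Segment nuclei from a preprocessed DNA-channel image
#'
#' Global Otsu threshold, hole filling, and a distance-transform watershed to
#' split touching objects, followed by an area filter. This classical
#' segmenter is deliberately pluggable: everything downstream consumes only
#' the label mask, so a learned segmenter can be substituted.
#'
#' @param img Numeric matrix (illumination- and background-corrected).
#' @param min_area,max_area Retained object area range in pixels.
#' @param threshold Either `"otsu"` or a numeric threshold on the raw scale.
#' @param watershed Split touching objects by distance-transform watershed.
#' @param tolerance Watershed tolerance (in distance-map units).
#' @return Integer label matrix with contiguous labels 1..N (0 = background).
#' @export
segment_nuclei <- function(img, min_area = 30, max_area = Inf,
                           threshold = "otsu", watershed = TRUE,
                           tolerance = 1) {
  stopifnot(is.matrix(img))
  mx <- max(img)
  if (mx <= 0) return(matrix(0L, nrow(img), ncol(img)))
  scaled <- img / mx
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  } else {
    threshold / mx
  }
  mask <- scaled > thr
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  mask <- EBImage::fillHull(EBImage::Image(mask))
  if (watershed) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = tolerance)
  } else {
    lab <- EBImage::bwlabel(mask)
  }
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(img), ncol(img))
  # area filter + contiguous relabel
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  newlab <- integer(length(areas))
  newlab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(img), ncol(img))
  nz <- lab > 0
  out[nz] <- newlab[lab[nz]]
  out
}

# polygon area by the shoelace formula (for convex-hull solidity)
.poly_area <- function(x, y) {
  n <- length(x)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Measure segmented nuclei
#'
#' Computes, per labelled object, the integrated (summed) intensity in every
#' supplied channel over the mask region, together with morphology features:
#' area, centroid, eccentricity, perimeter, and solidity (area / convex hull
#' area).
#'
#' @param mask Integer label matrix from [segment_nuclei()].
#' @param channels Named list of numeric matrices, same shape as `mask`.
#'   A channel named `dna` becomes the `dna` column; every other channel
#'   `x` becomes `mark_x`.
#' @return A tibble with one row per label: `label`, `area`,
#'   `centroid_row`, `centroid_col`, `eccentricity`, `perimeter`,
#'   `solidity`, `dna`, and `mark_*` columns.
#' @export
measure_nuclei <- function(mask, channels) {
  stopifnot(is.matrix(mask), is.list(channels), length(channels) >= 1)
  for (ch in channels) {
    if (!all(dim(ch) == dim(mask))) abort("Channel shape differs from mask.")
  }
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0) {
    return(tibble(label = integer(), area = numeric(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  eccentricity = numeric(), perimeter = numeric(),
                  solidity = numeric()))
  }
  nz <- which(mask > 0, arr.ind = TRUE)
  lv <- mask[nz]
  area <- tabulate(lv, nbins = max(labs))[labs]
  cr <- tapply(nz[, 1], lv, mean)[as.character(labs)]
  cc <- tapply(nz[, 2], lv, mean)[as.character(labs)]

  shp <- EBImage::computeFeatures.shape(mask)
  mom <- EBImage::computeFeatures.moment(mask)
  per <- shp[labs, "s.perimeter"]
  ecc <- mom[labs, "m.eccentricity"]

  solidity <- vapply(labs, function(l) {
    pix <- nz[lv == l, , drop = FALSE]
    if (nrow(pix) < 3) return(1)
    hull <- grDevices::chull(pix[, 2], pix[, 1])
    ha <- .poly_area(pix[hull, 2], pix[hull, 1])
    if (ha <= 0) 1 else min(sum(lv == l) / ha, 1.5)
  }, numeric(1))

  out <- tibble(
    label = as.integer(labs), area = as.numeric(area),
    centroid_row = as.numeric(cr) - 1, centroid_col = as.numeric(cc) - 1,
    eccentricity = as.numeric(ecc), perimeter = as.numeric(per),
    solidity = solidity
  )
  for (cn in names(channels)) {
    v <- tapply(channels[[cn]][nz], lv, sum)[as.character(labs)]
    colname <- if (cn == "dna") "dna" else paste0("mark_", cn)
    out[[colname]] <- as.numeric(v)
  }
  out
}
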