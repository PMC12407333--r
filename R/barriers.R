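BARRIER_CLASSES <- c("over_up", "insufficient_up", "over_down",
                     "insufficient_down", "none")

#' Classify reprogramming-barrier genes from four-state expression
#'
#' Applies the magnitude rules on mean log2 expression in MEF, pre-iPSC,
#' iPSC, and ESC:
#' * `over_up`: pre-iPSC exceeds all of MEF, iPSC, ESC by more than `delta`
#'   (a gene over-shot upward in the trapped intermediate);
#' * `insufficient_up`: both iPSC and ESC exceed both MEF and pre-iPSC by
#'   more than `delta` (a pluripotency gene the intermediate failed to
#'   activate);
#' * `over_down` / `insufficient_down`: the sign-mirrored rules.
#'
#' A gene matching none of the rules is classed `none`. In rare corner
#' configurations two rules can both hold; precedence is the order above and
#' each gene receives exactly one class.
#'
#' @param expr Tibble with columns `gene`, `MEF`, `pre_iPSC`, `iPSC`, `ESC`
#'   (mean log2 expression; all finite).
#' @param delta Log2 threshold (> 0), default 1.
#' @return Tibble with `gene` and `class` (factor over the five classes).
#' @examples
#' expr <- tibble::tibble(gene = "g", MEF = 5, pre_iPSC = 8, iPSC = 5, ESC = 5)
#' classify_barriers(expr) # over_up
#' @export
classify_barriers <- function(expr, delta = 1) {
  need <- c("gene", "MEF", "pre_iPSC", "iPSC", "ESC")
  missing <- setdiff(need, names(expr))
  if (length(missing)) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(expr[, c("MEF", "pre_iPSC", "iPSC", "ESC")])
  if (any(!is.finite(vals))) abort("Expression values must all be finite.")
  if (delta <= 0) abort("`delta` must be > 0.")
  m <- expr$MEF; p <- expr$pre_iPSC; i <- expr$iPSC; e <- expr$ESC
  over_up <- p - pmax(m, i, e) > delta
  insufficient_up <- pmin(i, e) - pmax(m, p) > delta
  over_down <- pmin(m, i, e) - p > delta
  insufficient_down <- pmin(m, p) - pmax(i, e) > delta
  cls <- case_when(
    over_up ~ "over_up",
    insufficient_up ~ "insufficient_up",
    over_down ~ "over_down",
    insufficient_down ~ "insufficient_down",
    TRUE ~ "none"
  )
  tibble(gene = expr$gene, class = factor(cls, levels = BARRIER_CLASSES))
}

#' Transcription-factor target enrichment per barrier class
#'
#' For every (barrier class, TF) pair, counts how many class members are TF
#' targets and tests over-representation against the classified universe with
#' a one-sided (upper tail) hypergeometric test.
#'
#' @param calls Tibble from [classify_barriers()].
#' @param targets Either a list of [target_set()] objects or a tibble with
#'   columns `tf` and `gene` (the up/down distinction is ignored here; a
#'   gene is a target if it appears in either list).
#' @return Tibble with `class`, `tf`, `n_class`, `n_in_targets`, `fraction`
#'   (NA for empty classes), and `p_hyper`.
#' @export
target_enrichment <- function(calls, targets) {
  stopifnot(is.data.frame(calls), all(c("gene", "class") %in% names(calls)))
  if (is.list(targets) && !is.data.frame(targets)) {
    targets <- map_df(targets, function(ts) {
      tibble(tf = ts$tf, gene = c(ts$up, ts$down))
    })
  }
  stopifnot(all(c("tf", "gene") %in% names(targets)))
  universe <- unique(calls$gene)
  n_univ <- length(universe)
  tfs <- unique(targets$tf)
  classes <- setdiff(BARRIER_CLASSES, "none")
  out <- list()
  for (cl in classes) {
    members <- calls$gene[calls$class == cl]
    for (tf in tfs) {
      tgt <- intersect(unique(targets$gene[targets$tf == tf]), universe)
      n_tgt <- length(tgt)
      n_cl <- length(members)
      hit <- length(intersect(members, tgt))
      frac <- if (n_cl == 0) NA_real_ else hit / n_cl
      p <- if (n_cl == 0) NA_real_ else {
        phyper(hit - 1, n_tgt, n_univ - n_tgt, n_cl, lower.tail = FALSE)
      }
      out[[length(out) + 1]] <- tibble(
        class = cl, tf = tf, n_class = n_cl, n_in_targets = hit,
        fraction = frac, p_hyper = p
      )
    }
  }
  bind_rows(out)
}
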