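#' Read a GMT file of TF target sets
#'
#' GMT format: one set per line, tab-separated `name`, `description`, then
#' gene IDs. Sets named `<TF>_up` / `<TF>_down` are paired into
#' [target_set()] objects; unmatched sets get one-sided target sets.
#'
#' @param path Path to a GMT file.
#' @return Named list of [target_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    list(name = f[1], genes = f[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  tf_names <- unique(sub("_(up|down)$", "", names(sets)))
  out <- list()
  for (tf in tf_names) {
    up <- sets[[paste0(tf, "_up")]]$genes %||% character()
    down <- sets[[paste0(tf, "_down")]]$genes %||% character()
    if (length(up) + length(down) == 0 && tf %in% names(sets)) {
      up <- sets[[tf]]$genes
    }
    out[[tf]] <- target_set(tf, up, down)
  }
  out
}

#' Write TF target sets to a GMT file
#'
#' @param target_sets List of [target_set()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(target_sets, path) {
  lines <- unlist(lapply(target_sets, function(ts) {
    c(
      if (length(ts$up)) {
        paste(c(paste0(ts$tf, "_up"), "upregulated targets", ts$up),
              collapse = "\t")
      },
      if (length(ts$down)) {
        paste(c(paste0(ts$tf, "_down"), "downregulated targets", ts$down),
              collapse = "\t")
      }
    )
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample IDs and genes as rows (first column =
#' gene ID).
#'
#' @param path Path to the TSV.
#' @return Tibble with a `gene` column plus one column per sample.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1] <- "gene"
  as_tibble(df)
}

#' Write a gene x sample expression matrix to TSV
#'
#' @param expr Tibble whose first column is the gene ID.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
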