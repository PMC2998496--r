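#' Read gene sets from a GMT file
#'
#' Standard tab format: set name, description, then member genes.
#'
#' @param path path to the GMT file.
#' @return A named list of character vectors; descriptions in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(path, ": line ", bad[1L], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop(path, ": duplicated set name: ",
         names(sets)[duplicated(names(sets))][1L])
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set descriptions (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the actual overlap between the query list and the set, drawing
#' `|list|` genes from the universe — equivalent to a one-sided Fisher exact
#' test on the 2x2 table. BH-adjusted q values are reported; significance
#' uses the raw p value (`p < alpha`), matching the common reporting
#' convention for these screens.
#'
#' @param genes character vector: the query gene list (must be contained in
#'   the universe).
#' @param sets named list of character vectors (gene sets); each set is
#'   intersected with the universe before testing.
#' @param universe character vector of all assayed genes.
#' @param alpha significance cutoff on the raw p value.
#' @return Data frame `set`, `set_size`, `overlap`, `p_value`, `q_value`,
#'   `significant`, sorted by p value.
#' @export
hypergeometric_enrichment <- function(genes, sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  genes <- unique(genes)
  if (!length(genes)) stop("empty gene list")
  outside <- setdiff(genes, universe)
  if (length(outside))
    stop("gene(s) not in universe: ", paste(utils::head(outside, 5L),
                                            collapse = ", "))
  n_list <- length(genes)
  n_univ <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(genes, s))
    # P[X >= k] for X ~ Hypergeometric(|set|, |universe|-|set|, |list|)
    p <- stats::phyper(k - 1L, length(s), n_univ - length(s), n_list,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
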