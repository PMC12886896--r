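# Gene-set integration: overlaps between the H3K4me3-enriched set, 22G and
# mRNA differential call sets, and external reference lists.

#' Overlap statistics for two gene sets
#'
#' Exact set arithmetic plus an upper-tail hypergeometric enrichment
#' p-value: the probability of drawing at least `n_overlap` marked elements
#' when `|a|` elements are drawn from the universe with `|b|` marked.  The
#' p-value is an explicit extension beyond plain overlap counting and is
#' reported, not used for any default decision.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Character vector containing every eligible gene id.
#' @return List with `n_a`, `n_b`, `n_overlap`, `n_union`,
#'   `p_hypergeometric`.
#' @export
overlap_sets <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop_format("element outside universe: %s", c(out_a, out_b)[1])
  n_ov <- length(intersect(set_a, set_b))
  list(n_a = length(set_a), n_b = length(set_b), n_overlap = n_ov,
       n_union = length(union(set_a, set_b)),
       p_hypergeometric = stats::phyper(n_ov - 1, length(set_b),
                                        length(universe) - length(set_b),
                                        length(set_a), lower.tail = FALSE))
}

#' Crosstab of enriched genes against 22G and mRNA call sets
#'
#' Counts how many H3K4me3-enriched genes fall in each differential
#' category; the up/down components of each call set must be disjoint.
#'
#' @param enriched Character vector of enriched gene ids.
#' @param de22g A `de_call_set` of 22G-RNA calls ([call_de()]).
#' @param demrna Optional `de_call_set` of mRNA calls; `NULL` leaves the
#'   mRNA counts at 0.
#' @return List of class `integration_crosstab` with `n_enriched`,
#'   `n_enriched_with_22g_change`, `n_22g_up`, `n_22g_down`,
#'   `n_enriched_with_mrna_change`, `n_mrna_up`, `n_mrna_down`.
#' @export
build_crosstab <- function(enriched, de22g, demrna = NULL) {
  enriched <- unique(enriched)
  check_disjoint <- function(cs, label) {
    if (length(intersect(cs$up, cs$down)))
      stop_format("%s call set has overlapping up/down components", label)
  }
  check_disjoint(de22g, "22G")
  up22 <- intersect(enriched, de22g$up)
  down22 <- intersect(enriched, de22g$down)
  upm <- downm <- character(0)
  if (!is.null(demrna)) {
    check_disjoint(demrna, "mRNA")
    upm <- intersect(enriched, demrna$up)
    downm <- intersect(enriched, demrna$down)
  }
  structure(list(n_enriched = length(enriched),
                 n_enriched_with_22g_change = length(up22) + length(down22),
                 n_22g_up = length(up22), n_22g_down = length(down22),
                 n_enriched_with_mrna_change = length(upm) + length(downm),
                 n_mrna_up = length(upm), n_mrna_down = length(downm)),
            class = "integration_crosstab")
}

#' @export
print.integration_crosstab <- function(x, ...) {
  cat(sprintf(paste0("<crosstab> %d enriched genes; %d with 22G change ",
                     "(%d up, %d down); %d with mRNA change (%d up, %d down)\n"),
              x$n_enriched, x$n_enriched_with_22g_change, x$n_22g_up,
              x$n_22g_down, x$n_enriched_with_mrna_change, x$n_mrna_up,
              x$n_mrna_down))
  invisible(x)
}

#' Fraction of a gene set found in a reference list
#'
#' @param gene_set Non-empty character vector.
#' @param reference_list Character vector (e.g. germline-expressed genes).
#' @return `|gene_set intersect reference| / |gene_set|`.
#' @export
fraction_in_reference <- function(gene_set, reference_list) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) stop_format("gene_set is empty")
  length(intersect(gene_set, unique(reference_list))) / length(gene_set)
}

#' Read a plain-text gene list
#' @param path File with one gene id per line; blank lines and `#` comments
#'   ignored.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(con <- gzfile(path)); close(con)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a plain-text gene list
#' @param genes Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
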