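# TSS-anchored metagene matrices, per-gene TSS-window scores, and the
# cumulative-contribution classifier for H3K4me3-enriched genes.

#' TSS-anchored metagene matrix
#'
#' For every gene, samples the enrichment track at bin resolution over
#' `[TSS - upstream, TSS + downstream)`.  Rows of minus-strand genes are
#' orientation-flipped so positive offsets always point downstream of
#' transcription.  Positions off the chromosome ends are `NA` and are
#' excluded from averages.
#'
#' @param track A log2_ratio [binned_track()] (any scale is accepted).
#' @param annotation A [genome_annotation()].
#' @param upstream,downstream Window extent in bp; multiples of the track's
#'   bin size.
#' @return Object of class `metagene_matrix`: list with `gene_ids`,
#'   `offsets` (bin-center offsets in bp relative to the TSS) and `values`
#'   (genes x offsets matrix).
#' @export
metagene_matrix <- function(track, annotation, upstream = 1000L,
                            downstream = 1000L) {
  bs <- track$bin_size
  if (upstream %% bs != 0 || downstream %% bs != 0)
    stop_format("upstream/downstream must be multiples of bin_size (%d)", bs)
  tss <- tss_of(annotation)
  chrom <- attr(tss, "chrom")
  missing_chrom <- setdiff(unique(chrom), names(track$values))
  if (length(missing_chrom))
    stop_format("gene on chromosome absent from track: %s", missing_chrom[1])
  offs <- seq(-upstream, downstream - bs, by = bs)
  strand <- annotation$genes$strand
  vals <- matrix(NA_real_, nrow = length(tss), ncol = length(offs),
                 dimnames = list(names(tss), NULL))
  for (i in seq_along(tss)) {
    pos <- if (strand[i] == "+") tss[i] + offs else tss[i] - offs
    v <- track$values[[chrom[i]]]
    bin <- pos %/% bs + 1L
    ok <- pos >= 0 & pos < track$lengths[[chrom[i]]]
    vals[i, ok] <- v[bin[ok]]
  }
  structure(list(gene_ids = names(tss), offsets = offs + bs / 2,
                 values = vals),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf("<metagene_matrix> %d genes x %d offsets (%g..%g bp)\n",
              nrow(x$values), ncol(x$values),
              min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' Average metagene profile
#'
#' Column-wise mean over genes, ignoring `NA` cells (off-chromosome
#' positions).  A column with no finite cell stays `NA`.
#'
#' @param matrix A [metagene_matrix()].
#' @return Numeric vector over offsets, named by offset.
#' @export
average_profile <- function(matrix) {
  stopifnot(nrow(matrix$values) >= 1)
  prof <- colMeans(matrix$values, na.rm = TRUE)
  prof[is.nan(prof)] <- NA_real_
  stats::setNames(prof, matrix$offsets)
}

#' Plot a metagene profile
#' @param x A [metagene_matrix()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the average profile.
#' @export
plot.metagene_matrix <- function(x, ...) {
  prof <- average_profile(x)
  graphics::plot(x$offsets, prof, type = "l",
                 xlab = "distance from TSS (bp)",
                 ylab = "mean enrichment", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(prof)
}

#' Mean enrichment in a TSS window
#'
#' Per gene, the arithmetic mean of the values of all bins intersecting
#' `[TSS - halfwidth, TSS + halfwidth)`, truncated at chromosome edges.
#' The window is symmetric about the TSS, so the score is strand-invariant.
#'
#' @param track A [binned_track()].
#' @param annotation A [genome_annotation()].
#' @param halfwidth Window half-width in bp; multiple of the bin size.
#' @return Named numeric vector of per-gene scores.
#' @export
tss_window_score <- function(track, annotation, halfwidth = 500L) {
  bs <- track$bin_size
  if (halfwidth %% bs != 0)
    stop_format("halfwidth must be a multiple of bin_size (%d)", bs)
  tss <- tss_of(annotation)
  chrom <- attr(tss, "chrom")
  missing_chrom <- setdiff(unique(chrom), names(track$values))
  if (length(missing_chrom))
    stop_format("gene on chromosome absent from track: %s", missing_chrom[1])
  out <- vapply(seq_along(tss), function(i) {
    v <- track$values[[chrom[i]]]
    b0 <- max((tss[i] - halfwidth) %/% bs, 0L)
    b1 <- min((tss[i] + halfwidth - 1L) %/% bs, length(v) - 1L)
    mean(v[(b0 + 1L):(b1 + 1L)])
  }, numeric(1))
  stats::setNames(out, names(tss))
}

#' Per-gene wild-type/mutant TSS score table
#'
#' TSS-window scores on both enrichment tracks plus their difference
#' (`delta = score_mut - score_wt`), for every annotated gene.
#'
#' @param track_wt,track_mut log2_ratio [binned_track()]s sharing bin
#'   structure.
#' @param annotation A [genome_annotation()].
#' @param halfwidth TSS window half-width in bp.
#' @return data.frame of class `gene_score_table` with columns `gene_id`,
#'   `score_wt`, `score_mut`, `delta`.
#' @export
build_score_table <- function(track_wt, track_mut, annotation,
                              halfwidth = 500L) {
  if (!same_bins(track_wt, track_mut))
    stop_format("tracks have mismatched bin structure")
  wt <- tss_window_score(track_wt, annotation, halfwidth)
  mut <- tss_window_score(track_mut, annotation, halfwidth)
  structure(data.frame(gene_id = names(wt), score_wt = unname(wt),
                       score_mut = unname(mut),
                       delta = unname(mut - wt),
                       stringsAsFactors = FALSE),
            class = c("gene_score_table", "data.frame"))
}

#' Cumulative-contribution selection of H3K4me3-enriched genes
#'
#' Genes with a positive mutant-minus-wild-type delta are ranked by delta
#' (descending, ties broken by gene id); the selection is the shortest
#' prefix whose cumulative delta reaches `fraction` of the total positive
#' delta.  With no positive deltas the selection is empty.
#'
#' @param table A [build_score_table()] result (needs `gene_id`, `delta`).
#' @param fraction Fraction of the total increased enrichment to cover
#'   (0 < fraction <= 1).
#' @param min_wt_score Optional: require `score_wt >= min_wt_score` before
#'   ranking (restricts selection to genes already marked in the wild
#'   type); `NULL` disables the filter.
#' @return Character vector of selected gene ids, in rank order.
#' @export
select_enriched_genes <- function(table, fraction = 0.8,
                                  min_wt_score = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  t <- as.data.frame(table)
  if (!is.null(min_wt_score))
    t <- t[t$score_wt >= min_wt_score, , drop = FALSE]
  pos <- t[t$delta > 0, , drop = FALSE]
  if (nrow(pos) == 0) return(character(0))
  pos <- pos[order(-pos$delta, pos$gene_id), , drop = FALSE]
  total <- sum(pos$delta)
  target <- fraction * total
  # tolerance keeps exact ties (e.g. 4 + 4 >= 0.8 * 10) from being broken
  # by binary floating point
  k <- which(cumsum(pos$delta) >= target - 1e-9 * max(1, total))[1]
  pos$gene_id[seq_len(k)]
}

#' Across-genes Welch test of mutant vs wild-type TSS scores
#'
#' Two-sided unpaired Welch t-test comparing the wild-type and mutant score
#' columns across genes.  The statistic is wild-type minus mutant, so a
#' negative t means higher mutant enrichment.
#'
#' @param table A [build_score_table()] result.
#' @return List with `t_statistic`, `df` (Welch-Satterthwaite), `p_value`,
#'   and `degenerate` (TRUE when both columns are constant with unequal
#'   means, in which case `p_value` is the smallest representable double).
#' @export
compare_scores <- function(table) {
  t <- as.data.frame(table)
  stopifnot(nrow(t) >= 2)
  wt <- t$score_wt
  mut <- t$score_mut
  if (stats::var(wt) == 0 && stats::var(mut) == 0) {
    if (mean(wt) == mean(mut))
      return(list(t_statistic = 0, df = 2 * (length(wt) - 1), p_value = 1,
                  degenerate = FALSE))
    return(list(t_statistic = sign(mean(wt) - mean(mut)) * Inf,
                df = 2 * (length(wt) - 1),
                p_value = .Machine$double.xmin, degenerate = TRUE))
  }
  ht <- stats::t.test(wt, mut, var.equal = FALSE)
  list(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, degenerate = FALSE)
}
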