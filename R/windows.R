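# Genome-wide sliding-window differential occupancy, built on the NB test.

#' Sliding-window grid over a genome
#'
#' Windows of `window_size` bp start at 0, `step`, `2*step`, ... while
#' `start + window_size <= chromosome length`; chromosomes shorter than one
#' window contribute none.
#'
#' @param genome A [genome()].
#' @param window_size Window width in bp.
#' @param step Shift between consecutive window starts in bp
#'   (`window_size >= step >= 1`).
#' @return Object of class `window_grid`: list with `window_size`, `step`
#'   and `windows` (data.frame `chrom`, `start`, `end`, `window_id`).
#' @export
make_windows <- function(genome, window_size = 200L, step = 10L) {
  stopifnot(window_size >= step, step >= 1)
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  lens <- chrom_lengths(genome)
  per <- lapply(names(lens), function(chrom) {
    L <- lens[[chrom]]
    if (L < window_size) return(NULL)
    starts <- seq(0L, L - window_size, by = step)
    data.frame(chrom = chrom, start = starts,
               end = starts + as.integer(window_size),
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, per)
  if (is.null(w)) w <- data.frame(chrom = character(0), start = integer(0),
                                  end = integer(0))
  w$window_id <- sprintf("%s:%d-%d", w$chrom, w$start, w$end)
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step), windows = w),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows (%d bp, step %d bp)\n",
              nrow(x$windows), x$window_size, x$step))
  invisible(x)
}

#' Per-window fragment counts
#'
#' Reads are extended to fragments exactly as in [bin_coverage()]; a
#' fragment adds 1 to every window it overlaps (overlapping windows each
#' count it; no deduplication across windows).
#'
#' @param grid A [make_windows()] grid.
#' @param read_sets Named list of [read_set()]s, one per sample.
#' @param genome The [genome()] the grid was built on.
#' @param condition Named per-sample group labels.
#' @param fragment_length Fragment extension in bp.
#' @return A [count_matrix()], windows x samples.
#' @export
window_counts <- function(grid, read_sets, genome, condition,
                          fragment_length = 200L) {
  lens <- chrom_lengths(genome)
  w <- grid$windows
  counts <- matrix(0L, nrow = nrow(w), ncol = length(read_sets),
                   dimnames = list(w$window_id, names(read_sets)))
  for (s in names(read_sets)) {
    fr <- fragments_of(read_sets[[s]], fragment_length, lens)
    for (chrom in unique(w$chrom)) {
      wi <- which(w$chrom == chrom)
      d <- fr[fr$chrom == chrom, ]
      if (!nrow(d)) next
      q <- IRanges::IRanges(start = w$start[wi] + 1L, end = w$end[wi])
      subj <- IRanges::IRanges(start = d$start + 1L, end = d$end)
      counts[wi, s] <- IRanges::countOverlaps(q, subj)
    }
  }
  count_matrix(counts, condition)
}

#' Differential occupancy over sliding windows
#'
#' Size factors, moderated dispersion and the NB Wald test applied to a
#' window count matrix.  Neighbouring windows share fragments, so their
#' tests are strongly correlated; window-level BH q-values are reported but
#' should be read with that caveat.
#'
#' @param cm A window [count_matrix()] with two condition groups.
#' @param ref Optional reference condition level.
#' @return A `de_result` data.frame over windows.
#' @export
window_differential <- function(cm, ref = NULL) {
  sf <- size_factors(cm)
  disp <- estimate_dispersion(cm, sf)
  nb_wald_test(cm, sf, disp, ref = ref)
}

#' Map significant windows to genes
#'
#' A gene is reported when its TSS +/- `halfwidth` window (mode
#' `"tss_window"`) or its gene body (mode `"gene_body"`) intersects at
#' least one of the given windows.
#'
#' @param significant_windows data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), e.g. a subset of a [make_windows()] grid.
#' @param annotation A [genome_annotation()].
#' @param mode `"tss_window"` or `"gene_body"`.
#' @param halfwidth TSS window half-width in bp (tss_window mode).
#' @return Character vector of gene ids.
#' @export
windows_to_genes <- function(significant_windows, annotation,
                             mode = c("tss_window", "gene_body"),
                             halfwidth = 500L) {
  mode <- match.arg(mode)
  g <- annotation$genes
  if (mode == "tss_window") {
    tss <- tss_of(annotation)
    gstart <- pmax(tss - halfwidth, 0)
    gend <- tss + halfwidth
    gchrom <- attr(tss, "chrom")
  } else {
    gstart <- g$start
    gend <- g$end
    gchrom <- g$chrom
  }
  if (nrow(significant_windows) == 0) return(character(0))
  win <- GenomicRanges::GRanges(
    significant_windows$chrom,
    IRanges::IRanges(start = significant_windows$start + 1L,
                     end = significant_windows$end))
  gr <- GenomicRanges::GRanges(gchrom,
                               IRanges::IRanges(start = gstart + 1L,
                                                end = gend))
  hits <- GenomicRanges::countOverlaps(gr, win)
  g$gene_id[hits > 0]
}

#' Write significant windows as BED
#'
#' BED6-style output with the window id in column 4, log2 fold-change in
#' column 5 and q-value in column 6.
#'
#' @param grid A [make_windows()] grid.
#' @param results The matching `de_result` over windows.
#' @param path Output path.
#' @param max_fdr Keep windows with `q_value <= max_fdr`.
#' @return Invisibly, the subset of `grid$windows` written.
#' @export
write_windows_bed <- function(grid, results, path, max_fdr = 0.05) {
  r <- as.data.frame(results)
  keep <- which(r$q_value <= max_fdr)
  w <- grid$windows[keep, , drop = FALSE]
  dt <- data.table::data.table(chrom = w$chrom, start = w$start,
                               end = w$end, name = w$window_id,
                               log2fc = fmt_num(r$log2fc[keep]),
                               q_value = fmt_num(r$q_value[keep]))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(w)
}
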