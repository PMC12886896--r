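# ChIP fragment tracks: binned coverage, CPM normalization, input correction.

# Extend each read from its 5' end in the strand direction to
# `fragment_length` bp, clipped to [0, chromosome length).
fragments_of <- function(rs, fragment_length, lengths) {
  r <- rs$reads
  L <- lengths[r$chrom]
  if (anyNA(L))
    stop_format("read on unknown chromosome: %s", r$chrom[is.na(L)][1])
  start <- ifelse(r$strand == "+", r$pos5, r$pos5 - fragment_length + 1L)
  end <- ifelse(r$strand == "+", r$pos5 + fragment_length, r$pos5 + 1L)
  data.frame(chrom = r$chrom,
             start = pmax(0, start),
             end = pmin(as.numeric(L), end),
             stringsAsFactors = FALSE)
}

#' Binned fragment coverage
#'
#' Extends each read to a fixed-length fragment from its 5' end and counts,
#' for every bin, the number of fragments overlapping it by at least 1 bp.
#' A fragment spanning several bins increments each of them.
#'
#' @param reads A [read_set()].
#' @param genome A [genome()] (chromosome lengths define the bin grid).
#' @param bin_size Bin width in bp.
#' @param fragment_length Extension length in bp.
#' @return A raw-scale [binned_track()].
#' @export
bin_coverage <- function(reads, genome, bin_size = 10L,
                         fragment_length = 200L) {
  stopifnot(bin_size >= 1, fragment_length >= 1)
  lens <- chrom_lengths(genome)
  fr <- fragments_of(reads, fragment_length, lens)
  values <- lapply(names(lens), function(chrom) {
    nb <- ceiling(lens[[chrom]] / bin_size)
    d <- fr[fr$chrom == chrom, ]
    if (!nrow(d)) return(numeric(nb))
    bins <- IRanges::IRanges(start = (seq_len(nb) - 1L) * bin_size + 1L,
                             end = pmin(seq_len(nb) * bin_size,
                                        lens[[chrom]]))
    frags <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    as.numeric(IRanges::countOverlaps(bins, frags))
  })
  names(values) <- names(lens)
  binned_track(values, bin_size, lens, "raw")
}

#' Counts-per-million normalization
#'
#' Scales every bin by `1e6 / library_size`.
#'
#' @param track A raw-scale [binned_track()].
#' @param library_size Total reads in the library (must be positive).
#' @return A cpm-scale [binned_track()].
#' @export
cpm_normalize <- function(track, library_size) {
  if (length(library_size) != 1 || library_size <= 0)
    stop_format("library_size must be a single positive number")
  track$values <- lapply(track$values, function(v) v * 1e6 / library_size)
  track$scale <- "cpm"
  track
}

#' Per-bin mean of several tracks
#'
#' Replicate tracks are averaged bin by bin; all tracks must share bin
#' structure and scale.
#'
#' @param tracks List of [binned_track()]s.
#' @return A [binned_track()] of the same scale.
#' @export
mean_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (!same_bins(ref, t)) stop_format("tracks have mismatched bin structure")
    if (!identical(ref$scale, t$scale))
      stop_format("tracks have mismatched scales (%s vs %s)",
                  ref$scale, t$scale)
  }
  ref$values <- lapply(names(ref$values), function(chrom) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[chrom]])) /
      length(tracks)
  })
  names(ref$values) <- names(tracks[[1]]$values)
  ref
}

#' Input-normalized enrichment track
#'
#' Per bin, `log2((ip + pseudocount) / (input + pseudocount))` on CPM-scale
#' tracks.  The pseudocount (in CPM units) bounds the ratio and pins bins
#' with no coverage in either library at exactly 0.
#'
#' @param ip,input cpm-scale [binned_track()]s with identical bin structure.
#' @param pseudocount Positive pseudocount in CPM units.
#' @param numerator_label,denominator_label Labels recorded on the result.
#' @return A log2_ratio [binned_track()] ("enrichment track") carrying
#'   `numerator_label`, `denominator_label` and `pseudocount` fields.
#' @export
enrichment_ratio <- function(ip, input, pseudocount = 1.0,
                             numerator_label = "IP",
                             denominator_label = "input") {
  if (pseudocount <= 0) stop_format("pseudocount must be > 0")
  if (!same_bins(ip, input))
    stop_format("IP and input tracks have mismatched bin structure")
  out <- ip
  out$values <- lapply(names(ip$values), function(chrom)
    log2((ip$values[[chrom]] + pseudocount) /
         (input$values[[chrom]] + pseudocount)))
  names(out$values) <- names(ip$values)
  out$scale <- "log2_ratio"
  out$numerator_label <- numerator_label
  out$denominator_label <- denominator_label
  out$pseudocount <- pseudocount
  out
}

#' Mutant vs wild-type fold-change track
#'
#' Per-bin difference of two log2 enrichment tracks (a log2 fold-change of
#' input-normalized enrichments).  Swapping the arguments negates every bin.
#'
#' @param mutant,wildtype log2_ratio [binned_track()]s with identical bin
#'   structure.
#' @return A log2_ratio [binned_track()] labelled mutant/wild_type.
#' @export
fold_change_track <- function(mutant, wildtype) {
  if (!identical(mutant$scale, "log2_ratio") ||
      !identical(wildtype$scale, "log2_ratio"))
    stop_format("fold_change_track expects log2_ratio tracks")
  if (!same_bins(mutant, wildtype))
    stop_format("tracks have mismatched bin structure")
  out <- mutant
  out$values <- lapply(names(mutant$values), function(chrom)
    mutant$values[[chrom]] - wildtype$values[[chrom]])
  names(out$values) <- names(mutant$values)
  out$numerator_label <- "mutant"
  out$denominator_label <- "wild_type"
  out$pseudocount <- NULL
  out
}
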