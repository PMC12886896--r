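#' Fixed-bin genomic signal track
#'
#' Bins of `bin_size` bp tile each chromosome left to right from position 0;
#' the last bin may be truncated.  `scale` records what the values mean:
#' raw fragment counts, counts-per-million, or a log2 ratio.
#'
#' @param values Named list of numeric vectors, one per chromosome, one value
#'   per bin.
#' @param bin_size Bin width in bp.
#' @param lengths Named chromosome lengths in bp; the number of bins per
#'   chromosome must equal `ceiling(length / bin_size)`.
#' @param scale One of `"raw"`, `"cpm"`, `"log2_ratio"`.
#' @return Object of class `binned_track`.
#' @export
binned_track <- function(values, bin_size, lengths,
                         scale = c("raw", "cpm", "log2_ratio")) {
  scale <- match.arg(scale)
  stopifnot(is.list(values), !is.null(names(values)))
  lengths <- lengths[names(values)]
  if (anyNA(lengths)) stop_format("missing chromosome length")
  expected <- ceiling(lengths / bin_size)
  got <- lengths(values)
  if (any(got != expected))
    stop_format("chromosome %s: %d bins given, %d expected",
                names(values)[got != expected][1],
                got[got != expected][1], expected[got != expected][1])
  if (!all(vapply(values, function(v) all(is.finite(v)), logical(1))))
    stop_format("track values must be finite")
  structure(list(values = values, bin_size = as.integer(bin_size),
                 lengths = lengths, scale = scale),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> scale=%s bin_size=%d bp, %d chromosome(s), %d bins\n",
              x$scale, x$bin_size, length(x$values),
              sum(lengths(x$values))))
  if (!is.null(x$numerator_label))
    cat(sprintf("  ratio: %s / %s (pseudocount %g)\n",
                x$numerator_label, x$denominator_label, x$pseudocount))
  invisible(x)
}

same_bins <- function(a, b) {
  identical(a$bin_size, b$bin_size) &&
    identical(names(a$values), names(b$values)) &&
    identical(unname(lengths(a$values)), unname(lengths(b$values)))
}

#' Write a track as bedGraph
#'
#' Four columns, 0-based half-open; runs of adjacent equal-valued bins are
#' merged into one line.  Values are serialized with 6 significant digits so
#' outputs are byte-stable across platforms.
#'
#' @param track A [binned_track()].
#' @param path Output path (".gz" supported).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  chunks <- lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    r <- rle(fmt_num(v))
    ends_bin <- cumsum(r$lengths)
    starts <- c(0, ends_bin[-length(ends_bin)]) * track$bin_size
    ends <- pmin(ends_bin * track$bin_size, track$lengths[[chrom]])
    sprintf("%s\t%d\t%d\t%s", chrom, starts, ends, r$values)
  })
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(unlist(chunks), con)
  close(con)
  invisible(path)
}

#' Read a bedGraph into a binned track
#'
#' Merged runs are expanded back to fixed bins; a write/read round trip
#' reproduces values exactly (up to the fixed 6-significant-digit text
#' format).  Overlapping intervals are a format error.
#'
#' @param path bedGraph file.
#' @param genome A [genome()] supplying chromosome lengths.
#' @param bin_size Bin width the file was written with.
#' @param scale Scale tag to stamp on the result.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, genome, bin_size,
                          scale = c("raw", "cpm", "log2_ratio")) {
  scale <- match.arg(scale)
  bg <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = list(character = 1, integer = 2:3,
                                            numeric = 4))
  lens <- chrom_lengths(genome)
  bad <- setdiff(unique(bg$chrom), names(lens))
  if (length(bad)) stop_format("bedGraph chromosome not in genome: %s", bad[1])
  values <- lapply(names(lens), function(chrom) {
    nb <- ceiling(lens[[chrom]] / bin_size)
    v <- numeric(nb)
    seen <- logical(nb)
    d <- bg[bg$chrom == chrom, ]
    if (nrow(d)) {
      d <- d[order(d$start), ]
      if (any(d$start[-1] < d$end[-nrow(d)]))
        stop_format("overlapping bedGraph intervals on %s", chrom)
      for (i in seq_len(nrow(d))) {
        b0 <- d$start[i] %/% bin_size
        b1 <- (d$end[i] - 1L) %/% bin_size
        v[(b0 + 1L):(b1 + 1L)] <- d$value[i]
        seen[(b0 + 1L):(b1 + 1L)] <- TRUE
      }
    }
    v
  })
  names(values) <- names(lens)
  binned_track(values, bin_size, lens, scale)
}

#' Aligned read set
#'
#' Reads are stored as 5' positions with strand and length; ChIP fragment
#' extension happens at counting time, not here.
#'
#' @param reads data.frame with columns `chrom`, `pos5` (0-based), `strand`
#'   (`+`/`-`), `length` (bp).
#' @param lengths Named chromosome lengths for bounds checking.
#' @return Object of class `read_set` with `library_size = nrow(reads)`.
#' @export
read_set <- function(reads, lengths = NULL) {
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos5", "strand", "length") %in% names(reads)))
  if (!all(reads$strand %in% c("+", "-")))
    stop_format("read strand must be '+' or '-'")
  if (!is.null(lengths)) {
    L <- lengths[reads$chrom]
    if (anyNA(L)) stop_format("read on unknown chromosome: %s",
                              reads$chrom[is.na(L)][1])
    if (any(reads$pos5 < 0 | reads$pos5 >= L))
      stop_format("read 5' position outside chromosome bounds")
  }
  rownames(reads) <- NULL
  structure(list(reads = reads, library_size = nrow(reads)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads on %d chromosome(s)\n",
              x$library_size, length(unique(x$reads$chrom))))
  invisible(x)
}

#' Write aligned reads as BED6
#'
#' Each read becomes a 1 bp interval at its 5' end; read length is stored in
#' the score column so [read_bed_reads()] can reconstruct the read set.
#'
#' @param rs A [read_set()].
#' @param path Output path (".gz" supported).
#' @return `path`, invisibly.
#' @export
write_bed_reads <- function(rs, path) {
  r <- rs$reads
  dt <- data.table::data.table(chrom = r$chrom, start = r$pos5,
                               end = r$pos5 + 1L, name = ".",
                               score = r$length, strand = r$strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a BED6 file of read 5' positions
#' @param path BED6 file written by [write_bed_reads()] (or any BED6 of
#'   single-base 5' positions with read length in the score column).
#' @param genome Optional [genome()] for bounds checking.
#' @return A [read_set()].
#' @export
read_bed_reads <- function(path, genome = NULL) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"),
                           colClasses = list(character = c(1, 4, 6),
                                             integer = c(2, 3, 5)))
  read_set(data.frame(chrom = bed$chrom, pos5 = bed$start,
                      strand = bed$strand, length = bed$score,
                      stringsAsFactors = FALSE),
           lengths = if (is.null(genome)) NULL else chrom_lengths(genome))
}
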