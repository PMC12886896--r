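# 22G-RNA read-class extraction, exact-match mapping with seeded random
# multimapper assignment, and per-gene counting.

#' Extract the 22G-RNA read class
#'
#' Keeps reads 21-23 nt long whose first base is `G` (uppercase comparison;
#' `N` fails).  Idempotent: filtering a filtered set changes nothing.
#'
#' @param reads data.frame with `read_id` and `sequence` columns (e.g. from
#'   [read_fastq()]).
#' @return List with `kept` (the passing subset, same columns) and `report`
#'   (named counts: `kept`, `too_short`, `too_long`, `non_g_start`).
#' @export
filter_22g <- function(reads) {
  len <- nchar(reads$sequence)
  first <- substr(reads$sequence, 1, 1)
  too_short <- len < 21
  too_long <- len > 23
  non_g <- !too_short & !too_long & first != "G"
  keep <- !too_short & !too_long & !non_g
  list(kept = reads[keep, , drop = FALSE],
       report = c(kept = sum(keep), too_short = sum(too_short),
                  too_long = sum(too_long), non_g_start = sum(non_g)))
}

#' Exact end-to-end mapping with seeded multimapper assignment
#'
#' Each read is matched, mismatch-free and end-to-end, against the forward
#' strand of every chromosome and against its reverse complement (reported
#' as a minus-strand alignment).  Reads with no hit are absent from the
#' output; reads with 1 to `max_hits` hits get exactly one alignment chosen
#' uniformly at random by a generator seeded from `(seed, read_id)`, so
#' reruns are identical read by read; reads with more than `max_hits` loci
#' are discarded.  Matching uses a Biostrings `PDict` per read length.
#'
#' @param reads data.frame with `read_id` and `sequence` (typically the
#'   `kept` component of [filter_22g()]).
#' @param genome A [genome()].
#' @param seed Integer seed for multimapper resolution.
#' @param max_hits Discard reads with more than this many exact loci.
#' @return data.frame of class `alignments`: `read_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `n_hits`.
#' @export
map_exact <- function(reads, genome, seed = 1L, max_hits = 100L) {
  empty <- structure(data.frame(read_id = character(0), chrom = character(0),
                                start = integer(0), end = integer(0),
                                strand = character(0), n_hits = integer(0),
                                stringsAsFactors = FALSE),
                     class = c("alignments", "data.frame"))
  if (nrow(reads) == 0) return(empty)
  mappable <- !grepl("[^ACGT]", reads$sequence)
  reads <- reads[mappable, , drop = FALSE]
  if (nrow(reads) == 0) return(empty)
  lens <- nchar(reads$sequence)
  chroms <- lapply(unclass(genome), Biostrings::DNAString)
  # accumulate every exact hit as parallel vectors: read index, locus
  h_read <- integer(0); h_chrom <- character(0)
  h_start <- integer(0); h_len <- integer(0); h_strand <- character(0)
  for (l in sort(unique(lens))) {
    idx <- which(lens == l)
    fwd <- Biostrings::DNAStringSet(reads$sequence[idx])
    pdicts <- list("+" = Biostrings::PDict(fwd),
                   "-" = Biostrings::PDict(Biostrings::reverseComplement(fwd)))
    for (chrom in names(chroms)) {
      for (sense in c("+", "-")) {
        m <- Biostrings::matchPDict(pdicts[[sense]], chroms[[chrom]])
        starts <- Biostrings::startIndex(m)   # list of 1-based starts
        n_each <- lengths(starts)
        if (!sum(n_each)) next
        h_read <- c(h_read, rep(idx, n_each))
        h_start <- c(h_start, unlist(starts) - 1L)
        h_chrom <- c(h_chrom, rep(chrom, sum(n_each)))
        h_len <- c(h_len, rep(l, sum(n_each)))
        h_strand <- c(h_strand, rep(sense, sum(n_each)))
      }
    }
  }
  if (!length(h_read)) return(empty)
  n_hits <- tabulate(h_read, nbins = nrow(reads))
  keep_hit <- n_hits[h_read] <= max_hits
  h_read <- h_read[keep_hit]; h_chrom <- h_chrom[keep_hit]
  h_start <- h_start[keep_hit]; h_len <- h_len[keep_hit]
  h_strand <- h_strand[keep_hit]
  if (!length(h_read)) return(empty)
  # one reported alignment per read: unique hits directly, multimappers by
  # a per-read seeded draw
  ord <- order(h_read, h_chrom, h_start, h_strand)
  h_read <- h_read[ord]; h_chrom <- h_chrom[ord]
  h_start <- h_start[ord]; h_len <- h_len[ord]; h_strand <- h_strand[ord]
  first <- which(!duplicated(h_read))
  nh <- n_hits[h_read[first]]
  pick <- first
  multi <- which(nh > 1)
  for (k in multi) {
    i <- h_read[first[k]]
    off <- with_seed(derive_seed(seed, "map", reads$read_id[i]),
                     sample.int(nh[k], 1))
    pick[k] <- first[k] + off - 1L
  }
  out <- data.frame(read_id = reads$read_id[h_read[pick]],
                    chrom = h_chrom[pick], start = h_start[pick],
                    end = h_start[pick] + h_len[pick],
                    strand = h_strand[pick], n_hits = nh,
                    stringsAsFactors = FALSE)
  class(out) <- c("alignments", "data.frame")
  out
}

#' Count alignments per gene over exons
#'
#' An alignment is assigned to a gene when it overlaps at least 1 bp of any
#' exon of that gene, strand-agnostic.  Alignments overlapping exons of
#' more than one gene are discarded as ambiguous; each alignment is counted
#' at most once.
#'
#' @param alignments An `alignments` data.frame from [map_exact()].
#' @param annotation A [genome_annotation()] with exons.
#' @return Named integer vector of counts, one entry per annotated gene
#'   (zeros included), in annotation order.
#' @export
count_per_gene <- function(alignments, annotation) {
  genes <- annotation$genes$gene_id
  out <- stats::setNames(integer(length(genes)), genes)
  if (nrow(alignments) == 0) return(out)
  ex <- annotation$exons
  al_gr <- GenomicRanges::GRanges(alignments$chrom,
                                  IRanges::IRanges(alignments$start + 1L,
                                                   alignments$end))
  ex_gr <- GenomicRanges::GRanges(ex$chrom,
                                  IRanges::IRanges(ex$start + 1L, ex$end))
  ov <- GenomicRanges::findOverlaps(al_gr, ex_gr, ignore.strand = TRUE)
  gene_hit <- ex$gene_id[S4Vectors::subjectHits(ov)]
  by_read <- split(gene_hit, S4Vectors::queryHits(ov))
  assigned <- vapply(by_read, function(g) {
    u <- unique(g)
    if (length(u) == 1) u else NA_character_   # multi-gene: ambiguous
  }, character(1))
  tab <- table(assigned[!is.na(assigned)])
  out[names(tab)] <- as.integer(tab)
  out
}

#' Build a 22G count matrix from FASTQ files
#'
#' Runs [read_fastq()], [filter_22g()], [map_exact()] and
#' [count_per_gene()] per sample and assembles a genes x samples
#' [count_matrix()].
#'
#' @param fastq_files Named character vector of FASTQ paths (names become
#'   sample ids).
#' @param genome A [genome()].
#' @param annotation A [genome_annotation()].
#' @param condition Named per-sample group labels.
#' @param seed Integer seed for multimapper assignment.
#' @return List with `counts` (a [count_matrix()]) and `reports` (per-sample
#'   filter reports).
#' @export
count_22g_samples <- function(fastq_files, genome, annotation, condition,
                              seed = 1L) {
  reports <- list()
  cols <- lapply(names(fastq_files), function(s) {
    fl <- filter_22g(read_fastq(fastq_files[[s]]))
    reports[[s]] <<- fl$report
    al <- map_exact(fl$kept, genome,
                    seed = derive_seed(seed, "sample", s))
    count_per_gene(al, annotation)
  })
  counts <- do.call(cbind, cols)
  colnames(counts) <- names(fastq_files)
  list(counts = count_matrix(counts, condition), reports = reports)
}
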