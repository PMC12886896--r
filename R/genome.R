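#' Genome container
#'
#' A `genome` holds one uppercase DNA string per chromosome.  All coordinates
#' in the package are 0-based half-open against these sequences.
#'
#' @param sequences Named character vector of DNA sequences (A/C/G/T/N).
#' @return An object of class `genome`: a named character vector with
#'   uppercase sequences.
#' @export
genome <- function(sequences) {
  if (length(sequences) == 0) stop_format("genome has no sequences")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm)))
    stop_format("all chromosomes must have non-empty names")
  if (anyDuplicated(nm))
    stop_format("duplicate chromosome name: %s", nm[duplicated(nm)][1])
  seqs <- toupper(as.character(sequences))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop_format("non-IUPAC (A/C/G/T/N) characters in record '%s'",
                nm[bad][1])
  structure(stats::setNames(seqs, nm), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d chromosome(s), %s bp total\n",
              length(x), format(sum(chrom_lengths(x)), big.mark = ",")))
  for (nm in head(names(x), 6))
    cat(sprintf("  %s: %d bp\n", nm, nchar(x[[nm]])))
  if (length(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param g A `genome`.
#' @return Named integer vector of sequence lengths in bp.
#' @export
chrom_lengths <- function(g) {
  stats::setNames(nchar(unclass(g)), names(g))
}

#' Read a FASTA file into a genome
#'
#' Record names are truncated at the first whitespace; sequences are
#' uppercased.  Reads plain or gzip-compressed files.
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A [genome()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop_format("FASTA parse error in %s: %s",
                                                 path, conditionMessage(e)))
  if (length(ss) == 0) stop_format("empty FASTA file: %s", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop_format("duplicate FASTA record name: %s", nm[duplicated(nm)][1])
  genome(stats::setNames(as.character(ss), nm))
}

#' Write a genome to FASTA
#' @param g A [genome()].
#' @param path Output path (".gz" suffix compresses).
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(g))
  Biostrings::writeXStringSet(ss, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
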