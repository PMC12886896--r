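#' Feature-by-sample count matrix
#'
#' Non-negative integer counts with unique feature and sample ids and a
#' condition (group) label per sample.
#'
#' @param counts Integer matrix, features in rows, samples in columns, with
#'   dimnames.
#' @param condition Named character vector mapping every sample id to a group
#'   label.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_format("counts must have feature and sample names")
  if (anyDuplicated(rownames(counts)))
    stop_format("duplicate feature id: %s",
                rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop_format("duplicate sample id: %s",
                colnames(counts)[duplicated(colnames(counts))][1])
  if (any(counts < 0) || any(counts != floor(counts)))
    stop_format("counts must be non-negative integers")
  missing_cond <- setdiff(colnames(counts), names(condition))
  if (length(missing_cond))
    stop_format("sample without condition label: %s", missing_cond[1])
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 condition = condition[colnames(counts)]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d samples; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s (n=%d)", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Write a count matrix as TSV
#'
#' First column `feature_id`, one column per sample.  Condition labels are
#' not serialized; supply them again on read.
#'
#' @param cm A [count_matrix()].
#' @param path Output path (".gz" supported).
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(cm, path) {
  dt <- data.table::data.table(feature_id = rownames(cm$counts))
  for (s in colnames(cm$counts)) dt[[s]] <- cm$counts[, s]
  data.table::fwrite(dt, path, sep = "\t",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a count matrix from TSV
#' @param path TSV with header row of sample ids and a `feature_id` first
#'   column (any first-column name is accepted).
#' @param condition Named character vector of per-sample group labels.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path, condition) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1])
  if (!is.numeric(m) || any(m != floor(m)))
    stop_format("non-integer count in %s", path)
  rownames(m) <- as.character(dt[[1]])
  count_matrix(m, condition)
}

#' Read small-RNA reads from FASTQ
#'
#' Standard 4-line records; qualities are discarded, sequences uppercased.
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with columns `read_id` and `sequence`, of class
#'   `smallrna_reads`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  lines <- readLines(con <- gzfile(path)); close(con)
  if (length(lines) %% 4 != 0)
    stop_format("truncated FASTQ record at record %d of %s",
                length(lines) %/% 4 + 1L, path)
  if (length(lines) == 0)
    return(structure(data.frame(read_id = character(0),
                                sequence = character(0)),
                     class = c("smallrna_reads", "data.frame")))
  heads <- lines[seq(1, length(lines), by = 4)]
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  plus <- lines[seq(3, length(lines), by = 4)]
  bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop_format("malformed FASTQ record %d in %s", bad[1], path)
  if (any(grepl("[^ACGTN]", seqs)))
    stop_format("non-IUPAC base in FASTQ record %d of %s",
                which(grepl("[^ACGTN]", seqs))[1], path)
  structure(data.frame(read_id = sub("^@", "", sub("\\s.*$", "", heads)),
                       sequence = seqs, stringsAsFactors = FALSE),
            class = c("smallrna_reads", "data.frame"))
}

#' Write small-RNA reads as FASTQ
#'
#' Emits constant "I" qualities; this package never uses quality scores.
#'
#' @param reads data.frame with `read_id` and `sequence` columns.
#' @param path Output path (".gz" supported).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- rbind(paste0("@", reads$read_id),
                 reads$sequence,
                 "+",
                 vapply(nchar(reads$sequence),
                        function(n) strrep("I", n), character(1)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(as.vector(lines), con)
  close(con)
  invisible(path)
}
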