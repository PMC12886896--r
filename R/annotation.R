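#' Gene annotation container
#'
#' Holds gene and exon intervals in the package-wide 0-based half-open
#' convention.  Every gene carries at least one exon; exons must lie within
#' their gene and share its chromosome and strand.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one of `+`, `-`, `.`) and `biotype`.
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param lengths Optional named chromosome lengths used to bounds-check
#'   intervals.
#' @return Object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, exons, lengths = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  stopifnot(all(need %in% names(genes)), all(need %in% names(exons)))
  if (!"biotype" %in% names(genes)) genes$biotype <- "protein_coding"
  if (anyDuplicated(genes$gene_id))
    stop_format("duplicate gene_id: %s",
                genes$gene_id[duplicated(genes$gene_id)][1])
  if (any(genes$start < 0 | genes$start >= genes$end))
    stop_format("gene intervals must satisfy 0 <= start < end")
  if (!is.null(lengths)) {
    L <- lengths[genes$chrom]
    if (anyNA(L))
      stop_format("gene on unknown chromosome: %s",
                  genes$chrom[is.na(L)][1])
    if (any(genes$end > L))
      stop_format("gene interval exceeds chromosome length: %s",
                  genes$gene_id[genes$end > L][1])
  }
  orphan <- setdiff(exons$gene_id, genes$gene_id)
  if (length(orphan))
    stop_format("exon with unknown parent gene: %s", orphan[1])
  noexon <- setdiff(genes$gene_id, exons$gene_id)
  if (length(noexon))
    stop_format("gene without exons: %s", noexon[1])
  gidx <- match(exons$gene_id, genes$gene_id)
  if (any(exons$chrom != genes$chrom[gidx] |
          exons$strand != genes$strand[gidx]))
    stop_format("exon chrom/strand differs from its gene")
  if (any(exons$start < genes$start[gidx] | exons$end > genes$end[gidx]))
    stop_format("exon outside its gene interval")
  rownames(genes) <- NULL
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features, converts 1-based closed GFF3
#' coordinates to the internal 0-based half-open convention, and keeps genes
#' whose `biotype` attribute matches `biotype_filter`.  Exons are attached to
#' parents through their `Parent` attribute; exons whose parent cannot be
#' resolved are skipped with a warning.  Genes without exon children receive
#' a single exon spanning the gene, so single-line gene annotations remain
#' usable.
#'
#' @param path GFF3 file (optionally gzipped).
#' @param biotype_filter Keep genes with this biotype; `NULL` keeps all.
#' @param genome Optional [genome()]; when given, chromosome names are
#'   cross-checked and intervals bounds-checked.
#' @return A [genome_annotation()].
#' @export
read_gff3 <- function(path, biotype_filter = "protein_coding",
                      genome = NULL) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  lines <- readLines(con <- gzfile(path)); close(con)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9))
    stop_format("malformed GFF3 (expected 9 columns) at line %d of %s",
                body[nfield != 9][1], path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  biotype <- if ("biotype" %in% names(md)) as.character(md$biotype)
             else rep(NA_character_, length(gr))
  biotype[is.na(biotype)] <- "protein_coding"
  keep <- is_gene &
    (if (is.null(biotype_filter)) TRUE else biotype %in% biotype_filter)
  ids <- as.character(md$ID)
  genes <- data.frame(
    gene_id = ids[keep],
    chrom = as.character(GenomicRanges::seqnames(gr))[keep],
    start = GenomicRanges::start(gr)[keep] - 1L,
    end = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    biotype = biotype[keep],
    stringsAsFactors = FALSE)
  stranded <- genes$strand %in% c("+", "-")
  genes$strand[!stranded] <- "."

  is_exon <- md$type == "exon"
  parent <- rep(NA_character_, length(gr))
  if ("Parent" %in% names(md)) {
    pl <- md$Parent
    has_p <- lengths(pl) > 0
    parent[has_p] <- vapply(as.list(pl[has_p]), `[`, character(1), 1)
  }
  ex_keep <- is_exon & parent %in% genes$gene_id
  orphan <- is_exon & !(parent %in% ids[is_gene])
  if (any(orphan))
    warning(sprintf("skipped %d exon(s) without a resolvable parent gene",
                    sum(orphan)), call. = FALSE)
  exons <- data.frame(
    gene_id = parent[ex_keep],
    chrom = as.character(GenomicRanges::seqnames(gr))[ex_keep],
    start = GenomicRanges::start(gr)[ex_keep] - 1L,
    end = GenomicRanges::end(gr)[ex_keep],
    strand = as.character(GenomicRanges::strand(gr))[ex_keep],
    stringsAsFactors = FALSE)
  solo <- setdiff(genes$gene_id, exons$gene_id)
  if (length(solo)) {
    g <- genes[match(solo, genes$gene_id), ]
    exons <- rbind(exons, g[, c("gene_id", "chrom", "start", "end", "strand")])
  }
  lens <- NULL
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    extra <- setdiff(unique(genes$chrom), names(lens))
    if (length(extra))
      stop_format("annotation chromosome(s) absent from genome: %s",
                  paste(extra, collapse = ", "))
  }
  genome_annotation(genes, exons, lengths = lens)
}

#' Write a genome_annotation as GFF3
#'
#' Emits one `gene` line and one `exon` line per exon, converting back to
#' 1-based closed coordinates; the round trip through [read_gff3()] is the
#' identity on intervals.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  gl <- sprintf("%s\ttei22g\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$biotype)
  el <- sprintf("%s\ttei22g\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                e$chrom, e$start + 1L, e$end, e$strand, e$gene_id,
                seq_len(nrow(e)), e$gene_id)
  ord <- order(c(g$chrom, e$chrom), c(g$start, e$start),
               c(rep(0L, nrow(g)), rep(1L, nrow(e))))
  writeLines(c("##gff-version 3", c(gl, el)[ord]), path)
  invisible(path)
}

#' Transcription start sites
#'
#' The TSS is the 0-based position of the first transcribed base: the gene
#' `start` on the plus strand, `end - 1` on the minus strand.  Unstranded
#' genes have no TSS and raise an error.
#'
#' @param annotation A [genome_annotation()] (possibly subset to one gene).
#' @return Named integer vector of TSS positions, one per gene, with a
#'   `chrom` attribute carrying the matching chromosomes.
#' @export
tss_of <- function(annotation) {
  g <- annotation$genes
  if (any(g$strand == "."))
    stop_format("unstranded gene has no TSS: %s",
                g$gene_id[g$strand == "."][1])
  pos <- ifelse(g$strand == "+", g$start, g$end - 1L)
  structure(stats::setNames(as.integer(pos), g$gene_id), chrom = g$chrom)
}

# subset helper used internally
annotation_subset <- function(annotation, gene_ids) {
  genome_annotation(
    annotation$genes[annotation$genes$gene_id %in% gene_ids, , drop = FALSE],
    annotation$exons[annotation$exons$gene_id %in% gene_ids, , drop = FALSE])
}
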