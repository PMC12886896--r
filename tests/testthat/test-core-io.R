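# File formats and the internal coordinate convention.

test_that("FASTA reading parses, folds case, truncates names, and rejects
          duplicates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT"), f)
  g <- read_fasta(f)
  expect_identical(unclass(g)[["chr1"]], "ACGT")
  expect_identical(unname(chrom_lengths(g)["chr1"]), 4L)

  writeLines(c(">c1 some description", "acg", "t"), f)
  g <- read_fasta(f)
  expect_identical(names(g), "c1")
  expect_identical(unclass(g)[["c1"]], "ACGT")

  writeLines(c(">a", "ACGT", ">a", "GGCC"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty|parse")
})

test_that("FASTA write/read round trip preserves the genome", {
  g <- simulate_genome(2, 1500, seed = 5)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, f)
  g2 <- read_fasta(f)
  expect_identical(unclass(g), unclass(g2))
})

test_that("GFF3 import converts 1-based closed to 0-based half-open and
          filters by biotype", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1;biotype=protein_coding",
    "chr1\tsrc\texon\t101\t150\t.\t+\t.\tID=g1.e1;Parent=g1",
    "chr1\tsrc\texon\t161\t200\t.\t+\t.\tID=g1.e2;Parent=g1",
    "chr1\tsrc\tgene\t301\t400\t.\t-\t.\tID=g2;biotype=pseudogene",
    "chr1\tsrc\texon\t301\t400\t.\t-\t.\tID=g2.e1;Parent=g2"), f)
  ann <- read_gff3(f)
  expect_identical(ann$genes$gene_id, "g1")
  expect_identical(ann$genes$start, 100L)
  expect_identical(ann$genes$end, 200L)
  expect_identical(nrow(ann$exons), 2L)
  ann_all <- read_gff3(f, biotype_filter = NULL)
  expect_setequal(ann_all$genes$gene_id, c("g1", "g2"))
})

test_that("GFF3 write/read round trip is the identity on intervals", {
  g <- simulate_genome(1, 20000, seed = 3)
  ann <- simulate_annotation(g, 8, 400, 800, seed = 3)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, f)
  ann2 <- read_gff3(f, genome = g)
  ord <- match(ann$genes$gene_id, ann2$genes$gene_id)
  expect_identical(ann$genes$start, ann2$genes$start[ord])
  expect_identical(ann$genes$end, ann2$genes$end[ord])
  expect_identical(ann$genes$strand, ann2$genes$strand[ord])
})

test_that("exons without any resolvable parent are skipped with a
          warning", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1;biotype=protein_coding",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=g1.e1;Parent=g1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tID=orphan.e1;Parent=ghost"), f)
  expect_warning(ann <- read_gff3(f), "resolvable parent")
  expect_identical(nrow(ann$exons), 1L)
})

test_that("malformed GFF3 reports the offending line", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chr1\tsrc\tgene\t101"), f)
  expect_error(read_gff3(f), "line 3")
})

test_that("TSS is the 5' end of the gene on its strand", {
  ann <- toy_annotation(list("gp", "chr1", 100, 200, "+"),
                        list("gm", "chr1", 100, 200, "-"))
  tss <- tss_of(ann)
  expect_identical(unname(tss["gp"]), 100L)
  expect_identical(unname(tss["gm"]), 199L)
  ann_dot <- genome_annotation(
    data.frame(gene_id = "gx", chrom = "chr1", start = 0L, end = 10L,
               strand = ".", biotype = "protein_coding"),
    data.frame(gene_id = "gx", chrom = "chr1", start = 0L, end = 10L,
               strand = "."))
  expect_error(tss_of(ann_dot), "no TSS")
})

test_that("TSS mirrors under strand flip plus interval reversal", {
  L <- 1000L
  set.seed(42)
  for (i in 1:20) {
    s <- sample(0:900, 1); e <- s + sample(10:99, 1)
    tssp <- tss_of(toy_annotation(list("g", "c", s, e, "+")))
    tssm <- tss_of(toy_annotation(list("g", "c", L - e, L - s, "-")))
    expect_identical(unname(tssm), L - 1L - unname(tssp))
  }
})

test_that("bedGraph writer merges equal runs and round-trips exactly", {
  g <- toy_genome(chr1 = strrep("A", 30))
  tr <- binned_track(list(chr1 = c(1, 1, 2)), 10, chrom_lengths(g), "cpm")
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  expect_identical(readLines(f), c("chr1\t0\t20\t1", "chr1\t20\t30\t2"))
  tr2 <- read_bedgraph(f, g, 10, "cpm")
  expect_equal(tr2$values, tr$values)

  set.seed(9)
  g2 <- toy_genome(chrA = strrep("C", 95), chrB = strrep("G", 40))
  rnd <- binned_track(list(chrA = round(runif(10), 4),
                           chrB = round(runif(4), 4)),
                      10, chrom_lengths(g2), "log2_ratio")
  write_bedgraph(rnd, f)
  expect_equal(read_bedgraph(f, g2, 10, "log2_ratio")$values, rnd$values)

  writeLines(c("chr1\t0\t20\t1", "chr1\t10\t30\t2"), f)
  expect_error(read_bedgraph(f, g, 10), "overlap")
})

test_that("FASTQ reader handles records and rejects truncation", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "acgtacgtacgtacgtacgtg", "+", strrep("I", 21),
               "@r2 extra", "GACGT", "+", "IIIII"), f)
  r <- read_fastq(f)
  expect_identical(nrow(r), 2L)
  expect_identical(r$read_id, c("r1", "r2"))
  expect_identical(r$sequence[1], "ACGTACGTACGTACGTACGTG")
  writeLines(c("@r1", "ACGT", "+"), f)
  expect_error(read_fastq(f), "truncated")
})

test_that("FASTQ and count-matrix TSV writers round trip", {
  reads <- data.frame(read_id = c("a", "b"),
                      sequence = c("GACGTACGTACGTACGTACGT", "ACGTA"))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  expect_equal(read_fastq(f)$sequence, reads$sequence)

  cm <- count_matrix(matrix(c(1L, 2L, 3L, 4L), 2,
                            dimnames = list(c("f1", "f2"), c("s1", "s2"))),
                     c(s1 = "a", s2 = "b"))
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(cm, ft)
  cm2 <- read_counts_tsv(ft, c(s1 = "a", s2 = "b"))
  expect_identical(cm2$counts, cm$counts)
  ftxt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1", "f1\t1.5"), ftxt)
  expect_error(read_counts_tsv(ftxt, c(s1 = "a")), "non-integer")
})

test_that("BED read-set round trip preserves reads", {
  g <- simulate_genome(1, 5000, seed = 2)
  rs <- read_set(data.frame(chrom = "chr1", pos5 = c(10L, 400L),
                            strand = c("+", "-"), length = 50L),
                 chrom_lengths(g))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed_reads(rs, f)
  rs2 <- read_bed_reads(f, g)
  expect_equal(rs2$reads$pos5, rs$reads$pos5)
  expect_equal(rs2$reads$strand, rs$reads$strand)
  expect_identical(rs2$library_size, 2L)
})
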