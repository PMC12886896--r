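# 22G read-class filtering, exact-match mapping, and per-gene counting.

test_that("the 22G filter keeps 21-23 nt G-start reads and explains
          rejections", {
  reads <- data.frame(
    read_id = c("ok22", "a21", "g24", "g20", "n21", "g21"),
    sequence = c(paste0("G", strrep("A", 21)),          # 22 nt, G start
                 paste0("A", strrep("C", 20)),          # 21 nt, A start
                 paste0("G", strrep("C", 23)),          # 24 nt
                 paste0("G", strrep("C", 19)),          # 20 nt
                 paste0("N", strrep("C", 20)),          # N start fails
                 paste0("G", strrep("T", 20))))         # 21 nt, G start
  fl <- filter_22g(reads)
  expect_setequal(fl$kept$read_id, c("ok22", "g21"))
  expect_equal(unname(fl$report),
               c(2, 1, 1, 2))  # kept, too_short, too_long, non_g_start
  # idempotence
  fl2 <- filter_22g(fl$kept)
  expect_identical(fl2$kept$read_id, fl$kept$read_id)
  expect_equal(sum(fl$report), nrow(reads))
})

test_that("exact mapping finds unique loci on both strands and verifies
          the match invariant", {
  seqs <- paste(rep("ACGT", 25), collapse = "")
  g <- toy_genome(c1 = paste0("AACCGGTTACGTACGTACGTAGCTTGCA",
                              "TTTTGGGGCCCCAAAATTTTGGGGCCCC"))
  fwd_read <- substr(unclass(g)[["c1"]], 3, 24)   # unique 22-mer
  al <- map_exact(data.frame(read_id = "r1", sequence = fwd_read), g)
  expect_identical(nrow(al), 1L)
  expect_identical(al$start, 2L)
  expect_identical(al$end, 24L)
  expect_identical(al$strand, "+")
  expect_identical(al$n_hits, 1L)

  rc_read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd_read)))
  al_rc <- map_exact(data.frame(read_id = "r2", sequence = rc_read), g)
  expect_identical(al_rc$start, 2L)
  expect_identical(al_rc$strand, "-")
  expect_true(check_alignment_invariant(
    al_rc, data.frame(read_id = "r2", sequence = rc_read), g))

  # absent sequence is unmapped
  none <- map_exact(data.frame(read_id = "r3",
                               sequence = strrep("A", 21)), g)
  expect_identical(nrow(none), 0L)
})

test_that("multimappers get one seeded, reproducible alignment", {
  core <- "GATTACAGATTACAGATTACAG"   # 22 nt
  g <- toy_genome(c1 = paste0(strrep("C", 40), core, strrep("T", 40),
                              core, strrep("C", 40)))
  reads <- data.frame(read_id = "mm", sequence = core)
  a1 <- map_exact(reads, g, seed = 5)
  a2 <- map_exact(reads, g, seed = 5)
  expect_identical(nrow(a1), 1L)
  expect_identical(a1$n_hits, 2L)
  expect_identical(a1$start, a2$start)
  # both loci are reachable across seeds
  starts <- vapply(1:40, function(s) map_exact(reads, g, seed = s)$start,
                   integer(1))
  expect_setequal(unique(starts), c(40L, 102L))
  # beyond max_hits the read is discarded
  many <- toy_genome(c1 = paste(rep(core, 4), collapse = ""))
  lots <- map_exact(data.frame(read_id = "x", sequence = "GATTACAGATTACA"),
                    many, max_hits = 1)
  expect_identical(nrow(lots), 0L)
})

test_that("per-gene counting assigns by exon overlap and drops ambiguous
          alignments", {
  ann <- genome_annotation(
    data.frame(gene_id = c("gA", "gB"), chrom = "c1",
               start = c(100L, 180L), end = c(200L, 280L),
               strand = "+", biotype = "protein_coding"),
    data.frame(gene_id = c("gA", "gB"), chrom = "c1",
               start = c(100L, 180L), end = c(200L, 280L), strand = "+"))
  al <- structure(data.frame(
    read_id = c("in_a", "intergenic", "ambig", "in_b"),
    chrom = "c1",
    start = c(120L, 500L, 190L, 250L),
    end = c(142L, 522L, 212L, 272L),
    strand = "+", n_hits = 1L), class = c("alignments", "data.frame"))
  counts <- count_per_gene(al, ann)
  expect_identical(unname(counts["gA"]), 1L)
  expect_identical(unname(counts["gB"]), 1L)
  expect_identical(sum(counts), 2L)
})

test_that("synthetic 22G libraries are recovered exactly by the filter and
          mapped consistently", {
  g <- simulate_genome(1, 30000, seed = 13)
  ann <- simulate_annotation(g, 10, 500, 1000, seed = 13)
  truth <- plant_effects(ann, n_enriched = 2, seed = 13)
  for (fv in c(1, 0)) {
    sim <- simulate_smallrna_fastq(g, ann, truth, 500, frac_valid = fv,
                                   seed = 13)
    fl <- filter_22g(sim$reads)
    expect_identical(fl$report[["kept"]], sim$n_valid)
    expect_identical(nrow(fl$kept), if (fv == 1) 500L else 0L)
  }
  sim <- simulate_smallrna_fastq(g, ann, truth, 4000, frac_valid = 0.6,
                                 seed = 13)
  fl <- filter_22g(sim$reads)
  expect_identical(fl$report[["kept"]], sim$n_valid)
  expect_identical(sum(sim$gene_counts), sim$n_valid)
  # binomial 99.9% bound around 0.6 * 4000
  expect_lt(abs(sim$n_valid - 2400), 3.3 * sqrt(4000 * 0.6 * 0.4))
  # every kept read is the generator's valid read: ids agree
  expect_true(all(grepl(":valid", fl$kept$read_id)))
  al <- map_exact(fl$kept, g, seed = 13)
  expect_true(check_alignment_invariant(al, fl$kept, g))
  # per-gene counts from mapping match the recorded truth closely
  # (losses only from multimapped/ambiguous reads)
  cnt <- count_per_gene(al, ann)
  expect_gt(cor(as.numeric(cnt), as.numeric(sim$gene_counts)), 0.99)
})
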