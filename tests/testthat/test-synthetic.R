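# Generators: seeded determinism, recorded truth, and the statistical shape
# of the simulated libraries.

test_that("genome and annotation generators are pure functions of their
          seeds", {
  g1 <- simulate_genome(2, 5000, seed = 1)
  g2 <- simulate_genome(2, 5000, seed = 1)
  expect_identical(unclass(g1), unclass(g2))
  expect_identical(unname(chrom_lengths(g1)), c(5000L, 5000L))
  g3 <- simulate_genome(2, 5000, seed = 2)
  expect_false(identical(unclass(g1), unclass(g3)))

  a1 <- simulate_annotation(g1, 5, 500, 1000, seed = 4)
  a2 <- simulate_annotation(g1, 5, 500, 1000, seed = 4)
  expect_identical(a1$genes, a2$genes)
  # non-overlap
  ord <- order(a1$genes$chrom, a1$genes$start)
  gg <- a1$genes[ord, ]
  same_chrom <- gg$chrom[-1] == gg$chrom[-nrow(gg)]
  expect_true(all(gg$start[-1][same_chrom] >= gg$end[-nrow(gg)][same_chrom]))
  expect_error(simulate_annotation(g1, 1000, 500, 1000, seed = 1),
               "capacity")
})

test_that("ChIP input libraries are flat and IP libraries are TSS-peaked", {
  g <- simulate_genome(1, 100000, seed = 6)
  ann <- simulate_annotation(g, 30, 500, 1500, seed = 6)
  truth <- plant_effects(ann, n_enriched = 5, seed = 6)
  p <- chip_sim_params(depth = 1e5, seed = 6)

  inp <- simulate_chip_library(g, ann, truth, p, "wild_type", "input", 1)
  expect_identical(inp$library_size, nrow(inp$reads))
  tr <- cpm_normalize(bin_coverage(inp, g), inp$library_size)
  mm <- metagene_matrix(tr, ann, 500, 500)
  prof <- average_profile(mm)
  overall <- mean(unlist(tr$values))
  # Monte-Carlo flatness: profile stays within 3 SE of the global mean
  se <- sd(unlist(tr$values)) / sqrt(nrow(mm$values))
  expect_true(all(abs(prof - overall) < 3 * se + 1e-9))

  ip <- simulate_chip_library(g, ann, truth, p, "wild_type", "IP", 1)
  trip <- cpm_normalize(bin_coverage(ip, g), ip$library_size)
  pip <- average_profile(metagene_matrix(trip, ann, 500, 500))
  centre <- mean(pip[abs(as.numeric(names(pip))) < 100])
  edge <- mean(pip[abs(as.numeric(names(pip))) > 400])
  expect_gt(centre, 3 * edge)
})

test_that("a single enriched gene shows the planted mutant:wild-type IP
          ratio at the TSS", {
  g <- simulate_genome(1, 60000, seed = 9)
  ann <- simulate_annotation(g, 20, 500, 1500, seed = 9)
  # plant exactly one enriched gene at multiplier 3
  truth <- plant_effects(ann, n_enriched = 1, enrich_multiplier = 3,
                         seed = 9)
  gene <- names(truth$enriched_genes)
  p <- chip_sim_params(depth = 1e5, seed = 9)
  tss <- tss_of(ann)[gene]
  chrom <- attr(tss_of(ann), "chrom")[match(gene, ann$genes$gene_id)]
  count_win <- function(rs) {
    r <- rs$reads
    sum(r$chrom == chrom & abs(r$pos5 - tss) <= 500)
  }
  wt <- simulate_chip_library(g, ann, truth, p, "wild_type", "IP", 1)
  mut <- simulate_chip_library(g, ann, truth, p, "mutant", "IP", 1)
  ratio <- count_win(mut) / count_win(wt)
  # binomial error around 3 (mild composition correction with 1/20 genes)
  expect_gt(ratio, 2.4)
  expect_lt(ratio, 3.6)
  # null case: multiplier 1 makes genotypes exchangeable
  t0 <- plant_effects(ann, n_enriched = 5, enrich_multiplier = 1, seed = 9)
  wt0 <- simulate_chip_library(g, ann, t0, p, "wild_type", "IP", 1)
  mut0 <- simulate_chip_library(g, ann, t0, p, "mutant", "IP", 1)
  r0 <- count_win(mut0) / count_win(wt0)
  expect_gt(r0, 0.8); expect_lt(r0, 1.25)
})

test_that("small-RNA generator bookkeeping is exact and seeded", {
  g <- simulate_genome(1, 40000, seed = 14)
  ann <- simulate_annotation(g, 12, 500, 1000, seed = 14)
  truth <- plant_effects(ann, n_enriched = 2, n_sr_up = 3, n_sr_down = 3,
                         seed = 14)
  s1 <- simulate_smallrna_fastq(g, ann, truth, 3000, 0.7, "mutant",
                                seed = 20)
  s2 <- simulate_smallrna_fastq(g, ann, truth, 3000, 0.7, "mutant",
                                seed = 20)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$gene_counts, s2$gene_counts)
  expect_identical(sum(s1$gene_counts), s1$n_valid)
  # mutant multipliers shift sampling toward up genes
  s_wt <- simulate_smallrna_fastq(g, ann, truth, 30000, 1, "wild_type",
                                  seed = 21)
  s_mut <- simulate_smallrna_fastq(g, ann, truth, 30000, 1, "mutant",
                                   seed = 21)
  up <- truth$sr_up_genes
  frac_wt <- sum(s_wt$gene_counts[up]) / sum(s_wt$gene_counts)
  frac_mut <- sum(s_mut$gene_counts[up]) / sum(s_mut$gene_counts)
  expect_gt(frac_mut, 2 * frac_wt)
})

test_that("NB count simulator plants recorded effects and honours the
          dispersion", {
  null <- simulate_count_matrix(500, reps = 3, effect_log2fc = 0, seed = 2)
  expect_identical(null$truth$affected, character(0))
  m1 <- rowMeans(null$counts$counts[, 1:3])
  m2 <- rowMeans(null$counts$counts[, 4:6])
  expect_lt(abs(mean(m1) - mean(m2)), 2)

  rerun <- simulate_count_matrix(500, reps = 3, effect_log2fc = 0, seed = 2)
  expect_identical(null$counts$counts, rerun$counts$counts)

  pois <- simulate_count_matrix(2000, reps = 10, base_mean = 50,
                                dispersion = 0, seed = 3)
  x <- pois$counts$counts
  disp_hat <- median((apply(x, 1, var) - rowMeans(x)) / rowMeans(x)^2)
  expect_lt(abs(disp_hat), 0.02)

  eff <- simulate_count_matrix(1000, reps = 4, base_mean = 100,
                               dispersion = 0.05, effect_log2fc = 2,
                               frac_affected = 0.2, seed = 4)
  aff <- eff$truth$affected
  expect_identical(length(aff), 200L)
  x <- eff$counts$counts
  fc <- rowMeans(x[aff, 5:8]) / rowMeans(x[aff, 1:4])
  expect_equal(mean(fc), 4, tolerance = 0.15)
})
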