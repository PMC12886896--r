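# Metagene extraction, TSS-window scoring, the cumulative-80% classifier,
# and the across-genes Welch comparison.

test_that("flat tracks give flat metagene matrices and profiles", {
  g <- toy_genome(c1 = strrep("A", 10000))
  tr <- flat_track(chrom_lengths(g), 10, value = 1.5)
  ann <- toy_annotation(list("g1", "c1", 4000, 4500, "+"),
                        list("g2", "c1", 6000, 6500, "-"))
  mm <- metagene_matrix(tr, ann, 1000, 1000)
  expect_true(all(mm$values == 1.5))
  expect_equal(unname(average_profile(mm)), rep(1.5, 200))
  expect_identical(dim(mm$values), c(2L, 200L))
})

test_that("plus and minus genes over mirrored ramps give mirrored rows", {
  L <- 10000
  g <- toy_genome(c1 = strrep("A", L))
  bs <- 10
  ramp <- seq_len(L / bs)   # strictly increasing bin values
  tr <- binned_track(list(c1 = ramp), bs, chrom_lengths(g), "log2_ratio")
  # + gene with TSS at 4000 reads the ramp forward; - gene with TSS at
  # 3999 (last base of the adjacent bin) covers the same bins in reverse
  ann <- toy_annotation(list("gp", "c1", 4000, 4500, "+"),
                        list("gm", "c1", 3499, 4000, "-"))
  mm <- metagene_matrix(tr, ann, 1000, 1000)
  expect_equal(unname(mm$values["gm", ]), rev(unname(mm$values["gp", ])))
})

test_that("metagene marks off-chromosome positions missing and averages
          ignore them", {
  g <- toy_genome(c1 = strrep("A", 2000))
  tr <- flat_track(chrom_lengths(g), 10, value = 2)
  ann <- toy_annotation(list("g1", "c1", 30, 530, "+"))
  mm <- metagene_matrix(tr, ann, 1000, 1000)
  expect_true(all(is.na(mm$values[1, 1:97])))
  expect_true(all(mm$values[1, 98:200] == 2))
  expect_equal(unname(average_profile(mm)[98:200]), rep(2, 103))
  expect_error(metagene_matrix(tr, toy_annotation(
    list("g2", "cX", 100, 200, "+")), 1000, 1000), "absent")
})

test_that("tss_window_score averages the covering bins (brute force)", {
  g <- toy_genome(c1 = strrep("A", 5000))
  set.seed(21)
  vals <- round(runif(500), 3)
  tr <- binned_track(list(c1 = vals), 10, chrom_lengths(g), "log2_ratio")
  ann <- toy_annotation(list("g1", "c1", 2000, 2400, "+"),
                        list("g2", "c1", 2000, 2400, "-"),
                        list("edge", "c1", 100, 600, "+"))
  sc <- tss_window_score(tr, ann, halfwidth = 500)
  # brute force for g1: bins covering [1500, 2500)
  expect_equal(unname(sc["g1"]), mean(vals[151:250]))
  # g2 TSS at 2399: bins covering [1899, 2899) -> bins 190..290
  expect_equal(unname(sc["g2"]), mean(vals[190:290]))
  # edge gene truncated at chromosome start: [0, 600)
  expect_equal(unname(sc["edge"]), mean(vals[1:60]))
  # uniform track scores the constant everywhere
  flat <- flat_track(chrom_lengths(g), 10, value = 0.7)
  expect_equal(unname(tss_window_score(flat, ann, 500)),
               rep(0.7, 3))
})

test_that("strand flip leaves the symmetric TSS-window score unchanged", {
  g <- toy_genome(c1 = strrep("A", 4000))
  set.seed(33)
  tr <- binned_track(list(c1 = round(runif(400), 3)), 10,
                     chrom_lengths(g), "log2_ratio")
  # genes sharing the same TSS coordinate on opposite strands
  tssp <- 2000; gene_len <- 500
  ann <- toy_annotation(
    list("gp", "c1", tssp, tssp + gene_len, "+"),
    list("gm", "c1", tssp - gene_len + 1, tssp + 1, "-"))
  sc <- tss_window_score(tr, ann, 500)
  expect_equal(unname(sc["gp"]), unname(sc["gm"]))
})

test_that("build_score_table assembles scores and deltas for every gene", {
  g <- toy_genome(c1 = strrep("A", 5000))
  ann <- toy_annotation(list("g1", "c1", 1000, 1500, "+"),
                        list("g2", "c1", 3000, 3500, "-"))
  wt <- flat_track(chrom_lengths(g), 10, value = 0.5)
  mut <- flat_track(chrom_lengths(g), 10, value = 1.5)
  tab <- build_score_table(wt, mut, ann, 500)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$delta, c(1, 1))
  same <- build_score_table(wt, wt, ann, 500)
  expect_equal(same$delta, c(0, 0))
})

test_that("cumulative-fraction selection follows the worked examples", {
  tab <- data.frame(gene_id = c("A", "B", "C", "D", "E"),
                    score_wt = 0, score_mut = 0,
                    delta = c(5, 3, 1, 1, -2))
  expect_identical(select_enriched_genes(tab, 0.8), c("A", "B"))
  tie <- data.frame(gene_id = c("A", "B", "C"), score_wt = 0,
                    score_mut = 0, delta = c(4, 4, 2))
  expect_identical(select_enriched_genes(tie, 0.8), c("A", "B"))
  none <- data.frame(gene_id = c("A", "B"), score_wt = 0, score_mut = 0,
                     delta = c(-1, 0))
  expect_identical(select_enriched_genes(none, 0.8), character(0))
})

test_that("selection equals exhaustive minimal-prefix search on random
          tables and is minimal and monotone", {
  for (seed in 1:300) {
    tab <- random_score_table(sample(1:20, 1), seed)
    sel <- select_enriched_genes(tab, 0.8)
    expect_identical(sel, oracle_select(tab, 0.8))
    # minimality: dropping the last selected gene falls short
    if (length(sel) > 1) {
      kept <- tab$delta[match(sel[-length(sel)], tab$gene_id)]
      total <- sum(tab$delta[tab$delta > 0])
      expect_lt(sum(kept), 0.8 * total)
    }
    # monotone in fraction
    s5 <- select_enriched_genes(tab, 0.5)
    expect_true(all(s5 %in% sel))
  }
})

test_that("Welch comparison reproduces the hand-computed example and
          degenerate cases", {
  tab <- data.frame(gene_id = c("a", "b"), score_wt = c(0, 1),
                    score_mut = c(10, 11), delta = 10)
  res <- compare_scores(tab)
  expect_equal(res$t_statistic, -14.142, tolerance = 1e-3)
  expect_equal(res$df, 2)
  # oracle p from the t distribution
  expect_equal(res$p_value, 2 * pt(-14.1421356, df = 2), tolerance = 1e-4)

  eq <- data.frame(gene_id = c("a", "b"), score_wt = c(1, 1),
                   score_mut = c(1, 1), delta = 0)
  res_eq <- compare_scores(eq)
  expect_equal(res_eq$t_statistic, 0)
  expect_equal(res_eq$p_value, 1)

  diff <- data.frame(gene_id = c("a", "b"), score_wt = c(1, 1),
                     score_mut = c(2, 2), delta = 1)
  res_d <- compare_scores(diff)
  expect_true(res_d$degenerate)
  expect_equal(res_d$p_value, .Machine$double.xmin)

  # location invariance: shifting both columns leaves t unchanged
  set.seed(5)
  tb <- data.frame(gene_id = letters[1:6], score_wt = rnorm(6),
                   score_mut = rnorm(6), delta = 0)
  tb2 <- tb; tb2$score_wt <- tb2$score_wt + 3; tb2$score_mut <- tb2$score_mut + 3
  expect_equal(compare_scores(tb)$t_statistic,
               compare_scores(tb2)$t_statistic)
})
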