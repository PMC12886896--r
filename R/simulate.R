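# Synthetic data with recorded ground truth.  Every generator is a pure
# function of its parameters (seed included): reruns are byte-identical and
# every planted effect is recorded, so downstream stages can be tested by
# parameter recovery.

#' Simulate a random genome
#'
#' I.i.d. uniform A/C/G/T sequences; chromosomes are named `chr1..chrN`.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length Length of each chromosome in bp (>= 1000).
#' @param seed Integer seed; fixed seed gives a byte-identical genome.
#' @return A [genome()].
#' @export
simulate_genome <- function(n_chrom, chrom_length, seed) {
  stopifnot(n_chrom >= 1, chrom_length >= 1000)
  with_seed(derive_seed(seed, "genome"), {
    seqs <- vapply(seq_len(n_chrom), function(i)
      paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
            collapse = ""), character(1))
    genome(stats::setNames(seqs, paste0("chr", seq_len(n_chrom))))
  })
}

#' Simulate a gene annotation
#'
#' Lays out non-overlapping single-exon genes with random strands, evenly
#' spaced along the chromosomes (spacing bp between consecutive genes).
#'
#' @param genome A [genome()].
#' @param n_genes Number of genes.
#' @param gene_length Gene length in bp.
#' @param spacing Gap between consecutive genes in bp.
#' @param seed Integer seed (controls strands and chromosome assignment).
#' @return A [genome_annotation()] with gene ids `g0001..`.
#' @export
simulate_annotation <- function(genome, n_genes, gene_length = 500L,
                                spacing = 1000L, seed = 1L) {
  lens <- chrom_lengths(genome)
  slot <- gene_length + spacing
  capacity <- sum(lens %/% slot)
  if (n_genes > capacity)
    stop_format("annotation does not fit: capacity %d genes (%d requested)",
                capacity, n_genes)
  with_seed(derive_seed(seed, "annotation"), {
    per_chrom <- lens %/% slot
    # fill chromosomes proportionally, then trim to n_genes
    chrom <- rep(names(lens), per_chrom)[seq_len(n_genes)]
    idx <- unlist(lapply(names(lens), function(cn) seq_len(sum(chrom == cn))))
    start <- as.integer(spacing %/% 2 + (idx - 1L) * slot)
    width <- max(nchar(as.character(n_genes)), 4L)
    genes <- data.frame(
      gene_id = sprintf(paste0("g%0", width, "d"), seq_len(n_genes)),
      chrom = chrom,
      start = start,
      end = start + as.integer(gene_length),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      biotype = "protein_coding",
      stringsAsFactors = FALSE)
    exons <- genes[, c("gene_id", "chrom", "start", "end", "strand")]
    genome_annotation(genes, exons, lengths = lens)
  })
}

#' Plant ground-truth effects on an annotation
#'
#' Chooses the gene sets that downstream stages must recover: genes with a
#' mutant H3K4me3 gain at the TSS, genes with up/down-regulated 22G-RNA
#' levels (optionally overlapping the enriched set, as observed in real
#' mutants), and genes with an mRNA change.  Per-gene baseline 22G
#' abundances are drawn log-normally and recorded.
#'
#' @param annotation A [genome_annotation()].
#' @param n_enriched Genes with planted H3K4me3 gain.
#' @param enrich_multiplier Fold applied to mutant IP peak height (>= 1).
#' @param n_sr_up,n_sr_down Genes with planted 22G up/down effects.
#' @param sr_up_in_enriched,sr_down_in_enriched How many of the 22G-effect
#'   genes are drawn from the enriched set (the rest are disjoint from it).
#' @param sr_log2fc Magnitude of the planted 22G log2 fold-change.
#' @param n_de_up,n_de_down Genes with planted mRNA changes.
#' @param de_up_in_enriched mRNA-up genes drawn from the enriched set.
#' @param de_log2fc Magnitude of the planted mRNA log2 fold-change.
#' @param sr_abundance_sdlog Log-normal sd of baseline 22G gene abundances.
#' @param seed Integer seed.
#' @return Object of class `synthetic_truth`: a list with `enriched_genes`
#'   (named multiplier vector), `sr_up_genes`, `sr_down_genes`, `sr_log2fc`,
#'   `de_up_genes`, `de_down_genes`, `de_log2fc`, `sr_abundance` and
#'   `params`.
#' @export
plant_effects <- function(annotation, n_enriched, enrich_multiplier = 3,
                          n_sr_up = 0L, n_sr_down = 0L,
                          sr_up_in_enriched = 0L, sr_down_in_enriched = 0L,
                          sr_log2fc = 2, n_de_up = 0L, n_de_down = 0L,
                          de_up_in_enriched = 0L, de_log2fc = 2,
                          sr_abundance_sdlog = 0.6, seed = 1L) {
  stopifnot(enrich_multiplier >= 1,
            sr_up_in_enriched <= n_sr_up, sr_down_in_enriched <= n_sr_down,
            de_up_in_enriched <= n_de_up,
            sr_up_in_enriched + sr_down_in_enriched <= n_enriched)
  ids <- annotation$genes$gene_id
  stopifnot(n_enriched <= length(ids))
  with_seed(derive_seed(seed, "truth"), {
    enriched <- sort(sample(ids, n_enriched))
    pool <- setdiff(ids, enriched)
    sr_up <- c(sample(enriched, sr_up_in_enriched),
               sample(pool, n_sr_up - sr_up_in_enriched))
    pool2 <- setdiff(pool, sr_up)
    sr_down <- c(sample(setdiff(enriched, sr_up), sr_down_in_enriched),
                 sample(pool2, n_sr_down - sr_down_in_enriched))
    de_pool <- setdiff(ids, c())
    de_up <- c(sample(setdiff(enriched, c()), de_up_in_enriched),
               sample(setdiff(pool, c(sr_up, sr_down)),
                      n_de_up - de_up_in_enriched))
    de_down <- sample(setdiff(pool, c(sr_up, sr_down, de_up)), n_de_down)
    structure(list(
      enriched_genes = stats::setNames(rep(enrich_multiplier, n_enriched),
                                       enriched),
      sr_up_genes = sort(sr_up),
      sr_down_genes = sort(sr_down),
      sr_log2fc = sr_log2fc,
      de_up_genes = sort(de_up),
      de_down_genes = sort(de_down),
      de_log2fc = de_log2fc,
      sr_abundance = stats::setNames(
        stats::rlnorm(length(ids), meanlog = 0, sdlog = sr_abundance_sdlog),
        ids),
      params = list(seed = seed, n_enriched = n_enriched,
                    enrich_multiplier = enrich_multiplier,
                    n_sr_up = n_sr_up, n_sr_down = n_sr_down,
                    sr_log2fc = sr_log2fc)),
      class = "synthetic_truth")
  })
}

#' ChIP simulation parameters
#'
#' @param n_replicates Replicates per genotype.
#' @param depth Expected reads per library.
#' @param peak_width SD (bp) of Gaussian fragment-center placement around
#'   the TSS.
#' @param background_rate Relative background weight in reads/bp.
#' @param baseline_peak_height Relative expected reads per gene TSS peak.
#' @param mutant_multiplier Fold applied to enriched genes in the mutant
#'   (>= 1); overridden per gene by the truth record when present.
#' @param fragment_length Fragment extension length in bp.
#' @param read_length Nominal read length stored on simulated reads.
#' @param seed Integer seed.
#' @return A list of class `chip_sim_params`.
#' @details `background_rate * genome length` and the per-gene peak heights
#'   act as relative weights: expected totals are rescaled so that each
#'   library's expected size equals `depth`.  This reproduces the
#'   composition effect of CPM normalization (a genome-wide gain in the
#'   mutant slightly depresses all other positions), as in real libraries
#'   sequenced to fixed depth.
#' @export
chip_sim_params <- function(n_replicates = 2L, depth = 2e5,
                            peak_width = 150, background_rate = 0.05,
                            baseline_peak_height = 400,
                            mutant_multiplier = 3, fragment_length = 200L,
                            read_length = 50L, seed = 1L) {
  p <- list(n_replicates = n_replicates, depth = depth,
            peak_width = peak_width, background_rate = background_rate,
            baseline_peak_height = baseline_peak_height,
            mutant_multiplier = mutant_multiplier,
            fragment_length = fragment_length, read_length = read_length,
            seed = seed)
  if (any(unlist(p[1:8]) <= 0)) stop_format("all ChIP parameters must be positive")
  if (mutant_multiplier < 1) stop_format("mutant_multiplier must be >= 1")
  structure(p, class = "chip_sim_params")
}

#' Simulate one ChIP library
#'
#' Input libraries are uniform over the genome.  IP libraries mix uniform
#' background with per-gene reads whose fragment centers are Gaussian around
#' the TSS; in the mutant genotype, genes in `truth$enriched_genes` get
#' their peak height multiplied by the planted multiplier.  Component counts
#' are Poisson, strands random, and the whole library is seeded
#' deterministically from `(seed, genotype, role, replicate)`.
#'
#' @param genome A [genome()].
#' @param annotation A [genome_annotation()].
#' @param truth A `synthetic_truth` from [plant_effects()].
#' @param params A [chip_sim_params()].
#' @param genotype `"wild_type"` or `"mutant"`.
#' @param role `"IP"` or `"input"`.
#' @param replicate Replicate number (part of the seed).
#' @return A [read_set()].
#' @export
simulate_chip_library <- function(genome, annotation, truth, params,
                                  genotype = c("wild_type", "mutant"),
                                  role = c("IP", "input"), replicate = 1L) {
  genotype <- match.arg(genotype)
  role <- match.arg(role)
  lens <- chrom_lengths(genome)
  with_seed(derive_seed(params$seed, "chip", genotype, role, replicate), {
    if (role == "input") {
      n <- stats::rpois(1, params$depth)
      pos <- sample_uniform_positions(lens, n)
      reads <- data.frame(chrom = pos$chrom, pos5 = pos$pos,
                          strand = sample(c("+", "-"), n, replace = TRUE),
                          length = params$read_length,
                          stringsAsFactors = FALSE)
      return(read_set(reads, lens))
    }
    tss <- tss_of(annotation)
    tss_chrom <- attr(tss, "chrom")
    mult <- rep(1, length(tss))
    if (genotype == "mutant") {
      hit <- match(names(truth$enriched_genes), names(tss))
      mult[hit[!is.na(hit)]] <- truth$enriched_genes[!is.na(hit)]
    }
    h <- params$baseline_peak_height * mult
    B <- params$background_rate * sum(lens)
    sc <- params$depth / (B + sum(h))
    n_bg <- stats::rpois(1, B * sc)
    n_gene <- stats::rpois(length(h), h * sc)
    bg <- sample_uniform_positions(lens, n_bg)
    gi <- rep(seq_along(h), n_gene)
    centers <- stats::rnorm(length(gi), mean = tss[gi],
                            sd = params$peak_width)
    strand <- sample(c("+", "-"), n_bg + length(gi), replace = TRUE)
    half <- params$fragment_length %/% 2
    gene_strand <- strand[-seq_len(n_bg)]
    gene_pos5 <- ifelse(gene_strand == "+",
                        round(centers) - half, round(centers) + half)
    chrom <- c(bg$chrom, tss_chrom[gi])
    pos5 <- c(bg$pos, gene_pos5)
    pos5 <- pmin(pmax(pos5, 0), lens[chrom] - 1)
    reads <- data.frame(chrom = chrom, pos5 = as.integer(pos5),
                        strand = strand, length = params$read_length,
                        stringsAsFactors = FALSE)
    read_set(reads, lens)
  })
}

sample_uniform_positions <- function(lens, n) {
  chrom <- sample(names(lens), n, replace = TRUE,
                  prob = lens / sum(lens))
  pos <- as.integer(floor(stats::runif(n) * lens[chrom]))
  list(chrom = chrom, pos = pos)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a small-RNA library with a planted 22G class
#'
#' A fraction `frac_valid` of reads are genuine 22G-RNAs: 21-23 nt, 5' G,
#' antisense to exons of genes sampled with probabilities proportional to
#' the planted abundances (22G up/down multipliers applied for the mutant
#' genotype).  Template positions are chosen so the antisense read starts
#' with G naturally where the exon sequence allows; otherwise the 5' base is
#' overwritten and the read id flagged `:forced`.  The remaining reads
#' violate the class rule by length or 5' base.  Realized per-gene valid
#' counts are recorded exactly.
#'
#' @param genome A [genome()].
#' @param annotation A [genome_annotation()] (must have exons).
#' @param truth A `synthetic_truth` (supplies abundances and 22G effects).
#' @param n_reads Total reads in the library.
#' @param frac_valid Fraction of reads passing the 22G class rule.
#' @param genotype `"wild_type"` or `"mutant"` (applies planted 22G
#'   multipliers).
#' @param seed Integer seed.
#' @return List of class `smallrna_sim`: `reads` (data.frame `read_id`,
#'   `sequence`), `gene_counts` (named realized valid counts per gene),
#'   `n_valid`.
#' @export
simulate_smallrna_fastq <- function(genome, annotation, truth, n_reads,
                                    frac_valid = 0.9,
                                    genotype = c("wild_type", "mutant"),
                                    seed = 1L) {
  genotype <- match.arg(genotype)
  stopifnot(frac_valid >= 0, frac_valid <= 1)
  if (nrow(annotation$exons) == 0) stop_format("annotation has no exons")
  lens <- chrom_lengths(genome)
  genes <- annotation$genes
  with_seed(derive_seed(seed, "smallrna", genotype), {
    ab <- truth$sr_abundance[genes$gene_id]
    if (genotype == "mutant") {
      ab[genes$gene_id %in% truth$sr_up_genes] <-
        ab[genes$gene_id %in% truth$sr_up_genes] * 2^truth$sr_log2fc
      ab[genes$gene_id %in% truth$sr_down_genes] <-
        ab[genes$gene_id %in% truth$sr_down_genes] * 2^-truth$sr_log2fc
    }
    n_valid <- stats::rbinom(1, n_reads, frac_valid)
    gene_idx <- sample(seq_len(nrow(genes)), n_valid, replace = TRUE,
                       prob = ab)
    len <- sample(21:23, n_valid, replace = TRUE)
    seqs <- character(n_valid)
    forced <- logical(n_valid)
    needs_rc <- logical(n_valid)
    for (gi in unique(gene_idx)) {
      sel <- which(gene_idx == gi)
      ex <- annotation$exons[annotation$exons$gene_id == genes$gene_id[gi], ][1, ]
      exseq <- substr(unclass(genome)[[ex$chrom]], ex$start + 1L, ex$end)
      plus_gene <- ex$strand == "+"
      needs_rc[sel] <- plus_gene
      # anchor = template position of the read's 5' base (exon-local,
      # 1-based): base must be C on a + gene (read is revcomp) or G on a -
      # gene (read is the forward sequence).
      anchors <- if (plus_gene)
        which(strsplit(exseq, "")[[1]] == "C")
      else which(strsplit(exseq, "")[[1]] == "G")
      for (l in unique(len[sel])) {
        si <- sel[len[sel] == l]
        ok <- if (plus_gene) anchors[anchors >= l]
              else anchors[anchors <= nchar(exseq) - l + 1L]
        if (length(ok)) {
          a <- ok[sample.int(length(ok), length(si), replace = TRUE)]
          seqs[si] <- if (plus_gene) substring(exseq, a - l + 1L, a)
                      else substring(exseq, a, a + l - 1L)
        } else {
          a <- sample.int(nchar(exseq) - l + 1L, length(si), replace = TRUE)
          # no naturally G-starting template position: overwrite the 5'
          # base after orienting, flagged via read id
          s <- substring(exseq, a, a + l - 1L)
          if (plus_gene) s <- revcomp(s)
          seqs[si] <- paste0("G", substring(s, 2, l))
          forced[si] <- TRUE
          needs_rc[si] <- FALSE
        }
      }
    }
    if (any(needs_rc)) seqs[needs_rc] <- revcomp(seqs[needs_rc])
    valid_ids <- sprintf("sr%06d:%s:valid%s", seq_len(n_valid),
                         genes$gene_id[gene_idx],
                         ifelse(forced, ":forced", ""))

    n_inv <- n_reads - n_valid
    inv_seqs <- character(n_inv)
    if (n_inv > 0) {
      wrong_len <- stats::runif(n_inv) < 0.5
      ilen <- ifelse(wrong_len,
                     sample(c(18:20, 24:26), n_inv, replace = TRUE),
                     sample(21:23, n_inv, replace = TRUE))
      pos <- sample_uniform_positions(lens - max(ilen), n_inv)
      inv_seqs <- substring(unclass(genome)[pos$chrom], pos$pos + 1L,
                            pos$pos + ilen)
      # wrong-length reads may start with anything; 21-23 nt invalid reads
      # must not start with G
      nonG <- sample(c("A", "C", "T"), n_inv, replace = TRUE)
      inv_seqs[!wrong_len] <- paste0(nonG[!wrong_len],
                                     substr(inv_seqs[!wrong_len], 2,
                                            ilen[!wrong_len]))
    }
    inv_ids <- if (n_inv > 0)
      sprintf("sr%06d:none:invalid", n_valid + seq_len(n_inv))
    else character(0)

    ord <- sample(n_reads)
    reads <- data.frame(read_id = c(valid_ids, inv_ids)[ord],
                        sequence = c(seqs, inv_seqs)[ord],
                        stringsAsFactors = FALSE)
    counts <- stats::setNames(integer(nrow(genes)), genes$gene_id)
    tab <- table(genes$gene_id[gene_idx])
    counts[names(tab)] <- as.integer(tab)
    structure(list(reads = reads, gene_counts = counts, n_valid = n_valid),
              class = "smallrna_sim")
  })
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Counts are NB with mean `base_mean` and dispersion `dispersion`
#' (`dispersion = 0` gives Poisson).  A fraction `frac_affected` of features
#' have their group-2 mean multiplied by `2^effect_log2fc`; affected ids are
#' recorded.
#'
#' @param n_features Number of features.
#' @param groups Two group labels (group 2 carries the effect).
#' @param reps Replicates per group (>= 2).
#' @param base_mean Baseline NB mean.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param effect_log2fc Planted log2 fold-change for affected features.
#' @param frac_affected Fraction of affected features.
#' @param seed Integer seed.
#' @param feature_ids Optional feature names (default `f00001..`).
#' @return List with `counts` (a [count_matrix()]) and `truth` (list with
#'   `affected` ids and the parameter record).
#' @export
simulate_count_matrix <- function(n_features, groups = c("wild_type",
                                                         "mutant"),
                                  reps = 4L, base_mean = 100,
                                  dispersion = 0.1, effect_log2fc = 0,
                                  frac_affected = 0.1, seed = 1L,
                                  feature_ids = NULL) {
  stopifnot(dispersion >= 0, reps >= 2, length(groups) == 2)
  with_seed(derive_seed(seed, "counts"), {
    if (is.null(feature_ids))
      feature_ids <- sprintf("f%05d", seq_len(n_features))
    stopifnot(length(feature_ids) == n_features)
    affected <- if (effect_log2fc != 0)
      sort(sample(feature_ids, round(n_features * frac_affected)))
    else character(0)
    mu1 <- rep(base_mean, n_features)
    mu2 <- mu1 * ifelse(feature_ids %in% affected, 2^effect_log2fc, 1)
    draw <- function(mu, n) {
      m <- matrix(0L, n_features, n)
      for (j in seq_len(n))
        m[, j] <- if (dispersion == 0) stats::rpois(n_features, mu)
                  else stats::rnbinom(n_features, mu = mu,
                                      size = 1 / dispersion)
      m
    }
    counts <- cbind(draw(mu1, reps), draw(mu2, reps))
    rownames(counts) <- feature_ids
    colnames(counts) <- c(paste0(groups[1], "_", seq_len(reps)),
                          paste0(groups[2], "_", seq_len(reps)))
    condition <- stats::setNames(rep(groups, each = reps), colnames(counts))
    list(counts = count_matrix(counts, condition),
         truth = list(affected = affected,
                      params = list(n_features = n_features, groups = groups,
                                    reps = reps, base_mean = base_mean,
                                    dispersion = dispersion,
                                    effect_log2fc = effect_log2fc,
                                    frac_affected = frac_affected,
                                    seed = seed)))
  })
}
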