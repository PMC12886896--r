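# Independent brute-force oracles and tiny fixture builders shared across
# test files.  Oracles are deliberately naive (loops, enumeration) and never
# call the implementation they check.

# genome made of a literal sequence per chromosome
toy_genome <- function(...) {
  genome(c(...))
}

# single-exon annotation from a compact spec:
# list(gene_id, chrom, start, end, strand)
toy_annotation <- function(..., lengths = NULL) {
  rows <- list(...)
  genes <- do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], chrom = r[[2]],
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               strand = r[[5]], biotype = "protein_coding",
               stringsAsFactors = FALSE)))
  genome_annotation(genes,
                    genes[, c("gene_id", "chrom", "start", "end", "strand")],
                    lengths = lengths)
}

# constant-valued track over one or more chromosomes
flat_track <- function(lengths, bin_size = 10, value = 0,
                       scale = "log2_ratio") {
  vals <- lapply(lengths, function(L)
    rep(value, ceiling(L / bin_size)))
  binned_track(vals, bin_size, lengths, scale)
}

# brute force: per-bin fragment-overlap count by explicit interval checks
oracle_bin_counts <- function(frags, L, bin_size) {
  nb <- ceiling(L / bin_size)
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    b0 <- (b - 1) * bin_size
    b1 <- min(b * bin_size, L)
    for (i in seq_len(nrow(frags)))
      if (frags$start[i] < b1 && frags$end[i] > b0) out[b] <- out[b] + 1
  }
  out
}

# brute force: extend reads to fragments exactly per the documented rule
oracle_fragments <- function(reads, fragment_length, L) {
  start <- ifelse(reads$strand == "+", reads$pos5,
                  reads$pos5 - fragment_length + 1)
  end <- ifelse(reads$strand == "+", reads$pos5 + fragment_length,
                reads$pos5 + 1)
  data.frame(start = pmax(0, start), end = pmin(L, end))
}

# brute force: per-window fragment-overlap count
oracle_window_counts <- function(frags, L, window_size, step) {
  if (L < window_size) return(numeric(0))
  starts <- seq(0, L - window_size, by = step)
  vapply(starts, function(s) {
    sum(frags$start < s + window_size & frags$end > s)
  }, numeric(1))
}

# brute force: minimal delta-ordered prefix reaching fraction of the total
# positive delta (plain loop, no vectorized cumsum)
oracle_select <- function(table, fraction) {
  pos <- table[table$delta > 0, , drop = FALSE]
  if (nrow(pos) == 0) return(character(0))
  pos <- pos[order(-pos$delta, pos$gene_id), , drop = FALSE]
  total <- sum(pos$delta)
  acc <- 0
  for (k in seq_len(nrow(pos))) {
    acc <- acc + pos$delta[k]
    if (acc >= fraction * total - 1e-9 * max(1, total))
      return(pos$gene_id[seq_len(k)])
  }
  pos$gene_id
}

# brute force BH step-up: find largest k with p_(k) <= k/m * q, by scan
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[ord[k]] * m / k)
    q[ord[k]] <- val
    prev <- val
  }
  q
}

# exhaustive hypergeometric upper tail by enumerating overlap counts
oracle_hyper_upper <- function(n_overlap, n_a, n_b, N) {
  ks <- max(0, n_a + n_b - N):min(n_a, n_b)
  mass <- vapply(ks, function(k)
    choose(n_b, k) * choose(N - n_b, n_a - k) / choose(N, n_a), numeric(1))
  sum(mass[ks >= n_overlap])
}

# random gene score table for selection-rule tests
random_score_table <- function(n, seed) {
  set.seed(seed)
  structure(data.frame(
    gene_id = sprintf("g%02d", seq_len(n)),
    score_wt = round(rnorm(n), 2),
    score_mut = round(rnorm(n), 2),
    delta = round(rnorm(n, sd = 2), sample(0:2, 1)),
    stringsAsFactors = FALSE), class = c("gene_score_table", "data.frame"))
}

# verify every alignment's sequence-match invariant against the genome
check_alignment_invariant <- function(al, reads, genome) {
  gs <- unclass(genome)
  for (i in seq_len(nrow(al))) {
    seg <- substr(gs[[al$chrom[i]]], al$start[i] + 1, al$end[i])
    rd <- reads$sequence[match(al$read_id[i], reads$read_id)]
    hit <- if (al$strand[i] == "+") seg == rd
           else as.character(Biostrings::reverseComplement(
             Biostrings::DNAString(seg))) == rd
    if (!hit) return(FALSE)
  }
  TRUE
}
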