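# Pipeline orchestration: a single YAML config drives tracks -> enrich ->
# windows -> smallrna -> mrna -> integrate, with a manifest of hashed
# outputs and a one-command synthetic demo.

#' Read and validate a pipeline configuration
#'
#' Relative paths are resolved against the config file's directory.  Every
#' referenced input must exist and a seed is mandatory.
#'
#' @param path YAML configuration file (see [make_demo()] for a complete
#'   example).
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_format("no such config: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  cfg$genome <- resolve(cfg$genome)
  cfg$annotation <- resolve(cfg$annotation)
  if (is.null(cfg$seed)) stop_format("config must set a seed")
  if (is.null(cfg$output_dir)) stop_format("config must set output_dir")
  cfg$output_dir <- resolve(cfg$output_dir)
  for (p in c(cfg$genome, cfg$annotation))
    if (!is.null(p) && !file.exists(p))
      stop_format("config references missing file: %s", p)
  for (sec in c("chip", "smallrna")) {
    for (i in seq_along(cfg[[sec]]$samples)) {
      cfg[[sec]]$samples[[i]]$file <- resolve(cfg[[sec]]$samples[[i]]$file)
      if (!file.exists(cfg[[sec]]$samples[[i]]$file))
        stop_format("config references missing file: %s",
                    cfg[[sec]]$samples[[i]]$file)
    }
  }
  if (!is.null(cfg$mrna$counts)) {
    cfg$mrna$counts <- resolve(cfg$mrna$counts)
    if (!file.exists(cfg$mrna$counts))
      stop_format("config references missing file: %s", cfg$mrna$counts)
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

chip_sample_frame <- function(cfg) {
  s <- cfg$chip$samples
  data.frame(file = vapply(s, `[[`, character(1), "file"),
             genotype = vapply(s, `[[`, character(1), "genotype"),
             role = vapply(s, `[[`, character(1), "role"),
             replicate = vapply(s, function(x) as.integer(x$replicate),
                                integer(1)),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes tracks, enrichment scoring/selection, sliding-window
#' differential binding, 22G-RNA counting and testing, mRNA testing, and
#' gene-set integration, in that order, skipping stages whose inputs are
#' absent from the config.  All outputs land under the config's
#' `output_dir`; a manifest (file list, sizes, md5 hashes, parameter echo)
#' is written last.  Identical config and seed give identical manifest
#' hashes.  A stage failure aborts the run with the stage named and leaves
#' a `FAILED.<stage>` marker next to any partial outputs.
#'
#' @param config Path to a YAML config or a list from
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the per-stage results and the manifest
#'   data.frame.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_msg <- function(...) message(sprintf("[tei22g %s] %s",
                                           format(Sys.time(), "%H:%M:%S"),
                                           sprintf(...)))
  run_stage <- function(stage, fn) {
    log_msg("stage %s: start", stage)
    res <- tryCatch(fn(), error = function(e) {
      writeLines(conditionMessage(e), file.path(out,
                                                paste0("FAILED.", stage)))
      stop_format("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e))
    })
    log_msg("stage %s: done", stage)
    res
  }

  g <- read_fasta(cfg$genome)
  ann <- read_gff3(cfg$annotation, genome = g)
  results <- list(config = cfg)

  # ---- tracks ---------------------------------------------------------
  have_chip <- length(cfg$chip$samples) > 0
  if (have_chip) results$tracks <- run_stage("tracks", function() {
    dir.create(file.path(out, "tracks"), showWarnings = FALSE)
    p <- cfg$chip
    bs <- p$bin_size %||% 10L
    fl <- p$fragment_length %||% 200L
    pc <- p$pseudocount %||% 1.0
    samples <- chip_sample_frame(cfg)
    rs <- lapply(samples$file, read_bed_reads, genome = g)
    cpm <- lapply(seq_along(rs), function(i)
      cpm_normalize(bin_coverage(rs[[i]], g, bs, fl),
                    rs[[i]]$library_size))
    enr <- list()
    for (gt in unique(samples$genotype)) {
      ip <- mean_tracks(cpm[samples$genotype == gt & samples$role == "IP"])
      inp <- mean_tracks(cpm[samples$genotype == gt &
                               samples$role == "input"])
      write_bedgraph(ip, file.path(out, "tracks",
                                   sprintf("ip_cpm_%s.bedgraph", gt)))
      write_bedgraph(inp, file.path(out, "tracks",
                                    sprintf("input_cpm_%s.bedgraph", gt)))
      enr[[gt]] <- enrichment_ratio(ip, inp, pc,
                                    numerator_label = paste0("IP_", gt),
                                    denominator_label = paste0("input_", gt))
      write_bedgraph(enr[[gt]],
                     file.path(out, "tracks",
                               sprintf("enrichment_%s.bedgraph", gt)))
    }
    if (all(c("wild_type", "mutant") %in% names(enr))) {
      fc <- fold_change_track(enr$mutant, enr$wild_type)
      write_bedgraph(fc, file.path(out, "tracks",
                                   "fold_change_mutant_vs_wild_type.bedgraph"))
    }
    list(enrichment = enr, read_sets = stats::setNames(rs, samples$file),
         samples = samples)
  })

  # ---- enrich ---------------------------------------------------------
  if (have_chip &&
      all(c("wild_type", "mutant") %in% names(results$tracks$enrichment)))
    results$enrich <- run_stage("enrich", function() {
      dir.create(file.path(out, "enrich"), showWarnings = FALSE)
      e <- cfg$enrich
      hw <- e$halfwidth %||% 500L
      frac <- e$fraction %||% 0.8
      up <- e$upstream %||% 1000L
      dn <- e$downstream %||% 1000L
      enr <- results$tracks$enrichment
      tab <- build_score_table(enr$wild_type, enr$mutant, ann, hw)
      sel <- select_enriched_genes(tab, frac,
                                   min_wt_score = e$min_wt_score)
      ttest <- compare_scores(tab[tab$gene_id %in% sel, , drop = FALSE])
      st <- data.frame(gene_id = tab$gene_id,
                       score_wt = fmt_num(tab$score_wt),
                       score_mut = fmt_num(tab$score_mut),
                       delta = fmt_num(tab$delta))
      data.table::fwrite(st, file.path(out, "enrich", "score_table.tsv"),
                         sep = "\t")
      write_gene_list(sel, file.path(out, "enrich", "enriched_genes.txt"))
      prof <- data.frame(
        offset = metagene_matrix(enr$wild_type, ann, up, dn)$offsets,
        wild_type = fmt_num(average_profile(
          metagene_matrix(enr$wild_type, ann, up, dn))),
        mutant = fmt_num(average_profile(
          metagene_matrix(enr$mutant, ann, up, dn))))
      data.table::fwrite(prof, file.path(out, "enrich",
                                         "metagene_profile.tsv"), sep = "\t")
      writeLines(sprintf("t_statistic\t%s\ndf\t%s\np_value\t%s",
                         fmt_num(ttest$t_statistic), fmt_num(ttest$df),
                         format(ttest$p_value, digits = 6)),
                 file.path(out, "enrich", "tss_score_ttest.tsv"))
      list(score_table = tab, selected = sel, ttest = ttest)
    })

  # ---- windows --------------------------------------------------------
  if (have_chip) results$windows <- run_stage("windows", function() {
    dir.create(file.path(out, "windows"), showWarnings = FALSE)
    wcfg <- cfg$windows
    samples <- results$tracks$samples
    ip <- samples$role == "IP"
    grid <- make_windows(g, wcfg$window_size %||% 200L, wcfg$step %||% 10L)
    cond <- stats::setNames(samples$genotype[ip], samples$file[ip])
    cm <- window_counts(grid, results$tracks$read_sets[samples$file[ip]],
                        g, cond,
                        cfg$chip$fragment_length %||% 200L)
    de <- window_differential(cm, ref = "wild_type")
    max_fdr <- wcfg$max_fdr %||% 0.05
    sig <- write_windows_bed(grid, de,
                             file.path(out, "windows",
                                       "significant_windows.bed"), max_fdr)
    genes <- windows_to_genes(sig, ann, "tss_window",
                              cfg$enrich$halfwidth %||% 500L)
    write_gene_list(genes, file.path(out, "windows", "window_genes.txt"))
    list(grid_size = nrow(grid$windows), de = de, significant = sig,
         genes = genes)
  })

  # ---- smallrna -------------------------------------------------------
  have_sr <- length(cfg$smallrna$samples) > 0
  if (have_sr) results$smallrna <- run_stage("smallrna", function() {
    dir.create(file.path(out, "smallrna"), showWarnings = FALSE)
    s <- cfg$smallrna$samples
    files <- stats::setNames(vapply(s, `[[`, character(1), "file"),
                             vapply(s, function(x)
                               sprintf("%s_%s", x$genotype, x$replicate),
                               character(1)))
    cond <- stats::setNames(vapply(s, `[[`, character(1), "genotype"),
                            names(files))
    res <- count_22g_samples(files, g, ann, cond, seed = cfg$seed)
    write_counts_tsv(res$counts, file.path(out, "smallrna",
                                           "counts_22g.tsv"))
    rep_df <- data.frame(sample = names(res$reports),
                         do.call(rbind, res$reports))
    data.table::fwrite(rep_df, file.path(out, "smallrna",
                                         "filter_report.tsv"), sep = "\t")
    sf <- size_factors(res$counts)
    disp <- estimate_dispersion(res$counts, sf)
    de <- nb_wald_test(res$counts, sf, disp, ref = "wild_type")
    write_de_tsv(de, file.path(out, "smallrna", "de_22g.tsv"))
    calls <- call_de(de, cfg$smallrna$min_fold_change %||% 2,
                     cfg$smallrna$max_fdr %||% 0.05)
    write_gene_list(calls$up, file.path(out, "smallrna", "genes_22g_up.txt"))
    write_gene_list(calls$down,
                    file.path(out, "smallrna", "genes_22g_down.txt"))
    list(counts = res$counts, de = de, calls = calls)
  })

  # ---- mrna -----------------------------------------------------------
  if (!is.null(cfg$mrna$counts)) results$mrna <- run_stage("mrna", function() {
    dir.create(file.path(out, "mrna"), showWarnings = FALSE)
    cond <- unlist(cfg$mrna$conditions)
    cm <- read_counts_tsv(cfg$mrna$counts, cond)
    sf <- size_factors(cm)
    disp <- estimate_dispersion(cm, sf)
    de <- nb_wald_test(cm, sf, disp, ref = "wild_type")
    write_de_tsv(de, file.path(out, "mrna", "de_mrna.tsv"))
    calls <- call_de(de, cfg$mrna$min_fold_change %||% 1,
                     cfg$mrna$max_fdr %||% 0.01)
    write_gene_list(calls$up, file.path(out, "mrna", "genes_mrna_up.txt"))
    write_gene_list(calls$down,
                    file.path(out, "mrna", "genes_mrna_down.txt"))
    list(de = de, calls = calls)
  })

  # ---- integrate ------------------------------------------------------
  if (!is.null(results$enrich) && !is.null(results$smallrna))
    results$integrate <- run_stage("integrate", function() {
      dir.create(file.path(out, "integrate"), showWarnings = FALSE)
      universe <- ann$genes$gene_id
      enriched <- results$enrich$selected
      ct <- build_crosstab(enriched, results$smallrna$calls,
                           results$mrna$calls)
      ct_df <- data.frame(quantity = names(unclass(ct)),
                          count = unlist(unclass(ct)))
      data.table::fwrite(ct_df, file.path(out, "integrate", "crosstab.tsv"),
                         sep = "\t")
      sr_changed <- union(results$smallrna$calls$up,
                          results$smallrna$calls$down)
      ov <- overlap_sets(enriched, sr_changed, universe)
      ov_df <- data.frame(set_a = "enriched", set_b = "22g_changed",
                          n_a = ov$n_a, n_b = ov$n_b,
                          n_overlap = ov$n_overlap, n_union = ov$n_union,
                          p_hypergeometric = format(ov$p_hypergeometric,
                                                    digits = 6))
      data.table::fwrite(ov_df, file.path(out, "integrate",
                                          "pairwise_overlaps.tsv"),
                         sep = "\t")
      venn <- list(enriched_only = ov$n_a - ov$n_overlap,
                   both = ov$n_overlap,
                   changed_only = ov$n_b - ov$n_overlap)
      jsonlite::write_json(venn, file.path(out, "integrate",
                                           "venn_counts.json"),
                           auto_unbox = TRUE)
      list(crosstab = ct, overlap = ov)
    })

  files <- sort(list.files(out, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest\\.tsv$", files)]
  manifest <- data.frame(file = sub(paste0("^", out, "/?"), "", files),
                         bytes = file.size(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  data.table::fwrite(manifest, file.path(out, "manifest.tsv"), sep = "\t")
  log_msg("pipeline complete in %.1f s (%d output files)",
          as.numeric(difftime(Sys.time(), t0, units = "secs")),
          nrow(manifest))
  results$manifest <- manifest
  invisible(results)
}

#' Write a ground-truth table as TSV
#' @param truth A `synthetic_truth` from [plant_effects()].
#' @param annotation The matching [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, annotation, path) {
  ids <- annotation$genes$gene_id
  df <- data.frame(
    gene_id = ids,
    enriched = as.integer(ids %in% names(truth$enriched_genes)),
    multiplier = ifelse(ids %in% names(truth$enriched_genes),
                        truth$enriched_genes[ids], 1),
    sr_up = as.integer(ids %in% truth$sr_up_genes),
    sr_down = as.integer(ids %in% truth$sr_down_genes),
    mrna_up = as.integer(ids %in% truth$de_up_genes),
    mrna_down = as.integer(ids %in% truth$de_down_genes),
    sr_abundance = fmt_num(truth$sr_abundance[ids]))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a ground-truth table written by [write_truth_tsv()]
#' @param path Truth TSV.
#' @return data.frame with one row per gene.
#' @export
read_truth_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Generate a complete synthetic demo scenario
#'
#' Writes a toy genome (2 x 0.5 Mb), a 300-gene annotation, wild-type and
#' mutant ChIP libraries (IP and input, 2 replicates each), 22G small-RNA
#' FASTQ libraries (4 replicates per genotype), an mRNA count matrix, the
#' ground-truth table, and a ready-to-run pipeline config.  30 genes carry
#' a planted 3x mutant H3K4me3 gain at the TSS; 20 genes each carry planted
#' 22G up/down effects of log2FC +/-2 (half inside the enriched set); a
#' handful of genes carry mRNA changes.
#'
#' @param output_dir Directory to populate (created if needed).
#' @param seed Integer seed driving every generator.
#' @param n_genes,n_enriched Annotation size and planted enriched genes.
#' @param chip_depth Expected reads per ChIP library.
#' @param chip_replicates ChIP replicates per genotype.
#' @param sr_reads Reads per small-RNA library.
#' @param sr_replicates Small-RNA replicates per genotype.
#' @param n_sr_up,n_sr_down Planted 22G up/down genes.
#' @param enrich_multiplier Mutant peak-height fold for enriched genes.
#' @param sr_log2fc Planted 22G effect magnitude (log2).
#' @return Path to the written config YAML.
#' @export
make_demo <- function(output_dir, seed = 1L, n_genes = 300L,
                      n_enriched = 30L, chip_depth = 1e6,
                      chip_replicates = 2L, sr_reads = 5e4,
                      sr_replicates = 4L, n_sr_up = 20L, n_sr_down = 20L,
                      enrich_multiplier = 3, sr_log2fc = 2) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(output_dir, 2) != 0)
    stop_format("output_dir not writable: %s", output_dir)
  g <- simulate_genome(2, 5e5, seed)
  ann <- simulate_annotation(g, n_genes, gene_length = 500L,
                             spacing = 1000L, seed = seed)
  in_enr <- min(10L, n_enriched %/% 3L)
  truth <- plant_effects(ann, n_enriched = n_enriched,
                         enrich_multiplier = enrich_multiplier,
                         n_sr_up = n_sr_up, n_sr_down = n_sr_down,
                         sr_up_in_enriched = min(in_enr, n_sr_up),
                         sr_down_in_enriched = min(in_enr, n_sr_down),
                         sr_log2fc = sr_log2fc,
                         n_de_up = min(6L, n_genes %/% 10L),
                         n_de_down = min(2L, n_genes %/% 20L),
                         de_up_in_enriched = min(4L, in_enr,
                                                 n_genes %/% 10L),
                         seed = seed)
  write_fasta(g, file.path(output_dir, "genome.fa"))
  write_gff3(ann, file.path(output_dir, "annotation.gff3"))
  write_truth_tsv(truth, ann, file.path(output_dir, "truth.tsv"))

  params <- chip_sim_params(n_replicates = chip_replicates,
                            depth = chip_depth,
                            mutant_multiplier = enrich_multiplier,
                            seed = seed)
  dir.create(file.path(output_dir, "chip"), showWarnings = FALSE)
  chip_samples <- list()
  for (gt in c("wild_type", "mutant")) for (role in c("IP", "input"))
    for (rep in seq_len(chip_replicates)) {
      rs <- simulate_chip_library(g, ann, truth, params, gt, role, rep)
      f <- sprintf("chip/%s_%s_%d.bed", gt, role, rep)
      write_bed_reads(rs, file.path(output_dir, f))
      chip_samples[[length(chip_samples) + 1L]] <-
        list(file = f, genotype = gt, role = role, replicate = rep)
    }

  dir.create(file.path(output_dir, "smallrna"), showWarnings = FALSE)
  sr_samples <- list()
  for (gt in c("wild_type", "mutant")) for (rep in seq_len(sr_replicates)) {
    sim <- simulate_smallrna_fastq(g, ann, truth, n_reads = sr_reads,
                                   frac_valid = 0.9, genotype = gt,
                                   seed = derive_seed(seed, "srlib", gt,
                                                      rep))
    f <- sprintf("smallrna/%s_%d.fastq", gt, rep)
    write_fastq(sim$reads, file.path(output_dir, f))
    sr_samples[[length(sr_samples) + 1L]] <-
      list(file = f, genotype = gt, replicate = rep)
  }

  mrna <- simulate_count_matrix(
    n_features = n_genes, reps = 4L, base_mean = 200, dispersion = 0.05,
    effect_log2fc = 0, seed = derive_seed(seed, "mrna"),
    feature_ids = ann$genes$gene_id)
  counts <- mrna$counts$counts
  # planted mRNA effects on the truth-designated genes
  eff <- with_seed(derive_seed(seed, "mrna-effects"), {
    m <- counts
    mut_cols <- grep("^mutant", colnames(m))
    for (gene in truth$de_up_genes)
      m[gene, mut_cols] <- stats::rpois(length(mut_cols),
                                        200 * 2^truth$de_log2fc)
    for (gene in truth$de_down_genes)
      m[gene, mut_cols] <- stats::rpois(length(mut_cols),
                                        200 * 2^-truth$de_log2fc)
    m
  })
  mrna_cm <- count_matrix(eff, mrna$counts$condition)
  write_counts_tsv(mrna_cm, file.path(output_dir, "mrna_counts.tsv"))

  cfg <- list(
    seed = as.integer(seed),
    output_dir = "results",
    genome = "genome.fa",
    annotation = "annotation.gff3",
    chip = list(bin_size = 10L, fragment_length = 200L, pseudocount = 1.0,
                samples = chip_samples),
    enrich = list(halfwidth = 500L, fraction = 0.8, upstream = 1000L,
                  downstream = 1000L),
    windows = list(window_size = 200L, step = 10L, max_fdr = 0.05),
    smallrna = list(min_fold_change = 2, max_fdr = 0.05,
                    samples = sr_samples),
    mrna = list(counts = "mrna_counts.tsv", min_fold_change = 1,
                max_fdr = 0.01,
                conditions = as.list(mrna_cm$condition)))
  cfg_path <- file.path(output_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
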