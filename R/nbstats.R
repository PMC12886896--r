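# Count-based differential statistics shared by the sliding-window,
# 22G-RNA, and mRNA stages: size factors, moderated dispersion, NB Wald
# test, BH correction, and threshold-based call sets.

norm_counts <- function(cm) {
  sweep(cm$counts, 2, attr(cm, "size_factors") %||% 1, "/")
}

#' Median-of-ratios size factors
#'
#' Per feature, the geometric mean across samples; per sample, the median
#' over features (with a positive geometric mean) of count / geometric
#' mean.  Scale-equivariant: doubling one sample's counts doubles its
#' factor.
#'
#' @param cm A [count_matrix()] (or plain integer matrix).
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  all_pos <- rowSums(counts <= 0) == 0
  if (!any(all_pos))
    stop_format(paste("no feature has positive counts in every sample;",
                      "consider total-count normalization"))
  logg <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - logg)))
  stats::setNames(sf, colnames(counts))
}

#' Moderated method-of-moments dispersion
#'
#' Per feature, a method-of-moments negative-binomial dispersion
#' `alpha = (s^2 - m) / m^2` is computed from normalized counts within each
#' condition group (df-weighted across groups, so group mean differences do
#' not inflate the estimate).  Per-feature estimates are then shrunk toward
#' the across-feature median with prior weight `prior_df` (empirical-Bayes
#' moderation, as is standard for small-replicate RNA-seq designs), and
#' floored at `1e-8`.  `prior_df = 0` gives the raw per-feature estimator.
#'
#' @param cm A [count_matrix()].
#' @param size_factors Per-sample factors from [size_factors()].
#' @param condition Optional group labels (defaults to the count matrix's
#'   condition); `NULL` treats all samples as one group.
#' @param prior_df Prior degrees of freedom for moderation.
#' @return Named per-feature dispersion vector with attributes `df_prior`
#'   and `df_residual` (used by [nb_wald_test()]'s t reference).
#' @export
estimate_dispersion <- function(cm, size_factors, condition = cm$condition,
                                prior_df = 12) {
  counts <- cm$counts
  stopifnot(ncol(counts) >= 2)
  nc <- sweep(counts, 2, size_factors, "/")
  if (is.null(condition))
    condition <- stats::setNames(rep("all", ncol(counts)),
                                 colnames(counts))
  groups <- split(seq_len(ncol(counts)), condition[colnames(counts)])
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups))
    stop_format("dispersion estimation needs a group with >= 2 samples")
  num <- 0
  df_res <- 0
  for (idx in groups) {
    x <- nc[, idx, drop = FALSE]
    m <- rowMeans(x)
    v <- rowSums((x - m)^2) / (length(idx) - 1)
    w <- length(idx) - 1
    num <- num + w * (v - m) / pmax(m, 1e-8)^2
    df_res <- df_res + w
  }
  raw <- num / df_res
  central <- max(stats::median(raw[is.finite(raw)]), 0)
  mod <- (prior_df * central + df_res * raw) / (prior_df + df_res)
  structure(stats::setNames(pmax(mod, 1e-8), rownames(counts)),
            df_prior = prior_df, df_residual = df_res)
}

#' Negative-binomial Wald test between two groups
#'
#' Per feature: group means of size-factor-normalized counts with a 0.5
#' pseudocount; `log2fc = log2(mean2 / mean1)` (second condition level vs
#' first); the standard error comes from the delta method applied to the NB
#' variance `mu + alpha mu^2` of each sample; the Wald statistic is
#' referred to a t distribution with `df_prior + df_residual` degrees of
#' freedom when the dispersions carry those attributes (see
#' [estimate_dispersion()]), otherwise to a standard normal.
#'
#' @param cm A [count_matrix()] with exactly two condition groups, each with
#'   at least 2 samples.
#' @param size_factors Per-sample factors from [size_factors()].
#' @param dispersions Per-feature dispersions from [estimate_dispersion()].
#' @param condition Optional group labels (defaults to the matrix's);
#'   the first unique label is the reference (group 1).
#' @param ref Optional explicit reference level.
#' @return data.frame of class `de_result` with columns `feature_id`,
#'   `base_mean`, `log2fc`, `se`, `p_value`, `q_value`, in input feature
#'   order.
#' @export
nb_wald_test <- function(cm, size_factors, dispersions,
                         condition = cm$condition, ref = NULL) {
  counts <- cm$counts
  condition <- condition[colnames(counts)]
  lev <- unique(condition)
  if (length(lev) != 2)
    stop_format("nb_wald_test needs exactly two groups (got %d)",
                length(lev))
  if (!is.null(ref)) lev <- c(ref, setdiff(lev, ref))
  g1 <- which(condition == lev[1])
  g2 <- which(condition == lev[2])
  if (length(g1) < 2 || length(g2) < 2)
    stop_format("each group needs >= 2 samples")
  nc <- sweep(counts, 2, size_factors, "/")
  a <- dispersions[rownames(counts)]
  m1 <- rowMeans(nc[, g1, drop = FALSE])
  m2 <- rowMeans(nc[, g2, drop = FALSE])
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  # delta method: Var(log2 mean_g) ~= Var(mean_g) / ((mean_g + 0.5) ln2)^2,
  # Var(mean_g) = sum over samples of (mu + alpha mu^2) / n^2
  v1 <- (m1 + a * m1^2) / length(g1)
  v2 <- (m2 + a * m2^2) / length(g2)
  se <- sqrt(v1 / (m1 + 0.5)^2 + v2 / (m2 + 0.5)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  df <- attr(dispersions, "df_prior") %||% Inf
  if (is.finite(df)) df <- df + (attr(dispersions, "df_residual") %||%
                                   (length(g1) + length(g2) - 2))
  p <- if (is.finite(df)) 2 * stats::pt(-abs(z), df = df)
       else 2 * stats::pnorm(-abs(z))
  p[se == 0 & log2fc == 0] <- 1
  structure(data.frame(feature_id = rownames(counts),
                       base_mean = rowMeans(nc),
                       log2fc = log2fc, se = se, p_value = p,
                       q_value = bh_adjust(p), row.names = NULL,
                       stringsAsFactors = FALSE),
            groups = lev, class = c("de_result", "data.frame"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment with monotonicity enforcement; order preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_format("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Threshold-based differential call sets
#'
#' `up` features satisfy `q <= max_fdr` and `log2fc > log2(min_fold_change)`;
#' `down` mirrors with the negated bound.  The default thresholds are the
#' conventional fold change > 2 at 5% FDR.
#'
#' @param results A `de_result` data.frame (needs `feature_id`, `log2fc`,
#'   `q_value`).
#' @param min_fold_change Minimum linear fold change (>= 1).
#' @param max_fdr FDR ceiling applied to `q_value`.
#' @return List of class `de_call_set` with `up`, `down` (character
#'   vectors, disjoint by construction) and `thresholds`.
#' @export
call_de <- function(results, min_fold_change = 2, max_fdr = 0.05) {
  if (min_fold_change < 1) stop_format("min_fold_change must be >= 1")
  r <- as.data.frame(results)
  lfc <- log2(min_fold_change)
  sig <- r$q_value <= max_fdr
  structure(list(up = r$feature_id[sig & r$log2fc > lfc],
                 down = r$feature_id[sig & r$log2fc < -lfc],
                 thresholds = list(min_fold_change = min_fold_change,
                                   max_fdr = max_fdr)),
            class = "de_call_set")
}

#' @export
print.de_call_set <- function(x, ...) {
  cat(sprintf("<de_call_set> %d up, %d down (FC > %g, FDR <= %g)\n",
              length(x$up), length(x$down), x$thresholds$min_fold_change,
              x$thresholds$max_fdr))
  invisible(x)
}

#' Write a DE result table as TSV
#' @param results A `de_result` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(results, path) {
  r <- as.data.frame(results)
  out <- data.frame(feature_id = r$feature_id,
                    base_mean = fmt_num(r$base_mean),
                    log2fc = fmt_num(r$log2fc), se = fmt_num(r$se),
                    p_value = fmt_num(r$p_value),
                    q_value = fmt_num(r$q_value))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
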