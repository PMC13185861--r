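#' Construct a pooled count matrix
#'
#' Genes x pools matrix of normalised counts (FPKM) where each pool value is
#' the mean expression of the individuals pooled into that library, together
#' with the group label and the number of pooled individuals per library.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), pools
#'   in columns (colnames = pool names); all values >= 0.
#' @param group Character vector of group labels, one per pool.
#' @param pool_n Integer vector, individuals per pool (>= 1), one per pool.
#' @return A `pooled_counts` object.
#' @export
pooled_counts <- function(values, group, pool_n) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("count values must be >= 0")
  if (length(group) != ncol(values) || length(pool_n) != ncol(values))
    stop("group and pool_n must have one entry per pool")
  if (any(pool_n < 1)) stop("pool_n must be >= 1")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("gene%05d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0(group, stats::ave(seq_along(group), group, FUN = seq_along))
  structure(list(values = values, group = as.character(group),
                 pool_n = as.numeric(pool_n)),
            class = "pooled_counts")
}

#' @export
print.pooled_counts <- function(x, ...) {
  cat(sprintf("<pooled_counts> %d genes x %d pools (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' FPKM normalisation
#'
#' `FPKM = counts * 1e9 / (gene_length_bp * library_size)`.
#'
#' @param raw_counts Genes x pools matrix of read counts.
#' @param gene_lengths Gene lengths in bp (> 0), one per gene.
#' @param library_sizes Mapped reads per pool (> 0), one per pool; default
#'   `colSums(raw_counts)`.
#' @param group,pool_n Optional pool metadata; when both are given a
#'   [pooled_counts()] object is returned, otherwise a plain matrix.
#' @return FPKM matrix or `pooled_counts`.
#' @export
compute_fpkm <- function(raw_counts, gene_lengths,
                         library_sizes = colSums(raw_counts),
                         group = NULL, pool_n = NULL) {
  raw_counts <- as.matrix(raw_counts)
  if (length(gene_lengths) != nrow(raw_counts))
    stop("gene_lengths must have one entry per gene")
  if (length(library_sizes) != ncol(raw_counts))
    stop("library_sizes must have one entry per pool")
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  fpkm <- raw_counts * 1e9 / outer(as.numeric(gene_lengths), as.numeric(library_sizes))
  dimnames(fpkm) <- dimnames(raw_counts)
  if (!is.null(group) && !is.null(pool_n)) pooled_counts(fpkm, group, pool_n) else fpkm
}

#' Zero-count gene filter
#'
#' Discards every gene with a zero in any of the selected pools, so that
#' downstream coefficients of variation are defined for all retained genes.
#' Pools can be restricted (e.g. to drop libraries sequenced in a different
#' batch) before the filter is applied.
#'
#' @param pc A [pooled_counts()].
#' @param pools Optional character vector of pool names (or integer indices)
#'   to keep; default all.
#' @return A filtered `pooled_counts` restricted to the selected pools, with
#'   attribute `n_filtered` = number of genes removed.
#' @export
filter_genes <- function(pc, pools = NULL) {
  stopifnot(inherits(pc, "pooled_counts"))
  sel <- if (is.null(pools)) seq_len(ncol(pc$values)) else pools
  v <- pc$values[, sel, drop = FALSE]
  if (ncol(v) < 2L) stop("need at least 2 pools after selection")
  keep <- rowSums(v <= 0) == 0L
  if (!any(keep)) stop("no genes survive the zero-count filter")
  out <- pooled_counts(v[keep, , drop = FALSE],
                       group = pc$group[if (is.character(sel))
                         match(sel, colnames(pc$values)) else sel],
                       pool_n = pc$pool_n[if (is.character(sel))
                         match(sel, colnames(pc$values)) else sel])
  attr(out, "n_filtered") <- sum(!keep)
  out
}

#' Individual-level coefficient of variation from pool replicates
#'
#' Because each pool value is the mean of the `n` individuals in that pool,
#' the standard deviation across a group's pools estimates the standard
#' error of the mean, `SE = sigma / sqrt(n)`. Multiplying the SE by
#' `sqrt(n)` recovers the individual-level standard deviation `sigma`, and
#' dividing by the mean pool value gives the individual-level coefficient of
#' variation. The grand mean across *all* pools of the matrix is stored for
#' abundance ranking.
#'
#' @param pc A filtered [pooled_counts()] containing the pools of both
#'   groups under comparison.
#' @param group Group label whose CV to compute (>= 2 pools).
#' @param n_eff_policy `"mean"` (default): `n` is the arithmetic mean of the
#'   group's per-pool individual counts; `"fixed"`: use `n_eff`.
#' @param n_eff Fixed `n` when `n_eff_policy = "fixed"`.
#' @return A `gene_cv` data.frame with columns `gene`, `mean` (group pool
#'   mean), `se`, `sigma`, `cv`, `grand_mean`; attributes `group` and
#'   `n_eff`.
#' @export
pooled_cv <- function(pc, group, n_eff_policy = c("mean", "fixed"), n_eff = NULL) {
  stopifnot(inherits(pc, "pooled_counts"))
  n_eff_policy <- match.arg(n_eff_policy)
  cols <- pc$group == group
  if (sum(cols) < 2L) stop("need at least 2 pools in the group for a CV")
  v <- pc$values[, cols, drop = FALSE]
  ne <- if (n_eff_policy == "fixed") {
    stop_if_not_scalar_number(n_eff, "n_eff", positive = TRUE)
    n_eff
  } else mean(pc$pool_n[cols])
  m <- rowMeans(v)
  se <- apply(v, 1L, stats::sd)      # sample sd across pools (n-1 denominator)
  sigma <- se * sqrt(ne)
  structure(data.frame(gene = rownames(pc$values),
                       mean = m, se = se, sigma = sigma, cv = sigma / m,
                       grand_mean = rowMeans(pc$values),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("gene_cv", "data.frame"), group = group, n_eff = ne)
}

#' Abundance-ranked percentile-bin CV dominance
#'
#' Genes are ranked by their grand mean abundance (across all pools of both
#' groups) from highest to lowest and partitioned into `n_bins` contiguous
#' bins of near-equal size (sizes differ by at most 1; the larger bins sit
#' at the high-abundance end). Per bin, the fraction of genes whose group-1
#' CV strictly exceeds the group-2 CV is reported; ties count as "not
#' greater".
#'
#' @param genecv_group1,genecv_group2 `gene_cv` tables from [pooled_cv()]
#'   over the same filtered gene set.
#' @param cfg A [permutation_config()] (only `n_bins` is used here).
#' @return A `bin_fractions` data.frame with columns `bin`, `n_genes`,
#'   `fraction`; attributes carry the ranked dominance indicators for
#'   [permutation_test()].
#' @export
bin_fractions <- function(genecv_group1, genecv_group2, cfg = permutation_config()) {
  stopifnot(inherits(cfg, "permutation_config"))
  if (!identical(genecv_group1$gene, genecv_group2$gene))
    stop("the two gene_cv tables must cover the same genes in the same order")
  g <- nrow(genecv_group1)
  if (g < cfg$n_bins) stop("fewer genes than bins")
  ord <- order(genecv_group1$grand_mean, decreasing = TRUE)
  gt <- genecv_group1$cv[ord] > genecv_group2$cv[ord]
  sizes <- bin_sizes(g, cfg$n_bins)
  binidx <- rep(seq_len(cfg$n_bins), times = sizes)
  frac <- as.numeric(rowsum(as.numeric(gt), binidx)) / sizes
  structure(data.frame(bin = seq_len(cfg$n_bins), n_genes = sizes,
                       fraction = frac),
            class = c("bin_fractions", "data.frame"),
            gt = gt, bin_index = binidx, sizes = sizes,
            groups = c(attr(genecv_group1, "group"), attr(genecv_group2, "group")))
}

bin_sizes <- function(g, n_bins) {
  base <- g %/% n_bins
  rem <- g %% n_bins
  base + as.integer(seq_len(n_bins) <= rem)
}

#' Permutation test configuration
#'
#' @param n_bins Number of abundance percentile bins (>= 2). Default 100.
#' @param n_perm Number of pair-preserving shuffles (>= 100). Default 1000.
#' @param alpha Significance level. Default 0.05.
#' @param seed Integer RNG seed for the shuffles.
#' @return A `permutation_config` object.
#' @export
permutation_config <- function(n_bins = 100L, n_perm = 1000L, alpha = 0.05,
                               seed = 1L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(n_bins = as.integer(n_bins), n_perm = as.integer(n_perm),
                 alpha = alpha, seed = as.integer(seed)),
            class = "permutation_config")
}

#' Pair-preserving permutation test of the bin fractions
#'
#' The order of the gene pairs is shuffled `n_perm` times (each gene's two
#' CVs stay together), the bins are rebuilt, and the per-bin fractions are
#' recorded. The p-value of a bin is the proportion of permuted fractions
#' that lie strictly farther (in absolute value) from the permutation-
#' distribution mean than the observed fraction; no small-sample correction
#' is applied, so p = 0 is possible.
#'
#' @param bf A `bin_fractions` result.
#' @param cfg A [permutation_config()].
#' @return `bf` with columns `perm_mean`, `p_value`, `significant`
#'   (`p < alpha`) appended.
#' @export
permutation_test <- function(bf, cfg = permutation_config()) {
  stopifnot(inherits(bf, "bin_fractions"), inherits(cfg, "permutation_config"))
  gt <- as.numeric(attr(bf, "gt"))
  binidx <- attr(bf, "bin_index")
  sizes <- attr(bf, "sizes")
  g <- length(gt)
  nb <- length(sizes)
  perm <- matrix(NA_real_, nrow = nb, ncol = cfg$n_perm)
  local_seed(cfg$seed, {
    for (b in seq_len(cfg$n_perm))
      perm[, b] <- rowsum(gt[sample.int(g)], binidx) / sizes
  })
  mu <- rowMeans(perm)
  dev_obs <- abs(bf$fraction - mu)
  p <- vapply(seq_len(nb),
              function(i) mean(abs(perm[i, ] - mu[i]) > dev_obs[i]),
              numeric(1))
  bf$perm_mean <- mu
  bf$p_value <- p
  bf$significant <- p < cfg$alpha
  attr(bf, "perm_fractions") <- perm   # bins x n_perm null distribution
  bf
}

#' Compare CV distributions across groups
#'
#' Omnibus Kruskal-Wallis test on the per-gene CV lists, followed by Tukey
#' HSD pairwise comparisons on the rank-transformed values, plus the
#' box-plot summaries (median, quartiles, 1.5 x IQR whiskers, outliers).
#'
#' @param cv_lists Named list (>= 2 groups) of numeric CV vectors.
#' @return A list with `kruskal` (htest), `tukey` (TukeyHSD on ranks) and
#'   `summaries` (per-group [box_summary()] list).
#' @export
group_cv_comparison <- function(cv_lists) {
  if (length(cv_lists) < 2L) stop("need at least 2 groups")
  if (any(!vapply(cv_lists, length, 1L))) stop("empty group")
  values <- unlist(cv_lists, use.names = FALSE)
  grp <- factor(rep(names(cv_lists), times = vapply(cv_lists, length, 1L)))
  kw <- stats::kruskal.test(values, grp)
  tk <- stats::TukeyHSD(stats::aov(rank(values) ~ grp))
  list(kruskal = kw, tukey = tk,
       summaries = lapply(cv_lists, box_summary))
}

#' Pool-level similarity: correlations and principal components
#'
#' Pearson correlation between pools of the log-transformed matrix
#' (`log(x + 1)` by default) and principal-component scores of the pools
#' from the gene-centred matrix.
#'
#' @param pc A [pooled_counts()] with >= 2 pools.
#' @param log_transform Apply `log(x + 1)` first. Default TRUE.
#' @return A list with `correlation` (pools x pools; pairs involving a
#'   constant pool are `NA`), `scores` (pools x PCs) and
#'   `variance_explained`.
#' @export
sample_similarity <- function(pc, log_transform = TRUE) {
  stopifnot(inherits(pc, "pooled_counts"))
  if (ncol(pc$values) < 2L) stop("need at least 2 pools")
  m <- if (log_transform) log1p(pc$values) else pc$values
  sds <- apply(m, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(m, method = "pearson"))
  cc[sds == 0, ] <- NA_real_; cc[, sds == 0] <- NA_real_
  diag(cc) <- ifelse(sds == 0, NA_real_, 1)
  if (any(sds == 0)) warning("constant pool: correlations reported as NA")
  pca <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  list(correlation = cc, scores = pca$x,
       variance_explained = pca$sdev^2 / sum(pca$sdev^2))
}
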