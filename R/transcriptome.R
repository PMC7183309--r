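# Count normalization, a simple DE substitute, log2FC matrices,
# clustering and trajectory summaries.

#' log2 counts-per-million normalization
#'
#' `log2((count + prior) / (libsize + 1) * 1e6)` with a prior count of
#' 0.5. This is a deliberately simple, fixed formula: it does not
#' replicate the prior-scaling of edgeR's `cpm(log = TRUE)`, and is
#' documented as such.
#'
#' @param counts non-negative gene x sample count matrix
#' @param prior prior count added before the log (default 0.5)
#' @return matrix of log2-CPM values, same dimnames
#' @export
log2_cpm <- function(counts, prior = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_config("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop_config("library sizes must be > 0")
  log2(sweep(counts + prior, 2, (lib + 1) / 1e6, "/"))
}

#' Simple differential-expression test on log2-CPM
#'
#' A documented substitute for a full count-model DE engine: per gene,
#' a Welch two-sample t-test on log2-CPM values between the two sample
#' groups, two-sided, with Benjamini-Hochberg adjustment across tested
#' genes. Genes with zero counts in every sample of both groups are
#' excluded from testing and reported in the `excluded_genes`
#' attribute. External DE tables (e.g. from DESeq2) can be used
#' anywhere a DE table is consumed — see [read_de_table()].
#'
#' @param counts gene x sample count matrix
#' @param group_a,group_b disjoint character vectors of column names
#'   (or index vectors), >= 2 samples each; `group_a` is the condition
#'   of interest, so `log2fc > 0` means higher in `group_a`
#' @param prior prior count for the log2-CPM transform
#' @return data.frame `gene`, `log2fc`, `p`, `padj` (BH), one row per
#'   tested gene
#' @export
simple_de <- function(counts, group_a, group_b, prior = 0.5) {
  counts <- as.matrix(counts)
  if (is.character(group_a)) group_a <- match(group_a, colnames(counts))
  if (is.character(group_b)) group_b <- match(group_b, colnames(counts))
  if (anyNA(group_a) || anyNA(group_b))
    stop_config("group sample(s) not found among count columns")
  if (length(intersect(group_a, group_b)))
    stop_config("groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_config("need >= 2 samples per group")
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  all_zero <- rowSums(sub) == 0
  if (any(all_zero))
    message(sum(all_zero), " gene(s) with all-zero counts excluded")
  sub <- sub[!all_zero, , drop = FALSE]
  lcpm <- log2_cpm(sub, prior = prior)
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(lcpm[, ia, drop = FALSE])
  mb <- rowMeans(lcpm[, ib, drop = FALSE])
  va <- row_vars(lcpm[, ia, drop = FALSE])
  vb <- row_vars(lcpm[, ib, drop = FALSE])
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate genes: zero variance in both groups
  degen <- se2 == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  out <- data.frame(gene = rownames(sub) %||% as.character(seq_len(nrow(sub))),
                    log2fc = unname(ma - mb), p = unname(p),
                    padj = unname(stats::p.adjust(p, method = "BH")))
  attr(out, "excluded_genes") <-
    (rownames(counts) %||% as.character(seq_len(nrow(counts))))[all_zero]
  out
}

validate_de_table <- function(table) {
  needed <- c("gene", "log2fc", "p", "padj")
  missing <- setdiff(needed, names(table))
  if (length(missing))
    stop_config("DE table missing column(s): %s", paste(missing, collapse = ", "))
  if (any(table$p < 0 | table$p > 1, na.rm = TRUE) ||
      any(table$padj < 0 | table$padj > 1, na.rm = TRUE))
    stop_config("p and padj must lie in [0, 1]")
  invisible(table)
}

#' Read / write DE tables
#'
#' Tab-separated with header `gene log2fc p padj`; columns from
#' external engines can be mapped by name on read.
#'
#' @param path file path
#' @param col_map optional named character vector mapping the standard
#'   names to the file's column names, e.g.
#'   `c(log2fc = "log2FoldChange", padj = "padj", p = "pvalue")`
#' @return data.frame `gene`, `log2fc`, `p`, `padj`
#' @export
read_de_table <- function(path, col_map = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(col_map))
    for (std in names(col_map))
      names(tab)[names(tab) == col_map[[std]]] <- std
  validate_de_table(tab)
  tab[c("gene", "log2fc", "p", "padj")]
}

#' @rdname read_de_table
#' @param table DE data.frame
#' @export
write_de_table <- function(table, path) {
  validate_de_table(table)
  utils::write.table(table[c("gene", "log2fc", "p", "padj")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Up/down differential gene sets at an adjusted-p cutoff
#'
#' Strict inequality at the cutoff (`padj < alpha`), matching the
#' usual "adjusted p-value < 0.05" filter; the universe is the set of
#' all tested genes.
#'
#' @param table DE table (`gene`, `log2fc`, `p`, `padj`)
#' @param alpha significance cutoff in (0, 1), default 0.05
#' @return list with character vectors `up`, `down`, `universe`
#' @export
de_gene_sets <- function(table, alpha = 0.05) {
  validate_de_table(table)
  if (!nrow(table)) stop_config("empty DE table")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  sig <- !is.na(table$padj) & table$padj < alpha
  list(up = table$gene[sig & table$log2fc > 0],
       down = table$gene[sig & table$log2fc < 0],
       universe = table$gene)
}

#' Headline numbers of a DE comparison
#'
#' @param table DE table
#' @param alpha significance cutoff
#' @return list `n_deregulated`, `fraction_up`,
#'   `mean_abs_log2fc_of_significant`; the latter two are `NA` (absent)
#'   when no gene is significant
#' @export
de_summary <- function(table, alpha = 0.05) {
  sets <- de_gene_sets(table, alpha)
  sig <- !is.na(table$padj) & table$padj < alpha
  n <- sum(sig)
  list(n_deregulated = n,
       fraction_up = if (n > 0) length(sets$up) / n else NA_real_,
       mean_abs_log2fc_of_significant =
         if (n > 0) mean(abs(table$log2fc[sig])) else NA_real_)
}

#' Assemble a genes x conditions log2 fold-change matrix
#'
#' @param tables named list of DE tables, one per condition (names
#'   become columns)
#' @param genes character vector of genes (rows)
#' @param missing policy for a gene absent from a table:
#'   `"fill-zero"` (default; 0 with a warning) or `"drop-gene"`
#' @return numeric matrix genes x conditions
#' @export
log2fc_matrix <- function(tables, genes,
                          missing = c("fill-zero", "drop-gene")) {
  missing <- match.arg(missing)
  if (!length(tables) || is.null(names(tables)))
    stop_config("tables must be a named list of DE tables")
  genes <- unique(as.character(genes))
  m <- vapply(tables, function(tab) {
    tab$log2fc[match(genes, tab$gene)]
  }, numeric(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, names(tables)))
  miss <- is.na(m)
  if (any(miss)) {
    if (missing == "fill-zero") {
      warning(sum(miss), " missing log2FC value(s) filled with 0",
              call. = FALSE)
      m[miss] <- 0
    } else {
      drop <- rowSums(miss) > 0
      warning(sum(drop), " gene(s) with missing log2FC dropped",
              call. = FALSE)
      m <- m[!drop, , drop = FALSE]
    }
  }
  m
}

#' Row-wise Z-score normalization
#'
#' Each row is centered and scaled to mean 0, sample SD 1 (ddof = 1).
#' Constant rows cannot be scaled: they are excluded with a warning
#' naming them.
#'
#' @param m numeric matrix
#' @return matrix of row Z-scores (constant rows removed)
#' @export
row_zscore <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant row(s) excluded: ",
            paste(utils::head(rownames(m)[sds == 0] %||%
                                which(sds == 0), 10), collapse = ", "),
            call. = FALSE)
    m <- m[sds != 0, , drop = FALSE]
    sds <- sds[sds != 0]
  }
  (m - rowMeans(m)) / sds
}

#' Knockdown-to-knockdown correlation of transcriptome responses
#'
#' Pairwise Pearson correlation of the columns of a genes x knockdowns
#' log2FC matrix: two knockdowns correlate highly when they deregulate
#' the same genes in the same direction.
#'
#' @param m genes x knockdowns numeric matrix (>= 3 genes)
#' @return symmetric correlation matrix over knockdowns
#' @export
transcriptome_correlation <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop_config("need >= 3 genes")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop_config("zero-variance log2FC column for knockdown(s): %s",
                paste(colnames(m)[sds == 0] %||% which(sds == 0),
                      collapse = ", "))
  r <- stats::cor(m)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  (r + t(r)) / 2
}

#' Agglomerative clustering of matrix rows into k groups
#'
#' Hierarchical clustering (`hclust`) of the rows with the chosen
#' metric and linkage, cut to exactly `k` clusters. Cluster labels are
#' renumbered by decreasing cluster size, ties broken by the first row
#' index in each cluster, so labels are deterministic and invariant to
#' row permutation (up to the same relabeling).
#'
#' @param m numeric matrix (rows are clustered)
#' @param k number of clusters, `2 <= k <= nrow(m)`
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson r)
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward.D2)
#' @return integer vector of cluster labels (1..k), named by rownames
#' @export
hierarchical_clusters <- function(m, k,
                                  metric = c("euclidean", "correlation"),
                                  linkage = c("average", "complete", "ward")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  m <- as.matrix(m)
  if (k < 2) stop_config("k must be >= 2")
  if (k > nrow(m)) stop_config("k (%d) exceeds number of rows (%d)", k, nrow(m))
  d <- switch(metric,
              euclidean = stats::dist(m),
              correlation = stats::as.dist(1 - stats::cor(t(m))))
  hc <- stats::hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
  raw <- stats::cutree(hc, k = k)
  size <- table(raw)
  first <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.integer(size), first)
  relabel <- integer(k)
  relabel[as.integer(names(size))[ord]] <- seq_len(k)
  stats::setNames(relabel[raw], rownames(m))
}

#' Max-normalized median trajectory of a gene set over timepoints
#'
#' Each gene's expression vector across timepoints is divided by its
#' maximum (so every gene attains 1 at its peak); the summary reports,
#' per timepoint, the median across genes with a bootstrap percentile
#' 95% confidence interval obtained by resampling genes.
#'
#' @param expr positive genes x timepoints matrix (for log-scale or
#'   signed data, shift to a positive scale first — an error reminds
#'   you)
#' @param gene_set optional character vector restricting rows
#' @param n_boot bootstrap resamples (default 1000)
#' @param seed integer seed for the bootstrap
#' @return data.frame `timepoint`, `median`, `ci_low`, `ci_high`, with
#'   attribute `n_genes`
#' @export
trajectory_summary <- function(expr, gene_set = NULL, n_boot = 1000,
                               seed = 1L) {
  expr <- as.matrix(expr)
  if (!is.null(gene_set)) {
    missing <- setdiff(gene_set, rownames(expr))
    if (length(missing))
      stop_config("gene(s) absent from expression matrix: %s",
                  paste(utils::head(missing, 5), collapse = ", "))
    expr <- expr[gene_set, , drop = FALSE]
  }
  if (!nrow(expr)) stop_config("empty gene set")
  if (any(expr <= 0))
    stop_config(paste("expression values must be > 0 for max-normalization;",
                      "shift or exponentiate log-scale input first"))
  norm <- expr / apply(expr, 1, max)
  med <- apply(norm, 2, stats::median)
  ci <- with_seed(seed, {
    idx <- matrix(sample.int(nrow(norm), n_boot * nrow(norm), replace = TRUE),
                  nrow = n_boot)
    boot <- apply(norm, 2, function(col)
      apply(idx, 1, function(i) stats::median(col[i])))
    boot <- matrix(boot, nrow = n_boot)
    apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  })
  out <- data.frame(
    timepoint = colnames(expr) %||% as.character(seq_len(ncol(expr))),
    median = unname(med),
    ci_low = pmin(ci[1, ], med),
    ci_high = pmax(ci[2, ], med))
  rownames(out) <- NULL
  attr(out, "n_genes") <- nrow(expr)
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' `fold = 2^-(ddCt)` with
#' `ddCt = (Ct_target,sample - Ct_ref,sample) -
#'         (Ct_target,control - Ct_ref,control)`,
#' the standard RT-qPCR quantification against a reference gene
#' (e.g. GAPDH).
#'
#' @param ct_target_s,ct_ref_s target/reference Ct in the sample
#' @param ct_target_c,ct_ref_c target/reference Ct in the control
#' @return fold change (vectorized)
#' @export
ddct <- function(ct_target_s, ct_ref_s, ct_target_c, ct_ref_c) {
  stopifnot(is.finite(ct_target_s), is.finite(ct_ref_s),
            is.finite(ct_target_c), is.finite(ct_ref_c))
  2^-((ct_target_s - ct_ref_s) - (ct_target_c - ct_ref_c))
}
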