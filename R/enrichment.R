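# Gene-set overlap statistics: hypergeometric tails, fold enrichment
# and three-set venn decomposition.

#' Upper-tail hypergeometric probability, in log space
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` — the probability
#' that drawing `n` items without replacement from a universe of `N`
#' containing `K` marked items yields at least `k` marked ones. The
#' tail includes `k` itself (the standard over-representation
#' convention). Terms are accumulated as log binomial coefficients via
#' `lgamma` and combined by log-sum-exp, so `log10_p` stays finite for
#' probabilities far below the smallest representable double
#' (p ~ 1e-300 and beyond); the tail is symmetric in `K` and `n`.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`
#' @param N universe size
#' @param K,n marked-set and draw sizes, both `<= N`
#' @return list with `p` (exact 1.0 when `k = 0`; may underflow to 0
#'   for extreme tails) and `log10_p`
#' @export
hypergeometric_tail <- function(k, N, K, n) {
  if (any(c(k, N, K, n) < 0) || K > N || n > N || k > min(K, n))
    stop_config("inconsistent hypergeometric counts (k=%s, N=%s, K=%s, n=%s)",
                k, N, K, n)
  if (k == 0) return(list(p = 1.0, log10_p = 0))
  i <- seq.int(k, min(K, n))
  # terms with n - i > N - K are impossible; lchoose yields -Inf there
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  lp <- logsumexp(log_terms)
  lp <- min(lp, 0)
  list(p = exp(lp), log10_p = lp / log(10))
}

#' Overlap enrichment of two gene sets against a universe
#'
#' Fold enrichment is the observed overlap divided by the overlap
#' expected under independence, `|a||b|/N`; significance is the
#' upper-tail hypergeometric probability of the observed overlap. The
#' universe must be explicit — it is the set of genes that could have
#' appeared in either list (typically all genes tested for DE).
#' Symbols are case-normalized before intersection.
#'
#' @param a,b character vectors of gene symbols, both subsets of
#'   `universe` (violations raise an error listing offenders)
#' @param universe character vector of gene symbols
#' @return one-row data.frame `k`, `n_a`, `n_b`, `N`, `expected`,
#'   `fold`, `p`, `log10_p`; when either set is empty, `fold` and
#'   `expected` are reported absent (`NA`) with `k = 0`, `p = 1`
#' @export
overlap_enrichment <- function(a, b, universe) {
  universe <- unique(norm_symbols(universe))
  if (!length(universe)) stop_config("empty universe")
  a <- unique(norm_symbols(a))
  b <- unique(norm_symbols(b))
  stray <- setdiff(c(setdiff(a, universe), setdiff(b, universe)), NULL)
  if (length(stray))
    stop_config("gene(s) outside the universe: %s%s",
                paste(utils::head(stray, 10), collapse = ", "),
                if (length(stray) > 10) ", ..." else "")
  N <- length(universe)
  if (!length(a) || !length(b))
    return(data.frame(k = 0L, n_a = length(a), n_b = length(b), N = N,
                      expected = NA_real_, fold = NA_real_,
                      p = 1.0, log10_p = 0))
  k <- length(intersect(a, b))
  expected <- length(a) * length(b) / N
  ht <- hypergeometric_tail(k, N, length(a), length(b))
  data.frame(k = k, n_a = length(a), n_b = length(b), N = N,
             expected = expected, fold = k / expected,
             p = ht$p, log10_p = ht$log10_p)
}

#' Three-set venn region counts
#'
#' Decomposes three gene sets into the seven exclusive regions of a
#' venn diagram; the regions partition `A union B union C`.
#'
#' @param a,b,c character vectors (case-normalized before comparison)
#' @return named integer vector with regions `A`, `B`, `AB`, `C`,
#'   `AC`, `BC`, `ABC` (exclusive counts)
#' @export
venn3_counts <- function(a, b, c) {
  a <- unique(norm_symbols(a)); b <- unique(norm_symbols(b))
  c <- unique(norm_symbols(c))
  u <- union(union(a, b), c)
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  c(A = sum(in_a & !in_b & !in_c),
    B = sum(!in_a & in_b & !in_c),
    AB = sum(in_a & in_b & !in_c),
    C = sum(!in_a & !in_b & in_c),
    AC = sum(in_a & !in_b & in_c),
    BC = sum(!in_a & in_b & in_c),
    ABC = sum(in_a & in_b & in_c))
}

#' Tabulate several overlap comparisons
#'
#' Convenience wrapper producing the usual enrichment summary table
#' (one comparison per row: fold enrichment and raw hypergeometric p,
#' with an optional BH-adjusted column for when many comparisons are
#' run).
#'
#' @param comparisons named list of `list(a = , b = )` gene-set pairs
#' @param universe shared universe
#' @param bh add a BH-adjusted p column? (default FALSE: a handful of
#'   planned comparisons is conventionally reported raw)
#' @return data.frame `comparison`, `fold_enrichment`, `p_value`,
#'   `log10_p`, `k`, `n_a`, `n_b`, `N` (+ `p_adj` when `bh`)
#' @export
enrichment_table <- function(comparisons, universe, bh = FALSE) {
  rows <- lapply(names(comparisons), function(nm) {
    res <- overlap_enrichment(comparisons[[nm]]$a, comparisons[[nm]]$b,
                              universe)
    data.frame(comparison = nm, fold_enrichment = res$fold,
               p_value = res$p, log10_p = res$log10_p,
               k = res$k, n_a = res$n_a, n_b = res$n_b, N = res$N)
  })
  out <- do.call(rbind, rows)
  if (bh) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Read / write gene sets
#'
#' One symbol per line, or a 2-column TSV `set <tab> gene` holding
#' several sets.
#'
#' @param path file path
#' @return `read_gene_set`: character vector; `read_gene_sets`: named
#'   list of character vectors
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' @rdname read_gene_set
#' @export
read_gene_sets <- function(path) {
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("set", "gene"),
                           stringsAsFactors = FALSE)
  split(tab$gene, tab$set)
}

#' @rdname read_gene_set
#' @param sets named list of character vectors
#' @export
write_gene_sets <- function(sets, path) {
  tab <- data.frame(set = rep(names(sets), lengths(sets)),
                    gene = unlist(sets, use.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
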