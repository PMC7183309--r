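# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use the most naive correct
# algorithm available and share no code with the functions they check.

# Benjamini-Hochberg step-up, straight from the definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pearson correlation from first principles
pearson_brute <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# P(X >= k) by enumerating every n-subset of an N-universe
hyper_tail_enum <- function(k, N, K, n) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# all overlapping pairs of two 0-based half-open interval tables,
# checked pair by pair
brute_intersect <- function(a, b) {
  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= 1) {
        rows[[length(rows) + 1L]] <- data.frame(
          a_idx = i, b_idx = j, chrom = a$chrom[i],
          a_start = a$start[i], a_end = a$end[i],
          b_start = b$start[j], b_end = b$end[j],
          overlap_bp = as.integer(ov))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      chrom = character(), a_start = integer(),
                      a_end = integer(), b_start = integer(),
                      b_end = integer(), overlap_bp = integer()))
  out <- out[order(out$chrom, out$a_start, out$b_start,
                   out$a_idx, out$b_idx), ]
  rownames(out) <- NULL
  out
}

# random 0-based interval table on a handful of chromosomes
random_intervals <- function(n, chrom_sizes) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  len <- sample(10:500, n, replace = TRUE)
  start <- floor(runif(n, 0, chrom_sizes[chrom] - len))
  data.frame(chrom = chrom, start = start, end = start + len)
}

# matched screen + DE inputs with one planted module, used for the
# network-recovery checks
make_dual_screen <- function(seed, n_knockdowns = 30, module_size = 3,
                             n_genes = 500) {
  kds <- sprintf("KD%03d", seq_len(n_knockdowns))
  module <- kds[seq_len(module_size)]
  scr <- generate_screen(n_knockdowns, n_features = 27, n_replicates = 4,
                         n_plates = 2,
                         truth = screen_truth(modules = list(module),
                                              effect_size = 2, noise_sd = 1),
                         seed = seed)
  corr_hc <- phenotype_correlation(
    aggregate_replicates(zscore_by_plate(scr$table)))
  studies <- generate_knockdown_studies(kds, list(module),
                                        n_genes = n_genes,
                                        seed = seed + 50000L)
  tables <- lapply(studies, function(s)
    simple_de(s$counts,
              group_a = s$samples$sample[s$samples$group != "ctrl"],
              group_b = s$samples$sample[s$samples$group == "ctrl"]))
  sets <- lapply(tables, de_gene_sets)
  sel <- sort(unique(unlist(lapply(sets, function(s) c(s$up, s$down)))))
  lfc <- suppressWarnings(log2fc_matrix(tables, sel))
  corr_rna <- transcriptome_correlation(lfc)
  list(module = module, corr_hc = corr_hc, corr_rna = corr_rna)
}

# precision / recall of the within-module edge set
edge_precision_recall <- function(net, module) {
  truth <- apply(t(utils::combn(sort(module), 2)), 1, paste,
                 collapse = "|")
  found <- paste(net$edges$a, net$edges$b, sep = "|")
  tp <- length(intersect(found, truth))
  list(precision = if (length(found)) tp / length(found) else 1,
       recall = tp / length(truth))
}
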