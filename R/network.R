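# Dual-evidence functional-interaction networks.
#
# An interaction network has knockdown nodes and undirected edges
# carrying two correlation weights: the high-content phenotype
# correlation and the transcriptome correlation. An edge exists only
# when BOTH correlations exceed the threshold (strictly), the
# dual-evidence filter that separates reproducible functional
# interactions from single-assay noise.

#' Build the dual-evidence interaction network
#'
#' Considers every knockdown pair present in both correlation matrices
#' and keeps the pair as an edge iff both correlations are strictly
#' above `threshold`. Negative correlations never form edges in the
#' default signed mode; `use_abs = TRUE` thresholds `|r|` instead.
#'
#' @param corr_hc,corr_rna symmetric correlation matrices with
#'   knockdown dimnames (high-content and transcriptome); their label
#'   sets must share >= 2 knockdowns, and only the intersection is
#'   used
#' @param threshold correlation cutoff, strict `>` (default 0.4)
#' @param keep_isolated keep degree-0 knockdowns as nodes? (default
#'   TRUE)
#' @param use_abs threshold absolute correlations? (default FALSE)
#' @return object of class `interaction_network`: list with `nodes`
#'   (character) and `edges` (data.frame `a`, `b`, `r_highcontent`,
#'   `r_transcriptome`, canonical `a < b` order, sorted)
#' @export
dual_evidence_network <- function(corr_hc, corr_rna, threshold = 0.4,
                                  keep_isolated = TRUE, use_abs = FALSE) {
  labels <- sort(intersect(rownames(corr_hc), rownames(corr_rna)))
  if (length(labels) < 2)
    stop_config("correlation matrices share fewer than 2 knockdowns")
  hc <- corr_hc[labels, labels]
  rna <- corr_rna[labels, labels]
  pairs <- which(upper.tri(hc), arr.ind = TRUE)
  r1 <- hc[pairs]; r2 <- rna[pairs]
  v1 <- if (use_abs) abs(r1) else r1
  v2 <- if (use_abs) abs(r2) else r2
  keep <- v1 > threshold & v2 > threshold
  edges <- data.frame(a = labels[pairs[keep, 1]],
                      b = labels[pairs[keep, 2]],
                      r_highcontent = r1[keep],
                      r_transcriptome = r2[keep])
  swap <- edges$a > edges$b
  tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
  edges <- edges[order(edges$a, edges$b), ]
  rownames(edges) <- NULL
  nodes <- if (keep_isolated) labels else
    sort(unique(c(edges$a, edges$b)))
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$a, to = net$edges$b,
               width = net$edges$r_highcontent,
               color_value = net$edges$r_transcriptome),
    directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

#' Export an interaction network to file
#'
#' Edge attributes follow the display convention of dual-screen
#' network figures: `width` is the high-content correlation and
#' `color_value` the transcriptome correlation. TSV and GraphML
#' exports round-trip losslessly through [import_network()]; SIF uses
#' the `A pp B` interaction line format (isolated nodes as single-name
#' lines).
#'
#' @param net an `interaction_network`
#' @param path output file
#' @param format `"tsv"`, `"graphml"` or `"sif"`
#' @return `path`, invisibly
#' @export
export_network <- function(net, path, format = c("tsv", "graphml", "sif")) {
  format <- match.arg(format)
  switch(format,
         tsv = {
           con <- file(path, "w")
           on.exit(close(con))
           writeLines(paste0("# nodes: ", paste(net$nodes, collapse = ",")),
                      con)
           utils::write.table(
             stats::setNames(net$edges,
                             c("a", "b", "r_highcontent", "r_transcriptome")),
             con, sep = "\t", quote = FALSE, row.names = FALSE)
         },
         graphml = {
           igraph::write_graph(as_igraph(net), path, format = "graphml")
         },
         sif = {
           deg <- c(net$edges$a, net$edges$b)
           iso <- setdiff(net$nodes, deg)
           lines <- c(if (nrow(net$edges))
             sprintf("%s\tpp\t%s", net$edges$a, net$edges$b),
             iso)
           writeLines(lines, path)
         })
  invisible(path)
}

#' Re-import an exported interaction network
#'
#' @param path file written by [export_network()]
#' @param format `"tsv"` or `"graphml"` (SIF drops the correlation
#'   weights and is export-only)
#' @return an `interaction_network`
#' @export
import_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    first <- readLines(path, n = 1L)
    nodes <- strsplit(sub("^# nodes: ", "", first), ",")[[1]]
    edges <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::V(g)$name
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(a = el$from, b = el$to,
                        r_highcontent = el$width,
                        r_transcriptome = el$color_value)
    if (!nrow(el))
      edges <- data.frame(a = character(), b = character(),
                          r_highcontent = numeric(),
                          r_transcriptome = numeric())
  }
  swap <- nrow(edges) > 0 & edges$a > edges$b
  if (any(swap)) {
    tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
  }
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(nodes), edges = edges),
            class = "interaction_network")
}
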