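#' Thresholded Pearson coexpression network
#'
#' Correlates every gene pair across samples and keeps the pairs with
#' `r >= r_min` — read as signed, positive-only correlation, matching
#' the stringent published cutoff of r >= 0.95; `absolute = TRUE`
#' thresholds |r| instead. Zero-variance genes are excluded with a
#' warning, and genes without any retained edge do not appear in the
#' node list.
#'
#' @param mat Gene-by-sample matrix with >= 3 samples.
#' @param genes Optional gene subset (default: all genes in `mat`).
#' @param r_min Correlation threshold in (0, 1].
#' @param absolute Threshold |r| instead of r.
#' @param node_labels Optional named character vector of node labels
#'   (e.g. `"CD"` marker / `"TF"` transcription factor annotations).
#' @return Object of class `coexpr_network`: `edges` (data.frame
#'   gene_a/gene_b/r with gene_a < gene_b, each unordered pair once, no
#'   self-edges), `nodes`, `node_labels`, `threshold`, `absolute`.
#' @export
coexpression_network <- function(mat, genes = NULL, r_min = 0.95,
                                 absolute = FALSE, node_labels = NULL) {
  .check_matrix(mat)
  if (ncol(mat) < 3L) stop("need >= 3 samples")
  if (!is.numeric(r_min) || length(r_min) != 1L || r_min <= 0 || r_min > 1)
    stop("r_min must lie in (0, 1]")
  if (is.null(genes)) genes <- rownames(mat)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  sub <- mat[genes, , drop = FALSE]
  v <- .row_vars(sub)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) excluded")
    sub <- sub[v > 0, , drop = FALSE]
  }
  edges <- data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), stringsAsFactors = FALSE)
  if (nrow(sub) >= 2L) {
    C <- cor(t(sub))
    idx <- which(upper.tri(C) &
                   (if (absolute) abs(C) else C) >= r_min,
                 arr.ind = TRUE)
    if (nrow(idx)) {
      a <- rownames(C)[idx[, 1L]]
      b <- colnames(C)[idx[, 2L]]
      swap <- a > b
      edges <- data.frame(gene_a = ifelse(swap, b, a),
                          gene_b = ifelse(swap, a, b),
                          r = C[idx], stringsAsFactors = FALSE)
      edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(edges = edges, nodes = nodes,
                 node_labels = node_labels[nodes],
                 threshold = r_min, absolute = absolute),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("Coexpression network: %d genes, %d interactions (r >= %g%s)\n",
              length(x$nodes), nrow(x$edges), x$threshold,
              if (x$absolute) ", absolute" else ""))
  invisible(x)
}

#' Export a coexpression network for Cytoscape
#'
#' Dialects: `"sif"` (simple interaction format, interaction type
#' `coexp`) and `"edgelist"` (TSV gene_a / gene_b / r). When node labels
#' are present a `<path>.nodes.tsv` attribute table is written
#' alongside.
#'
#' @param net A `coexpr_network`.
#' @param path Output path.
#' @param format `"sif"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edgelist", "sif")) {
  stopifnot(inherits(net, "coexpr_network"))
  format <- match.arg(format)
  if (!nrow(net$edges)) stop("network has no edges")
  if (format == "sif") {
    writeLines(paste(net$edges$gene_a, "coexp", net$edges$gene_b,
                     sep = "\t"), path)
  } else {
    out <- net$edges
    out$r <- sprintf("%.15g", out$r)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(net$node_labels) && any(!is.na(net$node_labels))) {
    write.table(data.frame(gene = net$nodes,
                           label = ifelse(is.na(net$node_labels), "",
                                          net$node_labels)),
                paste0(path, ".nodes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Re-import an exported network
#'
#' @param path File written by [export_network()].
#' @param format `"sif"` or `"edgelist"`.
#' @param r_min Threshold to record on the imported object.
#' @return A `coexpr_network` (SIF carries no r values; they are `NA`).
#' @export
read_network <- function(path, format = c("edgelist", "sif"),
                         r_min = NA_real_) {
  format <- match.arg(format)
  if (format == "sif") {
    parts <- strsplit(readLines(path), "\t", fixed = TRUE)
    bad <- lengths(parts) != 3L
    if (any(bad)) stop("malformed SIF line(s)")
    edges <- data.frame(gene_a = vapply(parts, `[[`, "", 1L),
                        gene_b = vapply(parts, `[[`, "", 3L),
                        r = NA_real_, stringsAsFactors = FALSE)
  } else {
    edges <- read.delim(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric"))
    colnames(edges) <- c("gene_a", "gene_b", "r")
  }
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 node_labels = NULL, threshold = r_min, absolute = FALSE),
            class = "coexpr_network")
}
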