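#' Principal component analysis of an expression matrix
#'
#' PCA via singular-value decomposition of the centered (optionally
#' scaled) data, in either orientation: with `variables = "genes"` the
#' samples are the observations (the usual sample-space PCA); with
#' `variables = "samples"` the genes are the observations.
#'
#' @param mat Gene-by-sample matrix.
#' @param variables `"genes"` or `"samples"` — which axis plays the
#'   role of variables.
#' @param center,scale Passed to the decomposition; scaling a constant
#'   variable is an error naming the offenders.
#' @return Object of class `pca_result`: `scores` (observations x
#'   components), `variance_fraction`, `cumulative_variance`,
#'   `variables`.
#' @export
pca_expression <- function(mat, variables = c("genes", "samples"),
                           center = TRUE, scale = FALSE) {
  .check_matrix(mat)
  variables <- match.arg(variables)
  x <- if (variables == "genes") t(mat) else mat
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need >= 2 observations and >= 2 variables")
  if (scale) {
    sds <- apply(x, 2L, sd)
    if (any(sds == 0))
      stop("constant variable(s) cannot be scaled: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
  }
  fit <- prcomp(x, center = center, scale. = scale)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x, variance_fraction = vf,
                 cumulative_variance = cumsum(vf),
                 rotation = fit$rotation, variables = variables),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3L, length(x$cumulative_variance))
  cat(sprintf(
    "PCA (%s as variables): cumulative variance %s\n", x$variables,
    paste(sprintf("PC%d %.2f%%", seq_len(k),
                  100 * x$cumulative_variance[seq_len(k)]),
          collapse = ", ")))
  invisible(x)
}

#' Sample distances derived from pairwise Pearson correlations
#'
#' First the sample-by-sample Pearson correlation matrix C is computed;
#' the distance between samples i and j is then the Euclidean distance
#' between rows C_i and C_j — i.e. samples are close when they correlate
#' similarly with every sample in the compendium.
#'
#' @param mat Gene-by-sample matrix with >= 3 samples.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
correlation_distance_matrix <- function(mat) {
  .check_matrix(mat)
  if (ncol(mat) < 3L) stop("need >= 3 samples")
  sds <- apply(mat, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  C <- cor(mat)
  as.matrix(dist(C))
}

#' Average-linkage (UPGMA) clustering of a distance matrix
#'
#' @param distances Symmetric distance matrix (e.g. from
#'   [correlation_distance_matrix()]).
#' @param method Agglomeration method, default `"average"` (UPGMA).
#' @return An [stats::hclust] tree.
#' @export
hcluster_samples <- function(distances, method = "average") {
  if (!isSymmetric(unname(as.matrix(distances))))
    stop("distance matrix must be symmetric")
  hclust(as.dist(distances), method = method)
}
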