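#' Build a frozen normalization reference from balanced batch subsets
#'
#' Pre-computes the "frozen" vectors used to normalize arrays without
#' refitting on the whole compendium: a reference quantile vector (the
#' per-rank mean of the sorted sample vectors over a balanced subsample
#' of `per_batch_n` arrays per batch) and, per batch, a frozen per-gene
#' offset vector (the mean residual of that batch's subsampled,
#' quantile-normalized arrays around the across-batch per-gene mean).
#' Because the offsets are estimated *after* quantile normalization they
#' capture gene-specific batch structure that rank mapping cannot remove;
#' a batch effect that is constant across all genes is already absorbed
#' by the quantile step.
#'
#' @param mat Gene-by-sample expression matrix.
#' @param batch Batch id per sample (character/factor, length
#'   `ncol(mat)`).
#' @param per_batch_n Arrays subsampled per batch (balanced subset size).
#' @param seed Integer seed for the balanced subsampling.
#' @return An object of class `frozen_reference`: list with
#'   `reference_quantiles` (sorted, length `nrow(mat)`), `batch_offsets`
#'   (named list of per-gene offset vectors) and `genes`.
#' @export
build_frozen_reference <- function(mat, batch, per_batch_n = 3L, seed = 1L) {
  .check_matrix(mat)
  per_batch_n <- .check_count(per_batch_n, "per_batch_n")
  batch <- as.character(batch)
  if (length(batch) != ncol(mat))
    stop("`batch` must have one entry per sample")
  batches <- unique(batch)
  if (length(batches) < 2L) stop("need >= 2 batches to freeze offsets")
  sizes <- table(batch)
  small <- names(sizes)[sizes < per_batch_n]
  if (length(small))
    stop("batch(es) smaller than per_batch_n: ",
         paste(small, collapse = ", "))
  set.seed(seed)
  picked <- lapply(batches, function(b)
    sample(which(batch == b), per_batch_n))
  names(picked) <- batches

  sub <- mat[, unlist(picked), drop = FALSE]
  refq <- unname(rowMeans(apply(sub, 2L, function(x) sort(unname(x)))))

  # quantile-normalize the subsample onto the reference, then average
  # residuals per batch around the across-batch per-gene mean
  qn <- apply(sub, 2L, .quantile_map, refq = refq)
  rownames(qn) <- rownames(mat)
  sub_batch <- rep(batches, each = per_batch_n)
  batch_means <- vapply(batches, function(b)
    rowMeans(qn[, sub_batch == b, drop = FALSE]), numeric(nrow(mat)))
  grand <- rowMeans(batch_means)  # balanced: mean over batch means
  offsets <- lapply(batches, function(b) batch_means[, b] - grand)
  names(offsets) <- batches

  structure(list(reference_quantiles = sort(refq),
                 batch_offsets = offsets,
                 genes = rownames(mat),
                 per_batch_n = per_batch_n),
            class = "frozen_reference")
}

# Map one sample vector onto the reference quantiles by rank; tied input
# values receive the mean of the reference values at their tied ranks.
.quantile_map <- function(x, refq) {
  refq <- sort(refq)
  ord <- order(x)
  out <- numeric(length(x))
  xs <- x[ord]
  # runs of equal values share the mean of their reference positions
  runs <- rle(xs)
  pos <- 1L
  vals <- numeric(length(xs))
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    vals[pos:(pos + len - 1L)] <- mean(refq[pos:(pos + len - 1L)])
    pos <- pos + len
  }
  out[ord] <- vals
  out
}

#' Apply frozen normalization to a matrix
#'
#' Each sample's values are replaced by the frozen reference quantiles at
#' the sample's value ranks (ties receive the mean of the tied reference
#' positions), then the sample's frozen batch offset vector is
#' subtracted. Samples from batches absent from the reference get the
#' quantile step only (reported with a message).
#'
#' @param mat Gene-by-sample matrix; gene ids must match the reference.
#' @param ref A [build_frozen_reference()] result.
#' @param batch Batch id per sample.
#' @return The normalized matrix.
#' @export
apply_frozen_normalization <- function(mat, ref, batch) {
  .check_matrix(mat)
  stopifnot(inherits(ref, "frozen_reference"))
  if (!identical(rownames(mat), ref$genes))
    stop("gene ids do not match the frozen reference")
  batch <- as.character(batch)
  if (length(batch) != ncol(mat))
    stop("`batch` must have one entry per sample")
  unknown <- setdiff(unique(batch), names(ref$batch_offsets))
  if (length(unknown))
    message("apply_frozen_normalization: batch(es) not in reference, ",
            "quantile step only: ", paste(unknown, collapse = ", "))
  out <- apply(mat, 2L, .quantile_map, refq = ref$reference_quantiles)
  dimnames(out) <- dimnames(mat)
  for (j in seq_len(ncol(out))) {
    off <- ref$batch_offsets[[batch[j]]]
    if (!is.null(off)) out[, j] <- out[, j] - off
  }
  out
}

#' Keep the most variable genes
#'
#' Retains `ceiling(keep_fraction * n_genes)` genes with the highest
#' per-gene variance across samples (population variance, divisor n);
#' ties are broken by gene-id lexicographic order. Mirrors the common
#' practice of filtering a marker panel to its most variable half before
#' pattern clustering.
#'
#' @param mat Gene-by-sample matrix.
#' @param keep_fraction Fraction of genes to keep, in (0, 1].
#' @return The filtered matrix (original row order preserved).
#' @export
variance_filter <- function(mat, keep_fraction) {
  .check_matrix(mat)
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1L ||
      keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  k <- ceiling(keep_fraction * nrow(mat))
  v <- .row_vars(mat, population = TRUE)
  keep <- rownames(mat)[order(-v, rownames(mat))][seq_len(k)]
  mat[rownames(mat) %in% keep, , drop = FALSE]
}

#' Fraction of expression variance attributable to batch
#'
#' One-way between/within decomposition pooled over genes: the returned
#' value is `sum_g SS_between(g) / sum_g SS_total(g)`. Used to verify
#' that frozen normalization removes batch structure.
#'
#' @param mat Gene-by-sample matrix.
#' @param batch Batch id per sample.
#' @return A single fraction in \[0, 1\].
#' @export
batch_variance_fraction <- function(mat, batch) {
  .check_matrix(mat)
  batch <- as.character(batch)
  stopifnot(length(batch) == ncol(mat))
  grand <- rowMeans(mat)
  ss_tot <- rowSums((mat - grand)^2)
  ss_between <- numeric(nrow(mat))
  for (b in unique(batch)) {
    cols <- batch == b
    mb <- rowMeans(mat[, cols, drop = FALSE])
    ss_between <- ss_between + sum(cols) * (mb - grand)^2
  }
  sum(ss_between) / sum(ss_tot)
}

#' Serialize / read a frozen reference as a TSV bundle
#'
#' Writes `quantiles.tsv`, one `offsets_<batch>.tsv` per batch, and a
#' small `index.yaml` tying the bundle together.
#'
#' @param ref A `frozen_reference`.
#' @param dir Directory to write into (created if absent).
#' @return `dir`, invisibly.
#' @export
write_frozen_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "frozen_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(
    data.frame(rank = seq_along(ref$reference_quantiles),
               value = sprintf("%.15g", ref$reference_quantiles)),
    file.path(dir, "quantiles.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (b in names(ref$batch_offsets)) {
    write.table(
      data.frame(gene_id = ref$genes,
                 offset = sprintf("%.15g", ref$batch_offsets[[b]])),
      file.path(dir, paste0("offsets_", b, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(list(batches = names(ref$batch_offsets),
                        per_batch_n = ref$per_batch_n,
                        n_genes = length(ref$genes)),
                   file.path(dir, "index.yaml"))
  invisible(dir)
}

#' @rdname write_frozen_reference
#' @export
read_frozen_reference <- function(dir) {
  idx <- yaml::read_yaml(file.path(dir, "index.yaml"))
  q <- read.delim(file.path(dir, "quantiles.tsv"))
  offsets <- list()
  genes <- NULL
  for (b in idx$batches) {
    df <- read.delim(file.path(dir, paste0("offsets_", b, ".tsv")),
                     colClasses = c("character", "numeric"))
    genes <- df$gene_id
    offsets[[b]] <- setNames(df$offset, df$gene_id)
  }
  structure(list(reference_quantiles = as.numeric(q$value),
                 batch_offsets = offsets, genes = genes,
                 per_batch_n = idx$per_batch_n),
            class = "frozen_reference")
}
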