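#' Read a gene-by-sample expression matrix from TSV
#'
#' The on-disk format is UTF-8 tab-separated text with a header row of
#' sample ids and a first column of gene ids ('.' decimal separator, no
#' thousands separators). Values are log2 intensities.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene-id column plus >= 1 sample")
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop("duplicated gene row(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicated sample column(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(genes, samples))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 genes[bad[1L]], samples[bad[2L]]))
  }
  .check_matrix(vals, "matrix read from file")
  vals
}

#' Write an expression matrix to TSV
#'
#' Values are written with 15 significant digits so that
#' `read_expression(write_expression(m))` round-trips to full double
#' precision.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param id_column Name for the gene-id column (default `"gene_id"`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, id_column = "gene_id") {
  .check_matrix(mat)
  out <- data.frame(rownames(mat),
                    apply(mat, 2L, function(v) sprintf("%.15g", v)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c(id_column, colnames(mat))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' The annotation is a TSV with at least the columns `sample_id`,
#' `cell_type`, `lineage` and `batch`.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` of sample annotations.
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("sample_id", "cell_type", "lineage", "batch")
  miss <- setdiff(need, colnames(ann))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicated sample_id in annotation")
  ann
}

#' @rdname read_annotation
#' @param ann Annotation `data.frame`.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Merge two paired array platforms by probe union and highest signal
#'
#' Both matrices must carry the *same* samples (paired arrays hybridized
#' from the same RNA). The merged matrix holds the union of the feature
#' sets; where a feature was measured on both platforms the higher
#' intensity is retained, features exclusive to one platform are carried
#' through unchanged. Sample order follows `mat_a`.
#'
#' @param mat_a,mat_b Expression matrices with identical sample-id sets.
#' @return The merged expression matrix.
#' @export
merge_paired_platforms <- function(mat_a, mat_b) {
  .check_matrix(mat_a, "mat_a"); .check_matrix(mat_b, "mat_b")
  if (!setequal(colnames(mat_a), colnames(mat_b)))
    stop("sample sets differ between platforms")
  mat_b <- mat_b[, colnames(mat_a), drop = FALSE]
  shared <- intersect(rownames(mat_a), rownames(mat_b))
  only_a <- setdiff(rownames(mat_a), shared)
  only_b <- setdiff(rownames(mat_b), shared)
  out <- rbind(
    pmax(mat_a[shared, , drop = FALSE], mat_b[shared, , drop = FALSE]),
    mat_a[only_a, , drop = FALSE],
    mat_b[only_b, , drop = FALSE])
  out[order(rownames(out)), , drop = FALSE]
}

#' Collapse probe-level rows to one row per gene
#'
#' Each gene's expression per sample is the median over its probes.
#' Probes absent from the map are dropped (their count is reported with a
#' message), matching a restriction to uniquely mapped features.
#'
#' @param mat Probe-level expression matrix (probes in rows).
#' @param map Probe-to-gene map: a `data.frame` with columns `probe_id`
#'   and `gene_id`, or a named character vector (`names` = probes).
#'   The map must be many-to-one: a probe may not map to two genes.
#' @return A gene-level expression matrix, genes in lexicographic order.
#' @export
collapse_probes_to_genes <- function(mat, map) {
  .check_matrix(mat)
  if (is.data.frame(map)) {
    if (!all(c("probe_id", "gene_id") %in% colnames(map)))
      stop("`map` must have columns probe_id and gene_id")
    map <- setNames(as.character(map$gene_id), as.character(map$probe_id))
  }
  if (!length(map)) stop("probe-gene map is empty")
  dup <- duplicated(names(map))
  if (any(dup)) {
    consistent <- tapply(unname(map), names(map),
                         function(g) length(unique(g)) == 1L)
    if (!all(consistent))
      stop("probe(s) mapping to more than one gene: ",
           paste(names(consistent)[!consistent], collapse = ", "))
    map <- map[!dup]
  }
  mapped <- rownames(mat) %in% names(map)
  if (!any(mapped)) stop("no matrix feature is present in the map")
  n_drop <- sum(!mapped)
  if (n_drop > 0L)
    message(sprintf("collapse_probes_to_genes: dropped %d unmapped probe(s)",
                    n_drop))
  sub <- mat[mapped, , drop = FALSE]
  gene <- unname(map[rownames(sub)])
  idx <- split(seq_len(nrow(sub)), gene)
  out <- t(vapply(idx, function(i)
    apply(sub[i, , drop = FALSE], 2L, median),
    numeric(ncol(sub))))
  # single-sample edge: vapply over columns keeps orientation
  if (ncol(sub) == 1L) out <- matrix(out, ncol = 1L,
                                     dimnames = list(names(idx), colnames(sub)))
  out[order(rownames(out)), , drop = FALSE]
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT dialect: one set per line, fields tab-separated — set
#' name, description, then the member gene ids. A collection is a named
#' list of character vectors with a `"description"` attribute.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(names_))
    stop("duplicate set name(s) in GMT: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- lapply(parts, function(p) {
    if (length(p) < 3L)
      stop(sprintf("GMT set '%s' is empty", p[[1L]]))
    unique(p[-(1:2)])
  })
  desc <- vapply(parts, `[[`, character(1L), 2L)
  gene_set_collection(setNames(sets, names_), setNames(desc, names_))
}

#' @rdname read_gmt
#' @param collection Named list of character vectors.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  desc <- attr(collection, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(collection)),
                                      names(collection))
  lines <- vapply(names(collection), function(nm) {
    members <- collection[[nm]]
    if (!length(members)) stop(sprintf("set '%s' is empty", nm))
    paste(c(nm, desc[[nm]], members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique names, non-empty
#'   sets).
#' @param description Optional character vector of per-set descriptions.
#' @return The collection, classed `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a non-empty named list")
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  if (any(!vapply(sets, length, 1L))) stop("sets must be non-empty")
  sets <- lapply(sets, as.character)
  if (is.null(description))
    description <- setNames(rep("", length(sets)), names(sets))
  structure(sets, description = description, class = "gene_set_collection")
}

#' Read / write a probe-to-gene map as 2-column TSV
#'
#' @param path Path to a TSV with columns `probe_id`, `gene_id`.
#' @return A `data.frame` with those two columns.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% colnames(df)))
    stop("probe map must have columns probe_id and gene_id")
  df[, c("probe_id", "gene_id")]
}

#' @rdname read_probe_map
#' @param map Probe-map `data.frame`.
#' @export
write_probe_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
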