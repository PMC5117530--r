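# Internal validation helpers shared across modules.

.check_matrix <- function(mat, arg = "mat") {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop(sprintf("`%s` must have gene rownames and sample colnames", arg),
         call. = FALSE)
  if (anyDuplicated(rownames(mat)))
    stop(sprintf("duplicate gene ids in `%s`: %s", arg,
                 paste(unique(rownames(mat)[duplicated(rownames(mat))]),
                       collapse = ", ")), call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop(sprintf("duplicate sample ids in `%s`: %s", arg,
                 paste(unique(colnames(mat)[duplicated(colnames(mat))]),
                       collapse = ", ")), call. = FALSE)
  if (!all(is.finite(mat)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(mat)
}

.check_count <- function(x, arg, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != as.integer(x))
    stop(sprintf("`%s` must be a single integer >= %d", arg, min),
         call. = FALSE)
  as.integer(x)
}

# Row variances with divisor `n` (population) or `n - 1` (sample).
.row_vars <- function(mat, population = FALSE) {
  n <- ncol(mat)
  ctr <- mat - rowMeans(mat)
  ss <- rowSums(ctr * ctr)
  if (population) ss / n else ss / (n - 1L)
}

# Deterministic per-stage seed derivation (kept below 2^31).
.derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
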