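#' Define a two-group contrast
#'
#' Orientation is A minus B: a positive log fold change means higher
#' expression in group A. Under resampling the supplied columns may
#' contain repeats; each side needs at least two columns.
#'
#' @param name Contrast label.
#' @param group_a,group_b Character vectors of sample ids.
#' @return A list of class `group_contrast`.
#' @export
group_contrast <- function(name, group_a, group_b) {
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each contrast side needs >= 2 columns")
  if (length(intersect(unique(group_a), unique(group_b))))
    stop("contrast groups share sample labels")
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "group_contrast")
}

#' Build a contrast from a sample annotation table
#'
#' @param annotation Annotation `data.frame` (see [read_annotation()]).
#' @param type_a,type_b Values selecting the two groups.
#' @param column Annotation column to match on (default `"cell_type"`;
#'   `"lineage"` is also common).
#' @param name Contrast label (default `"<A>_vs_<B>"`).
#' @return A [group_contrast()].
#' @export
contrast_from_annotation <- function(annotation, type_a, type_b,
                                     column = "cell_type",
                                     name = paste0(type_a, "_vs_", type_b)) {
  a <- annotation$sample_id[annotation[[column]] == type_a]
  b <- annotation$sample_id[annotation[[column]] == type_b]
  if (!length(a)) stop(sprintf("no samples with %s == '%s'", column, type_a))
  if (!length(b)) stop(sprintf("no samples with %s == '%s'", column, type_b))
  group_contrast(name, a, b)
}

#' Per-gene two-group summary statistics
#'
#' For every gene: log fold change `meanA - meanB`, pooled within-group
#' variance and residual degrees of freedom `nA + nB - 2`. Columns drawn
#' with replacement are used as-is (the df reflects the drawn counts).
#'
#' @param mat Gene-by-sample matrix.
#' @param contrast A [group_contrast()]; its columns must exist in `mat`.
#' @return List of class `group_stats` with per-gene `logfc`, `s2`, and
#'   scalars `df`, `n_a`, `n_b`.
#' @export
group_stats <- function(mat, contrast) {
  .check_matrix(mat)
  stopifnot(inherits(contrast, "group_contrast"))
  missing <- setdiff(unique(c(contrast$group_a, contrast$group_b)),
                     colnames(mat))
  if (length(missing))
    stop("contrast columns absent from matrix: ",
         paste(missing, collapse = ", "))
  xa <- mat[, contrast$group_a, drop = FALSE]
  xb <- mat[, contrast$group_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  df <- na + nb - 2L
  if (df <= 0L) stop("zero residual degrees of freedom")
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2); ssb <- rowSums((xb - mb)^2)
  structure(list(logfc = ma - mb, s2 = (ssa + ssb) / df,
                 df = df, n_a = na, n_b = nb,
                 genes = rownames(mat)),
            class = "group_stats")
}

# Newton inversion of the trigamma function (y > 0).
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-12) break
  }
  x
}

#' Estimate the variance prior by method of moments
#'
#' Fits the scaled inverse-chi-square prior of the moderated-t model to
#' the observed gene-wise variances, matching moments on the log scale:
#' with `z = log(s2)`, solve `trigamma(d0/2) = var(z) - trigamma(df/2)`
#' for the prior degrees of freedom `d0`, and recover the prior variance
#' `s0_sq` from `mean(z)` with the corresponding digamma corrections. If
#' the spread of `z` does not exceed the sampling component
#' `trigamma(df/2)`, the prior is degenerate: `d0 = Inf` and `s0_sq` is
#' the bias-corrected geometric mean of the variances.
#'
#' @param s2 Per-gene variances (genes with `s2 == 0` are excluded from
#'   the moment fit; at least 10 positive values are required).
#' @param df Residual degrees of freedom of each `s2` (single value).
#' @return List with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_prior <- function(s2, df) {
  if (all(s2 <= 0)) stop("all gene variances are zero")
  z <- log(s2[s2 > 0])
  if (length(z) < 10L)
    stop("need >= 10 genes with positive variance to estimate the prior")
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  half_d0 <- .trigamma_inverse(evar)
  d0 <- 2 * half_d0
  s0_sq <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-test with empirical-Bayes variance shrinkage
#'
#' Posterior variance `s2_post = (d0*s0_sq + df*s2) / (d0 + df)` (equal
#' to `s0_sq` when `d0 = Inf`), moderated statistic
#' `t = logfc / sqrt(s2_post * (1/nA + 1/nB))`, and two-sided p-value on
#' a t distribution with `d0 + df` degrees of freedom. With `d0 = 0` the
#' statistic reduces to the ordinary pooled two-sample t.
#'
#' @param stats A [group_stats()] result.
#' @param prior An [estimate_prior()] result (list with `d0`, `s0_sq`).
#' @return `data.frame` with per-gene `gene`, `logfc`, `s2`, `t`, `p`.
#' @export
moderated_test <- function(stats, prior) {
  stopifnot(inherits(stats, "group_stats"),
            is.list(prior), prior$d0 >= 0, prior$s0_sq >= 0)
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) rep(prior$s0_sq, length(stats$s2))
             else (d0 * prior$s0_sq + stats$df * stats$s2) / (d0 + stats$df)
  se2 <- s2_post * (1 / stats$n_a + 1 / stats$n_b)
  t <- stats$logfc / sqrt(se2)
  df_total <- d0 + stats$df
  p <- 2 * pt(abs(t), df = df_total, lower.tail = FALSE)
  zero <- se2 <= 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero posterior variance; ",
            "p set to smallest representable value")
    t[zero] <- sign(stats$logfc[zero]) * Inf
    p[zero] <- .Machine$double.xmin
  }
  data.frame(gene = stats$genes, logfc = stats$logfc, s2 = stats$s2,
             t = t, p = p, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false discovery rate control: sort p ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j` clipped at 1, mapped back to the
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of BH-adjusted p-values (FDR).
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p.adjust(p, method = "BH")
}

#' Full two-group moderated differential expression
#'
#' Runs [group_stats()], [estimate_prior()], [moderated_test()] and
#' [bh_adjust()], then ranks all genes by FDR ascending (ties averaged).
#'
#' @param mat Gene-by-sample matrix.
#' @param contrast A [group_contrast()].
#' @param alpha Significance level on the FDR scale (for [call_de()]).
#' @return Object of class `de_result`: list with `table` (gene, logfc,
#'   s2, t, p, fdr, rank), `d0`, `s0_sq`, `contrast`, `alpha`.
#' @export
run_de <- function(mat, contrast, alpha = 0.05) {
  st <- group_stats(mat, contrast)
  prior <- estimate_prior(st$s2, st$df)
  tab <- moderated_test(st, prior)
  tab$fdr <- bh_adjust(tab$p)
  tab$rank <- rank(tab$fdr, ties.method = "average")
  structure(list(table = tab, d0 = prior$d0, s0_sq = prior$s0_sq,
                 contrast = contrast, alpha = alpha),
            class = "de_result")
}

#' Call differentially expressed genes
#'
#' A gene is significant when `fdr < alpha` (strict); no fold-change
#' threshold is applied. Up and down sets follow the sign of the log
#' fold change.
#'
#' @param result A `de_result`.
#' @param alpha Significance level in (0, 1); defaults to the level
#'   stored in the result.
#' @return List with character vectors `up` and `down`.
#' @export
call_de <- function(result, alpha = result$alpha) {
  stopifnot(inherits(result, "de_result"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  tab <- result$table
  sig <- tab$fdr < alpha
  list(up = tab$gene[sig & tab$logfc > 0],
       down = tab$gene[sig & tab$logfc < 0])
}

#' Serialize a DE result table to TSV
#'
#' @param result A `de_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(result, path) {
  stopifnot(inherits(result, "de_result"))
  write.table(result$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.de_result <- function(x, ...) {
  calls <- call_de(x)
  cat(sprintf(
    "Moderated DE '%s': %d genes, d0 = %.3g, s0_sq = %.3g, %d up / %d down at fdr < %g\n",
    x$contrast$name, nrow(x$table), x$d0, x$s0_sq,
    length(calls$up), length(calls$down), x$alpha))
  invisible(x)
}
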