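#' Configuration of the resampling stability protocol
#'
#' Each iteration subsamples `k_per_group` columns per group *with
#' replacement* and runs the moderated DE test; genes significant (in a
#' consistent direction) in every iteration so far form the cumulative
#' stable set. Iteration stops at the first iteration `>= min_iters`
#' whose last `patience` cumulative stable-set sizes (both directions)
#' are all equal, or at `max_iters`.
#'
#' @param k_per_group Columns drawn per group each iteration (default 7).
#' @param alpha FDR significance level per iteration.
#' @param max_iters Iteration budget (default 200).
#' @param min_iters Minimum iterations before the plateau check.
#' @param patience Consecutive unchanged iterations that define the
#'   plateau.
#' @param seed Integer seed for the resampling stream.
#' @return A validated list of class `resampling_config`.
#' @export
resampling_config <- function(k_per_group = 7L, alpha = 0.05,
                              max_iters = 200L, min_iters = 50L,
                              patience = 20L, seed = 1L) {
  k_per_group <- .check_count(k_per_group, "k_per_group", min = 2L)
  max_iters <- .check_count(max_iters, "max_iters")
  min_iters <- .check_count(min_iters, "min_iters")
  patience <- .check_count(patience, "patience")
  if (min_iters > max_iters) stop("min_iters must be <= max_iters")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(k_per_group = k_per_group, alpha = alpha,
                 max_iters = max_iters, min_iters = min_iters,
                 patience = patience, seed = .check_count(seed, "seed", 0L)),
            class = "resampling_config")
}

#' Resampling stability analysis of one contrast
#'
#' The stability protocol: per iteration, draw `k_per_group` samples per
#' group uniformly with replacement, run the moderated DE pipeline
#' (group statistics, per-iteration empirical-Bayes prior, moderated t,
#' BH adjustment, FDR < alpha calls), and rank *all* genes by FDR
#' ascending with averaged ties. The cumulative stable sets are the
#' intersections of the per-iteration up (resp. down) calls; a gene
#' significant up in one iteration and down in another is thereby
#' excluded. Iteration stops once the cumulative sizes plateau (see
#' [plateau_reached()]) or at `max_iters`. Median ranks over all
#' executed iterations are reported for stable genes.
#'
#' @param mat Gene-by-sample matrix.
#' @param contrast A [group_contrast()] naming the two sample pools
#'   (each pool needs >= 2 distinct samples present in `mat`).
#' @param config A [resampling_config()].
#' @return Object of class `stability_result`: `stable_up`,
#'   `stable_down`, `call_frequency` (data.frame gene/up/down for genes
#'   ever called), `median_rank` (named, stable genes), `trace`
#'   (per-iteration de/stable sizes), `iterations_run`, `plateaued`,
#'   `config`, `contrast_name`.
#' @export
resample_contrast <- function(mat, contrast, config = resampling_config()) {
  .check_matrix(mat)
  stopifnot(inherits(contrast, "group_contrast"),
            inherits(config, "resampling_config"))
  pool_a <- unique(contrast$group_a)
  pool_b <- unique(contrast$group_b)
  missing <- setdiff(c(pool_a, pool_b), colnames(mat))
  if (length(missing))
    stop("contrast samples absent from matrix: ",
         paste(missing, collapse = ", "))
  if (length(pool_a) < 2L || length(pool_b) < 2L)
    stop("each group needs >= 2 distinct samples")
  k <- config$k_per_group
  genes <- rownames(mat)
  set.seed(config$seed)

  up_count <- setNames(integer(length(genes)), genes)
  down_count <- up_count
  s_up <- s_down <- NULL
  cand <- NULL          # candidate stable genes (fixed after iter 1)
  rank_store <- NULL    # ranks of candidates, iterations in columns
  trace <- data.frame(iteration = integer(), n_de_up = integer(),
                      n_de_down = integer(), n_stable_up = integer(),
                      n_stable_down = integer())

  for (i in seq_len(config$max_iters)) {
    draw_a <- sample(pool_a, k, replace = TRUE)
    draw_b <- sample(pool_b, k, replace = TRUE)
    it_contrast <- structure(list(name = contrast$name, group_a = draw_a,
                                  group_b = draw_b),
                             class = "group_contrast")
    de <- run_de(mat, it_contrast, alpha = config$alpha)
    calls <- call_de(de)
    up_count[calls$up] <- up_count[calls$up] + 1L
    down_count[calls$down] <- down_count[calls$down] + 1L

    if (i == 1L) {
      s_up <- calls$up; s_down <- calls$down
      cand <- union(calls$up, calls$down)
      rank_store <- matrix(NA_real_, nrow = length(cand),
                           ncol = config$max_iters,
                           dimnames = list(cand, NULL))
    } else {
      s_up <- intersect(s_up, calls$up)
      s_down <- intersect(s_down, calls$down)
    }
    if (length(cand))
      rank_store[, i] <- de$table$rank[match(cand, de$table$gene)]

    trace <- rbind(trace, data.frame(
      iteration = i, n_de_up = length(calls$up),
      n_de_down = length(calls$down), n_stable_up = length(s_up),
      n_stable_down = length(s_down)))

    if (plateau_reached(trace, config$patience, config$min_iters)) break
  }

  iterations_run <- nrow(trace)
  stable <- c(s_up, s_down)
  median_rank <- if (length(stable))
    apply(rank_store[stable, seq_len(iterations_run), drop = FALSE], 1L,
          median)
  else setNames(numeric(0), character(0))
  ever <- names(up_count)[up_count > 0L | down_count > 0L]
  call_frequency <- data.frame(
    gene = ever,
    up = up_count[ever] / iterations_run,
    down = down_count[ever] / iterations_run,
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(stable_up = s_up, stable_down = s_down,
                 call_frequency = call_frequency,
                 median_rank = median_rank, trace = trace,
                 iterations_run = iterations_run,
                 plateaued = plateau_reached(trace, config$patience,
                                             config$min_iters),
                 config = config, contrast_name = contrast$name),
            class = "stability_result")
}

#' Has the resampling trace reached its plateau?
#'
#' True iff the trace holds at least `min_iters` iterations and the last
#' `patience` values of the tracked size sequences are all equal. By
#' default the cumulative stable-set sizes (both directions) are
#' checked — the stopping rule of [resample_contrast()]. With
#' `which = "de"` the same windowed constancy check is applied to the
#' per-iteration DE call counts instead; an unstable, heterogeneous
#' contrast shows oscillating per-iteration counts that never satisfy
#' it, which is the practical diagnostic for such contrasts.
#'
#' @param trace The `trace` data.frame of a [resample_contrast()] run.
#' @param patience Window width (consecutive iterations).
#' @param min_iters Minimum trace length before a plateau can be
#'   declared.
#' @param which `"stable"` (cumulative sizes, default) or `"de"`
#'   (per-iteration call counts).
#' @return Logical scalar.
#' @export
plateau_reached <- function(trace, patience, min_iters,
                            which = c("stable", "de")) {
  which <- match.arg(which)
  if (!nrow(trace)) stop("trace is empty")
  n <- nrow(trace)
  if (n < min_iters || n < patience) return(FALSE)
  cols <- if (which == "stable") c("n_stable_up", "n_stable_down")
          else c("n_de_up", "n_de_down")
  win <- (n - patience + 1L):n
  all(vapply(cols, function(cl) {
    v <- trace[[cl]][win]
    all(v == v[1L])
  }, logical(1L)))
}

#' Median rank aggregation over iterations
#'
#' @param rank_table Numeric matrix, genes in rows (rownames required),
#'   one column per executed iteration.
#' @param genes Genes to aggregate (must be present in the table).
#' @return Named numeric vector of per-gene median ranks (true median:
#'   mean of the middle pair for even iteration counts).
#' @export
aggregate_ranks <- function(rank_table, genes) {
  stopifnot(is.matrix(rank_table), !is.null(rownames(rank_table)))
  missing <- setdiff(genes, rownames(rank_table))
  if (length(missing))
    stop("gene(s) absent from rank table: ", paste(missing, collapse = ", "))
  apply(rank_table[genes, , drop = FALSE], 1L, median)
}

#' Pairwise DE-count matrix across cell classes
#'
#' Summarizes the stability results of all ordered class pairs as the
#' asymmetric matrix of stable up-regulated gene counts: entry (i, j) is
#' the number of genes stably up in class i versus class j. By
#' orientation symmetry, entry (i, j) of this matrix equals the stable
#' *down* count of the (j, i) contrast. Suitable for distance-heatmap
#' rendering.
#'
#' @param results Named list of `stability_result` objects; names must
#'   be `"A_vs_B"` labels covering every ordered pair of the classes
#'   involved.
#' @return Square integer matrix of up-counts with class dimnames.
#' @export
de_count_matrix <- function(results) {
  stopifnot(is.list(results), !is.null(names(results)))
  pairs <- strsplit(names(results), "_vs_", fixed = TRUE)
  if (any(lengths(pairs) != 2L))
    stop("result names must be 'A_vs_B' labels")
  classes <- sort(unique(unlist(pairs)))
  m <- matrix(NA_integer_, length(classes), length(classes),
              dimnames = list(classes, classes))
  diag(m) <- 0L
  for (nm in names(results)) {
    p <- strsplit(nm, "_vs_", fixed = TRUE)[[1L]]
    m[p[1L], p[2L]] <- length(results[[nm]]$stable_up)
  }
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("missing contrast(s): ",
         paste(sprintf("%s_vs_%s", classes[miss[, 1L]], classes[miss[, 2L]]),
               collapse = ", "))
  }
  m
}

#' Serialize a stability result as a TSV pair plus YAML manifest
#'
#' Writes `<prefix>_stable.tsv` (gene, direction, call_frequency,
#' median_rank), `<prefix>_trace.tsv`, and `<prefix>_manifest.yaml`
#' (config echo, iterations run, plateau flag).
#'
#' @param result A `stability_result`.
#' @param prefix Path prefix for the three files.
#' @return The paths, invisibly.
#' @export
write_stability_result <- function(result, prefix) {
  stopifnot(inherits(result, "stability_result"))
  stable <- data.frame(
    gene = c(result$stable_up, result$stable_down),
    direction = rep(c("up", "down"),
                    c(length(result$stable_up), length(result$stable_down))),
    stringsAsFactors = FALSE)
  freq <- result$call_frequency
  stable$call_frequency <- ifelse(
    stable$direction == "up",
    freq$up[match(stable$gene, freq$gene)],
    freq$down[match(stable$gene, freq$gene)])
  stable$median_rank <- result$median_rank[stable$gene]
  paths <- paste0(prefix, c("_stable.tsv", "_trace.tsv", "_manifest.yaml"))
  write.table(stable, paths[1L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(result$trace, paths[2L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(list(contrast = result$contrast_name,
                        iterations_run = result$iterations_run,
                        plateaued = result$plateaued,
                        config = unclass(result$config)),
                   paths[3L])
  invisible(paths)
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "Stability result '%s': %d iterations%s, %d stable up / %d stable down\n",
    x$contrast_name, x$iterations_run,
    if (x$plateaued) " (plateau)" else " (no plateau)",
    length(x$stable_up), length(x$stable_down)))
  invisible(x)
}
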