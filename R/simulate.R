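#' Configuration for the synthetic expression compendium
#'
#' Describes a multi-cell-type, multi-batch compendium with planted
#' differential expression. Gene-wise noise variances follow a scaled
#' inverse-chi-square prior `s0_sq * d0 / chisq(d0)` — the distribution
#' assumed by the moderated-t model — so hyperparameter recovery is a
#' meaningful test downstream.
#'
#' @param n_genes Number of genes.
#' @param cell_classes `data.frame` with columns `name`, `lineage`
#'   (`"mesenchymal"` or `"hematopoietic"`) and `n_samples`.
#' @param n_batches Number of series/batches; samples are assigned
#'   round-robin across them.
#' @param batch_sd SD (log2 units) of the additive per-gene per-batch
#'   offsets, drawn N(0, batch_sd^2). `0` disables batch effects.
#' @param signature_plan `data.frame` with columns `contrast` (a label of
#'   the form `"A_vs_B"`, where each side names a cell class *or* a
#'   lineage), `n_up`, `n_down` and `effect` (log2 fold change > 0; an
#'   `effect` of 0 plants nothing). Planted gene sets are drawn without
#'   replacement from non-overlapping index blocks, so they are disjoint
#'   within and across contrasts.
#' @param noise_prior List with `d0` (prior degrees of freedom > 0) and
#'   `s0_sq` (prior variance, log2^2 units, > 0).
#' @param panel_plan Optional `data.frame` with columns `name`, `size`,
#'   `overlap` (fraction of the panel drawn from planted signature
#'   genes); used by [make_panel_collection()].
#' @param baseline_mean,baseline_sd Mean and SD (log2 units) of per-gene
#'   baseline expression.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       cell_classes = data.frame(
                         name = c("BM-MSC", "AD-MSC", "PL-MSC", "HSPC"),
                         lineage = c("mesenchymal", "mesenchymal",
                                     "mesenchymal", "hematopoietic"),
                         n_samples = c(10L, 10L, 10L, 10L)),
                       n_batches = 3L,
                       batch_sd = 0.5,
                       signature_plan = data.frame(
                         contrast = "mesenchymal_vs_hematopoietic",
                         n_up = 150L, n_down = 100L, effect = 1.5),
                       noise_prior = list(d0 = 4, s0_sq = 0.05),
                       panel_plan = NULL,
                       baseline_mean = 7, baseline_sd = 1.5,
                       seed = 1L) {
  n_genes <- .check_count(n_genes, "n_genes")
  n_batches <- .check_count(n_batches, "n_batches")
  seed <- .check_count(seed, "seed", min = 0L)
  stopifnot(is.data.frame(cell_classes),
            all(c("name", "lineage", "n_samples") %in% colnames(cell_classes)))
  if (nrow(cell_classes) < 1L) stop("cell class list is empty")
  if (anyDuplicated(cell_classes$name)) stop("duplicate cell class names")
  if (!all(cell_classes$lineage %in% c("mesenchymal", "hematopoietic")))
    stop("lineage must be 'mesenchymal' or 'hematopoietic'")
  if (any(cell_classes$n_samples < 1L)) stop("each class needs >= 1 sample")
  if (batch_sd < 0) stop("batch_sd must be >= 0")
  if (!is.null(signature_plan)) {
    stopifnot(is.data.frame(signature_plan),
              all(c("contrast", "n_up", "n_down", "effect") %in%
                    colnames(signature_plan)))
    if (any(signature_plan$effect < 0)) stop("effect sizes must be >= 0")
    if (any(signature_plan$n_up < 0 | signature_plan$n_down < 0))
      stop("planted set sizes must be >= 0")
    tot <- sum(signature_plan$n_up + signature_plan$n_down)
    if (tot > n_genes)
      stop(sprintf("planted signature sizes (%d) exceed n_genes (%d)",
                   tot, n_genes))
  }
  if (!(is.list(noise_prior) && noise_prior$d0 > 0 && noise_prior$s0_sq > 0))
    stop("noise_prior needs d0 > 0 and s0_sq > 0")
  structure(list(n_genes = n_genes, cell_classes = cell_classes,
                 n_batches = n_batches, batch_sd = batch_sd,
                 signature_plan = signature_plan, noise_prior = noise_prior,
                 panel_plan = panel_plan, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, seed = seed),
            class = "sim_config")
}

# Resolve one side of a contrast label to the cell classes it covers.
.contrast_side_classes <- function(side, cell_classes) {
  if (side %in% cell_classes$name) return(side)
  if (side %in% cell_classes$lineage)
    return(cell_classes$name[cell_classes$lineage == side])
  stop(sprintf("contrast side '%s' names no cell class or lineage", side))
}

.split_contrast <- function(label) {
  parts <- strsplit(label, "_vs_", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop(sprintf("contrast label '%s' is not of the form 'A_vs_B'", label))
  parts
}

#' Simulate a synthetic expression compendium with planted truth
#'
#' Generates a gene-by-sample log2 matrix: per-gene baselines
#' N(baseline_mean, baseline_sd^2), per-gene noise variances from a
#' scaled inverse-chi-square prior, additive per-gene per-batch offsets,
#' and class-mean shifts of +/- `effect` for the planted genes of each
#' contrast (A-minus-B orientation: "up" genes are shifted up in the A
#' side). Samples are assigned to batches round-robin in column order.
#'
#' @param config A [sim_config()].
#' @return A list with `matrix` (expression), `annotation` (one row per
#'   sample: sample_id, cell_type, lineage, tissue, batch) and `truth`
#'   (class `planted_truth`: `$de` data.frame of gene/contrast/direction/
#'   logfc, `$variance` named per-gene true noise variance, `$config`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  genes <- sprintf("G%05d", seq_len(G))
  cls <- config$cell_classes

  baseline <- rnorm(G, config$baseline_mean, config$baseline_sd)
  gvar <- config$noise_prior$s0_sq * config$noise_prior$d0 /
    rchisq(G, df = config$noise_prior$d0)
  batch_off <- matrix(rnorm(G * config$n_batches, 0, config$batch_sd),
                      nrow = G)

  # planted shifts: class-mean matrix, one column per cell class
  shift <- matrix(0, G, nrow(cls), dimnames = list(genes, cls$name))
  de <- data.frame(gene = character(), contrast = character(),
                   direction = character(), logfc = numeric(),
                   stringsAsFactors = FALSE)
  plan <- config$signature_plan
  if (!is.null(plan) && nrow(plan)) {
    pool <- sample.int(G)  # one shuffle; consecutive disjoint blocks
    ptr <- 0L
    for (i in seq_len(nrow(plan))) {
      eff <- plan$effect[i]
      n_up <- if (eff > 0) plan$n_up[i] else 0L
      n_dn <- if (eff > 0) plan$n_down[i] else 0L
      if (n_up + n_dn == 0L) next
      sides <- .split_contrast(plan$contrast[i])
      a_classes <- .contrast_side_classes(sides[1L], cls)
      up_idx <- pool[ptr + seq_len(n_up)]; ptr <- ptr + n_up
      dn_idx <- pool[ptr + seq_len(n_dn)]; ptr <- ptr + n_dn
      shift[up_idx, a_classes] <- shift[up_idx, a_classes] + eff
      shift[dn_idx, a_classes] <- shift[dn_idx, a_classes] - eff
      de <- rbind(de, data.frame(
        gene = genes[c(up_idx, dn_idx)],
        contrast = plan$contrast[i],
        direction = rep(c("up", "down"), c(n_up, n_dn)),
        logfc = rep(c(eff, -eff), c(n_up, n_dn)),
        stringsAsFactors = FALSE))
    }
  }

  class_of_col <- rep(cls$name, cls$n_samples)
  n_samp <- length(class_of_col)
  sample_ids <- unlist(lapply(seq_len(nrow(cls)), function(i)
    sprintf("%s_%02d", cls$name[i], seq_len(cls$n_samples[i]))))
  batch_idx <- ((seq_len(n_samp) - 1L) %% config$n_batches) + 1L

  noise <- matrix(rnorm(G * n_samp, 0, rep(sqrt(gvar), n_samp)),
                  nrow = G, ncol = n_samp)
  mat <- baseline + shift[, class_of_col, drop = FALSE] +
    batch_off[, batch_idx, drop = FALSE] + noise
  dimnames(mat) <- list(genes, sample_ids)

  annotation <- data.frame(
    sample_id = sample_ids,
    cell_type = class_of_col,
    lineage = cls$lineage[match(class_of_col, cls$name)],
    tissue = class_of_col,
    batch = sprintf("batch%d", batch_idx),
    stringsAsFactors = FALSE)

  truth <- structure(list(de = de, variance = setNames(gvar, genes),
                          genes = genes, config = config),
                     class = "planted_truth")
  list(matrix = mat, annotation = annotation, truth = truth)
}

#' Genes planted in one direction of a contrast
#'
#' @param truth A `planted_truth` object.
#' @param contrast Contrast label as in the signature plan.
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene ids.
#' @export
planted_genes <- function(truth, contrast, direction = "up") {
  stopifnot(inherits(truth, "planted_truth"))
  de <- truth$de
  de$gene[de$contrast == contrast & de$direction == direction]
}

#' Simulate growth records for population doubling-time analysis
#'
#' Emits per class/passage records of cells seeded (`q1`), cells
#' harvested (`q2`) and expansion time (`texpan`, hours), consistent with
#' exponential growth at a class-specific doubling time plus record-level
#' noise. Harvested counts are kept continuous so that with `noise_sd =
#' 0` the derived doubling time reproduces the class truth exactly; the
#' generator clamps noisy doubling times at 1 h so growth is always
#' positive (`q2 > q1`).
#'
#' @param true_pdt Named numeric vector of true population doubling times
#'   (hours), one per cell class.
#' @param n_passages Passages per class (>= 2).
#' @param records_per_passage Cultures recorded per class and passage.
#' @param texpan Expansion time per record (hours).
#' @param noise_sd SD (hours) of the per-record doubling-time noise.
#' @param seed Integer seed.
#' @return `data.frame` with columns `culture_id`, `class`, `passage`,
#'   `q1`, `q2`, `texpan`.
#' @export
simulate_growth_records <- function(true_pdt, n_passages = 3L,
                                    records_per_passage = 2L,
                                    texpan = 96, noise_sd = 3, seed = 1L) {
  if (!length(true_pdt) || is.null(names(true_pdt)))
    stop("true_pdt must be a named vector with >= 1 class")
  n_passages <- .check_count(n_passages, "n_passages", min = 2L)
  records_per_passage <- .check_count(records_per_passage,
                                      "records_per_passage")
  set.seed(seed)
  rows <- expand.grid(rec = seq_len(records_per_passage),
                      passage = seq_len(n_passages),
                      class = names(true_pdt),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pdt <- true_pdt[rows$class] + rnorm(nrow(rows), 0, noise_sd)
  pdt <- pmax(pdt, 1)  # clamp: always positive growth
  q1 <- 1e5
  data.frame(
    culture_id = sprintf("%s_p%d_r%d", rows$class, rows$passage, rows$rec),
    class = rows$class,
    passage = rows$passage,
    q1 = q1,
    q2 = q1 * 2 ^ (texpan / pdt),
    texpan = texpan,
    stringsAsFactors = FALSE)
}

#' Build synthetic marker panels from planted truth
#'
#' Emulates curated marker panels (CD antigens, cytokine genes): each
#' panel of size `size` draws `round(size * overlap)` members from the
#' planted signature genes and the remainder from unplanted genes.
#'
#' @param truth A `planted_truth` object.
#' @param panel_plan `data.frame` with columns `name`, `size`, `overlap`;
#'   defaults to the plan stored in the truth's config.
#' @param seed Integer seed.
#' @return A [gene_set_collection()].
#' @export
make_panel_collection <- function(truth, panel_plan = NULL, seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  if (is.null(panel_plan)) panel_plan <- truth$config$panel_plan
  if (is.null(panel_plan) || !nrow(panel_plan))
    stop("no panel plan supplied")
  stopifnot(all(c("name", "size", "overlap") %in% colnames(panel_plan)))
  set.seed(seed)
  planted <- unique(truth$de$gene)
  free <- setdiff(truth$genes, planted)
  sets <- lapply(seq_len(nrow(panel_plan)), function(i) {
    size <- panel_plan$size[i]
    n_in <- round(size * panel_plan$overlap[i])
    if (n_in > length(planted) || n_in > size ||
        (size - n_in) > length(free))
      stop(sprintf("panel '%s': requested overlap infeasible",
                   panel_plan$name[i]))
    c(if (n_in > 0L) sample(planted, n_in),
      if (size - n_in > 0L) sample(free, size - n_in))
  })
  gene_set_collection(setNames(sets, panel_plan$name))
}

#' Synthetic stand-in for an external expression footprint
#'
#' Real analyses intersect candidate signatures with an externally
#' derived list of genes expressed in the cell type of interest (for
#' example an RNA-Seq "ON" footprint). This helper builds such a list for
#' a synthetic run: all genes planted `up` in `contrast` plus `n_extra`
#' random unplanted genes. It is synthetic by construction and labelled
#' as such; it stands in for a published list, which is consumed as a
#' plain gene set.
#'
#' @param truth A `planted_truth` object.
#' @param contrast Contrast whose up-regulated plant the footprint must
#'   contain.
#' @param n_extra Number of additional random genes.
#' @param seed Integer seed.
#' @return Character vector of gene ids.
#' @export
make_footprint <- function(truth, contrast, n_extra = 200L, seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  set.seed(seed)
  core <- planted_genes(truth, contrast, "up")
  extra <- sample(setdiff(truth$genes, unique(truth$de$gene)),
                  min(n_extra, length(setdiff(truth$genes,
                                              unique(truth$de$gene)))))
  sort(unique(c(core, extra)))
}
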