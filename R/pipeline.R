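#' Default configuration of the end-to-end synthetic analysis
#'
#' The default run emulates the study conditions of a stromal
#' compendium analysis at desk scale: 2,000 genes; three mesenchymal
#' classes (BM-, AD-, PL-MSC) of 10 samples each plus 10 hematopoietic
#' HSPC samples; three batches with additive per-gene offsets
#' (SD 0.5 log2 units); a planted mesenchymal lineage core (150 genes up
#' at log2FC 1.5, 100 down) plus per-tissue plants (40 genes up per
#' tissue class); noise variances from scaled
#' inverse-chi-square(d0 = 4, s0_sq = 0.05); CD-like and cytokine-like
#' marker panels; 7-vs-7 resampling at FDR < 0.05 (60-iteration budget,
#' plateau patience 10 after 25); coexpression threshold r >= 0.95.
#'
#' @param seed Integer seed; all stage seeds derive from it.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      n_genes = 2000L,
      cell_classes = data.frame(
        name = c("BM-MSC", "AD-MSC", "PL-MSC", "HSPC"),
        lineage = c("mesenchymal", "mesenchymal", "mesenchymal",
                    "hematopoietic"),
        n_samples = c(10L, 10L, 10L, 10L)),
      n_batches = 3L,
      batch_sd = 0.5,
      signature_plan = data.frame(
        contrast = c("mesenchymal_vs_hematopoietic", "BM-MSC_vs_HSPC",
                     "AD-MSC_vs_HSPC", "PL-MSC_vs_HSPC"),
        n_up = c(150L, 40L, 40L, 40L),
        n_down = c(100L, 0L, 0L, 0L),
        effect = c(1.5, 1.5, 1.5, 1.5)),
      noise_prior = list(d0 = 4, s0_sq = 0.05),
      panel_plan = data.frame(
        name = c("CD_panel", "cytokine_panel"),
        size = c(120L, 80L),
        overlap = c(0.4, 0.3)),
      baseline_mean = 7, baseline_sd = 1.5,
      footprint_extra = 200L),
    normalize = list(per_batch_n = 3L),
    stability = list(k_per_group = 7L, alpha = 0.05, max_iters = 200L,
                     min_iters = 50L, patience = 20L,
                     meta_type_a = "BM-MSC", meta_type_b = "HSPC"),
    contrasts = data.frame(
      type_a = c("BM-MSC", "AD-MSC", "PL-MSC"),
      type_b = c("HSPC", "HSPC", "HSPC")),
    de = list(alpha = 0.05),
    filter = list(keep_fraction = 0.5),
    network = list(r_min = 0.95, absolute = FALSE),
    growth = list(true_pdt = list("BM-MSC" = 35, "AD-MSC" = 60),
                  n_passages = 5L, records_per_passage = 4L,
                  texpan = 120, noise_sd = 4))
}

# yaml round-trips data.frames as column lists; coerce back.
.cfg_df <- function(x) {
  if (is.null(x) || is.data.frame(x)) x
  else as.data.frame(x, stringsAsFactors = FALSE)
}

.normalize_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config$simulate$cell_classes <- .cfg_df(config$simulate$cell_classes)
  config$simulate$signature_plan <- .cfg_df(config$simulate$signature_plan)
  config$simulate$panel_plan <- .cfg_df(config$simulate$panel_plan)
  config$contrasts <- .cfg_df(config$contrasts)
  if (!is.null(config$growth$true_pdt))
    config$growth$true_pdt <- unlist(config$growth$true_pdt)
  config
}

# Hash an R object (via its yaml serialization) and files.
.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(x, f)
  unname(md5sum(f))
}

.hash_files <- function(paths) {
  h <- md5sum(paths)
  setNames(unname(h), basename(paths))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in dependency order: synthetic-data generation,
#' frozen-reference normalization, the resampling stability protocol for
#' every configured contrast, signature derivation (lineage core via the
#' intersection flow, plus recovery metrics against the planted truth),
#' marker-panel enrichment, structure analyses (PCA, correlation-derived
#' sample distances, average-linkage clustering) and the thresholded
#' coexpression network over the core signature. Every stage writes TSV
#' /GMT/YAML artifacts into `outdir` and is recorded in a run manifest
#' with input/output file hashes; re-running skips stages whose
#' configuration and inputs are hash-unchanged and whose outputs are
#' intact (use `force = TRUE` to re-execute everything).
#'
#' @param config Configuration list (see [default_pipeline_config()]) or
#'   path to an equivalent YAML file.
#' @param outdir Output directory (created if absent).
#' @param force Re-execute all stages regardless of the hash cache.
#' @return The run manifest (class `run_manifest`), invisibly; its
#'   `stages` element records per-stage hashes, timings and skip flags.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir,
                         force = FALSE) {
  config <- .normalize_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(outdir, "manifest.yaml")
  prev <- if (file.exists(manifest_path) && !force)
    yaml::read_yaml(manifest_path) else NULL
  seed <- config$seed
  manifest <- list(tool = "stromasig",
                   version = as.character(packageVersion("stromasig")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed, stages = list())
  log_msg <- function(...) message(sprintf(...))

  run_stage <- function(name, cfg_part, inputs, outputs, fn) {
    cfg_hash <- .hash_obj(cfg_part)
    in_hash <- if (length(inputs)) .hash_files(file.path(outdir, inputs))
               else character()
    ps <- prev$stages[[name]]
    out_paths <- file.path(outdir, outputs)
    can_skip <- !is.null(ps) &&
      identical(ps$config_hash, cfg_hash) &&
      identical(ps$input_hashes, as.list(in_hash)) &&
      all(file.exists(out_paths)) &&
      identical(as.list(.hash_files(out_paths)), ps$output_hashes)
    if (can_skip) {
      log_msg("stage %s: inputs unchanged, skipped", name)
      rec <- ps
      rec$skipped <- TRUE
    } else {
      t0 <- proc.time()[["elapsed"]]
      fn()
      rec <- list(config_hash = cfg_hash,
                  input_hashes = as.list(in_hash),
                  output_hashes = as.list(.hash_files(out_paths)),
                  outputs = as.list(outputs),
                  seconds = round(proc.time()[["elapsed"]] - t0, 3),
                  skipped = FALSE)
      log_msg("stage %s: done (%.1fs)", name, rec$seconds)
    }
    manifest$stages[[name]] <<- rec
  }

  ## -- simulate ------------------------------------------------------
  sim_cfg <- config$simulate
  run_stage(
    "simulate", list(sim = sim_cfg, growth = config$growth, seed = seed),
    inputs = character(),
    outputs = c("expression.tsv", "annotation.tsv", "truth.tsv",
                "panels.gmt", "footprint.gmt", "growth_records.tsv"),
    fn = function() {
      sc <- sim_config(
        n_genes = sim_cfg$n_genes, cell_classes = sim_cfg$cell_classes,
        n_batches = sim_cfg$n_batches, batch_sd = sim_cfg$batch_sd,
        signature_plan = sim_cfg$signature_plan,
        noise_prior = sim_cfg$noise_prior,
        panel_plan = sim_cfg$panel_plan,
        baseline_mean = sim_cfg$baseline_mean,
        baseline_sd = sim_cfg$baseline_sd,
        seed = .derive_seed(seed, "simulate"))
      sim <- simulate_dataset(sc)
      write_expression(sim$matrix, file.path(outdir, "expression.tsv"))
      write_annotation(sim$annotation, file.path(outdir, "annotation.tsv"))
      truth_tab <- sim$truth$de
      truth_tab$variance <- sim$truth$variance[truth_tab$gene]
      write.table(truth_tab, file.path(outdir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      panels <- make_panel_collection(sim$truth,
                                      seed = .derive_seed(seed, "panels"))
      write_gmt(panels, file.path(outdir, "panels.gmt"))
      fp <- make_footprint(sim$truth, "mesenchymal_vs_hematopoietic",
                           n_extra = sim_cfg$footprint_extra,
                           seed = .derive_seed(seed, "footprint"))
      write_gmt(gene_set_collection(list(footprint = fp)),
                file.path(outdir, "footprint.gmt"))
      gr <- simulate_growth_records(
        config$growth$true_pdt, n_passages = config$growth$n_passages,
        records_per_passage = config$growth$records_per_passage,
        texpan = config$growth$texpan, noise_sd = config$growth$noise_sd,
        seed = .derive_seed(seed, "growth"))
      write.table(gr, file.path(outdir, "growth_records.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    })

  ## -- normalize -----------------------------------------------------
  run_stage(
    "normalize", list(cfg = config$normalize, seed = seed),
    inputs = c("expression.tsv", "annotation.tsv"),
    outputs = c("normalized.tsv", file.path("frozen_ref", "index.yaml")),
    fn = function() {
      mat <- read_expression(file.path(outdir, "expression.tsv"))
      ann <- read_annotation(file.path(outdir, "annotation.tsv"))
      batch <- ann$batch[match(colnames(mat), ann$sample_id)]
      ref <- build_frozen_reference(
        mat, batch, per_batch_n = config$normalize$per_batch_n,
        seed = .derive_seed(seed, "normalize"))
      write_frozen_reference(ref, file.path(outdir, "frozen_ref"))
      norm <- apply_frozen_normalization(mat, ref, batch)
      write_expression(norm, file.path(outdir, "normalized.tsv"))
    })

  ## -- tissue-level moderated DE (one table per configured contrast) --
  contrast_names <- sprintf("%s_vs_%s", config$contrasts$type_a,
                            config$contrasts$type_b)
  run_stage(
    "diffexpr", list(cfg = config$de, contrasts = config$contrasts),
    inputs = c("normalized.tsv", "annotation.tsv"),
    outputs = paste0("de_", contrast_names, ".tsv"),
    fn = function() {
      mat <- read_expression(file.path(outdir, "normalized.tsv"))
      ann <- read_annotation(file.path(outdir, "annotation.tsv"))
      for (i in seq_len(nrow(config$contrasts))) {
        ct <- contrast_from_annotation(ann, config$contrasts$type_a[i],
                                       config$contrasts$type_b[i])
        de <- run_de(mat, ct, alpha = config$de$alpha)
        write_de_result(de, file.path(outdir,
                                      paste0("de_", contrast_names[i],
                                             ".tsv")))
      }
    })

  ## -- stability resampling of the meta-analysis contrast ------------
  run_stage(
    "stability", list(cfg = config$stability, seed = seed),
    inputs = c("normalized.tsv", "annotation.tsv"),
    outputs = paste0("stability_meta", c("_stable.tsv", "_trace.tsv",
                                         "_manifest.yaml")),
    fn = function() {
      mat <- read_expression(file.path(outdir, "normalized.tsv"))
      ann <- read_annotation(file.path(outdir, "annotation.tsv"))
      ct <- contrast_from_annotation(ann, config$stability$meta_type_a,
                                     config$stability$meta_type_b)
      rc <- resampling_config(
        k_per_group = config$stability$k_per_group,
        alpha = config$stability$alpha,
        max_iters = config$stability$max_iters,
        min_iters = config$stability$min_iters,
        patience = config$stability$patience,
        seed = .derive_seed(seed, "stability_meta"))
      res <- resample_contrast(mat, ct, rc)
      write_stability_result(res, file.path(outdir, "stability_meta"))
    })

  ## -- signatures: the cross-flow intersection -----------------------
  run_stage(
    "signatures", list(seed = seed),
    inputs = c(paste0("de_", contrast_names, ".tsv"),
               "stability_meta_stable.tsv", "footprint.gmt", "panels.gmt",
               "truth.tsv", "normalized.tsv"),
    outputs = c("core_signature.tsv", "enrichment.tsv", "recovery.yaml"),
    fn = function() {
      alpha <- config$de$alpha
      up_lists <- lapply(contrast_names, function(nm) {
        tab <- read.delim(file.path(outdir, paste0("de_", nm, ".tsv")),
                          stringsAsFactors = FALSE)
        tab$gene[tab$fdr < alpha & tab$logfc > 0]
      })
      names(up_lists) <- contrast_names
      meta <- read.delim(file.path(outdir, "stability_meta_stable.tsv"),
                         stringsAsFactors = FALSE)
      meta_up <- meta$gene[meta$direction == "up"]
      fp <- read_gmt(file.path(outdir, "footprint.gmt"))$footprint
      core <- lineage_core_signature(up_lists, meta_up = meta_up,
                                     footprint = fp)
      write.table(data.frame(gene = core$genes),
                  file.path(outdir, "core_signature.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      mat <- read_expression(file.path(outdir, "normalized.tsv"))
      panels <- read_gmt(file.path(outdir, "panels.gmt"))
      enr <- lapply(names(panels), function(p)
        panel_enrichment(core$genes, panels[[p]], rownames(mat),
                         panel_name = p))
      write.table(data.frame(
        panel = vapply(enr, `[[`, "", "panel"),
        N = vapply(enr, `[[`, 0L, "N"), K = vapply(enr, `[[`, 0L, "K"),
        n = vapply(enr, `[[`, 0L, "n"), k = vapply(enr, `[[`, 0L, "k"),
        p = vapply(enr, `[[`, 0, "p")),
        file.path(outdir, "enrichment.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      truth <- read.delim(file.path(outdir, "truth.tsv"),
                          stringsAsFactors = FALSE)
      planted <- truth$gene[
        truth$contrast == "mesenchymal_vs_hematopoietic" &
          truth$direction == "up"]
      sens <- if (length(planted))
        length(intersect(core$genes, planted)) / length(planted) else NA
      fir <- if (length(core$genes))
        length(setdiff(core$genes, planted)) / length(core$genes) else 0
      yaml::write_yaml(list(core_size = length(core$genes),
                            planted_size = length(planted),
                            sensitivity = sens,
                            false_inclusion_rate = fir,
                            stages = as.list(setNames(core$stages$size,
                                                      core$stages$stage))),
                       file.path(outdir, "recovery.yaml"))
    })

  ## -- structure -----------------------------------------------------
  run_stage(
    "structure", list(cfg = config$filter),
    inputs = "normalized.tsv",
    outputs = c("pca_variance.tsv", "sample_distances.tsv"),
    fn = function() {
      mat <- read_expression(file.path(outdir, "normalized.tsv"))
      pca <- pca_expression(mat, variables = "genes")
      write.table(data.frame(
        component = seq_along(pca$variance_fraction),
        variance_fraction = sprintf("%.15g", pca$variance_fraction),
        cumulative = sprintf("%.15g", pca$cumulative_variance)),
        file.path(outdir, "pca_variance.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      dmat <- correlation_distance_matrix(
        variance_filter(mat, config$filter$keep_fraction))
      hcluster_samples(dmat)  # validated; heights deterministic
      write_expression(dmat, file.path(outdir, "sample_distances.tsv"),
                       id_column = "sample_id")
    })

  ## -- network -------------------------------------------------------
  run_stage(
    "network", list(cfg = config$network),
    inputs = c("normalized.tsv", "core_signature.tsv"),
    outputs = c("network_edges.tsv", "network.sif"),
    fn = function() {
      mat <- read_expression(file.path(outdir, "normalized.tsv"))
      core <- read.delim(file.path(outdir, "core_signature.tsv"),
                         stringsAsFactors = FALSE)$gene
      genes <- if (length(core) >= 2L) core else rownames(mat)
      net <- coexpression_network(mat, genes = genes,
                                  r_min = config$network$r_min,
                                  absolute = config$network$absolute)
      if (nrow(net$edges)) {
        export_network(net, file.path(outdir, "network_edges.tsv"),
                       "edgelist")
        export_network(net, file.path(outdir, "network.sif"), "sif")
      } else {
        # no pair above threshold: still emit headers for downstream tools
        writeLines("gene_a\tgene_b\tr",
                   file.path(outdir, "network_edges.tsv"))
        writeLines(character(), file.path(outdir, "network.sif"))
      }
    })

  ## -- growth --------------------------------------------------------
  run_stage(
    "growth", list(cfg = config$growth),
    inputs = "growth_records.tsv",
    outputs = c("growth_pdt.tsv", "growth_test.yaml"),
    fn = function() {
      gr <- growth_pdt(read.delim(file.path(outdir, "growth_records.tsv"),
                                  stringsAsFactors = FALSE))
      write.table(gr, file.path(outdir, "growth_pdt.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      classes <- unique(gr$class)
      test <- if (length(classes) >= 2L)
        compare_growth(gr$pdt[gr$class == classes[1L]],
                       gr$pdt[gr$class == classes[2L]])
      else list(statistic = NA, p.value = NA, method = "single class")
      yaml::write_yaml(list(class_a = classes[1L],
                            class_b = if (length(classes) >= 2L)
                              classes[2L] else NA,
                            W = unname(test$statistic),
                            p_value = test$p.value,
                            method = test$method),
                       file.path(outdir, "growth_test.yaml"))
    })

  yaml::write_yaml(manifest, manifest_path)
  invisible(structure(manifest, class = "run_manifest"))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("stromasig run (seed %d): %d stages\n", x$seed,
              length(x$stages)))
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-10s %s\n", nm,
                if (isTRUE(s$skipped)) "skipped (cached)"
                else sprintf("ran in %.1fs", s$seconds)))
  }
  invisible(x)
}
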