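#' Read and validate a pipeline configuration
#'
#' Config files are YAML (or JSON, which YAML subsumes). Required keys:
#' `network`, `gene_sets_dir`, `annotations`, `locus` (`chrom`, `start`,
#' `end`), `seed`, `out_dir`, and either `snp_pvalues` (precomputed
#' associations) or both `genotypes` and `phenotype`. Optional: `ensemble`
#' (`n_runs`, `folds`, `max_size`, `max_refinements`, `fpr_floor`),
#' `alpha`, `annotations_format`, `max_snp_gene_dist`.
#'
#' @param path Path to the config file, or an already-parsed list.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  required <- c("network", "gene_sets_dir", "annotations", "locus", "seed",
                "out_dir")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    abort(sprintf("Pipeline config is missing: %s",
                  paste(missing, collapse = ", ")))
  }
  has_scan <- all(c("genotypes", "phenotype") %in% names(cfg))
  if (!has_scan && !("snp_pvalues" %in% names(cfg))) {
    abort("Config needs either `snp_pvalues` or `genotypes` + `phenotype`.")
  }
  for (key in intersect(
    c("network", "gene_sets_dir", "annotations", "genotypes", "phenotype",
      "snp_pvalues"),
    names(cfg)
  )) {
    if (!file.exists(cfg[[key]])) {
      abort(sprintf("Config path `%s` does not exist: %s", key, cfg[[key]]))
    }
  }
  cfg$locus <- as_region(cfg$locus)
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$annotations_format <- cfg$annotations_format %||% "tsv"
  cfg$max_snp_gene_dist <- cfg$max_snp_gene_dist %||% 1e6
  ens <- cfg$ensemble %||% list()
  cfg$ensemble <- list(
    n_runs = ens$n_runs %||% 100,
    folds = ens$folds %||% 10,
    max_size = ens$max_size %||% 400,
    max_refinements = ens$max_refinements %||% 5
  )
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full prioritization pipeline
#'
#' Executes, in order: input loading; selection of positional candidates
#' (annotated genes overlapping the locus); exclusion of candidates from
#' the training gene sets; iterative clustering of each set into modules;
#' per-module SVM ensemble training and per-gene FPR calibration;
#' mixed-model SNP association over the locus (or ingestion of precomputed
#' p-values) with the kinship computed from SNPs outside the locus;
#' SNP-to-gene assignment; the combined gene score with Pareto-front
#' flagging; and ranked TSV outputs. Each stage writes an intermediate file
#' under `out_dir` and logs counts to stderr and `run.log`. Reruns with an
#' identical config are bit-identical: all randomness derives from the
#' config seed via counter-based sub-seeds (one per module).
#'
#' @param config Path to a YAML/JSON config or a config list; see
#'   [read_pipeline_config()].
#' @return The `gene_score_table`, invisibly, with attributes
#'   `"module_scores"`, `"scan"`, `"ensembles"` (glances), and `"paths"`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- character()
  stage <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    log_msg(line)
  }
  with_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }

  # --- load ------------------------------------------------------------
  net <- with_stage("load_network", read_edge_list(cfg$network))
  ann <- with_stage("load_annotations",
                    read_gene_annotations(cfg$annotations,
                                          cfg$annotations_format))
  sets <- with_stage("load_gene_sets", read_gene_sets(cfg$gene_sets_dir))
  stage("Loaded %d network nodes, %d annotated genes, %d gene-set entries.",
        length(net$nodes), nrow(ann), nrow(sets))

  candidates <- dplyr::filter(
    ann, .data$chrom == cfg$locus$chrom,
    .data$end >= cfg$locus$start, .data$start <= cfg$locus$end
  )
  if (!nrow(candidates)) abort("No positional candidates inside the locus.")
  stage("%d positional candidate gene(s) in %s:%g-%g.",
        nrow(candidates), cfg$locus$chrom, cfg$locus$start, cfg$locus$end)

  # --- training sets and modules --------------------------------------
  sets <- with_stage("exclude_candidates",
                     exclude_genes(sets, candidates$gene_id))
  modules <- with_stage("cluster",
                        cluster_gene_sets(net, sets,
                                          max_size = cfg$ensemble$max_size))
  readr::write_tsv(modules, file.path(cfg$out_dir, "modules.tsv"))
  module_list <- modules |>
    dplyr::group_by(.data$term, .data$module_index) |>
    dplyr::group_split()
  stage("Training %d module ensemble(s), %d runs each.",
        length(module_list), cfg$ensemble$n_runs)

  # --- SVM ensembles ---------------------------------------------------
  ensembles <- with_stage("train", purrr::imap(module_list, function(md, k) {
    ens <- train_ensemble(
      net, md$gene_id,
      universe = net$nodes,
      n_runs = cfg$ensemble$n_runs,
      folds = cfg$ensemble$folds,
      max_refinements = cfg$ensemble$max_refinements,
      seed = derive_seed(cfg$seed, 1000 + k),
      term = md$term[1], module_index = md$module_index[1]
    )
    stage("Module %s/%d: AUC %.3f over %d run(s).",
          md$term[1], md$module_index[1], ens$auc, ens$n_runs)
    ens
  }))
  module_scores <- purrr::map_dfr(ensembles, tidy)
  readr::write_tsv(module_scores,
                   file.path(cfg$out_dir, "ensemble_scores.tsv"))

  func <- with_stage("functional_score", functional_score(module_scores))

  # --- association -----------------------------------------------------
  if (!is.null(cfg$snp_pvalues)) {
    scan <- with_stage("read_snp_pvalues", read_snp_pvalues(cfg$snp_pvalues))
    scan <- dplyr::filter(
      scan, .data$chrom == cfg$locus$chrom,
      .data$pos >= cfg$locus$start, .data$pos <= cfg$locus$end
    )
    stage("Ingested %d precomputed SNP p-value(s) in the locus.", nrow(scan))
  } else {
    geno <- with_stage("load_genotypes", read_genotypes(cfg$genotypes))
    pheno <- with_stage("load_phenotype", read_phenotype(cfg$phenotype))
    K <- with_stage("kinship",
                    compute_kinship(geno, exclude_region = cfg$locus))
    scan <- with_stage("scan", snp_scan(geno, pheno, K, region = cfg$locus))
    stage("Scanned %d locus SNP(s); min p = %.3g.",
          nrow(scan), min(scan$p_value))
  }
  thr <- bonferroni_threshold(cfg$alpha, max(nrow(scan), 1))
  scan_out <- dplyr::mutate(as_tibble(scan), significant = .data$p_value <= thr)
  readr::write_tsv(scan_out, file.path(cfg$out_dir, "assoc_snps.tsv"))
  stage("Bonferroni threshold %.3g (%d significant SNP(s)).",
        thr, sum(scan_out$significant))

  gene_assoc <- with_stage(
    "assign_snps",
    assign_snps_to_genes(scan, candidates, max_dist = cfg$max_snp_gene_dist)
  )
  readr::write_tsv(gene_assoc, file.path(cfg$out_dir, "gene_assoc.tsv"))

  # --- combine ---------------------------------------------------------
  table <- with_stage("combine", combined_score(
    candidates, func, gene_assoc, network_genes = net$nodes
  ))
  paths <- with_stage("write", write_ranked_outputs(
    table, cfg$out_dir,
    module_scores = module_scores,
    snp_assignments = attr(gene_assoc, "assignments")
  ))
  stage("Top candidate: %s (S_cg = %.3f); %d gene(s) on the Pareto front.",
        table$gene_id[1], table$s_cg[1], sum(table$pareto))
  writeLines(log_lines, log_path)

  attr(table, "module_scores") <- module_scores
  attr(table, "scan") <- scan_out
  attr(table, "ensembles") <- purrr::map_dfr(ensembles, glance)
  attr(table, "paths") <- paths
  invisible(table)
}
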