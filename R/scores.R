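#' Per-gene functional score across all trained modules
#'
#' A gene's functional score is the maximum of `-log10(FPR)` over every
#' module of every term. Taking the maximum (rather than an average) lets a
#' gene strongly tied to a single trait process outrank genes with uniform
#' moderate ties.
#'
#' @param module_scores Tibble stacking per-module ensemble scores
#'   (columns `term`, `module_index`, `gene_id`, `fpr`), e.g. bound rows of
#'   [tidy.svm_ensemble()].
#' @return Tibble (`gene_id`, `functional_score`, `best_term`,
#'   `best_module`).
#' @export
functional_score <- function(module_scores) {
  module_scores <- as_tibble(module_scores)
  if (!nrow(module_scores)) abort("No module scores supplied.")
  if (any(module_scores$fpr <= 0)) {
    abort("FPR <= 0 encountered; upstream flooring should prevent this.")
  }
  module_scores |>
    dplyr::mutate(neglog10_fpr = -log10(.data$fpr)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      functional_score = max(.data$neglog10_fpr),
      best_term = .data$term[which.max(.data$neglog10_fpr)],
      best_module = .data$module_index[which.max(.data$neglog10_fpr)]
    )
}

#' Combined gene score over the positional candidates
#'
#' For each positional candidate the raw positional term (`-log10 p` from
#' the mixed-model scan, via the gene's best assigned SNP) and the raw
#' functional term (`-log10 FPR`, max over modules) are each divided by
#' their maximum over the candidates, making the two axes comparable; the
#' combined score `s_cg` is their sum, so `s_cg` lies in `[0, 2]`. Genes
#' absent from the network keep a zero functional term and are flagged
#' `not_in_network`; genes with no assigned SNP keep a zero positional
#' term. A term whose maximum is zero is set to zero for all genes with a
#' warning. The Pareto front over the two normalized axes is flagged.
#'
#' @param candidates Gene annotation tibble of the positional candidates
#'   (`gene_id`, `chrom`, `start`, `end`).
#' @param functional Tibble from [functional_score()] (or any tibble with
#'   `gene_id`, `functional_score`).
#' @param positional Tibble with `gene_id`, `max_neglog10p` (e.g. from
#'   [assign_snps_to_genes()]).
#' @param network_genes Optional character vector of network node ids used
#'   to flag candidates absent from the network.
#' @return A `gene_score_table`: tibble sorted by `s_cg` descending
#'   (ties broken by `gene_id`) with columns `gene_id`, `chrom`, `start`,
#'   `end`, `neglog10_p`, `neglog10_fpr`, `norm_positional`,
#'   `norm_functional`, `s_cg`, `pareto`, `not_in_network`.
#' @export
combined_score <- function(candidates, functional, positional,
                           network_genes = NULL) {
  candidates <- as_tibble(candidates)
  if (!nrow(candidates)) abort("`candidates` must be non-empty.")
  tab <- candidates |>
    dplyr::left_join(
      dplyr::select(as_tibble(functional), "gene_id", "functional_score"),
      by = "gene_id"
    ) |>
    dplyr::left_join(
      dplyr::select(as_tibble(positional), "gene_id", "max_neglog10p"),
      by = "gene_id"
    ) |>
    dplyr::mutate(
      not_in_network = if (is.null(network_genes)) {
        is.na(.data$functional_score)
      } else {
        !(.data$gene_id %in% network_genes)
      },
      neglog10_fpr = dplyr::coalesce(.data$functional_score, 0),
      neglog10_p = dplyr::coalesce(.data$max_neglog10p, 0)
    )
  norm_by_max <- function(x, label) {
    m <- max(x)
    if (m <= 0) {
      warn(sprintf("All %s terms are zero; normalized term set to 0.", label))
      return(rep(0, length(x)))
    }
    x / m
  }
  tab <- tab |>
    dplyr::mutate(
      norm_positional = norm_by_max(.data$neglog10_p, "positional"),
      norm_functional = norm_by_max(.data$neglog10_fpr, "functional"),
      s_cg = .data$norm_positional + .data$norm_functional
    ) |>
    dplyr::select(
      "gene_id", "chrom", "start", "end", "neglog10_p", "neglog10_fpr",
      "norm_positional", "norm_functional", "s_cg", "not_in_network"
    ) |>
    dplyr::arrange(dplyr::desc(.data$s_cg), .data$gene_id)
  tab$pareto <- pareto_front(tab)
  class(tab) <- c("gene_score_table", class(tab))
  tab
}

#' Pareto front of the two score axes
#'
#' A gene is on the front iff no other gene is at least as good on both
#' normalized axes and strictly better on at least one. Computed by a
#' descending sweep over x groups; duplicated points are mutually
#' non-dominating and all kept.
#'
#' @param table Data frame with columns `norm_positional`,
#'   `norm_functional` (e.g. a `gene_score_table`).
#' @return Logical vector flagging front membership, aligned to rows of
#'   `table`.
#' @export
pareto_front <- function(table) {
  x <- table$norm_positional
  y <- table$norm_functional
  n <- length(x)
  if (!n) abort("`table` must be non-empty.")
  front <- logical(n)
  ord <- order(-x, -y)
  xs <- x[ord]; ys <- y[ord]
  best_y <- -Inf  # max y among points with strictly larger x
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && xs[j + 1] == xs[i]) j <- j + 1L
    grp <- i:j
    ymax_g <- ys[i]  # within ties on x, ys is sorted descending
    on <- ys[grp] > best_y & ys[grp] == ymax_g
    front[ord[grp]] <- on
    best_y <- max(best_y, ymax_g)
    i <- j + 1L
  }
  front
}

#' @export
print.gene_score_table <- function(x, ...) {
  cat(sprintf(
    "<gene_score_table> %d positional candidates, %d on the Pareto front\n",
    nrow(x), sum(x$pareto)
  ))
  NextMethod()
}

#' @export
autoplot.gene_score_table <- function(object, ...) {
  front <- dplyr::arrange(
    dplyr::filter(object, .data$pareto),
    dplyr::desc(.data$norm_positional), .data$norm_functional
  )
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$norm_positional, y = .data$norm_functional)
  ) +
    ggplot2::geom_path(data = front, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pareto)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "steelblue")) +
    ggplot2::labs(
      x = expression(-log[10](p) ~ "(normalized)"),
      y = expression(-log[10](FPR) ~ "(normalized)"),
      colour = "Pareto front"
    )
}

#' Write ranked outputs for a scored locus
#'
#' Writes three TSVs into `out_dir`: `ranked_genes.tsv` (the score table),
#' `module_matrix.tsv` (long gene-by-module table with the per-module
#' functional term, a per-module combined score, and a `high_confidence`
#' flag where the module FPR is at most `fpr_flag`), and `snp_track.tsv`
#' (per-SNP positions, p-values, and assigned genes, aligned to the gene
#' scores).
#'
#' @param table A `gene_score_table`.
#' @param out_dir Output directory (created if needed).
#' @param module_scores Optional tibble of per-module scores (`term`,
#'   `module_index`, `gene_id`, `fpr`).
#' @param snp_assignments Optional per-SNP assignment tibble (the
#'   `"assignments"` attribute of [assign_snps_to_genes()]).
#' @param fpr_flag FPR cutoff for the high-confidence flag (default 0.2).
#' @return Named character vector of written paths, invisibly.
#' @export
write_ranked_outputs <- function(table, out_dir, module_scores = NULL,
                                 snp_assignments = NULL, fpr_flag = 0.2) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory %s", out_dir))
  }
  paths <- c(ranked = file.path(out_dir, "ranked_genes.tsv"))
  readr::write_tsv(as_tibble(table), paths[["ranked"]])

  mm <- if (is.null(module_scores) || !nrow(module_scores)) {
    warn("No module scores supplied; module matrix has no module rows.")
    tibble(
      gene_id = character(), term = character(), module_index = integer(),
      neglog10_fpr = numeric(), module_s_cg = numeric(),
      high_confidence = logical()
    )
  } else {
    as_tibble(module_scores) |>
      dplyr::semi_join(as_tibble(table), by = "gene_id") |>
      dplyr::mutate(neglog10_fpr_module = -log10(.data$fpr)) |>
      dplyr::left_join(
        dplyr::select(as_tibble(table), "gene_id", "norm_positional",
                      "neglog10_fpr"),
        by = "gene_id"
      ) |>
      dplyr::mutate(
        module_s_cg = .data$norm_positional +
          ifelse(max(.data$neglog10_fpr) > 0,
                 .data$neglog10_fpr_module / max(.data$neglog10_fpr), 0),
        high_confidence = .data$fpr <= fpr_flag
      ) |>
      dplyr::select(
        "gene_id", "term", "module_index",
        neglog10_fpr = "neglog10_fpr_module", "module_s_cg",
        "high_confidence"
      )
  }
  paths[["module_matrix"]] <- file.path(out_dir, "module_matrix.tsv")
  readr::write_tsv(mm, paths[["module_matrix"]])

  if (!is.null(snp_assignments)) {
    paths[["snp_track"]] <- file.path(out_dir, "snp_track.tsv")
    track <- as_tibble(snp_assignments) |>
      dplyr::left_join(
        dplyr::select(as_tibble(table), "gene_id", "s_cg", "pareto"),
        by = "gene_id"
      )
    readr::write_tsv(track, paths[["snp_track"]])
  }
  invisible(paths)
}
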