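#' Read trait gene sets from a directory of text files
#'
#' Each `*.txt` file holds one gene id per line; the file stem becomes the
#' term name. Duplicate lines are de-duplicated with a logged count; files
#' with no valid lines are skipped with a warning.
#'
#' @param dir Directory containing gene-list text files.
#' @param pattern Filename pattern, default `"\\.txt$"`.
#' @return A tibble with columns `term`, `gene_id`.
#' @export
read_gene_sets <- function(dir, pattern = "\\.txt$") {
  if (!dir.exists(dir)) abort(sprintf("Directory not found: %s", dir))
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) abort(sprintf("No gene-set files in %s", dir))
  sets <- purrr::map(files, function(f) {
    genes <- trimws(readLines(f, warn = FALSE))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warn(sprintf("Gene-set file %s has no valid lines; skipped.", basename(f)))
      return(NULL)
    }
    n_dup <- sum(duplicated(genes))
    if (n_dup > 0) {
      warn(sprintf("%d duplicate line(s) removed from %s.", n_dup, basename(f)))
    }
    tibble(
      term = sub(pattern, "", basename(f)),
      gene_id = sort(unique(genes))
    )
  })
  out <- dplyr::bind_rows(sets)
  if (!nrow(out)) abort(sprintf("No non-empty gene sets in %s", dir))
  log_msg(sprintf(
    "Loaded %d gene set(s): %s",
    dplyr::n_distinct(out$term),
    paste(unique(out$term), collapse = ", ")
  ))
  out
}

#' Remove genes (e.g. positional candidates) from training gene sets
#'
#' Positional candidates must not appear among the known positives used for
#' training, otherwise the classifier is rewarded for memorizing the very
#' genes it is meant to rank. A term whose set becomes empty is untrainable
#' and raises an error.
#'
#' @param gene_sets Tibble with columns `term`, `gene_id`.
#' @param excluded Character vector of gene ids to remove.
#' @return Filtered tibble; the number removed per term is logged.
#' @export
exclude_genes <- function(gene_sets, excluded) {
  gene_sets <- as_tibble(gene_sets)
  out <- dplyr::filter(gene_sets, !(.data$gene_id %in% excluded))
  removed <- dplyr::count(
    dplyr::filter(gene_sets, .data$gene_id %in% excluded), .data$term
  )
  if (nrow(removed)) {
    log_msg(paste(
      sprintf("Excluded %d gene(s) from term '%s'.", removed$n, removed$term),
      collapse = "\n"
    ))
  }
  dead <- setdiff(unique(gene_sets$term), unique(out$term))
  if (length(dead)) {
    abort(sprintf(
      "Exclusion emptied gene set(s): %s (term untrainable).",
      paste(dead, collapse = ", ")
    ))
  }
  out
}

#' Fast-greedy community detection on an induced subgraph
#'
#' Runs greedy agglomerative modularity maximization (Clauset-Newman-Moore,
#' weighted) on the subgraph of the functional network induced by `genes`,
#' and returns the maximum-modularity cut of the merge dendrogram. Genes
#' absent from the network are excluded with a log message. An edgeless
#' induced subgraph yields a single community with a warning.
#'
#' @param net A [functional_network].
#' @param genes Character vector of gene ids (at least 2 in the network).
#' @return Tibble with columns `gene_id`, `community` (integer labels from
#'   1), carrying a `"modularity"` attribute.
#' @export
fast_greedy_partition <- function(net, genes) {
  present <- sort(intersect(unique(genes), net$nodes))
  absent <- setdiff(unique(genes), present)
  if (length(absent)) {
    log_msg(sprintf("%d gene(s) absent from the network excluded.", length(absent)))
  }
  if (length(present) < 2) {
    abort("Need at least 2 genes present in the network to partition.")
  }
  sub <- net$adj[present, present, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(
    sub, mode = "undirected", weighted = TRUE, diag = FALSE
  )
  if (igraph::ecount(g) == 0) {
    warn("Induced subgraph has no edges; returning a single community.")
    out <- tibble(gene_id = present, community = 1L)
    attr(out, "modularity") <- NA_real_
    return(out)
  }
  fg <- igraph::cluster_fast_greedy(
    g, weights = igraph::E(g)$weight, merges = TRUE, modularity = TRUE
  )
  # cut the merge dendrogram at maximum modularity; ties go to the cut with
  # the fewest communities (the later merge), so e.g. a clique stays whole
  mods <- fg$modularity
  step <- max(which(mods >= max(mods) - 1e-12))
  k <- length(present) - (step - 1L)
  memb <- igraph::cut_at(fg, no = k)
  names(memb) <- igraph::V(g)$name
  out <- tibble(gene_id = present, community = as.integer(memb[present]))
  attr(out, "modularity") <- max(mods)
  out
}

#' Cluster one gene set into modules of bounded size
#'
#' Sets that fit within `max_size` are returned as a single module without
#' clustering. Larger sets are partitioned by [fast_greedy_partition()] and
#' any community of at least `max_size` genes is recursively re-induced and
#' re-partitioned until all modules are smaller than `max_size`. A community
#' the algorithm cannot split is accepted as-is with a warning so the
#' recursion always terminates.
#'
#' @param net A [functional_network].
#' @param genes Character vector: the term's gene set.
#' @param term Term label carried into the output.
#' @param max_size Maximum module size (modules end up strictly smaller).
#' @return Tibble with columns `term`, `module_index`, `gene_id`.
#' @export
cluster_gene_set <- function(net, genes, term = "set", max_size = 400) {
  if (max_size < 2) abort("`max_size` must be >= 2.")
  mapped <- sort(intersect(unique(genes), net$nodes))
  dropped <- length(unique(genes)) - length(mapped)
  if (dropped > 0) {
    log_msg(sprintf("Term '%s': %d gene(s) not in network dropped.", term, dropped))
  }
  if (!length(mapped)) abort(sprintf("Term '%s' has no genes in the network.", term))
  modules <- list()
  recurse <- function(gs) {
    if (length(gs) < max_size || length(gs) < 2) {
      modules[[length(modules) + 1]] <<- gs
      return(invisible(NULL))
    }
    part <- fast_greedy_partition(net, gs)
    comms <- split(part$gene_id, part$community)
    if (length(comms) == 1) {
      warn(sprintf(
        "Community of %d genes could not be split further; kept as one module.",
        length(gs)
      ))
      modules[[length(modules) + 1]] <<- gs
      return(invisible(NULL))
    }
    for (cm in comms) recurse(sort(cm))
    invisible(NULL)
  }
  if (length(mapped) <= max_size) {
    modules <- list(mapped)
  } else {
    recurse(mapped)
  }
  purrr::imap_dfr(modules, function(gs, i) {
    tibble(term = term, module_index = as.integer(i), gene_id = gs)
  })
}

#' Cluster every trait gene set into functional modules
#'
#' @param net A [functional_network].
#' @param gene_sets Tibble with columns `term`, `gene_id`.
#' @param max_size Maximum module size, default 400.
#' @return Tibble with columns `term`, `module_index`, `gene_id`; modules of
#'   fewer than 10 genes trigger a warning (SVM training may be unstable).
#' @export
cluster_gene_sets <- function(net, gene_sets, max_size = 400) {
  gene_sets <- as_tibble(gene_sets)
  out <- purrr::imap_dfr(
    split(gene_sets$gene_id, gene_sets$term)[unique(gene_sets$term)],
    function(gs, tm) cluster_gene_set(net, gs, term = tm, max_size = max_size)
  )
  sizes <- dplyr::count(out, .data$term, .data$module_index)
  small <- dplyr::filter(sizes, .data$n < 10)
  if (nrow(small)) {
    warn(sprintf(
      "%d module(s) smaller than 10 genes; SVM training may be unstable.",
      nrow(small)
    ))
  }
  log_msg(sprintf(
    "Clustered %d term(s) into %d module(s).",
    dplyr::n_distinct(out$term), nrow(sizes)
  ))
  out
}
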