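#' Functional genomic networks
#'
#' A `functional_network` is a weighted, undirected gene graph whose edge
#' weights lie in `[0, 1]` and predict the degree of functional association
#' between gene pairs. Absent edges are weight 0; there are no self-loops.
#' Nodes are kept in lexicographic order so every derived matrix is
#' deterministic.
#'
#' @param edges A data frame with columns `from`, `to`, `weight`.
#' @param nodes Optional character vector of extra node ids to retain even if
#'   they carry no edge.
#' @return A `functional_network` object.
#' @export
functional_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  validate_edges(edges)
  build_network(edges, extra_nodes = nodes)
}

validate_edges <- function(edges, lines = NULL) {
  w <- edges$weight
  bad <- which(!is.finite(w) | w < 0 | w > 1)
  if (length(bad)) {
    where <- if (is.null(lines)) paste("row", bad[1]) else paste("line", lines[bad[1]])
    abort(sprintf(
      "Edge weight %s out of [0, 1] at %s.", format(w[bad[1]]), where
    ), class = "qtlprio_format_error")
  }
  invisible(edges)
}

# Canonicalize: drop self-loops (warning), order endpoints, de-duplicate.
# Conflicting duplicate weights are corrupt input and an error.
build_network <- function(edges, extra_nodes = NULL) {
  self <- edges$from == edges$to
  if (any(self)) {
    warn(sprintf("Dropped %d self-loop edge(s).", sum(self)))
    edges <- edges[!self, , drop = FALSE]
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first_w <- edges$weight[match(key, key)]
    conflict <- abs(edges$weight - first_w) > 0
    if (any(conflict)) {
      k <- strsplit(key[which(conflict)[1]], "\r", fixed = TRUE)[[1]]
      abort(sprintf(
        "Duplicate edge %s--%s has conflicting weights.", k[1], k[2]
      ), class = "qtlprio_format_error")
    }
    a <- a[!dup]; b <- b[!dup]
    edges <- edges[!dup, , drop = FALSE]
  }
  nodes <- sort(unique(c(a, b, extra_nodes)))
  i <- match(a, nodes)
  j <- match(b, nodes)
  adj <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = rep(edges$weight, 2),
    dims = c(length(nodes), length(nodes)),
    dimnames = list(nodes, nodes)
  )
  structure(
    list(nodes = nodes, adj = adj, n_edges = length(a)),
    class = "functional_network"
  )
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf(
    "<functional_network> %d nodes, %d weighted undirected edges\n",
    length(x$nodes), x$n_edges
  ))
  invisible(x)
}

#' @export
tidy.functional_network <- function(x, ...) {
  tri <- Matrix::triu(x$adj, k = 1)
  sm <- Matrix::summary(tri)
  tibble(
    from = x$nodes[sm$i],
    to = x$nodes[sm$j],
    weight = sm$x
  ) |>
    dplyr::arrange(.data$from, .data$to)
}

#' @export
glance.functional_network <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes),
    n_edges = x$n_edges,
    mean_degree = 2 * x$n_edges / length(x$nodes),
    mean_weight = sum(x$adj@x) / (2 * x$n_edges)
  )
}

#' Read a weighted edge list
#'
#' Reads a tab- or space-delimited 3-column file (gene, gene, weight). A
#' header line is auto-detected when the third field of the first line does
#' not parse as a number. Weights must lie in `[0, 1]`; self-loops are
#' dropped with a warning; duplicated edges with identical weight are
#' silently merged while conflicting duplicates raise a format error.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field separator regex; defaults to runs of tabs/spaces.
#' @return A [functional_network].
#' @export
read_edge_list <- function(path, delimiter = "[ \t]+") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (!length(lines)) abort(sprintf("Empty edge-list file: %s", path))
  fields <- strsplit(trimws(lines), delimiter)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf(
      "Line %d has %d field(s); expected at least 3 (gene, gene, weight).",
      line_no[which(nf < 3)[1]], nf[which(nf < 3)[1]]
    ), class = "qtlprio_format_error")
  }
  third <- vapply(fields, `[[`, "", 3)
  has_header <- is.na(suppressWarnings(as.numeric(third[1])))
  if (has_header) {
    fields <- fields[-1]
    third <- third[-1]
    line_no <- line_no[-1]
    if (!length(fields)) abort("Edge list contains only a header line.")
  }
  w <- suppressWarnings(as.numeric(third))
  if (anyNA(w)) {
    abort(sprintf(
      "Non-numeric weight at line %d.", line_no[which(is.na(w))[1]]
    ), class = "qtlprio_format_error")
  }
  edges <- tibble(
    from = vapply(fields, `[[`, "", 1),
    to = vapply(fields, `[[`, "", 2),
    weight = w
  )
  validate_edges(edges, lines = line_no)
  net <- build_network(edges)
  log_msg(sprintf(
    "Loaded network: %d nodes, %d edges from %s",
    length(net$nodes), net$n_edges, path
  ))
  net
}

#' Write a network back to a 3-column edge list
#'
#' @param net A [functional_network].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(tidy(net), path, col_names = TRUE)
  invisible(path)
}

#' Read gene annotations (BED or 4-column TSV)
#'
#' Internally coordinates are 1-based closed intervals. BED input (0-based
#' half-open, 4th column = gene id) is converted on load; TSV input
#' (`gene_id`, `chrom`, `start`, `end`) is taken as already 1-based closed.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"tsv"`.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_annotations <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn(sprintf("Empty annotation file: %s", path))
    return(tibble(
      gene_id = character(), chrom = character(),
      start = numeric(), end = numeric()
    ))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(fields) < 4)) {
    abort("Annotation rows need 4 fields.", class = "qtlprio_format_error")
  }
  pick <- function(k) vapply(fields, `[[`, "", k)
  if (format == "bed") {
    first_numeric <- !is.na(suppressWarnings(as.numeric(pick(2)[1])))
    if (!first_numeric) { fields <- fields[-1] }
    ann <- tibble(
      gene_id = vapply(fields, `[[`, "", 4),
      chrom = vapply(fields, `[[`, "", 1),
      start = as.numeric(vapply(fields, `[[`, "", 2)) + 1,
      end = as.numeric(vapply(fields, `[[`, "", 3))
    )
  } else {
    first_numeric <- !is.na(suppressWarnings(as.numeric(pick(3)[1])))
    if (!first_numeric) { fields <- fields[-1] }
    ann <- tibble(
      gene_id = vapply(fields, `[[`, "", 1),
      chrom = vapply(fields, `[[`, "", 2),
      start = as.numeric(vapply(fields, `[[`, "", 3)),
      end = as.numeric(vapply(fields, `[[`, "", 4))
    )
  }
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  if (anyNA(ann$start) || anyNA(ann$end)) {
    abort("Non-numeric coordinates in annotations.", class = "qtlprio_format_error")
  }
  if (any(ann$start > ann$end)) {
    bad <- ann$gene_id[which(ann$start > ann$end)[1]]
    abort(sprintf("Gene %s has start > end.", bad), class = "qtlprio_format_error")
  }
  if (any(ann$start < 0) || any(ann$end < 0)) {
    abort("Negative coordinates in annotations.", class = "qtlprio_format_error")
  }
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup)) {
    abort(sprintf(
      "Duplicate gene_id(s) in annotations: %s", paste(dup, collapse = ", ")
    ), class = "qtlprio_format_error")
  }
  ann
}

check_genes_known <- function(net, genes, what = "gene") {
  missing <- setdiff(genes, net$nodes)
  if (length(missing)) {
    abort(sprintf(
      "%s(s) not in network: %s", what,
      paste(head(missing, 5), collapse = ", ")
    ), class = "qtlprio_lookup_error")
  }
  invisible(TRUE)
}

#' Connectivity feature vector of a gene
#'
#' The feature vector of a gene against an ordered list of known positives is
#' its row of network connection weights restricted to those positives
#' (0 where no edge). A gene's entry against itself is 0 (no self-loops).
#'
#' @param net A [functional_network].
#' @param gene A gene id present in the network.
#' @param positives Ordered character vector of known-positive gene ids.
#' @return Named numeric vector of length `length(positives)`.
#' @export
feature_vector <- function(net, gene, positives) {
  check_genes_known(net, gene, "gene")
  check_genes_known(net, positives, "positive")
  v <- as.numeric(net$adj[gene, positives])
  names(v) <- positives
  v[positives == gene] <- 0
  v
}

#' Build a feature matrix (rows of connectivity features)
#'
#' Stacks [feature_vector()] rows: the sub-matrix of the network adjacency
#' matrix whose columns are the known positives.
#'
#' @param net A [functional_network].
#' @param rows Character vector of genes to represent (rows).
#' @param positives Ordered known positives (columns).
#' @return Numeric matrix `length(rows)` x `length(positives)` with dimnames.
#' @export
build_feature_matrix <- function(net, rows, positives) {
  if (!length(positives)) abort("`positives` must be non-empty.")
  check_genes_known(net, rows, "row gene")
  check_genes_known(net, positives, "positive")
  fm <- as.matrix(net$adj[rows, positives, drop = FALSE])
  shared <- intersect(rows, positives)
  if (length(shared)) {
    fm[cbind(match(shared, rows), match(shared, positives))] <- 0
  }
  dimnames(fm) <- list(rows, positives)
  fm
}
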