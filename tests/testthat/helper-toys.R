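# Shared builders and independent oracles used across the test files.

toy_edges <- function(...) {
  rows <- list(...)
  tibble::tibble(
    from = vapply(rows, `[[`, "", 1),
    to = vapply(rows, `[[`, "", 2),
    weight = as.numeric(vapply(rows, `[[`, "", 3))
  )
}

write_edge_file <- function(lines, path = withr::local_tempfile(
                              fileext = ".tsv", .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# Mann-Whitney AUC oracle: P(score_pos > score_neg) + 0.5 P(tie), computed
# from midranks -- independent of the package's threshold sweep.
mw_auc <- function(scores, positives, negatives) {
  sp <- scores[positives]
  sn <- scores[negatives]
  r <- rank(c(sp, sn), ties.method = "average")
  (sum(r[seq_along(sp)]) - length(sp) * (length(sp) + 1) / 2) /
    (length(sp) * length(sn))
}

# Brute-force per-gene FPR: direct enumeration of FP / (FP + TN).
brute_fpr <- function(scores, negatives, floor = 0.5 / length(negatives)) {
  sn <- scores[negatives]
  out <- vapply(scores, function(s) {
    fp <- sum(sn >= s)
    max(fp / (fp + sum(sn < s)), floor)
  }, numeric(1))
  names(out) <- names(scores)
  out
}

# O(n^2) dominance oracle for the Pareto front.
brute_pareto <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    !any(x >= x[i] & y >= y[i] & (x > x[i] | y > y[i]))
  }, logical(1))
}

# Two 5-cliques (weight 1) joined by a single weak edge.
two_clique_network <- function(bridge_weight = 0.1) {
  cl <- function(prefix) {
    pairs <- utils::combn(paste0(prefix, 1:5), 2)
    tibble::tibble(from = pairs[1, ], to = pairs[2, ], weight = 1)
  }
  edges <- dplyr::bind_rows(
    cl("a"), cl("b"),
    tibble::tibble(from = "a1", to = "b1", weight = bridge_weight)
  )
  functional_network(edges)
}

# A small planted-module network plus its truth, for ensemble tests.
small_planted <- function(n_genes = 300, n_modules = 1, module_size = 40,
                          seed = 7, ...) {
  cfg <- fixture_config(
    n_genes = n_genes, n_modules = n_modules, module_size = module_size,
    background_degree = 20, n_terms = 1, seed = seed, ...
  )
  suppressMessages(simulate_network(cfg))
}
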