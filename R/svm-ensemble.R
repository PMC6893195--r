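#' Sample negative training genes
#'
#' Draws `n` distinct genes uniformly without replacement from
#' `universe \ positives`.
#'
#' @param universe Character vector of candidate genes.
#' @param positives Character vector of known positives to exclude.
#' @param n Number of negatives to draw.
#' @param seed Optional integer seed for reproducible draws.
#' @return Character vector of length `n`.
#' @export
sample_negatives <- function(universe, positives, n, seed = NULL) {
  pool <- setdiff(universe, positives)
  if (length(pool) < n) {
    abort(sprintf(
      "Negative pool has %d gene(s); %d requested (short by %d).",
      length(pool), n, n - length(pool)
    ))
  }
  with_seed_or_ambient(seed, sample(pool, n))
}

# Stratified k-fold assignment: shuffle within each class, deal round-robin.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_linear_svm <- function(x, y, cost) {
  e1071::svm(
    x = x, y = y, kernel = "linear", cost = cost,
    scale = FALSE, type = "C-classification"
  )
}

cv_accuracy <- function(x, y, cost, fold) {
  k <- max(fold)
  acc <- vapply(seq_len(k), function(f) {
    test <- fold == f
    if (!any(test) || length(unique(y[!test])) < 2) return(NA_real_)
    m <- fit_linear_svm(x[!test, , drop = FALSE], y[!test], cost)
    mean(predict(m, x[test, , drop = FALSE]) == y[test])
  }, numeric(1))
  mean(acc, na.rm = TRUE)
}

#' Tune the SVM cost parameter by iterative grid refinement
#'
#' Evaluates mean k-fold cross-validated accuracy over the initial 8-point
#' geometric grid `1e-5 ... 1e2` (factors of 10), then repeatedly re-grids 8
#' geometric points spanning the neighbors of the current best cost. The
#' search stops when the best accuracy improves by less than `tol` or after
#' `max_refinements` rounds; the final grid always has 8 points.
#'
#' @param x Numeric feature matrix (rows = training genes).
#' @param y Factor or vector of two class labels, one per row.
#' @param folds Number of CV folds (default 10).
#' @param tol Minimum accuracy improvement to continue refining.
#' @param max_refinements Maximum number of re-gridding rounds.
#' @param seed Optional seed controlling fold assignment.
#' @return A `cost_search` object: list with `final_grid` (8 costs),
#'   `cv_accuracy` (tibble `cost`, `accuracy`), `best_cost`,
#'   `best_accuracy`, `n_refinements`.
#' @export
tune_cost <- function(x, y, folds = 10, tol = 1e-3, max_refinements = 5,
                      seed = NULL) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) {
    abort("Cost tuning needs two classes among the labels.")
  }
  if (nrow(x) < folds) {
    abort(sprintf("Need at least %d labeled rows for %d-fold CV.", folds, folds))
  }
  with_seed_or_ambient(seed, {
    fold <- stratified_folds(as.character(y), folds)
    grid <- 10^seq(-5, 2, by = 1)
    evaluate <- function(g) {
      vapply(g, function(cst) cv_accuracy(x, y, cst, fold), numeric(1))
    }
    acc <- evaluate(grid)
    best_acc <- max(acc)
    history <- tibble(cost = grid, accuracy = acc)
    n_ref <- 0L
    repeat {
      if (n_ref >= max_refinements) break
      i <- which.max(acc)
      lo <- grid[max(1L, i - 1L)]
      hi <- grid[min(length(grid), i + 1L)]
      if (hi / lo < 1 + 1e-9) break
      new_grid <- exp(seq(log(lo), log(hi), length.out = 8))
      new_acc <- evaluate(new_grid)
      n_ref <- n_ref + 1L
      history <- dplyr::bind_rows(history, tibble(cost = new_grid, accuracy = new_acc))
      improved <- max(new_acc) - best_acc
      grid <- new_grid
      acc <- new_acc
      best_acc <- max(best_acc, max(new_acc))
      if (improved < tol) break
    }
    best_i <- which.max(acc)
    structure(
      list(
        final_grid = grid,
        cv_accuracy = history,
        best_cost = grid[best_i],
        best_accuracy = best_acc,
        n_refinements = n_ref
      ),
      class = "cost_search"
    )
  })
}

#' @export
print.cost_search <- function(x, ...) {
  cat(sprintf(
    "<cost_search> best cost %.4g (CV accuracy %.3f) after %d refinement(s)\n",
    x$best_cost, x$best_accuracy, x$n_refinements
  ))
  invisible(x)
}

#' @export
tidy.cost_search <- function(x, ...) x$cv_accuracy

#' @export
glance.cost_search <- function(x, ...) {
  tibble(
    best_cost = x$best_cost,
    best_accuracy = x$best_accuracy,
    n_refinements = x$n_refinements
  )
}

#' Empirical ROC curve and AUC by threshold sweep
#'
#' Sweeps every unique decision score in descending order; at threshold `t`
#' a gene is called positive when its score is `>= t`. Confusion counts are
#' accumulated against the supplied positive/negative labels, the curve is
#' anchored at (0, 0) and (1, 1), and the AUC is the trapezoidal area. With
#' tied scores the trapezoids cut diagonally across ties, so the AUC equals
#' the Mann-Whitney statistic with ties counted one half.
#'
#' @param scores Named numeric vector of decision scores (names = gene ids).
#' @param positives Character vector of positive gene ids.
#' @param negatives Character vector of negative gene ids (disjoint from
#'   `positives`); both must be scored.
#' @return A tibble (`threshold`, `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`) of
#'   class `roc_sweep` carrying an `"auc"` attribute; see [roc_auc()].
#' @export
roc_curve <- function(scores, positives, negatives) {
  if (!length(positives) || !length(negatives)) {
    abort("`positives` and `negatives` must be non-empty.")
  }
  if (length(intersect(positives, negatives))) {
    abort("`positives` and `negatives` overlap.")
  }
  missing <- setdiff(c(positives, negatives), names(scores))
  if (length(missing)) {
    abort(sprintf("Unscored gene(s): %s", paste(head(missing, 5), collapse = ", ")))
  }
  sp <- scores[positives]
  sn <- scores[negatives]
  thr <- sort(unique(c(sp, sn)), decreasing = TRUE)
  tp <- c(0, vapply(thr, function(t) sum(sp >= t), numeric(1)))
  fp <- c(0, vapply(thr, function(t) sum(sn >= t), numeric(1)))
  out <- tibble(
    threshold = c(Inf, unname(thr)),
    tp = tp,
    fp = fp,
    tn = length(sn) - fp,
    fn = length(sp) - tp,
    tpr = tp / length(sp),
    fpr = fp / length(sn)
  )
  auc <- sum(diff(out$fpr) * (head(out$tpr, -1) + out$tpr[-1]) / 2)
  attr(out, "auc") <- auc
  class(out) <- c("roc_sweep", class(out))
  out
}

#' @rdname roc_curve
#' @param roc A `roc_sweep` object.
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' Per-gene false positive rate at each gene's own score
#'
#' Thresholding at a gene's score (inclusive), the FPR is
#' `FP / (FP + TN)` where FP counts negatives scoring at least as high and
#' TN the remaining negatives. Raw zero rates are floored at
#' `0.5 / length(negatives)` so `-log10(FPR)` stays finite; the floor makes
#' the gene-level functional score a bounded, monotone transform of the
#' decision score.
#'
#' @param scores Named numeric vector of decision scores.
#' @param negatives Character vector of negative gene ids (scored).
#' @param floor Lower bound applied to the raw rate; default
#'   `0.5 / length(negatives)`.
#' @return Named numeric vector: FPR per scored gene, in `(0, 1]`.
#' @export
gene_fpr <- function(scores, negatives, floor = NULL) {
  if (!length(negatives)) abort("`negatives` must be non-empty.")
  missing <- setdiff(negatives, names(scores))
  if (length(missing)) {
    abort(sprintf("Unscored negative(s): %s", paste(head(missing, 5), collapse = ", ")))
  }
  floor <- floor %||% (0.5 / length(negatives))
  ns <- sort(unname(scores[negatives]))
  n <- length(ns)
  # FP = # negatives with score >= s  =  n - # negatives with score < s
  fp <- n - findInterval(scores, ns, left.open = TRUE)
  fpr <- pmax(fp / n, floor)
  names(fpr) <- names(scores)
  fpr
}

#' Train an ensemble of linear SVMs for one functional module
#'
#' For each of `n_runs` runs, an equal-sized negative set is drawn at random
#' from outside the module, the cost parameter is tuned by [tune_cost()]
#' (10-fold CV with grid refinement), and a linear SVM is fit on the module
#' positives versus the sampled negatives using network connectivity
#' features against the module genes. Every gene in `universe` is then
#' scored with the fitted decision function (oriented so module genes score
#' high). Per-gene scores are averaged across runs, the per-gene FPR is
#' computed from the averaged score against all non-module genes, and the
#' ROC/AUC of the averaged score is recorded.
#'
#' @param net A [functional_network].
#' @param module_genes Character vector: the module's known positives
#'   (at least 2, all in the network).
#' @param universe Character vector of genes to score; defaults to all
#'   network nodes.
#' @param n_runs Ensemble size (default 100).
#' @param folds CV folds for cost tuning (default 10).
#' @param max_refinements,tol Passed to [tune_cost()].
#' @param seed Master seed; per-run seeds are derived counter-style so runs
#'   are independent and the whole ensemble is reproducible.
#' @param term,module_index Optional labels carried into the output.
#' @return An `svm_ensemble` object; see [tidy.svm_ensemble()] and
#'   [glance.svm_ensemble()].
#' @export
train_ensemble <- function(net, module_genes, universe = NULL, n_runs = 100,
                           folds = 10, max_refinements = 5, tol = 1e-3,
                           seed = 1, term = NA_character_,
                           module_index = NA_integer_) {
  universe <- sort(unique(universe %||% net$nodes))
  module_genes <- sort(unique(module_genes))
  if (length(module_genes) < 2) abort("Module must contain at least 2 genes.")
  check_genes_known(net, module_genes, "module gene")
  check_genes_known(net, universe, "universe gene")
  fm <- build_feature_matrix(net, universe, module_genes)
  pos_idx <- match(module_genes, universe)
  if (anyNA(pos_idx)) {
    fm_pos <- build_feature_matrix(net, setdiff(module_genes, universe), module_genes)
    fm <- rbind(fm, fm_pos)
    universe_ext <- c(universe, setdiff(module_genes, universe))
  } else {
    universe_ext <- universe
  }
  negatives_all <- setdiff(universe, module_genes)
  if (!length(negatives_all)) abort("Universe contains no non-module genes.")

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, r)
    runs[[r]] <- tryCatch(
      withr::with_seed(run_seed, {
        neg <- sample_negatives(universe, module_genes, length(module_genes))
        train_genes <- c(module_genes, neg)
        x <- fm[match(train_genes, universe_ext), , drop = FALSE]
        y <- factor(rep(c("pos", "neg"), c(length(module_genes), length(neg))),
                    levels = c("pos", "neg"))
        cs <- tune_cost(x, y, folds = folds, tol = tol,
                        max_refinements = max_refinements)
        model <- fit_linear_svm(x, y, cs$best_cost)
        dv <- attr(predict(model, fm, decision.values = TRUE), "decision.values")[, 1]
        # libsvm's decision sign depends on label order; orient so that the
        # training positives score higher than the training negatives.
        dtrain <- dv[match(train_genes, universe_ext)]
        if (mean(dtrain[seq_along(module_genes)]) <
            mean(dtrain[-seq_along(module_genes)])) {
          dv <- -dv
        }
        list(dv = dv, cost = cs$best_cost)
      }),
      error = function(e) {
        warn(sprintf("Ensemble run %d failed and was skipped: %s", r, conditionMessage(e)))
        NULL
      }
    )
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) abort("All ensemble runs failed.")
  costs <- vapply(runs[ok], `[[`, numeric(1), "cost")
  per_run <- do.call(cbind, lapply(runs[ok], `[[`, "dv"))
  rownames(per_run) <- universe_ext
  colnames(per_run) <- paste0("run", which(ok))
  mean_score <- rowMeans(per_run)
  fpr <- gene_fpr(mean_score, negatives_all)
  roc <- roc_curve(mean_score, module_genes, negatives_all)
  scored <- sort(universe_ext)
  scores <- tibble(
    gene_id = scored,
    mean_score = unname(mean_score[scored]),
    fpr = unname(fpr[scored]),
    in_module = scored %in% module_genes
  )
  structure(
    list(
      term = term,
      module_index = module_index,
      module_genes = module_genes,
      scores = scores,
      per_run = per_run,
      roc = roc,
      auc = roc_auc(roc),
      costs = costs,
      n_runs = sum(ok),
      n_runs_requested = n_runs,
      seed = seed
    ),
    class = "svm_ensemble"
  )
}

#' @export
print.svm_ensemble <- function(x, ...) {
  cat(sprintf(
    "<svm_ensemble> %d/%d runs, %d module genes, %d genes scored, AUC %.3f\n",
    x$n_runs, x$n_runs_requested, length(x$module_genes),
    nrow(x$scores), x$auc
  ))
  invisible(x)
}

#' Tidy per-gene scores of an SVM ensemble
#'
#' @param x An `svm_ensemble`.
#' @param ... Unused.
#' @return Tibble (`term`, `module_index`, `gene_id`, `mean_score`, `fpr`,
#'   `in_module`).
#' @export
tidy.svm_ensemble <- function(x, ...) {
  dplyr::mutate(x$scores, term = x$term, module_index = x$module_index,
                .before = 1)
}

#' @export
glance.svm_ensemble <- function(x, ...) {
  tibble(
    term = x$term,
    module_index = x$module_index,
    n_module_genes = length(x$module_genes),
    n_runs = x$n_runs,
    auc = x$auc,
    median_cost = stats::median(x$costs)
  )
}

#' @export
autoplot.svm_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Ensemble ROC (AUC = %.3f)", object$auc)
    )
}
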