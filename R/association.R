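#' Read a strain genotype table
#'
#' Expects a TSV with columns `snp_id`, `chrom`, `pos`, then one column per
#' strain with calls coded 0 (reference), 1 (alternate), or NA — the inbred
#' biallelic convention. Positions must be non-decreasing within chromosome.
#'
#' @param path Path to the genotype TSV.
#' @return A tibble (`snp_id`, `chrom`, `pos`, strain columns).
#' @export
read_genotypes <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_genotypes(g)
}

validate_genotypes <- function(g) {
  g <- as_tibble(g)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(g)))
  calls <- as.matrix(g[, setdiff(names(g), c("snp_id", "chrom", "pos"))])
  if (!all(calls %in% c(0, 1, NA))) {
    abort("Genotype calls must be 0, 1, or NA.", class = "qtlprio_format_error")
  }
  unsorted <- g |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos)) |>
    dplyr::filter(!.data$ok)
  if (nrow(unsorted)) {
    g <- dplyr::arrange(g, .data$chrom, .data$pos)
  }
  g
}

#' Read a two-column phenotype table
#'
#' @param path TSV with columns `strain`, `value`.
#' @return A tibble (`strain`, `value`).
#' @export
read_phenotype <- function(path) {
  p <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("strain", "value") %in% names(p)))
  as_tibble(p)
}

#' Read precomputed SNP association p-values
#'
#' Accepts external mixed-model output so the scan can be bypassed.
#'
#' @param path TSV with columns `snp_id`, `chrom`, `pos`, `p`.
#' @return An `assoc_scan` tibble (`snp_id`, `chrom`, `pos`, `p_value`,
#'   `flag`).
#' @export
read_snp_pvalues <- function(path) {
  p <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("snp_id", "chrom", "pos", "p") %in% names(p)))
  if (any(p$p <= 0 | p$p > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1].", class = "qtlprio_format_error")
  }
  out <- tibble(
    snp_id = as.character(p$snp_id),
    chrom = as.character(p$chrom),
    pos = as.numeric(p$pos),
    p_value = as.numeric(p$p),
    flag = "precomputed"
  )
  class(out) <- c("assoc_scan", class(out))
  out
}

genotype_calls <- function(geno, strains = NULL) {
  strain_cols <- setdiff(names(geno), c("snp_id", "chrom", "pos"))
  if (!is.null(strains)) {
    missing <- setdiff(strains, strain_cols)
    if (length(missing)) {
      abort(sprintf("Strain(s) missing from genotypes: %s",
                    paste(missing, collapse = ", ")))
    }
    strain_cols <- strains
  }
  calls <- as.matrix(geno[, strain_cols])
  rownames(calls) <- geno$snp_id
  storage.mode(calls) <- "double"
  calls
}

#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the proportion of SNPs, non-missing in both strains, at
#' which strains i and j carry the same allele. SNPs falling inside
#' `exclude_region` (e.g. the locus under test) are removed before the
#' computation so the random effect does not absorb the very signal being
#' scanned.
#'
#' @param geno Genotype tibble as returned by [read_genotypes()].
#' @param exclude_region Optional region `list(chrom, start, end)` whose
#'   SNPs are excluded.
#' @return A symmetric `kinship` matrix with unit diagonal, strains as
#'   dimnames.
#' @export
compute_kinship <- function(geno, exclude_region = NULL) {
  geno <- validate_genotypes(geno)
  region <- as_region(exclude_region)
  if (!is.null(region)) {
    keep <- !(geno$chrom == region$chrom &
                geno$pos >= region$start & geno$pos <= region$end)
    log_msg(sprintf("Kinship: excluded %d SNP(s) in %s:%d-%d; %d remain.",
                    sum(!keep), region$chrom, region$start, region$end,
                    sum(keep)))
    geno <- geno[keep, , drop = FALSE]
  }
  if (!nrow(geno)) abort("No SNPs remain for kinship after exclusion.")
  calls <- genotype_calls(geno)
  obs <- !is.na(calls)
  if (any(colSums(obs) == 0)) {
    bad <- colnames(calls)[colSums(obs) == 0]
    abort(sprintf("Strain(s) with all-missing calls: %s",
                  paste(bad, collapse = ", ")))
  }
  g1 <- calls; g1[!obs] <- 0            # alt-allele indicator, 0 where missing
  g0 <- (1 - calls); g0[!obs] <- 0      # ref-allele indicator
  agree <- crossprod(g1) + crossprod(g0)
  denom <- crossprod(obs * 1)
  if (any(denom == 0)) {
    abort("Some strain pairs share no non-missing SNPs.")
  }
  K <- agree / denom
  K <- (K + t(K)) / 2
  class(K) <- c("kinship", class(K))
  K
}

# Maximum-likelihood fit of y = X b + u + e with cov(u) = sg2 * K and
# cov(e) = se2 * I, profiled over delta = se2 / sg2 on a log grid with
# golden-section refinement. `eig` may carry a precomputed eigen(K).
lmm_ml_fit_impl <- function(y, X, eig, delta_grid) {
  n <- length(y)
  Ut <- t(eig$vectors)
  ys <- drop(Ut %*% y)
  Xs <- Ut %*% X
  S <- eig$values
  profile_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (S + delta)
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
    if (is.null(beta)) return(list(ll = -Inf))
    r <- ys - drop(Xs %*% beta)
    rss <- sum(r^2 * w)
    sg2 <- max(rss / n, 1e-12)
    ll <- -0.5 * (n * log(2 * pi) + n * log(sg2) + sum(log(S + delta)) + n)
    list(ll = ll, beta = beta, sg2 = sg2, delta = delta)
  }
  lg <- log(delta_grid)
  lls <- vapply(lg, function(d) profile_ll(d)$ll, numeric(1))
  i <- which.max(lls)
  lo <- lg[max(1L, i - 1L)]
  hi <- lg[min(length(lg), i + 1L)]
  opt <- optimize(function(d) profile_ll(d)$ll, c(lo, hi), maximum = TRUE)
  cand <- if (opt$objective >= lls[i]) opt$maximum else lg[i]
  fit <- profile_ll(cand)
  fit$boundary <- i == 1L || i == length(lg)
  fit
}

#' Maximum-likelihood linear mixed model with a kinship random effect
#'
#' Fits `y = X b + u + e`, `cov(u) = sg2 K`, `cov(e) = se2 I` by maximum
#' likelihood: K is eigendecomposed (negative eigenvalues clipped at 0 with
#' a message) and the likelihood is profiled over the variance ratio
#' `delta = se2 / sg2` on 64 log-spaced points in `[1e-5, 1e5]` followed by
#' golden-section refinement around the best grid point.
#'
#' @param y Numeric phenotype vector.
#' @param X Fixed-effect design matrix (includes the intercept).
#' @param K Kinship matrix from [compute_kinship()], or any symmetric PSD
#'   matrix matching `y`.
#' @param delta_grid Grid of variance-ratio values to profile over.
#' @return List with `loglik`, `delta`, `sigma_g2`, `sigma_e2`, `beta`,
#'   `boundary` (TRUE when the optimum sat at a grid end).
#' @export
lmm_ml_fit <- function(y, X, K, delta_grid = 10^seq(-5, 5, length.out = 64)) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) abort("Phenotype contains non-finite values.")
  X <- as.matrix(X)
  if (nrow(X) != length(y) || nrow(K) != length(y)) {
    abort("Dimensions of y, X, and K disagree.")
  }
  if (qr(X)$rank < ncol(X)) abort("Fixed-effect design X is singular.")
  Km <- unclass(K)
  Km <- (Km + t(Km)) / 2
  eig <- eigen(Km, symmetric = TRUE)
  if (any(eig$values < -1e-8)) {
    log_msg("Kinship has negative eigenvalues; clipped at 0.")
  }
  eig$values <- pmax(eig$values, 0)
  fit <- lmm_ml_fit_impl(y, X, eig, delta_grid)
  list(
    loglik = fit$ll,
    delta = fit$delta,
    sigma_g2 = fit$sg2,
    sigma_e2 = fit$sg2 * fit$delta,
    beta = drop(fit$beta),
    boundary = fit$boundary
  )
}

#' Mixed-model likelihood-ratio scan over SNPs
#'
#' EMMA-style maximum-likelihood association: for each SNP the full model
#' (intercept + genotype) and the intercept-only null are both fit under
#' the kinship random effect, and the LRT statistic
#' `2 (loglik_full - loglik_null)` is referred to a chi-square with 1 df.
#' Monomorphic SNPs and SNPs with fewer than 3 informative strains get
#' `p = 1` with a flag; SNPs with missing calls among the phenotyped
#' strains are dropped with a logged count. P-values are floored at 1e-300.
#'
#' @param geno Genotype tibble ([read_genotypes()] layout).
#' @param phenotype Tibble (`strain`, `value`) or named numeric vector.
#' @param K Kinship matrix covering the phenotyped strains.
#' @param region Optional region restricting the scan to SNPs inside it.
#' @return An `assoc_scan` tibble (`snp_id`, `chrom`, `pos`, `p_value`,
#'   `lrt`, `flag`) with attribute `"n_dropped_na"`.
#' @export
snp_scan <- function(geno, phenotype, K, region = NULL) {
  geno <- validate_genotypes(geno)
  region <- as_region(region)
  if (!is.null(region)) {
    geno <- dplyr::filter(
      geno, .data$chrom == region$chrom,
      .data$pos >= region$start, .data$pos <= region$end
    )
  }
  if (!nrow(geno)) abort("No SNPs to scan.")
  if (is.data.frame(phenotype)) {
    y <- setNames(as.numeric(phenotype$value), phenotype$strain)
  } else {
    y <- phenotype
  }
  strains <- names(y)
  if (is.null(strains)) abort("Phenotype must carry strain names.")
  if (!all(strains %in% rownames(K))) abort("Kinship is missing phenotyped strains.")
  calls <- genotype_calls(geno, strains)
  Km <- unclass(K)[strains, strains]
  Km <- (Km + t(Km)) / 2
  eig <- eigen(Km, symmetric = TRUE)
  eig$values <- pmax(eig$values, 0)
  delta_grid <- 10^seq(-5, 5, length.out = 64)
  n <- length(y)
  X0 <- matrix(1, n, 1)
  null_fit <- lmm_ml_fit_impl(as.numeric(y), X0, eig, delta_grid)

  has_na <- rowSums(is.na(calls)) > 0
  if (any(has_na)) {
    log_msg(sprintf("Dropped %d SNP(s) with missing calls from the scan.",
                    sum(has_na)))
  }
  keep <- unname(which(!has_na))
  res <- purrr::map(keep, function(i) {
    g <- calls[i, ]
    n_minor <- min(sum(g == 0), sum(g == 1))
    if (n_minor == 0) {
      return(list(p = 1, lrt = 0, flag = "monomorphic"))
    }
    if (n < 3) {
      return(list(p = 1, lrt = 0, flag = "too_few_informative"))
    }
    X <- cbind(X0, g)
    fit <- tryCatch(
      lmm_ml_fit_impl(as.numeric(y), X, eig, delta_grid),
      error = function(e) NULL
    )
    if (is.null(fit)) return(list(p = 1, lrt = 0, flag = "fit_failed"))
    lrt <- max(2 * (fit$ll - null_fit$ll), 0)
    p <- max(pchisq(lrt, df = 1, lower.tail = FALSE), 1e-300)
    list(p = p, lrt = lrt, flag = "ok")
  })
  out <- tibble(
    snp_id = geno$snp_id[keep],
    chrom = geno$chrom[keep],
    pos = geno$pos[keep],
    p_value = vapply(res, `[[`, numeric(1), "p"),
    lrt = vapply(res, `[[`, numeric(1), "lrt"),
    flag = vapply(res, `[[`, character(1), "flag")
  )
  attr(out, "n_dropped_na") <- sum(has_na)
  class(out) <- c("assoc_scan", class(out))
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in `(0, 1]`.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  if (n_tests < 1) abort("`n_tests` must be >= 1.")
  alpha / n_tests
}

#' Assign SNP p-values to the nearest gene within a distance cutoff
#'
#' Each SNP is assigned to the single gene minimizing the distance to the
#' gene body (0 when the SNP lies inside the body), provided the distance
#' does not exceed `max_dist` (default 1 Mb). Equidistant ties go to the
#' gene with the smaller start coordinate. A gene's positional evidence is
#' the maximum `-log10(p)` over its assigned SNPs; genes with no assigned
#' SNP score 0.
#'
#' @param scan An `assoc_scan` tibble (needs `snp_id`, `chrom`, `pos`,
#'   `p_value`).
#' @param genes Gene annotation tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param max_dist Maximum SNP-to-gene-body distance in bp.
#' @return Tibble (`gene_id`, `chrom`, `start`, `end`, `n_snps`, `best_snp`,
#'   `max_neglog10p`) with attribute `"assignments"`: the per-SNP
#'   assignment tibble.
#' @export
assign_snps_to_genes <- function(scan, genes, max_dist = 1e6) {
  genes <- validate_annotations(as_tibble(genes))
  scan <- as_tibble(scan)
  assign_one <- function(chrom, pos) {
    cand <- genes[genes$chrom == chrom, , drop = FALSE]
    if (!nrow(cand)) return(NA_character_)
    d <- ifelse(pos < cand$start, cand$start - pos,
                ifelse(pos > cand$end, pos - cand$end, 0))
    ok <- d <= max_dist
    if (!any(ok)) return(NA_character_)
    cand <- cand[ok, , drop = FALSE]
    d <- d[ok]
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[which.min(cand$start[best])]
    cand$gene_id[best]
  }
  assigned <- purrr::map2_chr(scan$chrom, scan$pos, assign_one)
  n_un <- sum(is.na(assigned))
  if (n_un) log_msg(sprintf("%d SNP(s) unassigned (no gene within %g bp).",
                            n_un, max_dist))
  assignments <- dplyr::mutate(
    scan, gene_id = assigned,
    neglog10_p = -log10(pmax(.data$p_value, 1e-300))
  )
  hits <- dplyr::filter(assignments, !is.na(.data$gene_id))
  per_gene <- if (nrow(hits)) {
    hits |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        n_snps = dplyr::n(),
        best_snp = .data$snp_id[which.max(.data$neglog10_p)],
        max_neglog10p = max(.data$neglog10_p)
      )
  } else {
    tibble(gene_id = character(), n_snps = integer(),
           best_snp = character(), max_neglog10p = numeric())
  }
  out <- genes |>
    dplyr::left_join(per_gene, by = "gene_id") |>
    dplyr::mutate(
      n_snps = dplyr::coalesce(.data$n_snps, 0L),
      max_neglog10p = dplyr::coalesce(.data$max_neglog10p, 0)
    )
  attr(out, "assignments") <- assignments
  out
}

#' @export
tidy.assoc_scan <- function(x, ...) as_tibble(x)

#' @export
glance.assoc_scan <- function(x, alpha = 0.05, ...) {
  thr <- bonferroni_threshold(alpha, nrow(x))
  tibble(
    n_snps = nrow(x),
    n_tested = sum(x$flag %in% c("ok", "precomputed")),
    threshold = thr,
    n_significant = sum(x$p_value <= thr),
    min_p = min(x$p_value)
  )
}

#' @export
autoplot.assoc_scan <- function(object, alpha = 0.05, ...) {
  thr <- bonferroni_threshold(alpha, nrow(object))
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$pos / 1e6, y = -log10(.data$p_value))
  ) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dotted",
                        colour = "red") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = expression(-log[10](p)))
}
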