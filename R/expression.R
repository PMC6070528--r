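# Differential expression: TMM normalization, common-dispersion estimation by
# conditional maximum likelihood, NB exact test conditioned on the per-gene
# total, multiple-testing corrections, and two-way clustering of the DEG.

#' TMM normalization factors
#'
#' Trimmed mean of M-values: per-sample scaling factors computed against a
#' reference library, with 30% trimming on M-values and 5% on A-values (both
#' tails). The reference is the library whose upper quartile of scaled counts
#' is closest to the mean upper quartile. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts A [count_matrix()] or numeric matrix.
#' @param logratio_trim,abundance_trim Fraction trimmed from each tail of the
#'   M and A distributions.
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abundance_trim = 0.05) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  lib <- colSums(m)
  .assert(all(lib > 0), "library totals must be positive")
  if (nrow(m) < 2) {
    warning("fewer than 2 genes: TMM factors set to 1")
    return(stats::setNames(rep(1, ncol(m)), colnames(m)))
  }
  uq <- apply(sweep(m, 2, lib, "/"), 2, function(x) stats::quantile(x[x > 0], 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(k) {
    .tmm_pair(m[, k], m[, ref], lib[k], lib[ref], logratio_trim, abundance_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(m))
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, lr_trim, a_trim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  # asymptotic (delta-method) inverse variance of M
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * lr_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * a_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Common NB dispersion
#'
#' Estimates a single dispersion phi shared by all genes under the NB
#' parameterization variance = mu + phi * mu^2. The default maximizes the
#' conditional likelihood of the within-group counts given their group totals
#' on library-size-equalized pseudo-counts; `"moments"` is a method-of-moments
#' fallback. The estimate is floored at 0.
#'
#' @param counts A [count_matrix()], or a matrix with `groups` supplied.
#' @param groups Group labels (taken from the `count_matrix` if absent).
#' @param method `"cml"` or `"moments"`.
#' @return Non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, groups = NULL,
                                       method = c("cml", "moments")) {
  method <- match.arg(method)
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (is.null(groups) && inherits(counts, "count_matrix")) groups <- counts$groups
  groups <- .as_group_factor(groups)
  .assert(max(tabulate(groups)) >= 2, "need >= 2 samples in some group")
  lib <- colSums(m)
  pseudo <- sweep(m, 2, exp(mean(log(lib))) / lib, "*")
  pseudo <- pseudo[rowSums(pseudo) > 0, , drop = FALSE]
  if (nrow(pseudo) == 0) return(0)
  if (method == "moments") return(.dispersion_moments(pseudo, groups))
  gl <- split(seq_along(groups), groups)
  negll <- function(logphi) -.cond_loglik(pseudo, gl, exp(logphi))
  opt <- stats::optimize(negll, interval = c(log(1e-6), log(20)))
  ll0 <- -negll(log(1e-6))
  if (ll0 >= -opt$objective - 1e-8) return(0)
  phi <- exp(opt$minimum)
  # estimates this close to the boundary are Poisson in all but name
  if (phi < 1e-4) 0 else phi
}

# Conditional log-likelihood of within-group counts given group totals,
# summed over genes and groups; terms constant in phi dropped.
.cond_loglik <- function(pseudo, group_idx, phi) {
  r <- 1 / phi
  ll <- 0
  for (idx in group_idx) {
    if (length(idx) < 2) next
    y <- pseudo[, idx, drop = FALSE]
    z <- rowSums(y)
    n <- length(idx)
    ll <- ll + sum(rowSums(lgamma(y + r)) - n * lgamma(r) -
                   lgamma(z + n * r) + lgamma(n * r))
  }
  ll
}

.dispersion_moments <- function(pseudo, groups) {
  phis <- c()
  for (idx in split(seq_along(groups), groups)) {
    if (length(idx) < 2) next
    y <- pseudo[, idx, drop = FALSE]
    mu <- rowMeans(y)
    v <- apply(y, 1, stats::var)
    ok <- mu > 0
    phis <- c(phis, (v[ok] - mu[ok]) / mu[ok]^2)
  }
  if (length(phis) == 0) return(0)
  max(0, stats::median(phis))
}

#' NB exact test for a two-group comparison
#'
#' For each gene, conditions on the total count and computes the exact
#' two-sided p-value of the observed split between the groups under a
#' negative-binomial model with common dispersion `dispersion` (a group sum
#' of n i.i.d. NB(mu, phi) counts is NB(n*mu, phi/n)). The two-sided p-value
#' sums the probabilities of all outcomes no more likely than the observed
#' one, so an observed modal split yields p = 1. At `dispersion = 0` the
#' conditional law reduces to a binomial split. Libraries are equalized
#' beforehand by scaling to the geometric-mean effective library size
#' (library total times normalization factor) and rounding.
#'
#' @param counts A [count_matrix()] (exactly two group levels).
#' @param dispersion Common dispersion phi >= 0.
#' @param norm_factors Optional per-sample normalization factors
#'   (e.g. [tmm_factors()]); default 1.
#' @param prior_count Prior added to per-sample group means for the log
#'   fold-change (avoids infinite logFC at zero counts).
#' @return data.frame with `gene_id`, `logFC` (log2, second group level vs
#'   first), `logCPM`, `pvalue`. A gene with zero total has p = 1 and
#'   logFC = 0 by contract.
#' @export
nb_exact_test <- function(counts, dispersion, norm_factors = NULL,
                          prior_count = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  .assert(nlevels(counts$groups) == 2, "exactly 2 groups required")
  .assert(dispersion >= 0, "dispersion must be >= 0")
  m <- counts$counts
  groups <- counts$groups
  lib <- colSums(m)
  f <- norm_factors %||% rep(1, ncol(m))
  eff <- lib * f
  common <- exp(mean(log(eff)))
  pseudo <- round(sweep(m, 2, common / eff, "*"))
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  y1 <- rowSums(pseudo[, i1, drop = FALSE])
  y2 <- rowSums(pseudo[, i2, drop = FALSE])
  n1 <- length(i1); n2 <- length(i2)
  p <- vapply(seq_len(nrow(m)), function(g) {
    .exact_nb_p(y1[g], y2[g], n1, n2, dispersion)
  }, numeric(1))
  logFC <- log2((y2 / n2 + prior_count) / (y1 / n1 + prior_count))
  logFC[(y1 + y2) == 0] <- 0
  logCPM <- log2(((y1 + y2) / (n1 + n2) + prior_count) / common * 1e6)
  data.frame(gene_id = rownames(m), logFC = logFC, logCPM = logCPM,
             pvalue = p, stringsAsFactors = FALSE)
}

# Exact conditional two-sided p for observed group sums (y1, y2) with n1, n2
# samples and common dispersion phi. Enumerates the conditional distribution
# of the group-1 sum given the total.
.exact_nb_p <- function(y1, y2, n1, n2, phi) {
  t <- y1 + y2
  if (t == 0) return(1)
  k <- 0:t
  if (phi <= 0) {
    logp <- stats::dbinom(k, t, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    mu0 <- t / (n1 + n2)
    logp <- stats::dnbinom(k, size = r1, mu = n1 * mu0, log = TRUE) +
      stats::dnbinom(t - k, size = r2, mu = n2 * mu0, log = TRUE)
    logp <- logp - .logsumexp(logp)
  }
  obs <- logp[y1 + 1]
  min(1, exp(.logsumexp(logp[logp <= obs + 1e-10])))
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Multiple-testing correction
#'
#' Adjusts p-values by one of the two FWER step methods plus Bonferroni, or
#' the Benjamini-Hochberg / Benjamini-Yekutieli FDR procedures. Thin
#' validated front-end over [stats::p.adjust()]; adjusted values are capped
#' at 1 and are never smaller than the raw p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method One of `"bonferroni"`, `"holm"`, `"hochberg"`, `"bh"`, `"by"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni", "holm",
                                         "hochberg", "by")) {
  method <- match.arg(method)
  .assert(all(is.finite(p)) && all(p >= 0) && all(p <= 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = c(bh = "BH", by = "BY", bonferroni = "bonferroni",
                                holm = "holm", hochberg = "hochberg")[method])
}

#' Run the differential expression stage
#'
#' Applies the mean-CPM expression filter, TMM normalization, common
#' dispersion estimation and the NB exact test; adjusts p-values by all five
#' supported methods and calls the DEG set at BH-adjusted p below
#' `fdr_threshold`.
#'
#' @param counts A [count_matrix()].
#' @param cpm_threshold Mean-CPM filter threshold (default 1).
#' @param fdr_threshold BH FDR threshold for the DEG call (default 0.05).
#' @param dispersion_method Passed to [estimate_common_dispersion()].
#' @param tmm Use TMM normalization factors (default TRUE).
#' @return Object of class `de_result`: list with `table` (per-gene results
#'   restricted to filter-passing genes, with all adjusted columns), `deg`
#'   (character vector), `dispersion`, `norm_factors`.
#' @export
run_de <- function(counts, cpm_threshold = 1, fdr_threshold = 0.05,
                   dispersion_method = "cml", tmm = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  keep <- expression_filter(cpm(counts), cpm_threshold)
  .assert(length(keep) >= 1, "no genes pass the expression filter")
  sub <- count_matrix(counts$counts[keep, , drop = FALSE], counts$groups)
  f <- if (tmm) tmm_factors(sub) else stats::setNames(rep(1, ncol(sub$counts)),
                                                      colnames(sub$counts))
  phi <- estimate_common_dispersion(sub, method = dispersion_method)
  tab <- nb_exact_test(sub, dispersion = phi, norm_factors = f)
  for (meth in c("bonferroni", "holm", "hochberg", "bh", "by")) {
    tab[[meth]] <- adjust_pvalues(tab$pvalue, meth)
  }
  tab$fdr <- tab$bh
  structure(list(table = tab, deg = tab$gene_id[tab$fdr < fdr_threshold],
                 dispersion = phi, norm_factors = f),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d genes tested, %d DEG, common dispersion %.4g\n",
              nrow(x$table), length(x$deg), x$dispersion))
  invisible(x)
}

#' log2 CPM with a count prior
#'
#' @param counts A [count_matrix()] or matrix.
#' @param prior_count Count added before the log to avoid log(0); default 0.5.
#' @return Matrix of log2 CPM values.
#' @export
log2_cpm <- function(counts, prior_count = 0.5) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  log2(sweep(m + prior_count, 2, colSums(m), "/") * 1e6)
}

#' Two-way clustering layout for a DEG heatmap
#'
#' Hierarchically clusters genes (rows) and samples (columns) of a log2 CPM
#' matrix and returns the reordered matrix together with both dendrograms,
#' ready for rendering. Defaults are Euclidean distance and complete linkage.
#'
#' @param mat Numeric matrix (genes x samples), e.g. [log2_cpm()] of the DEG.
#' @param distance [stats::dist()] method.
#' @param linkage [stats::hclust()] method.
#' @return List with `matrix` (reordered), `row_order`, `col_order`,
#'   `row_hclust`, `col_hclust` (NULL when a dimension has a single element).
#' @export
cluster_heatmap_data <- function(mat, distance = "euclidean",
                                 linkage = "complete") {
  mat <- as.matrix(mat)
  row_h <- col_h <- NULL
  row_order <- seq_len(nrow(mat))
  col_order <- seq_len(ncol(mat))
  if (nrow(mat) >= 2) {
    row_h <- stats::hclust(stats::dist(mat, method = distance), method = linkage)
    row_order <- row_h$order
  }
  if (ncol(mat) >= 2) {
    col_h <- stats::hclust(stats::dist(t(mat), method = distance), method = linkage)
    col_order <- col_h$order
  }
  list(matrix = mat[row_order, col_order, drop = FALSE],
       row_order = row_order, col_order = col_order,
       row_hclust = row_h, col_hclust = col_h)
}
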