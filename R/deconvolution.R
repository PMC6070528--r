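# Cell-type deconvolution from marker-gene expression: a digital-sorting
# style constrained least-squares estimator and a mean-marker-profile
# estimator, plus group comparison of the estimated proportions.

#' Default hepatic marker set
#'
#' Marker genes for the three hepatic cell types whose frequencies are large
#' enough to deconvolve (hepatocytes, Kupffer cells, sinusoidal endothelial
#' cells); rarer populations (stellate cells, cholangiocytes, below ~10%)
#' cannot be estimated accurately from bulk expression and are not modeled.
#'
#' @return Named list mapping cell type to marker gene ids.
#' @export
default_marker_set <- function() {
  list(
    hepatocytes = c("Baat", "Hpx", "Apoa5", "Itih1", "F12"),
    kupffer = c("Mrc1", "Fcgrt", "Vsig4"),
    sinusoidal_endothelial = c("Clec4g", "Stab2", "Flt1")
  )
}

#' Read a marker set from a 2-column TSV (cell_type, gene_id)
#'
#' @param path TSV path.
#' @return Named list mapping cell type to marker gene ids.
#' @export
read_marker_set <- function(path) {
  tab <- .read_tsv(path)
  .assert(all(c("cell_type", "gene_id") %in% names(tab)),
          "marker TSV needs columns cell_type and gene_id")
  split(tab$gene_id, tab$cell_type)
}

.check_markers <- function(expr, markers) {
  .assert(length(markers) >= 1 && all(lengths(markers) >= 1),
          "each cell type needs >= 1 marker")
  .assert(!anyDuplicated(unlist(markers)),
          "marker lists must be disjoint across cell types")
  missing <- setdiff(unlist(markers), rownames(expr))
  if (length(missing) > 0) {
    .stopf("marker genes missing from expression matrix: %s",
           paste(missing, collapse = ", "))
  }
}

# Cell-type x sample matrix of mean marker expression.
.marker_means <- function(expr, markers) {
  t(vapply(markers, function(g) {
    colMeans(expr[g, , drop = FALSE])
  }, numeric(ncol(expr))))
}

#' DSA-style proportion estimate
#'
#' The per-sample mean expression of each type's markers b_tj is modeled as
#' g_t * p_tj with an unknown type-specific signature level g_t and the
#' proportions constrained to the simplex. Writing x_t = 1/g_t, the sum-to-one
#' constraint over samples gives the linear system B' x = 1, solved by
#' non-negative least squares; proportions are then p_tj = x_t * b_tj,
#' renormalized per sample. Noiseless mixtures are recovered exactly.
#'
#' @param expr Expression matrix (genes x samples), linear scale.
#' @param markers Named list mapping cell type to marker gene ids.
#' @return Matrix of proportions (samples x cell types), rows summing to 1,
#'   with attribute `method = "dsa"`.
#' @export
dsa_proportions <- function(expr, markers = default_marker_set()) {
  expr <- as.matrix(expr)
  .check_markers(expr, markers)
  B <- .marker_means(expr, markers)                 # types x samples
  x <- .nnls(t(B), rep(1, ncol(B)))
  P <- B * x                                        # recycled per type (row)
  P <- pmax(P, 0)
  sums <- colSums(P)
  .assert(all(sums > 0), "degenerate marker expression: zero proportion mass")
  P <- sweep(P, 2, sums, "/")
  structure(t(P), method = "dsa",
            dimnames = list(colnames(expr), names(markers)))
}

#' Mean-marker-profile proportion estimate
#'
#' For each sample, the mean expression of each type's markers rescaled to
#' sum to one. Cruder than [dsa_proportions()] (no correction for signature
#' level), but monotone in the marker signal.
#'
#' @inheritParams dsa_proportions
#' @return Matrix of proportions (samples x cell types), rows summing to 1,
#'   with attribute `method = "meanProfile"`.
#' @export
mean_profile_proportions <- function(expr, markers = default_marker_set()) {
  expr <- as.matrix(expr)
  .check_markers(expr, markers)
  B <- .marker_means(expr, markers)
  sums <- colSums(B)
  .assert(all(sums > 0), "degenerate marker expression: zero proportion mass")
  structure(t(sweep(B, 2, sums, "/")), method = "meanProfile",
            dimnames = list(colnames(expr), names(markers)))
}

# Lawson-Hanson active-set non-negative least squares (small systems).
.nnls <- function(A, b, tol = 1e-12, max_iter = 200) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- qr.coef(qr(Ap), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Compare estimated proportions between groups
#'
#' Per cell type, a two-sided unpaired t-test of the estimated proportions
#' between the two groups. Pooled variance by default (`welch = TRUE` for
#' the unequal-variance form). When both groups are constant with equal
#' means, p = 1 by contract.
#'
#' @param estimates Proportion matrix (samples x cell types), e.g. from
#'   [dsa_proportions()].
#' @param groups Group labels, one per sample (2 levels).
#' @param welch Use the Welch t-test instead of pooled variance.
#' @return data.frame with `cell_type`, group means, `t`, `df`, `pvalue`.
#' @export
compare_group_proportions <- function(estimates, groups, welch = FALSE) {
  groups <- .as_group_factor(groups)
  .assert(nlevels(groups) == 2, "exactly 2 groups required")
  .assert(all(tabulate(groups) >= 2), "need >= 2 samples per group")
  res <- lapply(colnames(estimates), function(ct) {
    tt <- two_sample_t(estimates[groups == levels(groups)[1], ct],
                       estimates[groups == levels(groups)[2], ct],
                       welch = welch)
    data.frame(cell_type = ct,
               mean_1 = tt$mean_x, mean_2 = tt$mean_y,
               t = tt$t, df = tt$df, pvalue = tt$pvalue)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", levels(groups))
  out
}

#' Two-sample two-sided t-test (closed form)
#'
#' Pooled-variance by default, Welch optional. Degenerate inputs follow the
#' package contract: zero variance in both groups with equal means gives
#' p = 1; zero variance with different means gives the smallest positive p.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @param welch Use Welch degrees of freedom and standard error.
#' @return List with `t`, `df`, `pvalue`, `mean_x`, `mean_y`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  n1 <- length(x); n2 <- length(y)
  .assert(n1 >= 2 && n2 >= 2, "need >= 2 values per group")
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- if (se2 > 0) se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
          else n1 + n2 - 2
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (se2 <= 0) {
    if (m1 == m2) {
      return(list(t = 0, df = df, pvalue = 1, mean_x = m1, mean_y = m2))
    }
    return(list(t = sign(m1 - m2) * Inf, df = df,
                pvalue = .Machine$double.xmin, mean_x = m1, mean_y = m2))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  list(t = tstat, df = df, pvalue = 2 * stats::pt(-abs(tstat), df),
       mean_x = m1, mean_y = m2)
}

#' Write proportion estimates with group summaries as TSV
#'
#' One row per cell type: per-group mean and SEM (percent) and the two-sided
#' t-test p-value.
#'
#' @param estimates Proportion matrix (samples x cell types).
#' @param groups Group labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(estimates, groups, path) {
  groups <- .as_group_factor(groups)
  cmp <- compare_group_proportions(estimates, groups)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  g1 <- groups == levels(groups)[1]
  out <- data.frame(
    method = attr(estimates, "method") %||% NA_character_,
    cell_type = colnames(estimates),
    mean_pct_1 = 100 * colMeans(estimates[g1, , drop = FALSE]),
    sem_pct_1 = 100 * apply(estimates[g1, , drop = FALSE], 2, sem),
    mean_pct_2 = 100 * colMeans(estimates[!g1, , drop = FALSE]),
    sem_pct_2 = 100 * apply(estimates[!g1, , drop = FALSE], 2, sem),
    pvalue = cmp$pvalue
  )
  names(out)[3:6] <- c(paste0(c("mean_pct_", "sem_pct_"), levels(groups)[1]),
                       paste0(c("mean_pct_", "sem_pct_"), levels(groups)[2]))
  .write_tsv(out, path)
}
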