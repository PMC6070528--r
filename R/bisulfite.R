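# Targeted bisulfite amplicon analysis: per-cytosine methylation calls from
# ungapped plus-strand reads, per-site methylation percentages, non-CpG
# conversion QC, and per-site group comparison by t-test and exact
# Mann-Whitney.

#' Call per-cytosine methylation counts from amplicon reads
#'
#' Reads are ungapped relative to the amplicon reference (amplicon
#' sequencing), plus strand only. At every reference C position, a read C is
#' a methylated call, a read T an unmethylated call; any other base is
#' ignored (and tallied as mismatch). Context is `CpG` when the reference
#' dinucleotide is CG, else `non-CpG`.
#'
#' @param amplicons Named character vector (or `Biostrings::DNAStringSet`)
#'   of reference amplicon sequences.
#' @param reads data.frame with columns `amplicon`, `sample`, `offset`
#'   (0-based start of the read on the amplicon), `seq`.
#' @return data.frame of class `cpg_site_counts`: `amplicon`, `pos` (0-based
#'   C position), `context`, `sample`, `methylated`, `total`, `mismatches`.
#' @export
call_site_counts <- function(amplicons, reads) {
  amplicons <- stats::setNames(toupper(as.character(amplicons)),
                               names(amplicons))
  .assert(!is.null(names(amplicons)) && all(nzchar(names(amplicons))),
          "amplicons must be named")
  .assert(all(reads$amplicon %in% names(amplicons)),
          "reads reference unknown amplicons: %s",
          paste(setdiff(reads$amplicon, names(amplicons)), collapse = ", "))
  rows <- list()
  for (amp in names(amplicons)) {
    ref <- strsplit(amplicons[[amp]], "")[[1]]
    c_pos <- which(ref == "C")                      # 1-based
    if (length(c_pos) == 0) next
    context <- ifelse(c_pos < length(ref) & ref[pmin(c_pos + 1, length(ref))] == "G",
                      "CpG", "non-CpG")
    sub <- reads[reads$amplicon == amp, , drop = FALSE]
    for (smp in unique(sub$sample)) {
      rs <- sub[sub$sample == smp, , drop = FALSE]
      meth <- un <- mm <- integer(length(c_pos))
      for (i in seq_len(nrow(rs))) {
        s <- toupper(rs$seq[i])
        off <- rs$offset[i]
        .assert(off >= 0 && off + nchar(s) <= length(ref),
                "read %d on %s extends past the amplicon", i, amp)
        covered <- c_pos > off & c_pos <= off + nchar(s)
        if (!any(covered)) next
        base <- substring(s, c_pos[covered] - off, c_pos[covered] - off)
        meth[covered] <- meth[covered] + (base == "C")
        un[covered] <- un[covered] + (base == "T")
        mm[covered] <- mm[covered] + (base != "C" & base != "T")
      }
      rows[[length(rows) + 1]] <- data.frame(
        amplicon = amp, pos = c_pos - 1L, context = context, sample = smp,
        methylated = meth, total = meth + un, mismatches = mm)
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(amplicon = character(), pos = integer(), context = character(),
               sample = character(), methylated = integer(),
               total = integer(), mismatches = integer())
  } else do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cpg_site_counts", "data.frame")
  out
}

#' Per-site methylation percentages
#'
#' @param sites A `cpg_site_counts` data.frame.
#' @param context Restrict to `"CpG"` (default), `"non-CpG"`, or `"all"`.
#' @return `sites` with a `percent` column (methylated / total * 100) and a
#'   logical `flagged` column marking zero-coverage sites (percent `NA`),
#'   which are excluded from downstream comparisons.
#' @export
methylation_percent <- function(sites, context = "CpG") {
  if (context != "all") sites <- sites[sites$context == context, , drop = FALSE]
  sites$percent <- ifelse(sites$total > 0,
                          100 * sites$methylated / sites$total, NA_real_)
  sites$flagged <- sites$total == 0
  sites
}

#' Non-CpG conversion QC
#'
#' Apparent methylation at non-CpG cytosines estimates the bisulfite
#' conversion failure rate (a conversion rate c leaves about (1-c)*100%
#' apparent non-CpG methylation). Pooled per sample as the ratio of summed
#' methylated calls to summed total calls over all non-CpG sites (not a mean
#' of per-site ratios).
#'
#' @param sites A `cpg_site_counts` data.frame.
#' @return Named numeric vector: pooled non-CpG methylation percent per
#'   sample; `NA` with a warning when a sample has no covered non-CpG site.
#' @export
noncpg_conversion_qc <- function(sites) {
  nc <- sites[sites$context == "non-CpG", , drop = FALSE]
  if (nrow(nc) == 0) {
    warning("no non-CpG cytosines: conversion QC undefined")
    return(stats::setNames(numeric(0), character(0)))
  }
  out <- tapply(seq_len(nrow(nc)), nc$sample, function(idx) {
    tot <- sum(nc$total[idx])
    if (tot == 0) NA_real_ else 100 * sum(nc$methylated[idx]) / tot
  })
  if (anyNA(out)) warning("sample(s) with no covered non-CpG site")
  stats::setNames(as.numeric(out), names(out))
}

#' Compare per-site methylation between groups
#'
#' Per CpG site: two-tailed unpaired t-test and two-tailed Mann-Whitney test
#' of the per-sample methylation percentages, with significance at p < 0.05.
#' Sites with zero coverage in any sample are excluded and reported.
#'
#' @param sites A `cpg_site_counts` data.frame.
#' @param groups Named vector mapping sample id to group (2 levels).
#' @param alpha Significance level (default 0.05).
#' @param welch Use the Welch t-test.
#' @return data.frame per site: group mean percentages, `t_pvalue`,
#'   `mw_pvalue`, `significant` (t-test p < alpha), `excluded`.
#' @export
compare_site_methylation <- function(sites, groups, alpha = 0.05,
                                     welch = FALSE) {
  pct <- methylation_percent(sites, context = "CpG")
  groups <- factor(groups[as.character(unique(pct$sample))],
                   exclude = NULL)
  names(groups) <- as.character(unique(pct$sample))
  .assert(nlevels(groups) == 2, "exactly 2 groups required")
  key <- paste(pct$amplicon, pct$pos)
  res <- lapply(split(seq_len(nrow(pct)), key), function(idx) {
    sub <- pct[idx, , drop = FALSE]
    g <- groups[as.character(sub$sample)]
    excluded <- any(sub$flagged)
    x <- sub$percent[g == levels(groups)[1]]
    y <- sub$percent[g == levels(groups)[2]]
    if (excluded || length(x) < 2 || length(y) < 2) {
      return(data.frame(amplicon = sub$amplicon[1], pos = sub$pos[1],
                        mean_1 = NA_real_, mean_2 = NA_real_,
                        t_pvalue = NA_real_, mw_pvalue = NA_real_,
                        significant = NA, excluded = TRUE))
    }
    tt <- two_sample_t(x, y, welch = welch)
    mw <- mann_whitney_p(x, y)
    data.frame(amplicon = sub$amplicon[1], pos = sub$pos[1],
               mean_1 = mean(x), mean_2 = mean(y),
               t_pvalue = tt$pvalue, mw_pvalue = mw,
               significant = tt$pvalue < alpha, excluded = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[3:4] <- paste0("mean_", levels(groups))
  out <- out[order(out$amplicon, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-tailed Mann-Whitney p-value
#'
#' Exact by exhaustive enumeration of all rank assignments (with average
#' ranks for ties) when both groups have at most `exact_max` observations;
#' normal approximation with tie correction otherwise. The exact regime
#' covers the n = 3 vs 3 designs this package targets.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest per-group size for exact enumeration (default 8).
#' @return Two-tailed p-value in (0, 1].
#' @export
mann_whitney_p <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  .assert(n1 >= 1 && n2 >= 1, "both groups must be non-empty")
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    return(mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
  }
  ties <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 == 0) return(1)
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Write a site table as TSV
#'
#' @param sites A `cpg_site_counts` data.frame (optionally with percent
#'   columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) .write_tsv(as.data.frame(sites), path)

#' Read amplicon reads from TSV (amplicon, sample, offset, seq)
#'
#' @param path TSV path.
#' @return data.frame with the four columns.
#' @export
read_amplicon_reads <- function(path) {
  tab <- .read_tsv(path)
  .assert(all(c("amplicon", "sample", "offset", "seq") %in% names(tab)),
          "amplicon reads TSV needs columns amplicon, sample, offset, seq")
  tab
}
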