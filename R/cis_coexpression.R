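# Cis co-expression of lncRNA and protein-coding genes: pairing each
# expressed lncRNA with its overlapping or nearest flanking expressed
# protein-coding gene, geometry classification, correlation against the
# analytic critical r, and diet-responsiveness flags.

#' Pair lncRNA genes with overlapping or nearest protein-coding genes
#'
#' For each lncRNA in `lnc_ids`: one pair per expressed protein-coding gene
#' whose body it overlaps by at least one base (strand-agnostic); when none
#' overlap, exactly one pair with the nearest flanking expressed
#' protein-coding gene on the same chromosome (gap distance between gene
#' bodies; equidistant flanks produce both pairs, which is how more pairs
#' than lncRNAs can arise). lncRNAs with no protein-coding gene on their
#' chromosome yield no pair.
#'
#' @param catalog A [gene_catalog()].
#' @param lnc_ids Expressed lncRNA gene ids (filter-passing).
#' @param pc_ids Expressed protein-coding gene ids (filter-passing).
#' @return data.frame of pair skeletons: `lnc_id`, `pc_id`, `overlapping`
#'   (logical), `distance` (gap in bases, 0 for overlap).
#' @export
find_cis_pairs <- function(catalog, lnc_ids, pc_ids) {
  g <- catalog$genes
  .assert(all(lnc_ids %in% g$gene_id), "lnc_ids not all in catalog")
  .assert(all(pc_ids %in% g$gene_id), "pc_ids not all in catalog")
  lnc <- g[match(lnc_ids, g$gene_id), , drop = FALSE]
  pc <- g[match(pc_ids, g$gene_id), , drop = FALSE]
  empty <- data.frame(lnc_id = character(), pc_id = character(),
                      overlapping = logical(), distance = integer())
  if (nrow(lnc) == 0 || nrow(pc) == 0) return(empty)
  sl <- .seq_union(lnc$chrom, pc$chrom)
  gr_lnc <- .as_granges(lnc$chrom, lnc$start, lnc$end, seqlevels = sl)
  gr_pc <- .as_granges(pc$chrom, pc$start, pc$end, seqlevels = sl)
  hits <- GenomicRanges::findOverlaps(gr_lnc, gr_pc, ignore.strand = TRUE)
  ov <- data.frame(lnc_id = lnc$gene_id[S4Vectors::queryHits(hits)],
                   pc_id = pc$gene_id[S4Vectors::subjectHits(hits)],
                   overlapping = rep(TRUE, length(hits)),
                   distance = rep(0L, length(hits)))
  rows <- list(ov)
  no_overlap <- setdiff(lnc$gene_id, ov$lnc_id)
  for (id in no_overlap) {
    li <- lnc[lnc$gene_id == id, ]
    cand <- pc[pc$chrom == li$chrom, , drop = FALSE]
    if (nrow(cand) == 0) {
      message("lncRNA ", id, ": no protein-coding gene on its chromosome")
      next
    }
    gap <- .interval_gap(li$start, li$end, cand$start, cand$end)
    best <- which(gap == min(gap))
    rows[[length(rows) + 1]] <- data.frame(
      lnc_id = id, pc_id = cand$gene_id[best],
      overlapping = FALSE, distance = as.integer(gap[best]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify cis-pair geometry
#'
#' Adds `relation` (`overlap`, `upstream`, `downstream`: location of the
#' lncRNA relative to the protein-coding gene in the coding gene's strand
#' orientation) and, for overlapping pairs, `overlap_target`: `promoter`
#' when the lncRNA intersects the strand-aware promoter window around the
#' coding gene's TSS, else `body`.
#'
#' @param pairs Pair skeletons from [find_cis_pairs()].
#' @param catalog A [gene_catalog()].
#' @param promoter_upstream,promoter_downstream Promoter window half-widths
#'   in bases around the TSS (defaults 2000 upstream, 200 downstream).
#' @return `pairs` with `relation` and `overlap_target` columns.
#' @export
classify_pair_geometry <- function(pairs, catalog, promoter_upstream = 2000,
                                   promoter_downstream = 200) {
  g <- catalog$genes
  li <- g[match(pairs$lnc_id, g$gene_id), , drop = FALSE]
  pi <- g[match(pairs$pc_id, g$gene_id), , drop = FALSE]
  plus <- pi$strand == "+"
  tss <- ifelse(plus, pi$start, pi$end - 1L)
  prom_start <- ifelse(plus, tss - promoter_upstream,
                       tss - promoter_downstream + 1L)
  prom_end <- ifelse(plus, tss + promoter_downstream,
                     tss + promoter_upstream + 1L)
  relation <- rep("overlap", nrow(pairs))
  before <- li$end <= pi$start   # lncRNA at lower coordinates than pc body
  after <- li$start >= pi$end
  relation[pairs$overlapping == FALSE & before] <-
    ifelse(plus[pairs$overlapping == FALSE & before], "upstream", "downstream")
  relation[pairs$overlapping == FALSE & after] <-
    ifelse(plus[pairs$overlapping == FALSE & after], "downstream", "upstream")
  target <- rep("none", nrow(pairs))
  hit_prom <- .interval_overlaps(li$start, li$end, prom_start, prom_end)
  target[pairs$overlapping] <- ifelse(hit_prom[pairs$overlapping],
                                      "promoter", "body")
  pairs$relation <- relation
  pairs$overlap_target <- target
  pairs
}

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return Correlation in \[-1, 1\]; `NA` with a warning when either vector
#'   is constant (undefined correlation).
#' @export
pearson_r <- function(x, y) {
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(length(x) >= 3, "need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Critical Pearson correlation for a given sample size
#'
#' The threshold above which a sample correlation is significant at level
#' `alpha`: r* = t* / sqrt(t*^2 + n - 2) with t* the t quantile at n - 2
#' degrees of freedom (upper alpha for one-tailed, alpha/2 for two-tailed).
#' At n = 6, alpha = 0.05, one-tailed this is 0.7293 (0.73 at 2 decimals).
#'
#' @param n Number of samples (>= 3).
#' @param alpha Significance level in (0, 1).
#' @param tails `"one"` or `"two"`.
#' @return Critical r in (0, 1).
#' @export
critical_r <- function(n, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  .assert(n >= 3, "n must be >= 3")
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  df <- n - 2
  tstar <- stats::qt(1 - alpha / ifelse(tails == "two", 2, 1), df)
  tstar / sqrt(tstar^2 + df)
}

#' Co-expression analysis of cis pairs
#'
#' Computes the Pearson correlation of each pair across samples on the
#' configured expression transform and flags pairs with |r| at or above the
#' critical r as co-expressed, with the sign taken from r. Pairs with an
#' undefined correlation (constant expression) are retained with
#' `co_expressed = FALSE`, `sign = "none"` and a reason.
#'
#' @param pairs Pair table from [find_cis_pairs()] /
#'   [classify_pair_geometry()].
#' @param counts A [count_matrix()] covering all pair members.
#' @param alpha,tails See [critical_r()]; defaults 0.05, one-tailed.
#' @param transform `"log2cpm"` (default) or `"cpm"`.
#' @return `pairs` with columns `r`, `co_expressed`, `sign`, `exclude_reason`.
#' @export
coexpression_analysis <- function(pairs, counts, alpha = 0.05,
                                  tails = "one",
                                  transform = c("log2cpm", "cpm")) {
  transform <- match.arg(transform)
  expr <- if (transform == "log2cpm") log2_cpm(counts) else cpm(counts)
  members <- unique(c(pairs$lnc_id, pairs$pc_id))
  .assert(all(members %in% rownames(expr)),
          "pair members missing from counts: %s",
          paste(setdiff(members, rownames(expr)), collapse = ", "))
  n <- ncol(expr)
  rcrit <- critical_r(n, alpha, tails)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    suppressWarnings(pearson_r(expr[pairs$lnc_id[i], ], expr[pairs$pc_id[i], ]))
  }, numeric(1))
  pairs$r <- r
  pairs$co_expressed <- !is.na(r) & abs(r) >= rcrit
  pairs$sign <- ifelse(pairs$co_expressed, ifelse(r > 0, "positive", "negative"),
                       "none")
  pairs$exclude_reason <- ifelse(is.na(r), "constant expression vector", "")
  attr(pairs, "critical_r") <- rcrit
  pairs
}

#' Flag diet-responsive pairs
#'
#' A pair is diet-responsive iff both members are in the differentially
#' expressed gene set.
#'
#' @param pairs Pair table.
#' @param deg Character vector of DEG ids.
#' @return `pairs` with a logical `diet_responsive` column.
#' @export
diet_responsive_pairs <- function(pairs, deg) {
  pairs$diet_responsive <- pairs$lnc_id %in% deg & pairs$pc_id %in% deg
  pairs
}

#' Overlap of genes with an enhancer catalogue
#'
#' @param catalog A [gene_catalog()].
#' @param gene_ids Genes to test (e.g. co-expressed lncRNAs).
#' @param enhancers data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @return Named logical vector: TRUE iff the gene overlaps any enhancer by
#'   >= 1 base.
#' @export
enhancer_overlap <- function(catalog, gene_ids, enhancers) {
  g <- catalog$genes[match(gene_ids, catalog$genes$gene_id), , drop = FALSE]
  .assert(!anyNA(g$gene_id), "gene ids missing from catalog")
  if (nrow(enhancers) == 0 || nrow(g) == 0) {
    return(stats::setNames(rep(FALSE, length(gene_ids)), gene_ids))
  }
  sl <- .seq_union(g$chrom, enhancers$chrom)
  hits <- GenomicRanges::countOverlaps(
    .as_granges(g$chrom, g$start, g$end, seqlevels = sl),
    .as_granges(enhancers$chrom, enhancers$start, enhancers$end,
                seqlevels = sl),
    ignore.strand = TRUE)
  stats::setNames(hits > 0, gene_ids)
}

#' Read a BED file of intervals
#'
#' Minimal validating reader for BED3+ (browser/track/comment lines are
#' skipped). BED is 0-based half-open, which is the package's internal
#' convention, so coordinates pass through unchanged. A malformed line stops
#' with its line number.
#'
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  .assert(file.exists(path), "BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  rows <- vector("list", sum(keep))
  j <- 0
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) .stopf("BED line %d: fewer than 3 fields", i)
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || start >= end) {
      .stopf("BED line %d: invalid interval [%s, %s)", i, f[2], f[3])
    }
    j <- j + 1
    rows[[j]] <- data.frame(
      chrom = f[1], start = start, end = end,
      name = if (length(f) >= 4) f[4] else NA_character_,
      score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_,
      strand = if (length(f) >= 6) f[6] else NA_character_)
  }
  if (j == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a pair table as TSV
#'
#' @param pairs Pair table with all computed columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) .write_tsv(pairs, path)
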