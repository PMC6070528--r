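# 5meDIP-seq stack: in-silico fragment extension of 5'-end reads, binned
# fragment density, SICER-style island calling against an input control,
# cross-sample merging of peaks into methylated regions, annotation relative
# to gene bodies / flanks / CpG islands, differential methylation (t-test
# with FWER+FDR corrections, and an NB count test), and k-means clustering
# of midpoint-anchored fragment-density profiles.

#' Island-calling configuration
#'
#' @param fragment_length In-silico extension length in bases (default 150).
#' @param bin_size Bin width for fragment density (default 32).
#' @param window Window size for enrichment testing in bases (default 200).
#' @param gap Maximum gap between enriched windows inside one island, in
#'   bases (default 0: windows must be adjacent).
#' @param island_fdr BH FDR threshold across islands (default 1e-10).
#' @param window_p0 Per-window Poisson eligibility p-value (default 0.2).
#' @param depth Optional per-sample read depth: when set, samples are
#'   subsampled (seeded) to this many reads before calling.
#' @return List of class `island_config`.
#' @export
island_config <- function(fragment_length = 150, bin_size = 32, window = 200,
                          gap = 0, island_fdr = 1e-10, window_p0 = 0.2,
                          depth = NULL) {
  .assert(fragment_length > 0 && bin_size > 0 && window > 0,
          "fragment_length, bin_size and window must be positive")
  .assert(gap >= 0, "gap must be >= 0")
  structure(list(fragment_length = fragment_length, bin_size = bin_size,
                 window = window, gap = gap, island_fdr = island_fdr,
                 window_p0 = window_p0, depth = depth),
            class = "island_config")
}

#' Read 5'-end read positions from a 6-column BED file
#'
#' The `start` column is interpreted as the 0-based 5'-end position of the
#' read on its strand (for minus-strand reads this is the rightmost base,
#' not BED's leftmost coordinate; the writer in this package uses the same
#' convention).
#'
#' @param path BED path.
#' @return data.frame with `chrom`, `pos`, `strand`.
#' @export
read_medip_bed <- function(path) {
  bed <- read_bed(path)
  .assert(all(bed$strand %in% c("+", "-")),
          "MeDIP read BED needs a +/- strand column")
  data.frame(chrom = bed$chrom, pos = bed$start, strand = bed$strand)
}

#' Extend 5'-end reads to fragments
#'
#' A plus-strand 5' position p becomes \[p, p+L); a minus-strand 5' position
#' p becomes \[p-L+1, p+1) (extension at the 3' end, i.e. leftward in genome
#' coordinates). Fragments are clipped at chromosome bounds.
#'
#' @param reads data.frame with `chrom`, `pos`, `strand`.
#' @param fragment_length Extension length L.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
extend_reads <- function(reads, fragment_length, chrom_lengths) {
  .assert(fragment_length > 0, "fragment_length must be > 0")
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$pos, reads$pos - fragment_length + 1L)
  end <- ifelse(plus, reads$pos + fragment_length, reads$pos + 1L)
  len <- chrom_lengths[reads$chrom]
  start <- pmax(0L, as.integer(start))
  end <- pmin(as.integer(len), as.integer(end))
  keep <- start < end
  data.frame(chrom = reads$chrom[keep], start = start[keep], end = end[keep])
}

#' Binned fragment density
#'
#' Divides each chromosome into fixed-size bins and counts, per bin, the
#' fragments overlapping it by at least one base (a fragment spanning several
#' bins increments each of them).
#'
#' @param fragments data.frame with `chrom`, `start`, `end`.
#' @param bin_size Bin width in bases.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return Named list (per chromosome) of integer vectors of bin counts; bin
#'   i (1-based) covers \[(i-1)*bin_size, i*bin_size).
#' @export
bin_fragment_density <- function(fragments, bin_size, chrom_lengths) {
  .assert(bin_size > 0, "bin_size must be > 0")
  out <- lapply(names(chrom_lengths), function(chr) {
    nbins <- ceiling(chrom_lengths[[chr]] / bin_size)
    f <- fragments[fragments$chrom == chr, , drop = FALSE]
    if (nrow(f) == 0) return(integer(nbins))
    first <- pmin(f$start %/% bin_size, nbins - 1L)
    last <- pmin((f$end - 1L) %/% bin_size, nbins - 1L)
    add <- tabulate(first + 1L, nbins)
    rem <- tabulate(last + 2L, nbins + 1L)
    as.integer(cumsum(add - rem[seq_len(nbins)]))
  })
  names(out) <- names(chrom_lengths)
  out
}

#' Seeded read subsampling to a fixed depth
#'
#' @param reads Read data.frame.
#' @param depth Number of reads to keep (error if more than available).
#' @param seed RNG seed.
#' @return Subsampled read data.frame.
#' @export
subsample_reads <- function(reads, depth, seed = 1) {
  .assert(depth <= nrow(reads), "depth %d exceeds available reads %d",
          depth, nrow(reads))
  idx <- .with_seed(seed, sample.int(nrow(reads), depth))
  reads[sort(idx), , drop = FALSE]
}

#' Call enriched islands against an input control
#'
#' SICER-style reduction: the genome is tiled into fixed-size windows; each
#' window's fragment count in the sample is tested against a Poisson rate
#' given by the depth-scaled input count (floored at the input's genome-wide
#' average, so sparse input cannot produce spurious enrichment). Windows
#' with Poisson upper-tail p below `window_p0` are eligible; islands are
#' maximal runs of eligible windows separated by at most `gap` bases; the
#' island p-value is the product of its window probabilities; BH across
#' islands at `island_fdr` keeps the significant ones.
#'
#' @param sample_fragments,input_fragments Fragment data.frames from
#'   [extend_reads()].
#' @param config An [island_config()].
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param sample_id Label stored with the peaks.
#' @return data.frame of peaks: `chrom`, `start`, `end`, `sample`, `score`
#'   (-log10 island p), `pvalue`, `padj`.
#' @export
call_islands <- function(sample_fragments, input_fragments, config,
                         chrom_lengths, sample_id = "sample") {
  stopifnot(inherits(config, "island_config"))
  .assert(nrow(input_fragments) > 0, "input control must be non-empty")
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      sample = character(), score = numeric(),
                      pvalue = numeric(), padj = numeric())
  if (nrow(sample_fragments) == 0) return(empty)
  W <- config$window
  dens_s <- bin_fragment_density(sample_fragments, W, chrom_lengths)
  dens_i <- bin_fragment_density(input_fragments, W, chrom_lengths)
  scale <- nrow(sample_fragments) / nrow(input_fragments)
  mean_input <- mean(unlist(dens_i))
  gap_windows <- config$gap %/% W
  islands <- list()
  for (chr in names(chrom_lengths)) {
    cnt <- dens_s[[chr]]
    lambda <- scale * pmax(dens_i[[chr]], mean_input)
    logp <- stats::ppois(cnt - 1L, lambda, lower.tail = FALSE, log.p = TRUE)
    eligible <- which(logp < log(config$window_p0))
    if (length(eligible) == 0) next
    run <- cumsum(c(1L, diff(eligible) > gap_windows + 1L))
    for (grp in split(eligible, run)) {
      islands[[length(islands) + 1]] <- data.frame(
        chrom = chr,
        start = (min(grp) - 1L) * W,
        end = min(max(grp) * W, chrom_lengths[[chr]]),
        sample = sample_id,
        log_p = sum(logp[grp]))
    }
  }
  if (length(islands) == 0) return(empty)
  out <- do.call(rbind, islands)
  out$pvalue <- exp(out$log_p)
  out$padj <- adjust_pvalues(out$pvalue, "bh")
  out$score <- -out$log_p / log(10)
  out <- out[out$padj <= config$island_fdr, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "sample", "score", "pvalue", "padj")]
}

#' Merge peaks across samples into methylated regions
#'
#' Regions are the connected components of the >= 1-base-overlap graph over
#' the pooled peaks of all samples: each region spans from the start of its
#' most upstream member peak to the end of its most downstream member peak.
#' Touching (but not overlapping) peaks stay separate. A peak present in a
#' single sample defines a region by itself.
#'
#' @param peaks data.frame of pooled peaks (`chrom`, `start`, `end`, and
#'   optionally `sample`), or a list of per-sample peak data.frames.
#' @return data.frame of regions: `region_id`, `chrom`, `start`, `end`,
#'   `n_peaks`, `n_samples`.
#' @export
merge_regions <- function(peaks) {
  if (is.list(peaks) && !is.data.frame(peaks)) {
    peaks <- do.call(rbind, lapply(peaks, function(p) {
      p[, intersect(c("chrom", "start", "end", "sample"), names(p)),
        drop = FALSE]
    }))
  }
  if (is.null(peaks) || nrow(peaks) == 0) {
    return(data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_peaks = integer(),
                      n_samples = integer()))
  }
  gr <- .as_granges(peaks$chrom, peaks$start, peaks$end)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, red, ignore.strand = TRUE)
  member <- S4Vectors::subjectHits(hits)
  n_peaks <- tabulate(member, length(red))
  n_samples <- if ("sample" %in% names(peaks)) {
    vapply(seq_along(red), function(i) {
      length(unique(peaks$sample[member == i]))
    }, integer(1))
  } else n_peaks
  ord <- order(as.character(GenomicRanges::seqnames(red)),
               GenomicRanges::start(red))
  out <- data.frame(
    region_id = sprintf("region_%05d", seq_along(red)),
    chrom = as.character(GenomicRanges::seqnames(red))[ord],
    start = GenomicRanges::start(red)[ord] - 1L,
    end = GenomicRanges::end(red)[ord],
    n_peaks = n_peaks[ord], n_samples = n_samples[ord])
  rownames(out) <- NULL
  out
}

#' Per-region per-sample fragment counts
#'
#' A fragment counts toward a region iff it overlaps it by >= 1 base.
#'
#' @param regions Region data.frame from [merge_regions()].
#' @param fragments_by_sample Named list of fragment data.frames.
#' @return Integer matrix, regions x samples, rownames = region ids.
#' @export
region_fragment_counts <- function(regions, fragments_by_sample) {
  sl <- .seq_union(regions$chrom,
                   unlist(lapply(fragments_by_sample, `[[`, "chrom")))
  gr <- .as_granges(regions$chrom, regions$start, regions$end, seqlevels = sl)
  counts <- vapply(fragments_by_sample, function(f) {
    GenomicRanges::countOverlaps(
      gr, .as_granges(f$chrom, f$start, f$end, seqlevels = sl),
      ignore.strand = TRUE)
  }, integer(length(gr)))
  counts <- matrix(counts, nrow = length(gr),
                   dimnames = list(regions$region_id,
                                   names(fragments_by_sample)))
  counts
}

#' Annotate regions relative to genes and CpG islands
#'
#' Classifies each region by its overlap pattern with gene bodies and
#' strand-aware flanks (default 10 kb) over all genes: `intergenic` (no
#' overlap at all), `body_only`, `upstream_only`, `downstream_only`, or
#' `combination`. Also flags >= 1-base overlap with CpG islands.
#'
#' @param regions Region data.frame.
#' @param catalog A [gene_catalog()].
#' @param flank Flank width in bases (default 10000).
#' @param cgi Optional CpG-island data.frame (`chrom`, `start`, `end`).
#' @return `regions` with `annotation` and `cgi_overlap` columns.
#' @export
annotate_regions <- function(regions, catalog, flank = 10000, cgi = NULL) {
  .assert(flank >= 0, "flank must be >= 0")
  g <- catalog$genes
  cgi_chrom <- if (is.null(cgi)) character(0) else cgi$chrom
  sl <- .seq_union(regions$chrom, g$chrom, cgi_chrom)
  gr_reg <- .as_granges(regions$chrom, regions$start, regions$end,
                        seqlevels = sl)
  plus <- g$strand == "+"
  up_start <- ifelse(plus, pmax(0L, g$start - flank), g$end)
  up_end <- ifelse(plus, g$start, g$end + flank)
  dn_start <- ifelse(plus, g$end, pmax(0L, g$start - flank))
  dn_end <- ifelse(plus, g$end + flank, g$start)
  ov <- function(s, e) {
    keep <- s < e
    if (!any(keep)) return(logical(nrow(regions)))
    GenomicRanges::countOverlaps(
      gr_reg, .as_granges(g$chrom[keep], s[keep], e[keep], seqlevels = sl),
      ignore.strand = TRUE) > 0
  }
  in_body <- ov(g$start, g$end)
  in_up <- ov(up_start, up_end)
  in_dn <- ov(dn_start, dn_end)
  cls <- rep("combination", nrow(regions))
  cls[in_body & !in_up & !in_dn] <- "body_only"
  cls[!in_body & in_up & !in_dn] <- "upstream_only"
  cls[!in_body & !in_up & in_dn] <- "downstream_only"
  cls[!in_body & !in_up & !in_dn] <- "intergenic"
  regions$annotation <- cls
  regions$cgi_overlap <- if (is.null(cgi) || nrow(cgi) == 0) {
    rep(FALSE, nrow(regions))
  } else {
    GenomicRanges::countOverlaps(
      gr_reg, .as_granges(cgi$chrom, cgi$start, cgi$end, seqlevels = sl),
      ignore.strand = TRUE) > 0
  }
  regions
}

#' Differential methylation by t-test with FWER and FDR corrections
#'
#' Per region, a two-sided unpaired t-test (pooled variance by default) of
#' the per-sample fragment counts between the groups, followed by all five
#' correction columns (Bonferroni, Holm, Hochberg, BH, BY).
#'
#' @param counts Region x sample count matrix.
#' @param groups Group labels (2 levels, >= 2 samples each).
#' @param welch Use the Welch t-test.
#' @return data.frame with `region_id`, group means, `pvalue` and the five
#'   adjusted columns.
#' @export
differential_methylation_ttest <- function(counts, groups, welch = FALSE) {
  groups <- .as_group_factor(groups)
  .assert(nlevels(groups) == 2, "exactly 2 groups required")
  .assert(all(tabulate(groups) >= 2), "need >= 2 samples per group")
  i1 <- groups == levels(groups)[1]
  res <- t(apply(counts, 1, function(v) {
    tt <- two_sample_t(v[i1], v[!i1], welch = welch)
    c(tt$mean_x, tt$mean_y, tt$pvalue)
  }))
  out <- data.frame(region_id = rownames(counts),
                    mean_1 = res[, 1], mean_2 = res[, 2], pvalue = res[, 3],
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", levels(groups))
  for (meth in c("bonferroni", "holm", "hochberg", "bh", "by")) {
    out[[meth]] <- adjust_pvalues(out$pvalue, meth)
  }
  out
}

#' Differential methylation by an NB count test
#'
#' Median-of-ratios size factors (geometric-mean reference over regions with
#' all-positive counts), counts scaled to a common size, a common dispersion
#' by conditional maximum likelihood moderated per region toward the
#' method-of-moments estimate, then the exact conditional NB test per region
#' and BH adjustment. Significance at adjusted p < `fdr_threshold`
#' (default 0.1).
#'
#' @param counts Region x sample integer count matrix.
#' @param groups Group labels (2 levels).
#' @param fdr_threshold BH threshold for the significant set.
#' @param prior_df Weight (pseudo-degrees of freedom) of the common
#'   dispersion in the per-region moderation.
#' @return List with `table` (region_id, logFC, pvalue, padj), `significant`
#'   (region ids), `size_factors`, `dispersion`.
#' @export
differential_methylation_nb <- function(counts, groups, fdr_threshold = 0.1,
                                        prior_df = 10) {
  groups <- .as_group_factor(groups)
  .assert(nlevels(groups) == 2, "exactly 2 groups required")
  .assert(all(counts == round(counts)), "counts must be integers")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  .assert(sum(all_pos) >= 2,
          "size factors undefined: fewer than 2 regions with all-positive counts")
  logref <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logref))
  })
  sf <- sf / exp(mean(log(sf)))
  cm <- count_matrix(counts, groups)
  phi_common <- estimate_common_dispersion(cm, method = "cml")
  pseudo <- round(sweep(counts, 2, sf, "/"))
  i1 <- groups == levels(groups)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  # per-region moments dispersion, moderated toward the common value
  mu <- rowMeans(pseudo)
  v <- apply(pseudo, 1, stats::var)
  phi_raw <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  d <- ncol(counts) - 2
  phi <- (prior_df * phi_common + d * phi_raw) / (prior_df + d)
  y1 <- rowSums(pseudo[, i1, drop = FALSE])
  y2 <- rowSums(pseudo[, !i1, drop = FALSE])
  p <- vapply(seq_len(nrow(counts)), function(i) {
    .exact_nb_p(y1[i], y2[i], n1, n2, phi[i])
  }, numeric(1))
  tab <- data.frame(region_id = rownames(counts),
                    logFC = log2((y2 / n2 + 0.5) / (y1 / n1 + 0.5)),
                    pvalue = p, padj = adjust_pvalues(p, "bh"),
                    stringsAsFactors = FALSE)
  list(table = tab, significant = tab$region_id[tab$padj < fdr_threshold],
       size_factors = sf, dispersion = phi_common)
}

#' Midpoint-anchored fragment-density profiles with k-means clustering
#'
#' For each region, counts fragments in fixed-size bins across a window
#' centered on the region midpoint (defaults: +/- 2000 bases at 32-base
#' bins, i.e. 125 columns), then clusters the profiles by k-means with
#' seeded k-means++ initialization and 10 restarts.
#'
#' @param regions Region data.frame (`chrom`, `start`, `end`).
#' @param fragments Fragment data.frame (typically pooled over samples).
#' @param half_width Half window width in bases (default 2000).
#' @param bin_size Bin width in bases (default 32).
#' @param k Number of clusters (default 5; reduced with a warning when there
#'   are fewer regions than clusters).
#' @param seed RNG seed for the initialization.
#' @return List with `profile` (regions x bins matrix), `cluster` (labels in
#'   1..k), `centers`.
#' @export
region_profile_kmeans <- function(regions, fragments, half_width = 2000,
                                  bin_size = 32, k = 5, seed = 1) {
  .assert(k >= 1, "k must be >= 1")
  nbin <- (2 * half_width) %/% bin_size
  mid <- (regions$start + regions$end) %/% 2L
  offsets <- seq(-half_width, half_width - bin_size, by = bin_size)
  bin_start <- rep(mid, each = nbin) + rep(offsets, times = nrow(regions))
  bin_chrom <- rep(regions$chrom, each = nbin)
  sl <- .seq_union(regions$chrom, fragments$chrom)
  gr_bins <- .as_granges(bin_chrom, bin_start, bin_start + bin_size,
                         seqlevels = sl)
  cnt <- GenomicRanges::countOverlaps(
    gr_bins, .as_granges(fragments$chrom, fragments$start, fragments$end,
                         seqlevels = sl),
    ignore.strand = TRUE)
  prof <- matrix(cnt, nrow = nrow(regions), ncol = nbin, byrow = TRUE,
                 dimnames = list(regions$region_id, NULL))
  if (nrow(prof) < k) {
    warning(sprintf("fewer regions (%d) than clusters (%d): k reduced",
                    nrow(prof), k))
    k <- nrow(prof)
  }
  km <- .with_seed(seed, .kmeans_pp(prof, k, restarts = 10))
  list(profile = prof, cluster = km$cluster, centers = km$centers)
}

# k-means with k-means++ initialization and restarts.
.kmeans_pp <- function(x, k, restarts = 10) {
  if (k == 1 || nrow(x) == 1) {
    return(list(cluster = rep(1L, nrow(x)),
                centers = matrix(colMeans(x), nrow = 1)))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- .kmeanspp_centers(x, k)
    fit <- suppressWarnings(stats::kmeans(x, centers = centers,
                                          iter.max = 100))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- apply(x, 1, function(row) {
      min(colSums((t(x[idx, , drop = FALSE]) - row)^2))
    })
    d2[idx] <- 0
    if (sum(d2) == 0) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
    } else {
      idx <- c(idx, sample.int(n, 1, prob = d2))
    }
  }
  x[idx, , drop = FALSE] + matrix(stats::runif(k * ncol(x), 0, 1e-8),
                                  nrow = k)
}

#' Write intervals as a BED file
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns (0-based half-open, i.e. BED-native).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, df$start, df$end)
  if (!is.null(df$name)) {
    cols <- c(cols, list(df$name, df$score %||% 0,
                         df$strand %||% rep(".", nrow(df))))
  }
  tab <- do.call(data.frame, c(cols, list(stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
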