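lens1 <- c(chr1 = 100000)

test_that("read extension follows strand and clips at chromosome bounds", {
  reads <- data.frame(chrom = "chr1", pos = c(1000, 1000, 99960, 40),
                      strand = c("+", "-", "+", "-"))
  fr <- extend_reads(reads, 150, lens1)
  expect_equal(fr$start, c(1000, 851, 99960, 0))
  expect_equal(fr$end, c(1150, 1001, 100000, 41))
})

test_that("binned density increments every overlapped bin", {
  fr <- data.frame(chrom = "chr1", start = 0, end = 150)
  d <- bin_fragment_density(fr, 32, lens1)$chr1
  expect_equal(d[1:5], rep(1L, 5))   # bin 5 spans 128..159
  expect_equal(sum(d), 5)
  expect_equal(sum(bin_fragment_density(fr[0, ], 32, lens1)$chr1), 0)
  # brute-force per-bin scan on random fragments
  set.seed(19)
  frr <- data.frame(chrom = "chr1", start = sample.int(99000, 200))
  frr$end <- pmin(frr$start + sample(1:500, 200, replace = TRUE), 100000)
  d2 <- bin_fragment_density(frr, 64, lens1)$chr1
  nbins <- length(d2)
  manual <- integer(nbins)
  for (i in seq_len(nrow(frr))) {
    for (b in seq_len(nbins)) {
      bs <- (b - 1) * 64; be <- b * 64
      if (max(bs, frr$start[i]) < min(be, frr$end[i])) {
        manual[b] <- manual[b] + 1L
      }
    }
  }
  expect_equal(d2, manual)
})

test_that("region merging matches the connected-components oracle", {
  # the published rule: one sample's lone peak defines its region
  single <- merge_regions(data.frame(chrom = "chr1", start = 500L,
                                     end = 900L, sample = "s1"))
  expect_equal(single$start, 500)
  expect_equal(single$end, 900)
  expect_equal(single$n_samples, 1)
  # identical peak in 6 samples -> one region with those coordinates
  six <- merge_regions(data.frame(chrom = "chr1", start = 500L, end = 900L,
                                  sample = paste0("s", 1:6)))
  expect_equal(nrow(six), 1)
  expect_equal(six$n_samples, 6)
  # touching half-open intervals do not merge
  touch <- merge_regions(data.frame(chrom = "chr1", start = c(0L, 100L),
                                    end = c(100L, 200L), sample = "s1"))
  expect_equal(nrow(touch), 2)
  # random peaks across 6 samples vs the sweep oracle
  set.seed(27)
  for (rep in 1:10) {
    peaks <- do.call(rbind, lapply(1:6, function(s) {
      n <- sample(20:60, 1)
      st <- sample.int(50000, n)
      data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                 start = st, end = st + sample(50:2000, n, replace = TRUE),
                 sample = paste0("s", s))
    }))
    ours <- merge_regions(peaks)
    oracle <- oracle_merge(peaks)
    expect_equal(ours$start, oracle$start)
    expect_equal(ours$end, oracle$end)
    expect_equal(sum(ours$n_peaks), nrow(peaks))  # partition of the peaks
  }
})

test_that("region counts equal a naive overlap-count oracle", {
  regions <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                        start = c(1000L, 5000L), end = c(2000L, 6000L))
  frags <- list(
    s1 = data.frame(chrom = "chr1", start = c(1100, 1900, 999, 2000, 5500),
                    end = c(1200, 2100, 1001, 2100, 5600)),
    s2 = data.frame(chrom = "chr1", start = c(100), end = c(200)))
  cnt <- region_fragment_counts(regions, frags)
  # boundary overlap by one base counts; touching at the end does not
  expect_equal(cnt["r1", "s1"], 3)
  expect_equal(cnt["r2", "s1"], 1)
  expect_equal(cnt["r1", "s2"], 0)
  set.seed(31)
  rr <- data.frame(region_id = paste0("r", 1:20), chrom = "chr1",
                   start = seq(0, 95000, by = 5000))
  rr$end <- rr$start + 3000
  fr <- data.frame(chrom = "chr1", start = sample.int(99000, 500))
  fr$end <- fr$start + 150
  got <- region_fragment_counts(rr, list(x = fr))[, "x"]
  manual <- vapply(seq_len(nrow(rr)), function(i) {
    sum(pmax(rr$start[i], fr$start) < pmin(rr$end[i], fr$end))
  }, integer(1))
  expect_equal(unname(got), manual)
})

test_that("region annotation classifies overlap patterns with hand geometry", {
  genes <- data.frame(
    gene_id = c("G+", "G-"), chrom = "chr1",
    start = c(50000, 200000), end = c(60000, 210000),
    strand = c("+", "-"), biotype = "protein_coding")
  cat <- suppressMessages(gene_catalog(genes, chrom_lengths = c(chr1 = 3e5)))
  regions <- data.frame(
    region_id = paste0("r", 1:6), chrom = "chr1",
    start = c(100000L, 52000L, 45000L, 61000L, 39500L, 211000L),
    end = c(101000L, 53000L, 46000L, 62000L, 52000L, 212000L))
  out <- annotate_regions(regions, cat, flank = 10000)
  expect_equal(out$annotation,
               c("intergenic",      # >10 kb from every gene
                 "body_only",       # strictly inside G+
                 "upstream_only",   # in the 10 kb 5' flank of G+
                 "downstream_only", # in the 10 kb 3' flank of G+
                 "combination",     # spans flank into body
                 "upstream_only"))  # minus-strand gene: upstream = right
  cgi <- data.frame(chrom = "chr1", start = 52500L, end = 52600L)
  out2 <- annotate_regions(regions, cat, flank = 10000, cgi = cgi)
  expect_equal(out2$cgi_overlap, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("island caller: nulls stay empty, planted regions are recovered", {
  cfg <- island_config()
  # same-rate sample and input: no islands at FDR 1e-10
  nulls <- vapply(1:5, function(s) {
    sim <- simulate_medip_reads(synthetic_medip_config(
      chrom_lengths = c(chr1 = 1e6), n_reads = 20000, n_input_reads = 60000,
      n_samples_per_group = 1, seed = s))
    fr <- extend_reads(sim$samples[[1]], 150, sim$chrom_lengths)
    fi <- extend_reads(sim$input, 150, sim$chrom_lengths)
    nrow(call_islands(fr, fi, cfg, sim$chrom_lengths))
  }, numeric(1))
  expect_true(all(nulls == 0))
  # planted 10x region: recovered island covers >= 80% of the span
  covs <- vapply(1:5, function(s) {
    sim <- simulate_medip_reads(synthetic_medip_config(
      chrom_lengths = c(chr1 = 1e6),
      planted_regions = data.frame(chrom = "chr1", start = 400000,
                                   end = 402000, enrichment = 10,
                                   group_effect = 0),
      n_reads = 50000, n_input_reads = 150000, n_samples_per_group = 1,
      seed = 100 + s))
    fr <- extend_reads(sim$samples[[1]], 150, sim$chrom_lengths)
    fi <- extend_reads(sim$input, 150, sim$chrom_lengths)
    pk <- call_islands(fr, fi, cfg, sim$chrom_lengths)
    if (nrow(pk) == 0) return(0)
    cov <- sum(pmin(pk$end, 402000) - pmax(pk$start, 400000))
    cov / 2000
  }, numeric(1))
  expect_true(all(covs >= 0.8))
  # empty sample -> empty peak list
  empty <- call_islands(data.frame(chrom = character(), start = integer(),
                                   end = integer()),
                        data.frame(chrom = "chr1", start = 0, end = 150),
                        cfg, lens1)
  expect_equal(nrow(empty), 0)
})

test_that("island coverage is monotone in planted enrichment", {
  cfg <- island_config()
  cov_at <- function(enr) {
    sim <- simulate_medip_reads(synthetic_medip_config(
      chrom_lengths = c(chr1 = 1e6),
      planted_regions = data.frame(chrom = "chr1", start = 400000,
                                   end = 402000, enrichment = enr,
                                   group_effect = 0),
      n_reads = 40000, n_input_reads = 120000, n_samples_per_group = 1,
      seed = 7))
    fr <- extend_reads(sim$samples[[1]], 150, sim$chrom_lengths)
    fi <- extend_reads(sim$input, 150, sim$chrom_lengths)
    pk <- call_islands(fr, fi, cfg, sim$chrom_lengths)
    if (nrow(pk) == 0) return(0)
    sum(pmin(pk$end, 402000) - pmax(pk$start, 400000)) / 2000
  }
  covs <- vapply(c(1, 4, 10, 25), cov_at, numeric(1))
  expect_true(all(diff(covs) >= -1e-9))
})

test_that("differential methylation t-test honors its contracts", {
  cnt <- rbind(r1 = c(10, 12, 14, 10, 12, 14),
               r2 = c(100, 110, 120, 160, 170, 180))
  colnames(cnt) <- paste0("s", 1:6)
  groups <- rep(c("STD", "HFD"), each = 3)
  out <- differential_methylation_ttest(cnt, groups)
  expect_equal(out$pvalue[1], 1)   # identical non-constant groups
  tt <- two_sample_t(c(100, 110, 120), c(160, 170, 180))
  expect_equal(out$pvalue[2], tt$pvalue)
  for (meth in c("bonferroni", "holm", "hochberg", "bh", "by")) {
    expect_true(all(out[[meth]] >= out$pvalue))
  }
  swap <- differential_methylation_ttest(cnt, rev(groups))
  expect_equal(out$pvalue, swap$pvalue)
})

test_that("NB differential methylation finds a planted group effect", {
  set.seed(3)
  cnt <- matrix(rnbinom(40 * 6, mu = 200, size = 30), ncol = 6,
                dimnames = list(paste0("r", 1:40), paste0("s", 1:6)))
  groups <- rep(c("STD", "HFD"), each = 3)
  # identical columns -> unit size factors
  same <- matrix(rep(c(5L, 50L, 500L, 20L), 6), ncol = 6,
                 dimnames = list(paste0("q", 1:4), paste0("s", 1:6)))
  sf <- differential_methylation_nb(same, groups)$size_factors
  expect_equal(unname(sf), rep(1, 6), tolerance = 1e-9)
  # planted 5x effect in one region
  cnt["r1", 4:6] <- rnbinom(3, mu = 1000, size = 30)
  res <- differential_methylation_nb(cnt, groups, fdr_threshold = 0.1)
  expect_true("r1" %in% res$significant)
  expect_true(all(res$table$padj >= res$table$pvalue))
  expect_error(differential_methylation_nb(matrix(0L, 3, 6,
    dimnames = list(letters[1:3], paste0("s", 1:6))), groups),
    "size factors")
})

test_that("profile matrix has the expected geometry and separates shapes", {
  # defaults: +/-2000 at 32-base bins -> 125 columns
  regions <- data.frame(region_id = paste0("r", 1:10), chrom = "chr1",
                        start = seq(10000, 82000, by = 8000))
  regions$end <- regions$start + 1000
  mids <- (regions$start + regions$end) %/% 2
  # two planted shapes: tight central pile-up vs broad flat coverage
  frag_rows <- list()
  for (i in 1:10) {
    if (i <= 5) {
      st <- rep(mids[i] - 50, 40)
      frag_rows[[i]] <- data.frame(chrom = "chr1", start = st, end = st + 100)
    } else {
      st <- seq(mids[i] - 1900, mids[i] + 1700, length.out = 40)
      frag_rows[[i]] <- data.frame(chrom = "chr1", start = round(st),
                                   end = round(st) + 100)
    }
  }
  frags <- do.call(rbind, frag_rows)
  out <- region_profile_kmeans(regions, frags, k = 2, seed = 4)
  expect_equal(ncol(out$profile), 125)
  expect_length(out$cluster, 10)
  expect_equal(length(unique(out$cluster[1:5])), 1)
  expect_equal(length(unique(out$cluster[6:10])), 1)
  expect_true(out$cluster[1] != out$cluster[6])
  # one region -> one occupied cluster, k reduced with warning
  expect_warning(one <- region_profile_kmeans(regions[1, ], frags, k = 5,
                                              seed = 1), "reduced")
  expect_equal(unique(one$cluster), 1L)
})
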