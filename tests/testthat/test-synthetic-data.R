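test_that("generated catalogs honor pair specs and are deterministic", {
  specs <- data.frame(
    relation = c("overlap-body", "overlap-promoter", "upstream-flank",
                 "downstream-flank", "antisense-overlap"),
    distance = c(0, 0, 750, 1200, 0), count = 2)
  cfg <- synthetic_annotation_config(n_chromosomes = 2,
                                     chromosome_length = 1.5e6,
                                     n_protein_coding = 20,
                                     pair_specs = specs, seed = 11)
  out <- generate_gene_catalog(cfg)
  g <- out$catalog$genes
  expect_equal(sum(g$class == "lncRNA"), 10)
  # verify every planted relation by direct interval arithmetic
  for (i in seq_len(nrow(out$truth))) {
    tr <- out$truth[i, ]
    l <- g[g$gene_id == tr$lnc_id, ]
    p <- g[g$gene_id == tr$pc_id, ]
    expect_equal(l$chrom, p$chrom)
    overlaps <- max(l$start, p$start) < min(l$end, p$end)
    gap <- max(l$start, p$start) - min(l$end, p$end)
    tss <- if (p$strand == "+") p$start else p$end - 1
    if (tr$relation %in% c("overlap-body", "overlap-promoter",
                           "antisense-overlap")) {
      expect_true(overlaps)
    } else {
      expect_false(overlaps)
      expect_equal(gap, tr$distance)
    }
    if (tr$relation == "overlap-promoter") {
      expect_true(l$start <= tss && tss < l$end)
    }
    if (tr$relation == "antisense-overlap") expect_true(l$strand != p$strand)
    if (tr$relation == "upstream-flank") {
      if (p$strand == "+") expect_true(l$end <= p$start)
      else expect_true(l$start >= p$end)
    }
  }
  expect_true(all(g$start >= 0 & g$end <= 1.5e6))
  # determinism and the empty case
  out2 <- generate_gene_catalog(cfg)
  expect_identical(out, out2)
  none <- generate_gene_catalog(synthetic_annotation_config(
    n_chromosomes = 1, chromosome_length = 1e6, n_protein_coding = 5,
    seed = 2))
  expect_true(all(none$catalog$genes$class == "protein_coding"))
  expect_equal(nrow(none$truth), 0)
})

test_that("impossible planted geometry errors, naming the spec", {
  cfg <- synthetic_annotation_config(
    n_chromosomes = 1, chromosome_length = 200000, n_protein_coding = 1,
    pair_specs = data.frame(relation = "upstream-flank", distance = 300000,
                            count = 1), seed = 1)
  expect_error(generate_gene_catalog(cfg), "upstream-flank")
})

test_that("simulated counts match NB expectations and plant correlations", {
  cat1 <- suppressMessages(gene_catalog(data.frame(
    gene_id = c("target", "lncA", "pcA", "filler"),
    chrom = "chr1", start = c(0, 100, 200, 300) * 1000,
    end = c(10, 110, 210, 310) * 1000, strand = "+",
    biotype = c("protein_coding", "lincRNA", "protein_coding",
                "protein_coding"))))
  # a gene at CPM 250000 (1 of 4 equal genes) and depth 1e4 has mean 2500;
  # check the empirical mean across many simulated samples
  cfg <- synthetic_counts_config(n_samples_per_group = 50, depth = 1e4,
                                 baseline_sdlog = 0, dispersion = 0.1,
                                 de_fraction = 0, seed = 5)
  sim <- simulate_counts(cat1, cfg)
  expect_equal(nrow(sim$truth_de), 0)
  expect_equal(nrow(sim$truth_pairs), 0)
  counts <- sim$counts$counts
  expect_true(all(counts >= 0 & counts == round(counts)))
  mu <- 2500
  se <- sqrt((mu + 0.1 * mu^2) / 100)
  expect_lt(abs(mean(counts["target", ]) - mu), 3 * se)

  # planted rho = 0.9: average sample r over repeated 6-sample draws.
  # Plenty of filler genes keep the pair a small fraction of the library,
  # so CPM normalization does not soak up the shared latent factor.
  filler <- data.frame(
    gene_id = paste0("f", 1:60), chrom = "chr1",
    start = (4:63) * 10000, end = (4:63) * 10000 + 5000,
    strand = "+", biotype = "protein_coding")
  cat_big <- suppressMessages(gene_catalog(rbind(cat1$genes[, 1:6], filler)))
  rs <- vapply(1:200, function(s) {
    cfgp <- synthetic_counts_config(
      n_samples_per_group = 3, depth = 1e6, baseline_sdlog = 0,
      dispersion = 0.05, de_fraction = 0,
      correlated_pairs = data.frame(lnc_id = "lncA", pc_id = "pcA",
                                    rho = 0.9),
      seed = s)
    simp <- simulate_counts(cat_big, cfgp)
    lc <- log2_cpm(simp$counts)
    cor(lc["lncA", ], lc["pcA", ])
  }, numeric(1))
  expect_gt(mean(rs), 0.6)

  expect_error(simulate_counts(cat1, synthetic_counts_config(depth = 0)),
               "depth")
})

test_that("mixture simulation equals the matrix product when noiseless", {
  sig <- matrix(c(100, 0, 0, 0, 50, 0, 0, 0, 20), nrow = 3,
                dimnames = list(paste0("m", 1:3), paste0("t", 1:3)))
  pure <- matrix(c(1, 0, 0), nrow = 1)
  expect_equal(unname(simulate_mixture_expression(sig, pure)[, 1]),
               unname(sig[, 1]))
  set.seed(1)
  pr <- matrix(runif(15), nrow = 5)
  pr <- pr / rowSums(pr)
  expect_equal(simulate_mixture_expression(sig, pr),
               sig %*% t(pr))
  # seed changes only the noise, not the expectation
  a <- simulate_mixture_expression(sig, pr, noise_sd = 0.1, seed = 1)
  b <- simulate_mixture_expression(sig, pr, noise_sd = 0.1, seed = 2)
  expect_false(identical(a, b))
  expect_equal(dim(a), dim(sig %*% t(pr)))
  expect_error(simulate_mixture_expression(sig, -pr), "non-negative")
})

test_that("medip read simulation hits Poisson expectations in planted regions", {
  cfg <- synthetic_medip_config(
    chrom_lengths = c(chr1 = 1e6),
    planted_regions = data.frame(chrom = "chr1", start = 500000,
                                 end = 502000, enrichment = 10,
                                 group_effect = 0),
    n_reads = 50000, n_input_reads = 50000, n_samples_per_group = 1,
    seed = 3)
  sim <- simulate_medip_reads(cfg)
  r <- sim$samples[[1]]
  expect_true(all(r$pos >= 0 & r$pos < 1e6))
  # expected reads in the region: n * weight_region / total_weight
  w_reg <- 2000 * 10
  w_tot <- (1e6 - 2000) + w_reg
  lambda <- 50000 * w_reg / w_tot
  n_in <- sum(r$pos >= 500000 & r$pos < 502000)
  expect_lt(abs(n_in - lambda), 3 * sqrt(lambda))
  # input control is uniform: same interval close to unenriched expectation
  lam0 <- 50000 * 2000 / 1e6
  n_input <- sum(sim$input$pos >= 500000 & sim$input$pos < 502000)
  expect_lt(abs(n_input - lam0), 4 * sqrt(lam0))
  # enrichment 1 everywhere -> empty truth; different seeds differ
  flat <- simulate_medip_reads(synthetic_medip_config(
    chrom_lengths = c(chr1 = 1e5), n_reads = 1000, n_input_reads = 1000,
    n_samples_per_group = 1, seed = 1))
  expect_equal(nrow(flat$truth), 0)
  flat2 <- simulate_medip_reads(synthetic_medip_config(
    chrom_lengths = c(chr1 = 1e5), n_reads = 1000, n_input_reads = 1000,
    n_samples_per_group = 1, seed = 2))
  expect_false(identical(flat$samples, flat2$samples))
})

test_that("bisulfite simulation recovers planted levels and conversion", {
  amp <- c(a1 = "ATCGATTCGGATCGATACGATCCGATCG")
  cfg <- synthetic_bisulfite_config(
    amplicon_sequences = amp,
    per_cpg_methylation = list(STD = 0.25, HFD = 0.25),
    conversion_rate = 1.0, coverage = 1e4, n_samples_per_group = 1,
    seed = 9)
  sim <- simulate_bisulfite_counts(cfg)
  s <- sim$sites
  expect_true(all(s$methylated <= s$total))
  cpg <- s[s$context == "CpG" & s$sample == "STD_1", ]
  frac <- sum(cpg$methylated) / sum(cpg$total)
  se <- sqrt(0.25 * 0.75 / sum(cpg$total))
  expect_lt(abs(frac - 0.25), 3 * se)
  # full conversion + zero methylation: every call unmethylated
  cfg0 <- synthetic_bisulfite_config(amp,
    per_cpg_methylation = list(STD = 0), conversion_rate = 1.0,
    coverage = 100, n_samples_per_group = 2, seed = 1)
  sim0 <- simulate_bisulfite_counts(cfg0)
  expect_true(all(sim0$sites$methylated == 0))
  # conversion 0.99 leaves ~1% apparent non-CpG methylation
  cfg99 <- synthetic_bisulfite_config(amp,
    per_cpg_methylation = list(STD = 0.8), conversion_rate = 0.99,
    coverage = 1e4, n_samples_per_group = 1, seed = 2)
  sim99 <- simulate_bisulfite_counts(cfg99)
  qc <- noncpg_conversion_qc(sim99$sites)
  ncpg_tot <- sum(sim99$sites$total[sim99$sites$context == "non-CpG"])
  se_pct <- 100 * sqrt(0.01 * 0.99 / ncpg_tot)
  expect_lt(abs(qc[["STD_1"]] - 1), 3 * se_pct)
  expect_error(synthetic_bisulfite_config(character(0)), "non-empty")
})
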