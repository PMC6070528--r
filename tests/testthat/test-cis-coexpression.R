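test_that("critical r reproduces the published one-tailed threshold", {
  expect_equal(critical_r(6, 0.05, "one"), 0.7293, tolerance = 1e-4)
  expect_equal(round(critical_r(6, 0.05, "one"), 2), 0.73)
  expect_equal(critical_r(4, 0.05, "one"), 0.900, tolerance = 1e-3)
  expect_true(critical_r(6, 0.05, "one") < critical_r(5, 0.05, "one"))
  expect_true(critical_r(5, 0.05, "one") < critical_r(4, 0.05, "one"))
  expect_true(critical_r(6, 0.01, "one") > critical_r(6, 0.05, "one"))
  expect_error(critical_r(2), ">= 3")
})

test_that("pearson_r matches hand values and flags constant vectors", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, 5:1), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 5)), -0.5)
  expect_warning(r <- pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
})

test_that("cis pairing equals the exhaustive oracle on random catalogs", {
  set.seed(33)
  for (i in 1:100) {
    cat <- random_catalog(n_pc = sample(3:10, 1), n_lnc = sample(1:6, 1),
                          n_chrom = sample(1:3, 1))
    g <- cat$genes
    lnc <- g$gene_id[g$class == "lncRNA"]
    pc <- g$gene_id[g$class == "protein_coding"]
    ours <- suppressMessages(find_cis_pairs(cat, lnc, pc))
    oracle <- oracle_cis_pairs(cat, lnc, pc)
    expect_equal(pair_key(ours), pair_key(oracle))
  }
})

test_that("edge cases: lone lncRNA, spanning lncRNA, equidistant flanks", {
  genes <- data.frame(
    gene_id = c("L1", "L2", "L3", "P1", "P2", "P3"),
    chrom = c("chr2", "chr1", "chr1", "chr1", "chr1", "chr1"),
    start = c(100, 4900, 20000, 1000, 5000, 30000),
    end = c(600, 6100, 21000, 2000, 6000, 31000),
    strand = "+",
    biotype = c(rep("lincRNA", 3), rep("protein_coding", 3)))
  cat <- suppressMessages(gene_catalog(genes))
  # L1 alone on chr2 -> no pair
  expect_equal(nrow(suppressMessages(
    find_cis_pairs(cat, "L1", c("P1", "P2", "P3")))), 0)
  # L2 spans into P2 and would also reach P1? It overlaps only P2 here;
  # widen it to overlap both
  genes2 <- genes
  genes2$start[genes2$gene_id == "L2"] <- 1500
  cat2 <- suppressMessages(gene_catalog(genes2))
  p <- find_cis_pairs(cat2, "L2", c("P1", "P2", "P3"))
  expect_setequal(p$pc_id, c("P1", "P2"))
  # equidistant flanks emit both pairs
  genes3 <- data.frame(
    gene_id = c("LX", "PA", "PB"), chrom = "chr1",
    start = c(5000, 1000, 7000), end = c(6000, 4000, 9000),
    strand = "+", biotype = c("lincRNA", "protein_coding", "protein_coding"))
  cat3 <- suppressMessages(gene_catalog(genes3))
  p3 <- find_cis_pairs(cat3, "LX", c("PA", "PB"))
  expect_equal(nrow(p3), 2)
  expect_equal(p3$distance, c(1000, 1000))
})

test_that("pair geometry is classified strand-aware with hand coordinates", {
  genes <- data.frame(
    gene_id = c("Lbody", "Ltss", "Lup", "Lupm", "P+", "P-"),
    chrom = "chr1",
    start = c(13000, 9800, 7500, 26000, 10000, 20000),
    end = c(14000, 10300, 9500, 27000, 18000, 25000),
    strand = c("+", "+", "+", "+", "+", "-"),
    biotype = c(rep("lincRNA", 4), "protein_coding", "protein_coding"))
  cat <- suppressMessages(gene_catalog(genes))
  pairs <- data.frame(
    lnc_id = c("Lbody", "Ltss", "Lup", "Lupm"),
    pc_id = c("P+", "P+", "P+", "P-"),
    overlapping = c(TRUE, TRUE, FALSE, FALSE),
    distance = c(0L, 0L, 500L, 1000L))
  out <- classify_pair_geometry(pairs, cat)
  # inside the body, beyond the 200-base downstream promoter window
  expect_equal(out$relation[1], "overlap"); expect_equal(out$overlap_target[1], "body")
  # straddles the TSS at 10000
  expect_equal(out$overlap_target[2], "promoter")
  # ends 500 bases 5' of the plus-strand gene start
  expect_equal(out$relation[3], "upstream")
  expect_equal(out$distance[3], 500)
  # minus-strand gene: higher coordinates are upstream
  expect_equal(out$relation[4], "upstream")
})

test_that("co-expression flags respect the critical threshold", {
  # construct counts with controlled linear correlations across 6 samples;
  # a padding row equalizes library totals so CPM preserves correlations
  x <- c(1, 2, 3, 4, 5, 6)
  make_y <- function(target_r) {
    e <- c(1, -1, 0.5, -0.5, 1, -1)
    e <- e - mean(e); xc <- x - mean(x)
    e <- e - sum(e * xc) / sum(xc^2) * xc  # orthogonalize against x
    xc / sd(xc) * target_r + e / sd(e) * sqrt(1 - target_r^2)
  }
  counts <- rbind(L1 = x * 1e4, P1 = round((make_y(0.74) + 4) * 1e4),
                  L2 = x * 1e4, P2 = round((make_y(0.70) + 4) * 1e4),
                  L3 = rep(2e4, 6), P3 = x * 1e4)
  counts <- rbind(counts, PAD = max(colSums(counts)) + 1e5 - colSums(counts))
  colnames(counts) <- paste0("s", 1:6)
  cm <- count_matrix(counts, rep(c("STD", "HFD"), each = 3))
  pairs <- data.frame(lnc_id = c("L1", "L2", "L3"),
                      pc_id = c("P1", "P2", "P3"),
                      overlapping = TRUE, distance = 0L)
  out <- suppressWarnings(
    coexpression_analysis(pairs, cm, transform = "cpm"))
  rcrit <- attr(out, "critical_r")
  expect_equal(rcrit, critical_r(6, 0.05, "one"))
  expect_equal(out$r[1], 0.74, tolerance = 1e-3)
  expect_equal(out$r[2], 0.70, tolerance = 1e-3)
  expect_true(out$co_expressed[1])
  expect_equal(out$sign[1], "positive")
  expect_false(out$co_expressed[2])
  expect_true(is.na(out$r[3]))
  expect_false(out$co_expressed[3])
  expect_match(out$exclude_reason[3], "constant")
})

test_that("r = 0.74 is called co-expressed and r = 0.70 is not at n = 6", {
  rcrit <- critical_r(6, 0.05, "one")
  expect_true(0.74 >= rcrit)
  expect_false(0.70 >= rcrit)
})

test_that("planted rho = 0.95 pairs are detected with sensitivity >= 0.9", {
  gen <- generate_gene_catalog(synthetic_annotation_config(
    n_chromosomes = 2, chromosome_length = 6e6, n_protein_coding = 100,
    pair_specs = data.frame(relation = "upstream-flank", distance = 2000,
                            count = 10), seed = 1))
  truth <- gen$truth
  rcrit <- critical_r(6, 0.05, "one")
  hits <- tot <- 0
  for (s in 1:10) {
    sim <- simulate_counts(gen$catalog, synthetic_counts_config(
      n_samples_per_group = 3, depth = 1e6, baseline_sdlog = 1,
      dispersion = 0.01, de_fraction = 0,
      correlated_pairs = data.frame(lnc_id = truth$lnc_id,
                                    pc_id = truth$pc_id, rho = 0.95),
      seed = 5000 + s))
    lc <- log2_cpm(sim$counts)
    for (i in seq_len(nrow(truth))) {
      r <- cor(lc[truth$lnc_id[i], ], lc[truth$pc_id[i], ])
      tot <- tot + 1
      hits <- hits + (abs(r) >= rcrit)
    }
  }
  expect_gte(hits / tot, 0.9)
})

test_that("diet-responsive flag equals the set-intersection oracle", {
  set.seed(14)
  for (i in 1:20) {
    pairs <- data.frame(lnc_id = sample(paste0("L", 1:10), 5),
                        pc_id = sample(paste0("P", 1:10), 5))
    deg <- sample(c(paste0("L", 1:10), paste0("P", 1:10)), 8)
    out <- diet_responsive_pairs(pairs, deg)
    oracle <- pairs$lnc_id %in% deg & pairs$pc_id %in% deg
    expect_equal(out$diet_responsive, oracle)
  }
  both <- diet_responsive_pairs(data.frame(lnc_id = "a", pc_id = "b"),
                                c("a", "b"))
  expect_true(both$diet_responsive)
  neither <- diet_responsive_pairs(data.frame(lnc_id = "a", pc_id = "b"),
                                   character(0))
  expect_false(neither$diet_responsive)
})

test_that("enhancer overlap equals a brute-force interval check", {
  set.seed(25)
  cat <- random_catalog(n_pc = 5, n_lnc = 8, n_chrom = 2)
  enh <- data.frame(chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                    start = sample.int(90000, 30))
  enh$end <- enh$start + sample(100:3000, 30, replace = TRUE)
  g <- cat$genes
  lnc <- g$gene_id[g$class == "lncRNA"]
  flags <- enhancer_overlap(cat, lnc, enh)
  for (id in lnc) {
    l <- g[g$gene_id == id, ]
    manual <- any(enh$chrom == l$chrom &
                  pmax(enh$start, l$start) < pmin(enh$end, l$end))
    expect_equal(unname(flags[id]), manual)
  }
  none <- enhancer_overlap(cat, lnc, enh[0, ])
  expect_true(all(!none))
})

test_that("BED reading validates lines and keeps 0-based coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1\t100\t200\tfeat\t0\t+",
               "chr2\t0\t50"), bed)
  out <- read_bed(bed)
  expect_equal(out$start, c(100, 0))
  expect_equal(out$end, c(200, 50))
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t300"), bad)
  expect_error(read_bed(bad), "line 2")
  bad2 <- tempfile(fileext = ".bed")
  writeLines("chr1\t500\t400", bad2)
  expect_error(read_bed(bad2), "line 1")
})
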