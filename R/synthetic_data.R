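# Synthetic-data generators: every input the pipeline consumes can be
# produced with known ground truth (planted cis-pair geometries, DE genes,
# correlated pairs, cell-type mixtures, enriched methylation regions,
# per-CpG methylation levels), so all stages are testable without
# sequencing data. Identical configs and seeds give identical outputs.

#' Synthetic annotation configuration
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome in bases.
#' @param n_protein_coding Number of protein-coding genes (spread evenly
#'   over chromosomes).
#' @param pair_specs data.frame with columns `relation` (one of
#'   `overlap-promoter`, `overlap-body`, `upstream-flank`,
#'   `downstream-flank`, `antisense-overlap`), `distance` (gap in bases,
#'   used by the flank relations) and `count`.
#' @param seed RNG seed.
#' @return List of class `synthetic_annotation_config`.
#' @export
synthetic_annotation_config <- function(n_chromosomes = 3,
                                        chromosome_length = 3e6,
                                        n_protein_coding = 60,
                                        pair_specs = NULL,
                                        seed = 1) {
  if (is.null(pair_specs)) {
    pair_specs <- data.frame(relation = character(), distance = integer(),
                             count = integer())
  }
  ok <- c("overlap-promoter", "overlap-body", "upstream-flank",
          "downstream-flank", "antisense-overlap")
  .assert(all(pair_specs$relation %in% ok),
          "unknown relation(s): %s",
          paste(setdiff(pair_specs$relation, ok), collapse = ", "))
  .assert(all(pair_specs$distance >= 0) && all(pair_specs$count >= 0),
          "distances and counts must be >= 0")
  .assert(n_chromosomes >= 1 && n_protein_coding >= 0,
          "counts must be >= 0")
  structure(list(n_chromosomes = n_chromosomes,
                 chromosome_length = chromosome_length,
                 n_protein_coding = n_protein_coding,
                 pair_specs = pair_specs, seed = seed),
            class = "synthetic_annotation_config")
}

#' Generate a gene catalog with planted lncRNA/protein-coding geometries
#'
#' Protein-coding genes are laid out in non-overlapping slots along each
#' chromosome (random length and jittered position inside the slot, random
#' strand). Each pair spec plants lncRNAs against distinct protein-coding
#' partners realizing the requested relation exactly: overlapping the
#' promoter (straddling the TSS), overlapping the body away from the
#' promoter window, flanking upstream/downstream at the requested gap, or
#' overlapping antisense.
#'
#' @param config A [synthetic_annotation_config()].
#' @return List with `catalog` (a [gene_catalog()]) and `truth` (data.frame
#'   `lnc_id`, `pc_id`, `relation`, `distance`).
#' @export
generate_gene_catalog <- function(config) {
  stopifnot(inherits(config, "synthetic_annotation_config"))
  .with_seed(config$seed, .generate_gene_catalog(config))
}

.generate_gene_catalog <- function(config) {
  n_pairs <- sum(config$pair_specs$count)
  .assert(n_pairs <= config$n_protein_coding,
          "more planted pairs (%d) than protein-coding genes (%d)",
          n_pairs, config$n_protein_coding)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  per_chrom <- table(factor(rep(chroms, length.out = config$n_protein_coding),
                            levels = chroms))
  margin <- 25000  # room inside a slot for flanking lncRNAs
  genes <- list()
  pc_ids <- character(0)
  for (chr in chroms) {
    n <- per_chrom[[chr]]
    if (n == 0) next
    slot <- config$chromosome_length %/% n
    .assert(slot >= 2 * margin + 20000,
            "chromosome_length %d too short for %d genes per chromosome",
            config$chromosome_length, n)
    for (i in seq_len(n)) {
      len <- round(stats::runif(1, 5000, 15000))
      lo <- (i - 1) * slot + margin
      hi <- i * slot - margin - len
      start <- round(stats::runif(1, lo, hi))
      id <- sprintf("PC%04d", length(pc_ids) + 1)
      pc_ids <- c(pc_ids, id)
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = id, chrom = chr, start = start, end = start + len,
        strand = sample(c("+", "-"), 1), biotype = "protein_coding")
    }
  }
  genes <- do.call(rbind, genes)
  truth <- data.frame(lnc_id = character(), pc_id = character(),
                      relation = character(), distance = integer())
  lnc_rows <- list()
  partners <- if (n_pairs > 0) sample(pc_ids, n_pairs) else character(0)
  pi <- 0
  for (s in seq_len(nrow(config$pair_specs))) {
    spec <- config$pair_specs[s, ]
    for (j in seq_len(spec$count)) {
      pi <- pi + 1
      pc <- genes[genes$gene_id == partners[pi], ]
      lnc <- .plant_lncrna(pc, spec$relation, spec$distance,
                           config$chromosome_length,
                           sprintf("LNC%04d", pi))
      lnc_rows[[pi]] <- lnc
      truth <- rbind(truth, data.frame(lnc_id = lnc$gene_id,
                                       pc_id = pc$gene_id,
                                       relation = spec$relation,
                                       distance = spec$distance))
    }
  }
  all_genes <- rbind(genes, do.call(rbind, lnc_rows))
  catalog <- gene_catalog(
    all_genes,
    chrom_lengths = stats::setNames(rep(config$chromosome_length,
                                        length(chroms)), chroms))
  list(catalog = catalog, truth = truth)
}

.plant_lncrna <- function(pc, relation, distance, chrom_len, id) {
  plus <- pc$strand == "+"
  tss <- if (plus) pc$start else pc$end - 1L
  lnc_len <- 1000L
  coords <- switch(relation,
    "overlap-promoter" = c(tss - lnc_len %/% 2, tss + lnc_len %/% 2),
    "overlap-body" = {
      .assert(pc$end - pc$start > 2500,
              "pair spec '%s': gene too short for a body-only overlap",
              relation)
      if (plus) c(pc$start + 2300, min(pc$end, pc$start + 2300 + lnc_len))
      else c(max(pc$start, pc$end - 2300 - lnc_len), pc$end - 2300)
    },
    "antisense-overlap" = {
      mid <- (pc$start + pc$end) %/% 2
      c(mid - lnc_len %/% 2, mid + lnc_len %/% 2)
    },
    "upstream-flank" = if (plus) c(pc$start - distance - lnc_len,
                                   pc$start - distance)
                       else c(pc$end + distance, pc$end + distance + lnc_len),
    "downstream-flank" = if (plus) c(pc$end + distance,
                                     pc$end + distance + lnc_len)
                         else c(pc$start - distance - lnc_len,
                                pc$start - distance),
    .stopf("unknown relation '%s'", relation))
  .assert(coords[1] >= 0 && coords[2] <= chrom_len && coords[1] < coords[2],
          "pair spec '%s' (distance %d) does not fit within the chromosome",
          relation, distance)
  strand <- if (relation == "antisense-overlap") {
    if (plus) "-" else "+"
  } else pc$strand
  biotype <- switch(relation,
                    "antisense-overlap" = "antisense",
                    "overlap-promoter" = "antisense",
                    "overlap-body" = "sense_intronic",
                    "lincRNA")
  data.frame(gene_id = id, chrom = pc$chrom, start = as.integer(coords[1]),
             end = as.integer(coords[2]), strand = strand, biotype = biotype)
}

#' Synthetic counts configuration
#'
#' Defaults mirror the 2-diet, 3-pools-per-diet RNA-seq design: two groups
#' (`STD`, `HFD`) of 3 libraries each with NB noise around a log-normal
#' baseline.
#'
#' @param n_samples_per_group Libraries per group (default 3).
#' @param depth Reads per library (default 2e6; a desk-scale library).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   relative gene abundances (normalized to CPM internally).
#' @param dispersion NB dispersion phi (variance mu + phi mu^2; default 0.1,
#'   typical of pooled liver libraries).
#' @param de_fraction Fraction of genes planted as differentially expressed.
#' @param logfc_min,logfc_max Planted |log2 fold-change| range (random sign;
#'   set both equal for a fixed effect size).
#' @param correlated_pairs data.frame (`lnc_id`, `pc_id`, `rho`) of planted
#'   co-expressed pairs (latent correlation on the log scale).
#' @param latent_sd Standard deviation (log2 units) of the shared latent
#'   factor driving correlated pairs (default 1.5).
#' @param seed RNG seed.
#' @return List of class `synthetic_counts_config`.
#' @export
synthetic_counts_config <- function(n_samples_per_group = 3, depth = 2e6,
                                    baseline_meanlog = 3, baseline_sdlog = 1.5,
                                    dispersion = 0.1, de_fraction = 0.03,
                                    logfc_min = 1, logfc_max = 3,
                                    correlated_pairs = NULL,
                                    latent_sd = 1.5, seed = 1) {
  .assert(dispersion >= 0, "dispersion must be >= 0")
  .assert(de_fraction >= 0 && de_fraction <= 1, "de_fraction must be in [0,1]")
  if (is.null(correlated_pairs)) {
    correlated_pairs <- data.frame(lnc_id = character(), pc_id = character(),
                                   rho = numeric())
  }
  .assert(all(abs(correlated_pairs$rho) <= 1), "|rho| must be <= 1")
  structure(list(n_samples_per_group = n_samples_per_group, depth = depth,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, dispersion = dispersion,
                 de_fraction = de_fraction, logfc_min = logfc_min,
                 logfc_max = logfc_max, correlated_pairs = correlated_pairs,
                 latent_sd = latent_sd, seed = seed),
            class = "synthetic_counts_config")
}

#' Simulate a count matrix with planted effects
#'
#' Gene baselines are log-normal, normalized to CPM. Planted DE genes get a
#' signed log2 fold-change applied to the second group. Planted correlated
#' pairs share a per-sample latent log2 factor scaled so the latent
#' correlation equals rho (negative rho flips the partner's loading).
#' Counts are NB with common dispersion (Poisson when dispersion is 0).
#'
#' @param catalog A [gene_catalog()]; all its genes are simulated.
#' @param config A [synthetic_counts_config()].
#' @return List with `counts` (a [count_matrix()]; groups `STD`/`HFD`),
#'   `truth_de` (`gene_id`, `logfc`), `truth_pairs` (the planted pair table),
#'   `baseline_cpm`.
#' @export
simulate_counts <- function(catalog, config) {
  stopifnot(inherits(catalog, "gene_catalog"),
            inherits(config, "synthetic_counts_config"))
  .assert(nrow(catalog$genes) > 0, "catalog must be non-empty")
  .assert(config$depth > 0, "depth must be > 0")
  .with_seed(config$seed, .simulate_counts(catalog, config))
}

.simulate_counts <- function(catalog, config) {
  ids <- catalog$genes$gene_id
  G <- length(ids)
  n <- config$n_samples_per_group
  samples <- c(paste0("STD_", seq_len(n)), paste0("HFD_", seq_len(n)))
  groups <- rep(c("STD", "HFD"), each = n)
  w <- stats::rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
  base_cpm <- stats::setNames(w / sum(w) * 1e6, ids)
  pair_ids <- unique(c(config$correlated_pairs$lnc_id,
                       config$correlated_pairs$pc_id))
  .assert(all(pair_ids %in% ids),
          "correlated pair members missing from catalog: %s",
          paste(setdiff(pair_ids, ids), collapse = ", "))
  n_de <- round(config$de_fraction * G)
  de_pool <- setdiff(ids, pair_ids)
  de_ids <- if (n_de > 0) sample(de_pool, min(n_de, length(de_pool)))
            else character(0)
  lfc <- stats::setNames(numeric(G), ids)
  if (length(de_ids) > 0) {
    lfc[de_ids] <- sample(c(-1, 1), length(de_ids), replace = TRUE) *
      stats::runif(length(de_ids), config$logfc_min, config$logfc_max)
  }
  # per-sample log2 multipliers from the shared latent factor of each pair
  logmult <- matrix(0, nrow = G, ncol = 2 * n, dimnames = list(ids, samples))
  cp <- config$correlated_pairs
  for (i in seq_len(nrow(cp))) {
    z <- stats::rnorm(2 * n)
    a <- sqrt(abs(cp$rho[i]))
    b <- sqrt(1 - abs(cp$rho[i]))
    logmult[cp$lnc_id[i], ] <- logmult[cp$lnc_id[i], ] +
      config$latent_sd * (a * z + b * stats::rnorm(2 * n))
    logmult[cp$pc_id[i], ] <- logmult[cp$pc_id[i], ] +
      config$latent_sd * (sign(cp$rho[i]) * a * z + b * stats::rnorm(2 * n))
  }
  mu <- matrix(base_cpm / 1e6 * config$depth, nrow = G, ncol = 2 * n,
               dimnames = list(ids, samples))
  mu[, groups == "HFD"] <- mu[, groups == "HFD"] * 2^lfc
  mu <- mu * 2^logmult
  counts <- matrix(0L, nrow = G, ncol = 2 * n,
                   dimnames = list(ids, samples))
  for (j in seq_len(2 * n)) {
    counts[, j] <- if (config$dispersion > 0) {
      stats::rnbinom(G, size = 1 / config$dispersion, mu = mu[, j])
    } else {
      stats::rpois(G, mu[, j])
    }
  }
  list(counts = count_matrix(counts, groups),
       truth_de = data.frame(gene_id = de_ids,
                             logfc = unname(lfc[de_ids])),
       truth_pairs = cp,
       baseline_cpm = base_cpm)
}

#' Simulate mixed-cell-type expression
#'
#' Noiseless output is exactly `signatures %*% t(proportions)`; noise is
#' multiplicative log-normal with the given sdlog.
#'
#' @param signatures Genes x cell-types expression matrix.
#' @param proportions Samples x cell-types matrix; each row sums to 1,
#'   entries >= 0.
#' @param noise_sd sdlog of the multiplicative noise (0 for none).
#' @param seed RNG seed (changes only the noise, not the expectation).
#' @return Genes x samples expression matrix.
#' @export
simulate_mixture_expression <- function(signatures, proportions,
                                        noise_sd = 0, seed = 1) {
  signatures <- as.matrix(signatures)
  proportions <- as.matrix(proportions)
  .assert(all(proportions >= 0), "proportions must be non-negative")
  .assert(max(abs(rowSums(proportions) - 1)) < 1e-8,
          "each proportion row must sum to 1")
  .assert(ncol(signatures) == ncol(proportions),
          "signatures and proportions disagree on the number of cell types")
  expected <- signatures %*% t(proportions)
  if (is.null(rownames(expected))) rownames(expected) <- rownames(signatures)
  if (noise_sd == 0) return(expected)
  noise <- .with_seed(seed,
    matrix(stats::rlnorm(length(expected), 0, noise_sd),
           nrow = nrow(expected)))
  expected * noise
}

#' Synthetic MeDIP configuration
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param background_rate Expected reads per base outside planted regions.
#' @param planted_regions data.frame `chrom`, `start`, `end`, `enrichment`
#'   (>= 1), `group_effect` (log2 extra enrichment in the second group; 0
#'   for no diet effect).
#' @param read_length Sequenced read length (bases; default 50).
#' @param n_reads Reads per immunoprecipitated sample.
#' @param n_input_reads Reads in the pooled input control (uniform rate,
#'   enrichment 1 everywhere).
#' @param n_samples_per_group Samples per group (default 3).
#' @param seed RNG seed.
#' @return List of class `synthetic_medip_config`.
#' @export
synthetic_medip_config <- function(chrom_lengths = c(chr1 = 1e6),
                                   background_rate = 0.05,
                                   planted_regions = NULL,
                                   read_length = 50, n_reads = 50000,
                                   n_input_reads = 200000,
                                   n_samples_per_group = 3, seed = 1) {
  if (is.null(planted_regions)) {
    planted_regions <- data.frame(chrom = character(), start = integer(),
                                  end = integer(), enrichment = numeric(),
                                  group_effect = numeric())
  }
  .assert(all(planted_regions$enrichment >= 1), "enrichment must be >= 1")
  .assert(all(planted_regions$chrom %in% names(chrom_lengths)) &&
          all(planted_regions$start >= 0) &&
          all(planted_regions$end <= chrom_lengths[planted_regions$chrom]),
          "planted regions must lie within the genome")
  structure(list(chrom_lengths = chrom_lengths,
                 background_rate = background_rate,
                 planted_regions = planted_regions,
                 read_length = read_length, n_reads = n_reads,
                 n_input_reads = n_input_reads,
                 n_samples_per_group = n_samples_per_group, seed = seed),
            class = "synthetic_medip_config")
}

#' Simulate MeDIP read 5'-end positions
#'
#' Reads fall uniformly over the genome except inside planted regions, where
#' the sampling weight is multiplied by the enrichment factor (times
#' 2^group_effect in the second group). The pooled input control is uniform.
#'
#' @param config A [synthetic_medip_config()].
#' @return List with `samples` (named list of read data.frames
#'   `chrom`/`pos`/`strand`; groups `STD`/`HFD`), `input` (read data.frame),
#'   `groups` (named vector), `truth` (planted regions with enrichment > 1),
#'   `chrom_lengths`.
#' @export
simulate_medip_reads <- function(config) {
  stopifnot(inherits(config, "synthetic_medip_config"))
  .with_seed(config$seed, .simulate_medip_reads(config))
}

.simulate_medip_reads <- function(config) {
  n <- config$n_samples_per_group
  samples <- c(paste0("STD_", seq_len(n)), paste0("HFD_", seq_len(n)))
  groups <- stats::setNames(rep(c("STD", "HFD"), each = n), samples)
  draw <- function(n_reads, extra_log2 = 0, enriched = TRUE) {
    pr <- config$planted_regions
    glen <- sum(config$chrom_lengths)
    w_region <- if (enriched && nrow(pr) > 0) {
      (pr$end - pr$start) * pr$enrichment * 2^(extra_log2 * pr$group_effect)
    } else if (nrow(pr) > 0) (pr$end - pr$start) else numeric(0)
    w_bg <- glen - sum(if (nrow(pr) > 0) pr$end - pr$start else 0)
    w <- c(w_bg, w_region)
    comp <- sample.int(length(w), n_reads, replace = TRUE, prob = w)
    pos <- integer(n_reads)
    chrom <- character(n_reads)
    bg <- comp == 1
    if (any(bg)) {
      # uniform over the complement of the planted regions (rejection)
      n_bg <- sum(bg)
      cum <- cumsum(as.numeric(config$chrom_lengths))
      u <- floor(stats::runif(n_bg, 0, glen))
      if (nrow(pr) > 0) {
        reg_lo <- c(0, cum)[match(pr$chrom, names(config$chrom_lengths))] +
          pr$start
        reg_hi <- reg_lo + (pr$end - pr$start)
        in_region <- function(v) {
          hit <- rep(FALSE, length(v))
          for (k in seq_along(reg_lo)) {
            hit <- hit | (v >= reg_lo[k] & v < reg_hi[k])
          }
          hit
        }
        bad <- in_region(u)
        while (any(bad)) {
          u[bad] <- floor(stats::runif(sum(bad), 0, glen))
          bad <- in_region(u)
        }
      }
      ci <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
      chrom[bg] <- names(config$chrom_lengths)[ci]
      pos[bg] <- as.integer(u - c(0, cum)[ci])
    }
    for (k in seq_len(nrow(pr))) {
      sel <- comp == k + 1
      if (!any(sel)) next
      chrom[sel] <- pr$chrom[k]
      pos[sel] <- as.integer(floor(stats::runif(sum(sel), pr$start[k],
                                                pr$end[k])))
    }
    data.frame(chrom = chrom, pos = pos,
               strand = sample(c("+", "-"), n_reads, replace = TRUE))
  }
  reads <- lapply(samples, function(s) {
    draw(config$n_reads, extra_log2 = as.numeric(groups[s] == "HFD"))
  })
  names(reads) <- samples
  input <- draw(config$n_input_reads, enriched = FALSE)
  truth <- config$planted_regions[config$planted_regions$enrichment > 1, ,
                                  drop = FALSE]
  list(samples = reads, input = input, groups = groups, truth = truth,
       chrom_lengths = config$chrom_lengths)
}

#' Synthetic bisulfite configuration
#'
#' @param amplicon_sequences Named character vector of amplicon references
#'   (plus strand; each must contain at least one CpG).
#' @param per_cpg_methylation Named list (one entry per group, e.g. `STD`,
#'   `HFD`) of methylation proportions; each entry is recycled over an
#'   amplicon's CpG sites, or a named list per amplicon.
#' @param conversion_rate Bisulfite conversion rate in \[0, 1\]
#'   (default 0.99).
#' @param coverage Reads (calls) per site (default 1000).
#' @param n_samples_per_group Samples per group (default 3).
#' @param seed RNG seed.
#' @return List of class `synthetic_bisulfite_config`.
#' @export
synthetic_bisulfite_config <- function(amplicon_sequences,
                                       per_cpg_methylation =
                                         list(STD = 0.8, HFD = 0.8),
                                       conversion_rate = 0.99,
                                       coverage = 1000,
                                       n_samples_per_group = 3, seed = 1) {
  .assert(length(amplicon_sequences) > 0, "amplicon list must be non-empty")
  .assert(!is.null(names(amplicon_sequences)), "amplicons must be named")
  .assert(all(grepl("CG", toupper(amplicon_sequences))),
          "every amplicon must contain >= 1 CpG")
  .assert(conversion_rate >= 0 && conversion_rate <= 1,
          "conversion_rate must be in [0, 1]")
  .assert(coverage >= 0, "coverage must be >= 0")
  .assert(all(unlist(per_cpg_methylation) >= 0) &&
          all(unlist(per_cpg_methylation) <= 1),
          "methylation proportions must be in [0, 1]")
  structure(list(amplicon_sequences = amplicon_sequences,
                 per_cpg_methylation = per_cpg_methylation,
                 conversion_rate = conversion_rate, coverage = coverage,
                 n_samples_per_group = n_samples_per_group, seed = seed),
            class = "synthetic_bisulfite_config")
}

#' Simulate per-CpG bisulfite call counts
#'
#' Per cytosine and sample, methylated calls are binomial with success
#' probability theta + (1 - theta) * (1 - conversion_rate): a methylated C
#' is always read as C, an unmethylated C escapes conversion with
#' probability 1 - conversion_rate. Non-CpG cytosines have theta = 0, so
#' their apparent methylation estimates the conversion failure rate.
#'
#' @param config A [synthetic_bisulfite_config()].
#' @return List with `sites` (a `cpg_site_counts` data.frame over all
#'   samples), `groups` (named vector), `truth` (amplicon x group planted
#'   CpG levels).
#' @export
simulate_bisulfite_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_bisulfite_config"))
  .with_seed(config$seed, .simulate_bisulfite_counts(config))
}

.simulate_bisulfite_counts <- function(config) {
  n <- config$n_samples_per_group
  grp_names <- names(config$per_cpg_methylation)
  .assert(length(grp_names) >= 1, "per_cpg_methylation must be named by group")
  samples <- unlist(lapply(grp_names, function(g) paste0(g, "_", seq_len(n))))
  groups <- stats::setNames(rep(grp_names, each = n), samples)
  rows <- list()
  truth <- list()
  for (amp in names(config$amplicon_sequences)) {
    ref <- strsplit(toupper(config$amplicon_sequences[[amp]]), "")[[1]]
    c_pos <- which(ref == "C")
    ctx <- ifelse(c_pos < length(ref) & ref[pmin(c_pos + 1, length(ref))] == "G",
                  "CpG", "non-CpG")
    n_cpg <- sum(ctx == "CpG")
    for (smp in samples) {
      g <- groups[[smp]]
      lv <- config$per_cpg_methylation[[g]]
      if (is.list(lv)) lv <- lv[[amp]]
      theta <- numeric(length(c_pos))
      theta[ctx == "CpG"] <- rep_len(lv, n_cpg)
      p_call <- theta + (1 - theta) * (1 - config$conversion_rate)
      meth <- stats::rbinom(length(c_pos), config$coverage, p_call)
      rows[[length(rows) + 1]] <- data.frame(
        amplicon = amp, pos = c_pos - 1L, context = ctx, sample = smp,
        methylated = meth, total = rep(config$coverage, length(c_pos)),
        mismatches = 0L)
    }
    for (g in grp_names) {
      lv <- config$per_cpg_methylation[[g]]
      if (is.list(lv)) lv <- lv[[amp]]
      truth[[length(truth) + 1]] <- data.frame(
        amplicon = amp, group = g, level = mean(rep_len(lv, n_cpg)))
    }
  }
  sites <- do.call(rbind, rows)
  rownames(sites) <- NULL
  class(sites) <- c("cpg_site_counts", "data.frame")
  list(sites = sites, groups = groups, truth = do.call(rbind, truth))
}

#' Write a gene catalog as GTF
#'
#' Gene features only; internal 0-based half-open coordinates are converted
#' back to GTF's 1-based inclusive convention.
#'
#' @param catalog A [gene_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(catalog, path) {
  g <- catalog$genes
  attrs <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id, g$biotype)
  lines <- paste(g$chrom, "cisliver", "gene", g$start + 1L, g$end, ".",
                 g$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write named sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(sequences)), filepath = path)
  invisible(path)
}
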