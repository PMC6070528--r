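# End-to-end orchestration: a single YAML config drives either a fully
# synthetic run (every input generated with known truth) or a run on user
# files (GTF + counts + group map, optionally enhancer/CGI BEDs). One global
# seed is fanned out to per-stage seeds so stages are independently
# reproducible.

.config_defaults <- function() {
  list(
    seed = 1,
    output_dir = "cisliver_out",
    simulate = TRUE,
    inputs = list(gtf = NULL, counts = NULL, groups = NULL,
                  enhancers = NULL, cgi = NULL),
    catalog = list(cpm_threshold = 1),
    de = list(fdr_threshold = 0.05, dispersion_method = "cml", tmm = TRUE),
    coexpression = list(alpha = 0.05, tails = "one",
                        promoter_upstream = 2000, promoter_downstream = 200,
                        transform = "log2cpm"),
    medip = list(enabled = TRUE, fragment_length = 150, bin_size = 32,
                 window = 200, gap = 0, island_fdr = 1e-10, window_p0 = 0.2,
                 flank = 10000, profile_half_width = 2000, profile_k = 5,
                 nb_fdr = 0.1),
    bisulfite = list(enabled = TRUE, alpha = 0.05),
    simulate_params = list(
      annotation = list(n_chromosomes = 3, chromosome_length = 3e6,
                        n_protein_coding = 60,
                        pair_specs = list(
                          list(relation = "overlap-body", distance = 0,
                               count = 4),
                          list(relation = "upstream-flank", distance = 2000,
                               count = 4),
                          list(relation = "antisense-overlap", distance = 0,
                               count = 4))),
      counts = list(n_samples_per_group = 3, depth = 2e6, dispersion = 0.1,
                    de_fraction = 0.03, n_correlated_pairs = 6, rho = 0.95),
      medip = list(background_rate = 0.05, n_reads = 50000,
                   n_input_reads = 200000, n_planted_regions = 20,
                   enrichment = 10, group_effect = 0),
      bisulfite = list(conversion_rate = 0.99, coverage = 1000,
                       level_std = 0.8, level_hfd = 0.8)))
}

# Recursive merge of user config onto defaults; unknown keys are rejected.
.merge_config <- function(defaults, user, prefix = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    .stopf("unknown config key(s): %s",
           paste0(prefix, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                         !is.null(names(defaults[[k]])) &&
                         !(k %in% c("pair_specs"))) {
      .merge_config(defaults[[k]], user[[k]], paste0(prefix, k, "."))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML config, fills in documented defaults (CPM threshold 1, FDR
#' 0.05, island window 200, annotation flank 10000, profile k 5, ...),
#' rejects unknown keys by name, resolves relative input paths against the
#' config file's directory, and checks that referenced files exist.
#'
#' @param path Path to a YAML config file.
#' @return Normalized config list of class `pipeline_config`.
#' @export
validate_config <- function(path) {
  .assert(file.exists(path), "config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- .merge_config(.config_defaults(), user)
  base <- dirname(normalizePath(path))
  missing <- character(0)
  for (k in names(cfg$inputs)) {
    p <- cfg$inputs[[k]]
    if (is.null(p)) next
    if (!grepl("^/", p)) p <- file.path(base, p)
    if (!file.exists(p)) missing <- c(missing, sprintf("%s (%s)", k, p))
    cfg$inputs[[k]] <- p
  }
  if (length(missing) > 0) {
    .stopf("missing input file(s): %s", paste(missing, collapse = "; "))
  }
  if (!cfg$simulate) {
    need <- c("gtf", "counts", "groups")
    absent <- need[vapply(cfg$inputs[need], is.null, logical(1))]
    .assert(length(absent) == 0,
            "simulate is false but inputs lack: %s",
            paste(absent, collapse = ", "))
  }
  if (!grepl("^/", cfg$output_dir)) cfg$output_dir <- file.path(base, cfg$output_dir)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the stages in order (simulate/load inputs, catalog composition,
#' differential expression, cis co-expression, 5meDIP methylation,
#' bisulfite validation), writing each stage's tables under
#' `config$output_dir` plus a run summary with per-stage counts. A stage
#' failure halts the run with the stage name and cause; outputs of earlier
#' stages are preserved. Deterministic under a fixed seed.
#'
#' @param config A `pipeline_config` from [validate_config()], or a path to
#'   a YAML config.
#' @return Invisible list with the in-memory results of every stage plus
#'   `summary` (data.frame of per-stage counts).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  summary <- list()
  note <- function(stage, metric, value) {
    summary[[length(summary) + 1]] <<- data.frame(stage = stage,
                                                  metric = metric,
                                                  value = value)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # --- inputs -------------------------------------------------------------
  sim <- NULL
  if (isTRUE(config$simulate)) {
    sim <- stage("simulate", .simulate_stage(config))
    catalog <- sim$annotation$catalog
    counts <- sim$counts$counts
    note("simulate", "planted_pairs", nrow(sim$annotation$truth))
    note("simulate", "planted_de", nrow(sim$counts$truth_de))
  } else {
    catalog <- stage("load", read_gtf(config$inputs$gtf))
    counts <- stage("load", read_counts(config$inputs$counts,
                                        config$inputs$groups))
  }

  # --- catalog composition ------------------------------------------------
  comp <- stage("catalog", classify_biotypes(catalog))
  write_composition(comp, file.path(config$output_dir, "composition.tsv"))
  note("catalog", "genes", comp$total)

  # --- differential expression -------------------------------------------
  de <- stage("de", run_de(counts,
                           cpm_threshold = config$catalog$cpm_threshold,
                           fdr_threshold = config$de$fdr_threshold,
                           dispersion_method = config$de$dispersion_method,
                           tmm = config$de$tmm))
  .write_tsv(de$table, file.path(config$output_dir, "de_results.tsv"))
  note("de", "tested", nrow(de$table))
  note("de", "deg", length(de$deg))

  # --- cis co-expression --------------------------------------------------
  pairs <- stage("cispairs", {
    keep <- expression_filter(cpm(counts), config$catalog$cpm_threshold)
    g <- catalog$genes
    lnc <- intersect(keep, g$gene_id[g$class == "lncRNA"])
    pc <- intersect(keep, g$gene_id[g$class == "protein_coding"])
    p <- find_cis_pairs(catalog, lnc, pc)
    if (nrow(p) > 0) {
      p <- classify_pair_geometry(p, catalog,
             promoter_upstream = config$coexpression$promoter_upstream,
             promoter_downstream = config$coexpression$promoter_downstream)
      sub <- count_matrix(counts$counts[keep, , drop = FALSE], counts$groups)
      p <- coexpression_analysis(p, sub,
             alpha = config$coexpression$alpha,
             tails = config$coexpression$tails,
             transform = config$coexpression$transform)
      p <- diet_responsive_pairs(p, de$deg)
    }
    p
  })
  write_pairs(pairs, file.path(config$output_dir, "cis_pairs.tsv"))
  note("cispairs", "pairs", nrow(pairs))
  note("cispairs", "co_expressed", sum(pairs$co_expressed %||% logical(0)))
  note("cispairs", "diet_responsive", sum(pairs$diet_responsive %||% logical(0)))

  # --- 5meDIP -------------------------------------------------------------
  medip <- NULL
  if (isTRUE(config$medip$enabled) && !is.null(sim)) {
    medip <- stage("medip", .medip_stage(config, sim$medip, catalog))
    write_bed(medip$regions[, c("chrom", "start", "end", "region_id")],
              file.path(config$output_dir, "methyl_regions.bed"))
    .write_tsv(medip$ttest, file.path(config$output_dir, "medip_ttest.tsv"))
    .write_tsv(medip$nb$table, file.path(config$output_dir, "medip_nb.tsv"))
    note("medip", "regions", nrow(medip$regions))
    note("medip", "fwer_significant",
         sum(medip$ttest$holm < 0.05))
    note("medip", "nb_significant", length(medip$nb$significant))
  }

  # --- bisulfite ----------------------------------------------------------
  bs <- NULL
  if (isTRUE(config$bisulfite$enabled) && !is.null(sim)) {
    bs <- stage("bisulfite", {
      sites <- sim$bisulfite$sites
      cmp <- compare_site_methylation(sites, sim$bisulfite$groups,
                                      alpha = config$bisulfite$alpha)
      qc <- noncpg_conversion_qc(sites)
      list(comparison = cmp, conversion_qc = qc)
    })
    .write_tsv(bs$comparison, file.path(config$output_dir, "bsseq_sites.tsv"))
    note("bisulfite", "sites", nrow(bs$comparison))
    note("bisulfite", "significant",
         sum(bs$comparison$significant, na.rm = TRUE))
  }

  summary <- do.call(rbind, summary)
  .write_tsv(summary, file.path(config$output_dir, "summary.tsv"))
  invisible(list(catalog = catalog, composition = comp, counts = counts,
                 de = de, pairs = pairs, medip = medip, bisulfite = bs,
                 simulation = sim, summary = summary))
}

.simulate_stage <- function(config) {
  sp <- config$simulate_params
  pair_specs <- do.call(rbind, lapply(sp$annotation$pair_specs, function(x) {
    data.frame(relation = x$relation, distance = x$distance, count = x$count)
  }))
  ann_cfg <- synthetic_annotation_config(
    n_chromosomes = sp$annotation$n_chromosomes,
    chromosome_length = sp$annotation$chromosome_length,
    n_protein_coding = sp$annotation$n_protein_coding,
    pair_specs = pair_specs,
    seed = stage_seed(config$seed, "annotation"))
  ann <- generate_gene_catalog(ann_cfg)
  truth <- ann$truth
  n_cp <- min(sp$counts$n_correlated_pairs, nrow(truth))
  correlated <- if (n_cp > 0) {
    data.frame(lnc_id = truth$lnc_id[seq_len(n_cp)],
               pc_id = truth$pc_id[seq_len(n_cp)],
               rho = rep(sp$counts$rho, n_cp))
  } else NULL
  cnt_cfg <- synthetic_counts_config(
    n_samples_per_group = sp$counts$n_samples_per_group,
    depth = sp$counts$depth, dispersion = sp$counts$dispersion,
    de_fraction = sp$counts$de_fraction, correlated_pairs = correlated,
    seed = stage_seed(config$seed, "counts"))
  cnt <- simulate_counts(ann$catalog, cnt_cfg)
  chrom_lengths <- ann$catalog$chrom_lengths
  n_pl <- sp$medip$n_planted_regions
  planted <- if (n_pl > 0) {
    chr <- rep(names(chrom_lengths), length.out = n_pl)
    span <- 2000
    pos <- vapply(seq_len(n_pl), function(i) {
      k <- sum(chr[seq_len(i)] == chr[i])
      as.integer(50000 + (k - 1) * 100000)
    }, integer(1))
    data.frame(chrom = chr, start = pos, end = pos + span,
               enrichment = sp$medip$enrichment,
               group_effect = sp$medip$group_effect)
  } else NULL
  medip_cfg <- synthetic_medip_config(
    chrom_lengths = chrom_lengths,
    background_rate = sp$medip$background_rate,
    planted_regions = planted,
    n_reads = sp$medip$n_reads, n_input_reads = sp$medip$n_input_reads,
    n_samples_per_group = sp$counts$n_samples_per_group,
    seed = stage_seed(config$seed, "medip"))
  medip <- simulate_medip_reads(medip_cfg)
  amp <- c(amp1 = "ATTCGATCGGATTACGGATCGTTACGTACGAATCCGATGCATCACGTAGG",
           amp2 = "GGCGTTATCCGGTAATCGCATTACGGATGGTACGCATCCGTTAACGGTAC")
  bs_cfg <- synthetic_bisulfite_config(
    amplicon_sequences = amp,
    per_cpg_methylation = list(STD = sp$bisulfite$level_std,
                               HFD = sp$bisulfite$level_hfd),
    conversion_rate = sp$bisulfite$conversion_rate,
    coverage = sp$bisulfite$coverage,
    n_samples_per_group = sp$counts$n_samples_per_group,
    seed = stage_seed(config$seed, "bisulfite"))
  bs <- simulate_bisulfite_counts(bs_cfg)
  list(annotation = ann, counts = cnt, medip = medip, bisulfite = bs)
}

.medip_stage <- function(config, medip_sim, catalog = NULL) {
  mc <- config$medip
  icfg <- island_config(fragment_length = mc$fragment_length,
                        bin_size = mc$bin_size, window = mc$window,
                        gap = mc$gap, island_fdr = mc$island_fdr,
                        window_p0 = mc$window_p0)
  lens <- medip_sim$chrom_lengths
  frags <- lapply(medip_sim$samples, extend_reads,
                  fragment_length = mc$fragment_length, chrom_lengths = lens)
  input_frags <- extend_reads(medip_sim$input, mc$fragment_length, lens)
  peaks <- lapply(names(frags), function(s) {
    call_islands(frags[[s]], input_frags, icfg, lens, sample_id = s)
  })
  regions <- merge_regions(peaks)
  counts <- region_fragment_counts(regions, frags)
  groups <- medip_sim$groups[colnames(counts)]
  regions <- annotate_regions(regions, catalog %||% NULL_catalog(lens),
                              flank = mc$flank)
  tt <- differential_methylation_ttest(counts, groups)
  nb <- differential_methylation_nb(counts, groups, fdr_threshold = mc$nb_fdr)
  prof <- region_profile_kmeans(regions, do.call(rbind, frags),
                                half_width = mc$profile_half_width,
                                bin_size = mc$bin_size, k = mc$profile_k,
                                seed = stage_seed(config$seed, "profile"))
  list(fragments = frags, peaks = peaks, regions = regions, counts = counts,
       ttest = tt, nb = nb, profile = prof)
}

# Minimal empty catalog over a genome (for annotation when the MeDIP
# simulation has no gene track of its own).
NULL_catalog <- function(chrom_lengths) {
  structure(list(genes = data.frame(gene_id = character(),
                                    chrom = character(), start = integer(),
                                    end = integer(), strand = character(),
                                    biotype = character(), class = character(),
                                    subclass = character()),
                 chrom_lengths = chrom_lengths),
            class = "gene_catalog")
}
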