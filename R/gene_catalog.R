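#' Gene catalog
#'
#' Ordered collection of gene-level models (one row per gene) with GENCODE
#' biotypes classified into the composition hierarchy used throughout the
#' package: `protein_coding`, `pseudogene`, `short_ncRNA` (snoRNA, snRNA,
#' miRNA, rRNA, miscRNA), `lncRNA` (lincRNA, antisense, sense_intronic,
#' sense_overlapping), `processed_transcript`, and `other` for biotypes not
#' in the mapping table. Coordinates are 0-based half-open.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`), `biotype`.
#' @param chrom_lengths Optional named vector of chromosome lengths; inferred
#'   as the maximum gene end per chromosome when absent.
#' @param biotype_map Biotype-to-class mapping, as returned by
#'   [biotype_class_map()]. The GENCODE mapping shipped with the package is
#'   the default; supply your own table to re-bucket biotypes.
#' @return Object of class `gene_catalog`: list with `genes` (data.frame
#'   gaining `class` and `subclass` columns) and `chrom_lengths`.
#' @export
gene_catalog <- function(genes, chrom_lengths = NULL,
                         biotype_map = biotype_class_map()) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  .assert(all(need %in% names(genes)),
          "genes lacks columns: %s", paste(setdiff(need, names(genes)), collapse = ", "))
  .assert(!anyDuplicated(genes$gene_id), "gene_ids must be unique")
  .assert(all(genes$start < genes$end), "every gene must have start < end")
  .assert(all(genes$strand %in% c("+", "-")), "strand must be '+' or '-'")
  idx <- match(genes$biotype, biotype_map$biotype)
  unknown <- unique(genes$biotype[is.na(idx)])
  if (length(unknown) > 0) {
    message("biotypes not in mapping table counted under 'other': ",
            paste(unknown, collapse = ", "))
  }
  genes$class <- ifelse(is.na(idx), "other", biotype_map$class[idx])
  genes$subclass <- ifelse(is.na(idx), "other", biotype_map$subclass[idx])
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end, genes$chrom, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  }
  rownames(genes) <- NULL
  structure(list(genes = genes, chrom_lengths = chrom_lengths),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  print(table(x$genes$class))
  invisible(x)
}

#' Biotype-to-class mapping table
#'
#' Maps GENCODE gene biotypes into the composition classes and subclasses.
#' The shipped table covers the GENCODE vocabulary; it is deliberately a data
#' file so the bucketing (e.g. where TEC or scaRNA fall) can be overridden.
#'
#' @param path Optional path to a replacement TSV with columns `biotype`,
#'   `class`, `subclass`.
#' @return data.frame with columns `biotype`, `class`, `subclass`.
#' @export
biotype_class_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "biotype_classes.tsv", package = "cisliver",
                        mustWork = TRUE)
  }
  .read_tsv(path)
}

#' Read gene models from a GTF file
#'
#' Imports `gene` features (transcript and exon features are ignored:
#' analysis is gene-level only) and converts the 1-based inclusive GTF
#' coordinates to the internal 0-based half-open convention. Both
#' `gene_biotype` and `gene_type` attribute names are accepted. Gzipped
#' files are handled transparently.
#'
#' @param path Path to a GTF file.
#' @param biotype_map See [gene_catalog()].
#' @return A [gene_catalog()].
#' @export
read_gtf <- function(path, biotype_map = biotype_class_map()) {
  .assert(file.exists(path), "GTF file not found: %s", path)
  .check_gtf_gene_ids(path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if ("type" %in% names(meta)) {
    keep <- as.character(meta$type) == "gene"
    # files with no explicit gene features: fall back to all rows
    if (any(keep)) gr <- gr[keep]
  }
  meta <- S4Vectors::mcols(gr)
  biotype <- if ("gene_biotype" %in% names(meta)) meta$gene_biotype
             else if ("gene_type" %in% names(meta)) meta$gene_type
             else rep(NA_character_, length(gr))
  genes <- data.frame(
    gene_id = as.character(meta$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = as.character(biotype),
    stringsAsFactors = FALSE
  )
  gene_catalog(genes, biotype_map = biotype_map)
}

# Pre-scan of gene feature lines so a missing gene_id can be reported with
# its line number (rtracklayer silently yields NA).
.check_gtf_gene_ids <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], "#") || !nzchar(lines[i])) next
    f <- fields[[i]]
    if (length(f) < 9) next
    if (f[3] == "gene" && !grepl("gene_id", f[9], fixed = TRUE)) {
      .stopf("GTF line %d lacks a gene_id attribute", i)
    }
  }
  invisible(TRUE)
}

#' Transcriptome composition summary
#'
#' Tallies a catalog by class and subclass, mirroring the composition
#' breakdown of a bulk liver transcriptome into protein-coding genes,
#' pseudogenes, short ncRNA and lncRNA subclasses, and processed transcripts.
#'
#' @param catalog A [gene_catalog()].
#' @return A list with `total` (gene count), `class_counts` (named integer
#'   vector over all classes), and `subclass_counts` (data.frame `class`,
#'   `subclass`, `n`). Subclass counts sum to class counts, class counts to
#'   the total.
#' @export
classify_biotypes <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  classes <- c("protein_coding", "pseudogene", "short_ncRNA", "lncRNA",
               "processed_transcript", "other")
  g <- catalog$genes
  class_counts <- stats::setNames(integer(length(classes)), classes)
  tab <- table(g$class)
  class_counts[names(tab)] <- as.integer(tab)
  if (nrow(g) > 0) {
    agg <- stats::aggregate(list(n = g$gene_id), by = list(class = g$class,
                            subclass = g$subclass), FUN = length)
    agg <- agg[order(match(agg$class, classes), agg$subclass), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(class = character(), subclass = character(),
                      n = integer())
  }
  list(total = nrow(g), class_counts = class_counts, subclass_counts = agg)
}

#' Counts per million
#'
#' Normalizes each library by its total: a gene's count divided by the
#' library total, times 1e6. Every column of the result sums to 1e6.
#'
#' @param counts A [count_matrix()] or a numeric matrix.
#' @return CPM matrix with the same dimnames.
#' @export
cpm <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  totals <- colSums(m)
  bad <- which(totals <= 0)
  if (length(bad) > 0) {
    .stopf("library total is zero for sample(s): %s",
           paste(colnames(m)[bad] %||% bad, collapse = ", "))
  }
  sweep(m, 2, totals, "/") * 1e6
}

#' Mean-CPM expression filter
#'
#' Retains genes whose mean CPM across all samples strictly exceeds the
#' threshold (a gene at exactly the threshold is dropped). Idempotent.
#'
#' @param cpm_matrix CPM matrix from [cpm()].
#' @param cpm_threshold Threshold in CPM units (default 1).
#' @return Character vector of retained gene ids.
#' @export
expression_filter <- function(cpm_matrix, cpm_threshold = 1) {
  .assert(cpm_threshold >= 0, "cpm_threshold must be >= 0")
  rownames(cpm_matrix)[rowMeans(cpm_matrix) > cpm_threshold]
}

#' Write a composition summary as TSV
#'
#' @param summary Result of [classify_biotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(summary, path) {
  .write_tsv(summary$subclass_counts, path)
}
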