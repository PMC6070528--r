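# Internal helpers shared across modules.
#
# All genomic intervals inside the package are 0-based half-open [start, end);
# conversion to/from 1-based inclusive happens only at the GTF boundary and
# when talking to IRanges/GenomicRanges machinery.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom IRanges IRanges
.as_iranges <- function(start, end) {
  # 0-based half-open -> IRanges (1-based closed)
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors Rle
.as_granges <- function(chrom, start, end, strand = "*", seqlevels = NULL) {
  if (!is.null(seqlevels)) chrom <- factor(chrom, levels = seqlevels)
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = .as_iranges(start, end),
                         strand = strand)
}

# Common seqlevels for two interval sets, so comparisons do not warn about
# disjoint chromosome universes.
.seq_union <- function(...) unique(unlist(lapply(list(...), as.character)))

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(ok, fmt, ...) if (!ok) .stopf(fmt, ...)

# Gap (in bases) between two disjoint 0-based half-open intervals; 0 if they
# touch or overlap.
.interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2))
}

.interval_overlaps <- function(s1, e1, s2, e2) {
  pmax(s1, s2) < pmin(e1, e2)
}

# Group labels -> factor. An existing factor keeps its level order (the
# first level is the reference); plain labels get levels in order of first
# appearance.
.as_group_factor <- function(groups) {
  if (is.factor(groups)) factor(groups)
  else factor(groups, levels = unique(as.character(groups)))
}

#' Derive a per-stage seed from a global seed
#'
#' Maps a global integer seed and a stage label to a 32-bit seed, so each
#' pipeline stage is reproducible independently of the others.
#'
#' @param seed Global integer seed.
#' @param stage Stage label (character).
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483647)
}

# Seeded evaluation that restores the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Provenance header written at the top of tabular outputs.
.provenance <- function() {
  sprintf("# cisliver %s",
          as.character(utils::packageVersion("cisliver")))
}

.write_tsv <- function(df, path, provenance = TRUE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (provenance) writeLines(.provenance(), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}
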