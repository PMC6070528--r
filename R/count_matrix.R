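#' Gene-by-sample count matrix with group labels
#'
#' Container for an integer count matrix (genes in rows, samples in columns)
#' together with a group label per sample (e.g. `"STD"` vs `"HFD"`). This is
#' the input to differential expression, CPM normalization, deconvolution and
#' co-expression.
#'
#' @param counts Integer matrix, genes x samples, with row and column names.
#' @param groups Character or factor of length `ncol(counts)` assigning each
#'   sample to a group.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `groups` (factor named by sample).
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cm <- count_matrix(m, c("STD", "STD", "HFD", "HFD"))
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  .assert(is.numeric(counts), "counts must be numeric")
  .assert(all(counts >= 0), "counts must be non-negative")
  .assert(all(counts == round(counts)), "counts must be integers")
  .assert(!is.null(rownames(counts)), "counts must have gene ids as rownames")
  .assert(!is.null(colnames(counts)), "counts must have sample ids as colnames")
  .assert(length(groups) == ncol(counts),
          "groups must have one label per sample (%d != %d)",
          length(groups), ncol(counts))
  # a factor keeps its declared level order (reference first); otherwise
  # levels follow first appearance, so the second level (test group, e.g.
  # HFD) is compared against the first (reference, e.g. STD)
  groups <- .as_group_factor(groups)
  names(groups) <- colnames(counts)
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s (n=%d)", levels(x$groups),
                            tabulate(x$groups)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and group map from TSV files
#'
#' The counts file is a TSV with a header row of sample ids and gene ids in
#' the first column. The group map is a 2-column TSV (`sample`, `group`).
#'
#' @param counts_path Path to the counts TSV.
#' @param groups_path Path to the sample-to-group map TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, groups_path) {
  tab <- .read_tsv(counts_path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  gm <- .read_tsv(groups_path)
  .assert(all(c("sample", "group") %in% names(gm)),
          "group map must have columns 'sample' and 'group'")
  .assert(all(colnames(m) %in% gm$sample),
          "samples missing from group map: %s",
          paste(setdiff(colnames(m), gm$sample), collapse = ", "))
  count_matrix(m, gm$group[match(colnames(m), gm$sample)])
}

#' Write a count matrix to TSV
#'
#' @param cm A [count_matrix()].
#' @param counts_path,groups_path Output paths; the group map is written only
#'   when `groups_path` is given.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(cm, counts_path, groups_path = NULL) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  .write_tsv(df, counts_path)
  if (!is.null(groups_path)) {
    .write_tsv(data.frame(sample = names(cm$groups),
                          group = as.character(cm$groups)), groups_path)
  }
  invisible(counts_path)
}
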