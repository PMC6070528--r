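# Gene-set over-representation for DEG lists, and PWM scanning of promoter
# windows with an exact score-distribution threshold computed by dynamic
# programming over the discretized log-odds distribution.

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set id, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    .assert(length(f) >= 3, "GMT line with fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}

#' Gene-set over-representation test
#'
#' One-sided (enrichment) hypergeometric upper-tail test per set: the
#' probability of drawing at least the observed overlap when sampling
#' `length(study)` genes from the background; BH adjustment across sets.
#'
#' @param study Character vector of study genes (e.g. the DEG set); must be
#'   a subset of `background`.
#' @param sets Named list of gene sets (intersected with the background).
#' @param background Character vector: the annotation universe.
#' @return data.frame with `set`, `set_size`, `overlap`, `pvalue`, `fdr`,
#'   `genes` (comma-separated overlap).
#' @export
overrepresentation_test <- function(study, sets, background) {
  study <- unique(study)
  background <- unique(background)
  outside <- setdiff(study, background)
  if (length(outside) > 0) {
    .stopf("study genes outside the background: %s",
           paste(outside, collapse = ", "))
  }
  N <- length(background)
  n <- length(study)
  res <- lapply(names(sets), function(id) {
    set <- intersect(sets[[id]], background)
    k <- length(intersect(study, set))
    p <- stats::phyper(k - 1, length(set), N - length(set), n,
                       lower.tail = FALSE)
    data.frame(set = id, set_size = length(set), overlap = k, pvalue = p,
               genes = paste(sort(intersect(study, set)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- adjust_pvalues(out$pvalue, "bh")
  out[, c("set", "set_size", "overlap", "pvalue", "fdr", "genes")]
}

#' Read a JASPAR-format position matrix
#'
#' Accepts the JASPAR text format: a `>` header followed by four rows
#' `A [ ... ]`, `C [ ... ]`, `G [ ... ]`, `T [ ... ]` of counts or
#' frequencies. Columns are normalized to probabilities.
#'
#' @param path Path to the matrix file (first matrix read).
#' @return 4 x width probability matrix with rownames A, C, G, T.
#' @export
read_jaspar_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
  .assert(length(lines) >= 4, "JASPAR file needs 4 base rows")
  rows <- lapply(lines[1:4], function(l) {
    x <- sub("^\\s*[ACGTacgt]", "", l)
    as.numeric(regmatches(x, gregexpr("[0-9.eE+-]+", x))[[1]])
  })
  bases <- toupper(substr(trimws(lines[1:4]), 1, 1))
  .assert(setequal(bases, c("A", "C", "G", "T")), "expected rows A, C, G, T")
  m <- do.call(rbind, rows)
  rownames(m) <- bases
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  sweep(m, 2, colSums(m), "/")
}

#' Motif-scan configuration
#'
#' @param pwm 4 x width probability matrix (rows A, C, G, T; columns sum
#'   to 1).
#' @param background Background base frequencies (named, order A, C, G, T);
#'   default uniform.
#' @param p_cutoff Score threshold tail probability (default 0.001).
#' @param window TSS-relative scan window, c(upstream, downstream) (default
#'   -5000 .. +1000).
#' @param pseudocount Added to PWM entries before log-odds (default 1e-4).
#' @param resolution Log-odds discretization step for the exact score
#'   distribution (default 1e-3).
#' @return List of class `motif_scan_config`.
#' @export
motif_scan_config <- function(pwm, background = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                              p_cutoff = 0.001, window = c(-5000, 1000),
                              pseudocount = 1e-4, resolution = 1e-3) {
  .assert(nrow(pwm) == 4, "pwm must have 4 rows (A, C, G, T)")
  .assert(max(abs(colSums(pwm) - 1)) < 1e-6, "pwm columns must sum to 1")
  .assert(window[1] < window[2], "window must be ordered")
  .assert(all(background > 0) && abs(sum(background) - 1) < 1e-6,
          "background must be positive frequencies summing to 1")
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  structure(list(pwm = pwm, background = background[c("A", "C", "G", "T")],
                 p_cutoff = p_cutoff, window = window,
                 pseudocount = pseudocount, resolution = resolution),
            class = "motif_scan_config")
}

# Integer (discretized) log2-odds score matrix.
.pwm_int_scores <- function(config) {
  lo <- log2((config$pwm + config$pseudocount) /
             matrix(config$background, nrow = 4, ncol = ncol(config$pwm)))
  round(lo / config$resolution)
}

#' Exact PWM score distribution under the background model
#'
#' Dynamic programming over the discretized log-odds scores: the returned
#' vector gives the probability of each achievable integer score for a
#' random background word. Probabilities sum to 1.
#'
#' @param config A [motif_scan_config()].
#' @return List with `scores` (integer score values) and `prob`.
#' @export
pwm_score_distribution <- function(config) {
  s <- .pwm_int_scores(config)
  bg <- config$background
  lo <- sum(apply(s, 2, min)); hi <- sum(apply(s, 2, max))
  prob <- numeric(hi - lo + 1)
  # distribution of the partial sum, origin shifted by its running minimum
  cur <- 1
  cur_lo <- 0
  for (j in seq_len(ncol(s))) {
    new_lo <- cur_lo + min(s[, j])
    new_hi <- cur_lo + length(cur) - 1 + max(s[, j])
    nxt <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      shift <- cur_lo + s[b, j] - new_lo
      idx <- seq_along(cur) + shift
      nxt[idx] <- nxt[idx] + cur * bg[b]
    }
    cur <- nxt
    cur_lo <- new_lo
  }
  list(scores = seq(cur_lo, length.out = length(cur)), prob = cur)
}

#' Score threshold for a tail probability
#'
#' The smallest discretized log-odds score whose upper-tail probability
#' under the background model is at most `p_cutoff`.
#'
#' @param config A [motif_scan_config()].
#' @return List with `int_score` (threshold on the discretized scale),
#'   `score` (log2-odds units), and `tail_p` (achieved tail probability).
#' @export
pwm_threshold <- function(config) {
  d <- pwm_score_distribution(config)
  tail_p <- rev(cumsum(rev(d$prob)))
  # threshold must be an achievable score, not just any integer in range
  ok <- which(tail_p <= config$p_cutoff + 1e-12 & d$prob > 0)
  if (length(ok) == 0) {
    # even a perfect match is more probable than the cutoff (short motif):
    # no position can ever be called, so the threshold is unattainable
    warning("no achievable score has tail probability <= p_cutoff; ",
            "scans will report no hits")
    return(list(int_score = Inf, score = Inf, tail_p = 0))
  }
  i <- ok[1]
  list(int_score = d$scores[i], score = d$scores[i] * config$resolution,
       tail_p = tail_p[i])
}

#' Scan a promoter sequence for PWM hits
#'
#' Scans both strands of a TSS-anchored sequence and reports every window
#' whose discretized log-odds score reaches the exact-threshold score for
#' `p_cutoff`. Hit positions are the 5'-end of the match relative to the
#' TSS (negative = upstream); for minus-strand hits the 5' end is the
#' rightmost base of the matched window.
#'
#' @param sequence Character promoter sequence (plus strand).
#' @param config A [motif_scan_config()].
#' @param seq_start TSS-relative position of the first base of `sequence`
#'   (default `config$window[1]`).
#' @return data.frame with `position` (5'-end, TSS-relative), `strand`,
#'   `score` (log2-odds). Empty when the sequence is shorter than the motif.
#' @export
pwm_scan <- function(sequence, config, seq_start = config$window[1]) {
  sequence <- toupper(as.character(sequence))
  w <- ncol(config$pwm)
  empty <- data.frame(position = integer(), strand = character(),
                      score = numeric())
  if (nchar(sequence) < w) return(empty)
  thr <- pwm_threshold(config)
  s_fwd <- .pwm_int_scores(config)
  # reverse-complement motif scanned on the forward sequence
  s_rev <- s_fwd[c("T", "G", "C", "A"), rev(seq_len(w)), drop = FALSE]
  rownames(s_rev) <- c("A", "C", "G", "T")
  base_idx <- match(strsplit(sequence, "")[[1]], c("A", "C", "G", "T"))
  n <- length(base_idx)
  starts <- seq_len(n - w + 1)
  score_at <- function(sm) {
    sc <- rep(0L, length(starts))
    valid <- rep(TRUE, length(starts))
    for (j in seq_len(w)) {
      b <- base_idx[starts + j - 1]
      valid <- valid & !is.na(b)
      sc <- sc + ifelse(is.na(b), 0L, sm[cbind(b, j)])
    }
    ifelse(valid, sc, NA_integer_)
  }
  sc_f <- score_at(s_fwd)
  sc_r <- score_at(s_rev)
  hits <- list()
  hf <- which(!is.na(sc_f) & sc_f >= thr$int_score)
  if (length(hf) > 0) {
    hits[[1]] <- data.frame(position = seq_start + hf - 1L, strand = "+",
                            score = sc_f[hf] * config$resolution)
  }
  hr <- which(!is.na(sc_r) & sc_r >= thr$int_score)
  if (length(hr) > 0) {
    hits[[2]] <- data.frame(position = seq_start + hr - 1L + w - 1L,
                            strand = "-",
                            score = sc_r[hr] * config$resolution)
  }
  if (length(hits) == 0) return(empty)
  out <- do.call(rbind, hits)
  out <- out[out$position >= config$window[1] &
             out$position <= config$window[2], , drop = FALSE]
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
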