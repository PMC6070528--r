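# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (no IRanges, no dnbinom products) so
# each check is a genuine dual route.

# Build a random toy catalog directly from a data.frame (no generator).
random_catalog <- function(n_pc, n_lnc, n_chrom = 2, chrom_len = 100000) {
  mk <- function(n, prefix, biotype) {
    if (n == 0) {
      return(data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), biotype = character()))
    }
    start <- sample.int(chrom_len - 5000, n)
    len <- sample(200:4000, n, replace = TRUE)
    data.frame(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
               chrom = sprintf("chr%d", sample.int(n_chrom, n, replace = TRUE)),
               start = start, end = pmin(start + len, chrom_len),
               strand = sample(c("+", "-"), n, replace = TRUE),
               biotype = biotype)
  }
  suppressMessages(gene_catalog(
    rbind(mk(n_pc, "PC", "protein_coding"), mk(n_lnc, "LNC", "lincRNA")),
    chrom_lengths = stats::setNames(rep(chrom_len, n_chrom),
                                    sprintf("chr%d", seq_len(n_chrom)))))
}

# Exhaustive overlap/nearest pairing oracle (strict interval overlap; gap
# distance; ties emit both).
oracle_cis_pairs <- function(catalog, lnc_ids, pc_ids) {
  g <- catalog$genes
  out <- list()
  for (lid in lnc_ids) {
    l <- g[g$gene_id == lid, ]
    ov <- character(0)
    gaps <- c()
    cand_ids <- c()
    for (pid in pc_ids) {
      p <- g[g$gene_id == pid, ]
      if (p$chrom != l$chrom) next
      if (max(l$start, p$start) < min(l$end, p$end)) {
        ov <- c(ov, pid)
      } else {
        cand_ids <- c(cand_ids, pid)
        gaps <- c(gaps, max(l$start, p$start) - min(l$end, p$end))
      }
    }
    if (length(ov) > 0) {
      out[[length(out) + 1]] <- data.frame(lnc_id = lid, pc_id = ov,
                                           distance = 0L)
    } else if (length(cand_ids) > 0) {
      best <- which(gaps == min(gaps))
      out[[length(out) + 1]] <- data.frame(lnc_id = lid,
                                           pc_id = cand_ids[best],
                                           distance = gaps[best])
    }
  }
  if (length(out) == 0) {
    return(data.frame(lnc_id = character(), pc_id = character(),
                      distance = integer()))
  }
  do.call(rbind, out)
}

pair_key <- function(df) sort(paste(df$lnc_id, df$pc_id, df$distance))

# Connected components of strictly-overlapping intervals by plane sweep.
oracle_merge <- function(df) {
  out <- list()
  for (chr in unique(df$chrom)) {
    sub <- df[df$chrom == chr, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    cur_s <- sub$start[1]; cur_e <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] < cur_e) {
        cur_e <- max(cur_e, sub$end[i])
      } else {
        out[[length(out) + 1]] <- data.frame(chrom = chr, start = cur_s,
                                             end = cur_e)
        cur_s <- sub$start[i]; cur_e <- sub$end[i]
      }
    }
    out[[length(out) + 1]] <- data.frame(chrom = chr, start = cur_s,
                                         end = cur_e)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Closed-form conditional distribution of the group-1 sum given the total
# under NB with common dispersion (gamma-function form of the negative
# hypergeometric), two-sided minimum-likelihood p-value.
oracle_exact_nb_p <- function(y1, y2, n1, n2, phi) {
  t <- y1 + y2
  if (t == 0) return(1)
  k <- 0:t
  if (phi <= 0) {
    pr <- exp(lchoose(t, k) + k * log(n1 / (n1 + n2)) +
              (t - k) * log(n2 / (n1 + n2)))
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi
    logpr <- lgamma(k + r1) - lgamma(r1) - lfactorial(k) +
      lgamma(t - k + r2) - lgamma(r2) - lfactorial(t - k) -
      (lgamma(t + r1 + r2) - lgamma(r1 + r2) - lfactorial(t))
    pr <- exp(logpr)
    pr <- pr / sum(pr)
  }
  sum(pr[pr <= pr[y1 + 1] * (1 + 1e-9)])
}

# Exhaustive-word PWM threshold for short motifs: enumerate all 4^L words,
# score them on the discretized scale, and find the smallest score whose
# upper-tail probability is <= the cutoff.
oracle_pwm_threshold <- function(config) {
  pwm <- config$pwm
  L <- ncol(pwm)
  s <- round(log2((pwm + config$pseudocount) /
                  matrix(config$background, 4, L)) / config$resolution)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  score <- numeric(nrow(words))
  prob <- rep(1, nrow(words))
  for (j in 1:L) {
    score <- score + s[cbind(words[, j], j)]
    prob <- prob * config$background[words[, j]]
  }
  vals <- sort(unique(score))
  tails <- vapply(vals, function(v) sum(prob[score >= v]), numeric(1))
  vals[which(tails <= config$p_cutoff + 1e-12)[1]]
}

# Hypergeometric upper tail by explicit summation.
oracle_hyper_tail <- function(k, set_size, bg_size, study_size) {
  kk <- k:min(set_size, study_size)
  sum(exp(lchoose(set_size, kk) + lchoose(bg_size - set_size, study_size - kk) -
          lchoose(bg_size, study_size)))
}
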