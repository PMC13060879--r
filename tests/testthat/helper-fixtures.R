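# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (position marking, enumeration, step-up recursion) so they stay
# independent of the implementation paths they check.

toy_genome <- function(seq, name = "T1") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

# Minimal activity table (the element_activity output shape).
activity_table <- function(log_alpha, ids = NULL, n_barcodes = 10L) {
  data.frame(
    element_id = if (is.null(ids)) sprintf("e%05d", seq_along(log_alpha))
                 else ids,
    n_barcodes = n_barcodes,
    alpha = exp(log_alpha),
    log_alpha = log_alpha,
    stringsAsFactors = FALSE
  )
}

# Brute-force per-base pileup coverage of a set of [start, end] intervals
# over positions 1..L.
pileup_coverage <- function(starts, ends, L) {
  cov <- integer(L)
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    cov[idx] <- cov[idx] + 1L
  }
  cov
}

# Brute-force interval union with an adjacency gap: mark covered bases,
# then join runs separated by an uncovered gap of at most `gap` bases.
union_oracle <- function(starts, ends, gap = 0L) {
  L <- max(ends) + 1L
  covered <- logical(L)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  runs <- rle(covered)
  pos <- cumsum(c(1L, runs$lengths))
  spans <- data.frame(start = pos[-length(pos)][runs$values],
                      end = (pos[-1] - 1L)[runs$values])
  if (nrow(spans) <= 1) return(spans)
  out <- spans[1, ]
  for (i in 2:nrow(spans)) {
    if (spans$start[i] - out$end[nrow(out)] - 1L <= gap) {
      out$end[nrow(out)] <- spans$end[i]
    } else {
      out <- rbind(out, spans[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

# Brute-force Benjamini-Hochberg step-up adjusted p-values.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# Brute-force Spearman rho via the rank-based Pearson formula with
# average ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Write a minimal SAM file of association reads (barcode in qname).
write_test_sam <- function(path, qname, flag, rname, pos, cigar,
                           refs = c(oligoA = 219L, oligoB = 219L)) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                  qname, flag, rname, pos, cigar)
  writeLines(c(header, body), path)
  path
}

# Random 15-mer barcodes for fixtures.
fixture_barcodes <- function(n, seed = 99L) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE), collapse = "")
  }, character(1))
}
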