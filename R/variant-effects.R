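# Variant-effect estimation and classification: per-variant logFC of
# alternate vs reference oligo activity, gain/loss calls, cross-cell-type
# sharing, genomic-window summaries, a simplified PWM motif-disruption
# score, and agreement with externally computed per-variant scores.

#' Estimate variant effects from paired ref/alt activities
#'
#' For each variant, the per-replicate effect is
#' \eqn{d_r = \log\alpha_{alt,r} - \log\alpha_{ref,r}} and
#' \code{logFC = mean(d_r)} (natural log by default; \code{log_base = 2}
#' rescales). The p-value is a two-sided one-sample t-test on the
#' \eqn{d_r} (\code{test = "t"}) or a seeded barcode-permutation test
#' (\code{test = "permutation"}, requires barcode-level data via
#' \code{\link{permutation_logfc_test}}). SNVs and InDels form separate
#' Benjamini-Hochberg families, so changing oligo length cannot distort the
#' SNV family. Calls follow the effect-size-gated rule: \code{gain} iff
#' \code{adj_p <= alpha} and \code{logFC > lfc}; \code{loss} iff
#' \code{adj_p <= alpha} and \code{logFC < -lfc}; otherwise \code{ns}.
#'
#' @param ref_activity,alt_activity Activity tables
#'   (\code{\link{element_activity}} output with per-replicate
#'   \code{alpha_*} columns) for reference and alternate oligos; matched on
#'   \code{variant_key}.
#' @param variant_class Optional named vector (by \code{variant_key}) giving
#'   \code{"snv"} or \code{"indel"}; defaults to \code{"snv"} for all, i.e.
#'   a single BH family.
#' @param lfc Absolute logFC threshold for a call (default 0.1, strict
#'   inequality).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param log_base Base of the reported logFC: \code{exp(1)} (default)
#'   or \code{2}.
#' @return \code{data.frame}: \code{variant_key}, \code{class},
#'   \code{logFC}, \code{se}, \code{p}, \code{adj_p}, \code{call},
#'   \code{n_replicates}; variants missing a partner oligo appear with
#'   \code{call = "untestable"}.
#' @export
variant_logfc <- function(ref_activity, alt_activity, variant_class = NULL,
                          lfc = 0.1, alpha = 0.05, log_base = exp(1)) {
  stopifnot("variant_key" %in% names(ref_activity),
            "variant_key" %in% names(alt_activity))
  rep_cols <- function(x) grep("^alpha_[0-9]+$", names(x), value = TRUE)
  rc <- intersect(rep_cols(ref_activity), rep_cols(alt_activity))
  if (length(rc) < 2) stop("need >= 2 replicates with counts")
  keys <- union(ref_activity$variant_key, alt_activity$variant_key)
  ri <- match(keys, ref_activity$variant_key)
  ai <- match(keys, alt_activity$variant_key)
  rows <- lapply(seq_along(keys), function(i) {
    key <- keys[i]
    cls <- if (is.null(variant_class)) "snv"
           else unname(variant_class[key])
    if (is.na(ri[i]) || is.na(ai[i])) {
      return(data.frame(variant_key = key, class = cls, logFC = NA_real_,
                        se = NA_real_, p = NA_real_,
                        n_replicates = 0L, untestable = TRUE,
                        stringsAsFactors = FALSE))
    }
    d <- log(as.numeric(unlist(alt_activity[ai[i], rc]))) -
         log(as.numeric(unlist(ref_activity[ri[i], rc])))
    d <- d / log(log_base)
    est <- mean(d)
    se <- stats::sd(d) / sqrt(length(d))
    p <- if (se == 0) {
      if (est == 0) 1 else NA_real_  # degenerate: no within-variant spread
    } else {
      stats::t.test(d)$p.value
    }
    data.frame(variant_key = key, class = cls, logFC = est, se = se, p = p,
               n_replicates = length(d), untestable = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- NA_real_
  for (cls in unique(out$class)) {  # separate BH family per variant class
    sel <- out$class %in% cls & !is.na(out$p)
    out$adj_p[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out$call <- ifelse(out$untestable | is.na(out$adj_p), "untestable",
              ifelse(out$adj_p <= alpha & out$logFC > lfc, "gain",
              ifelse(out$adj_p <= alpha & out$logFC < -lfc, "loss", "ns")))
  out$untestable <- NULL
  rownames(out) <- NULL
  out
}

#' Barcode-permutation test for one variant's logFC
#'
#' Permutes barcode-to-allele labels between the reference and alternate
#' oligo's barcodes, recomputing the logFC (ratio-of-sums per replicate,
#' averaged) each time. Two-sided p with the add-one correction.
#'
#' @param ref_counts,alt_counts Normalized count rows (barcode-level) for
#'   the reference and alternate oligo (columns \code{DNA_*}, \code{RNA_*}).
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @param pseudocount Pseudocount as in \code{\link{element_activity}}.
#' @return List: \code{logFC} (observed), \code{p}.
#' @export
permutation_logfc_test <- function(ref_counts, alt_counts, n_perm = 10000L,
                                   seed = 1L, pseudocount = 1) {
  cc <- count_columns(ref_counts)
  pooled <- rbind(ref_counts[c("barcode", cc$cols)],
                  alt_counts[c("barcode", cc$cols)])
  n_ref <- nrow(ref_counts)
  n_tot <- nrow(pooled)
  lfc_of <- function(ref_idx) {
    alt_idx <- setdiff(seq_len(n_tot), ref_idx)
    d <- vapply(cc$replicates, function(r) {
      a_ref <- (sum(pooled[[paste0("RNA_", r)]][ref_idx]) + pseudocount) /
               (sum(pooled[[paste0("DNA_", r)]][ref_idx]) + pseudocount)
      a_alt <- (sum(pooled[[paste0("RNA_", r)]][alt_idx]) + pseudocount) /
               (sum(pooled[[paste0("DNA_", r)]][alt_idx]) + pseudocount)
      log(a_alt) - log(a_ref)
    }, numeric(1))
    mean(d)
  }
  obs <- lfc_of(seq_len(n_ref))
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    lfc_of(sample.int(n_tot, n_ref))
  }, numeric(1)))
  list(logFC = obs, p = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1))
}

#' Classify cross-cell-type sharing of a variant effect
#'
#' \code{shared}: called (gain or loss) in both cell types with the same
#' logFC direction; \code{<label>_only}: called in exactly one;
#' \code{discordant}: called in both with opposite directions;
#' \code{none}: called in neither.
#'
#' @param call_a,call_b Calls (\code{"gain"}/\code{"loss"}/\code{"ns"}) in
#'   the two cell types (vectorized).
#' @param labels Length-2 cell-type labels (default
#'   \code{c("neuron", "hek")}).
#' @return Character vector of sharing labels.
#' @export
classify_sharing <- function(call_a, call_b, labels = c("neuron", "hek")) {
  called_a <- call_a %in% c("gain", "loss")
  called_b <- call_b %in% c("gain", "loss")
  ifelse(called_a & called_b & call_a == call_b, "shared",
  ifelse(called_a & called_b, "discordant",
  ifelse(called_a, paste0(labels[1], "_only"),
  ifelse(called_b, paste0(labels[2], "_only"), "none"))))
}

#' Summarize variant calls over a genomic window
#'
#' Counts gain/loss/called/tested variants whose focal position lies inside
#' the window (1-based inclusive membership), e.g. to quantify enrichment of
#' effects in a high-occupancy-target (HOT) region.
#'
#' @param effects \code{\link{variant_logfc}} output joined with columns
#'   \code{chrom} and \code{focal_pos}.
#' @param window Single-interval \code{GRanges}.
#' @return Named list: \code{gain}, \code{loss}, \code{total_called},
#'   \code{total_tested} (within the window), and
#'   \code{fraction_of_called} (window share of all called effects).
#' @export
window_summary <- function(effects, window) {
  stopifnot(all(c("chrom", "focal_pos") %in% names(effects)))
  inside <- effects$chrom == as.character(GenomicRanges::seqnames(window)) &
    effects$focal_pos >= GenomicRanges::start(window) &
    effects$focal_pos <= GenomicRanges::end(window)
  called <- effects$call %in% c("gain", "loss")
  list(
    gain = sum(inside & effects$call == "gain"),
    loss = sum(inside & effects$call == "loss"),
    total_called = sum(inside & called),
    total_tested = sum(inside & effects$call != "untestable"),
    fraction_of_called = if (sum(called) == 0) NA_real_
                         else sum(inside & called) / sum(called)
  )
}

#' Build a position weight matrix
#'
#' @param probs 4-row matrix of per-position base probabilities (rows
#'   A, C, G, T; each column sums to 1).
#' @param name Motif name.
#' @return A \code{pwm} object (probability matrix with attributes).
#' @export
pwm_matrix <- function(probs, name = "motif") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 4) stop("PWM must have length >= 4")
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("PWM columns must each sum to 1")
  }
  rownames(probs) <- c("A", "C", "G", "T")
  structure(probs, name = name, class = c("pwm", "matrix"))
}

# Best log-odds PWM hit over all offsets and both strands.
pwm_best_score <- function(pwm, seq, background = 0.25, eps = 1e-6) {
  lo <- log2(pmax(unclass(pwm), eps) / background)
  w <- ncol(lo)
  score_one <- function(s) {
    n <- nchar(s)
    if (n < w) return(-Inf)
    chars <- strsplit(s, "")[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    best <- -Inf
    for (off in 0:(n - w)) {
      ii <- idx[(off + 1):(off + w)]
      if (anyNA(ii)) next
      sc <- sum(lo[cbind(ii, seq_len(w))])
      if (sc > best) best <- sc
    }
    best
  }
  max(score_one(toupper(seq)), score_one(revcomp_chr(toupper(seq))))
}

#' Motif-disruption score for a ref/alt sequence pair
#'
#' Scores both sequences with the PWM's log-odds (uniform background),
#' taking the best hit over all offsets and both strands, and reports the
#' difference (alt minus ref). Negative values mean the alternate allele
#' disrupts the motif's best binding site; positive values mean it creates
#' or strengthens one. A simplified single-motif analogue of
#' motif-disruption screens.
#'
#' @param pwm A \code{\link{pwm_matrix}}.
#' @param ref_seq,alt_seq Reference and alternate sequences.
#' @param background Background base probability (uniform, default 0.25).
#' @return Named list: \code{ref_score}, \code{alt_score}, \code{delta}
#'   (alt - ref, log2 odds units).
#' @export
motif_delta <- function(pwm, ref_seq, alt_seq, background = 0.25) {
  r <- pwm_best_score(pwm, ref_seq, background)
  a <- pwm_best_score(pwm, alt_seq, background)
  list(ref_score = r, alt_score = a, delta = a - r)
}

#' Agreement between MPRA effects and external variant scores
#'
#' Joins external per-variant score tables (e.g. sequence-model predictions)
#' on \code{variant_key} and reports the Spearman rank correlation (average
#' ranks for ties, p by the t-approximation) plus the fraction of called
#' effects whose logFC sign matches the external score's sign. Unmatched
#' keys are reported, never silently dropped.
#'
#' @param effects \code{\link{variant_logfc}} output.
#' @param external_scores \code{data.frame} with \code{variant_key},
#'   \code{score} (and optionally \code{source}).
#' @return List: \code{rho}, \code{p}, \code{n}, \code{sign_concordance},
#'   \code{n_called}, \code{unmatched_keys}.
#' @export
score_agreement <- function(effects, external_scores) {
  m <- merge(effects, external_scores, by = "variant_key")
  unmatched <- setdiff(external_scores$variant_key, effects$variant_key)
  ok <- !is.na(m$logFC) & !is.na(m$score)
  if (sum(ok) < 3) stop("fewer than 3 matched variant scores")
  ct <- stats::cor.test(m$logFC[ok], m$score[ok], method = "spearman",
                        exact = FALSE)
  called <- ok & m$call %in% c("gain", "loss") & m$score != 0
  list(
    rho = unname(ct$estimate),
    p = ct$p.value,
    n = sum(ok),
    sign_concordance = if (sum(called) == 0) NA_real_
      else mean(sign(m$logFC[called]) == sign(m$score[called])),
    n_called = sum(called),
    unmatched_keys = unmatched
  )
}
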