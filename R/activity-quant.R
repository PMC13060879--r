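# RNA/DNA activity quantification: CPM normalization, ratio-of-sums element
# activity, and the robust median/MAD empirical-null test against scrambled
# controls (mad.score / pval.mad).

# Count tables are data.frames with columns barcode, element_id and one
# numeric column per (fraction, replicate) named DNA_1, RNA_1, DNA_2, ...

count_columns <- function(cm) {
  cols <- grep("^(DNA|RNA)_[0-9]+$", names(cm), value = TRUE)
  if (length(cols) == 0) stop("no DNA_*/RNA_* count columns found")
  frac <- sub("_.*$", "", cols)
  rep <- as.integer(sub("^.*_", "", cols))
  reps <- sort(unique(rep))
  missing <- c(
    setdiff(paste0("DNA_", reps), cols),
    setdiff(paste0("RNA_", reps), cols)
  )
  if (length(missing) > 0) {
    stop("unpaired count columns; missing: ", paste(missing, collapse = ", "))
  }
  list(cols = cols, fraction = frac, replicate = rep, replicates = reps)
}

#' Library-size normalize barcode counts
#'
#' Scales each (fraction, replicate) column to counts per million so RNA/DNA
#' ratios are comparable across sequencing depths. The input counts are not
#' modified; library sizes are attached as an attribute.
#'
#' @param cm Count \code{data.frame} (columns \code{barcode},
#'   \code{element_id}, \code{DNA_1}, \code{RNA_1}, ...).
#' @return The table with count columns replaced by CPM values; attribute
#'   \code{"library_sizes"} holds the original column sums.
#' @export
normalize_counts <- function(cm) {
  cc <- count_columns(cm)
  sizes <- vapply(cm[cc$cols], sum, numeric(1))
  zero <- names(sizes)[sizes == 0]
  if (length(zero) > 0) {
    stop("zero total counts in replicate column(s): ",
         paste(zero, collapse = ", "))
  }
  out <- cm
  for (col in cc$cols) out[[col]] <- cm[[col]] / sizes[[col]] * 1e6
  attr(out, "library_sizes") <- sizes
  out
}

#' Per-element activity from normalized counts
#'
#' For each element and replicate, activity is the ratio of sums over the
#' element's barcodes:
#' \deqn{\alpha_r = \frac{\sum_b RNA_{b,r} + c}{\sum_b DNA_{b,r} + c}}
#' with pseudocount \eqn{c}. The element activity is the geometric mean of
#' the per-replicate ratios, so \code{log_alpha} is the mean of per-replicate
#' log ratios. Ratio-of-sums (rather than mean-of-ratios) keeps low-DNA
#' barcodes from dominating.
#'
#' @param cm_norm Normalized count table (\code{\link{normalize_counts}}).
#' @param dictionary Optional barcode dictionary \code{data.frame}
#'   (\code{barcode}, \code{element_id}); if supplied, element assignment is
#'   taken from it (barcodes absent from the dictionary are dropped).
#' @param pseudocount Added to both sums (default 1).
#' @param min_barcodes Minimum barcodes per element (default 1).
#' @return \code{data.frame}: \code{element_id}, \code{n_barcodes},
#'   \code{alpha}, \code{log_alpha} (natural log), and per-replicate columns
#'   \code{alpha_1}, \code{alpha_2}, ...
#' @export
element_activity <- function(cm_norm, dictionary = NULL, pseudocount = 1,
                             min_barcodes = 1L) {
  cc <- count_columns(cm_norm)
  if (!is.null(dictionary)) {
    if (is.list(dictionary) && !is.data.frame(dictionary)) {
      dictionary <- dictionary$dictionary
    }
    idx <- match(cm_norm$barcode, dictionary$barcode)
    cm_norm$element_id <- dictionary$element_id[idx]
    cm_norm <- cm_norm[!is.na(cm_norm$element_id), , drop = FALSE]
  }
  if (is.null(cm_norm$element_id)) {
    stop("no element_id column and no dictionary supplied")
  }
  split_idx <- split(seq_len(nrow(cm_norm)), cm_norm$element_id)
  reps <- cc$replicates
  rows <- lapply(names(split_idx), function(el) {
    idx <- split_idx[[el]]
    if (length(idx) < min_barcodes) return(NULL)
    a_r <- vapply(reps, function(r) {
      rna <- sum(cm_norm[[paste0("RNA_", r)]][idx])
      dna <- sum(cm_norm[[paste0("DNA_", r)]][idx])
      (rna + pseudocount) / (dna + pseudocount)
    }, numeric(1))
    out <- data.frame(element_id = el, n_barcodes = length(idx),
                      alpha = exp(mean(log(a_r))),
                      log_alpha = mean(log(a_r)),
                      stringsAsFactors = FALSE)
    for (i in seq_along(reps)) out[[paste0("alpha_", reps[i])]] <- a_r[i]
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(element_id = character(), n_barcodes = integer(),
                      alpha = numeric(), log_alpha = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Robust empirical-null activity test (mad.score / pval.mad)
#'
#' Scores each tested element's log activity against the scrambled-control
#' null distribution:
#' \deqn{mad.score = \frac{\log\alpha - median(\log\alpha_{null})}
#'                        {1.4826 \cdot MAD(\log\alpha_{null})}}
#' \code{pval_mad} is the upper-tail standard-normal probability of the
#' score (one-sided activation test by default; the parametric tail allows
#' p-values far below 1/n_null), floored at \code{cap} (default
#' 2.2e-16). \code{adj_p} is Benjamini-Hochberg over the tested elements.
#' An element is called active when \code{pval_mad <= alpha}.
#'
#' @param elements Activity table for tested elements
#'   (\code{\link{element_activity}} output).
#' @param null_elements Activity table for scrambled/negative controls
#'   (>= 20 required).
#' @param two_sided If \code{TRUE}, test both tails (default one-sided
#'   activation).
#' @param cap Lower p-value floor (default 2.2e-16).
#' @param alpha Significance threshold for the \code{active} call
#'   (default 0.05).
#' @return \code{elements} with added columns \code{mad_score},
#'   \code{pval_mad}, \code{adj_p}, \code{active}; attributes
#'   \code{null_median} and \code{null_mad} record the null location/scale.
#' @export
mad_test <- function(elements, null_elements, two_sided = FALSE,
                     cap = 2.2e-16, alpha = 0.05) {
  if (nrow(null_elements) < 20) {
    stop("need >= 20 null (scrambled) elements; got ", nrow(null_elements))
  }
  null_la <- null_elements$log_alpha
  m <- stats::median(null_la)
  s <- stats::mad(null_la)  # 1.4826 * median absolute deviation
  if (s == 0) {
    stop("MAD of null log-activities is 0; supply more / more varied ",
         "scrambled controls")
  }
  z <- (elements$log_alpha - m) / s
  p <- if (two_sided) 2 * stats::pnorm(abs(z), lower.tail = FALSE)
       else stats::pnorm(z, lower.tail = FALSE)
  p <- pmax(pmin(p, 1), cap)
  out <- elements
  out$mad_score <- z
  out$pval_mad <- p
  out$adj_p <- stats::p.adjust(p, method = "BH")
  out$active <- out$pval_mad <= alpha
  attr(out, "null_median") <- m
  attr(out, "null_mad") <- s
  out
}

#' Combine forward and reverse strand results into one region
#'
#' Tiled designs test each window on both strands; for analysis the strands
#' are combined into a single region of interest: the combined log activity
#' is the mean of the strand log activities, barcodes are pooled for
#' \code{n_barcodes}, and significance is recomputed downstream on the
#' combined value (rerun \code{\link{mad_test}} on the output). Windows seen
#' on only one strand pass through with \code{single_strand = TRUE}.
#'
#' @param activity Activity table with columns \code{window} (region key),
#'   \code{strand}, \code{log_alpha}, \code{n_barcodes}.
#' @return Per-window table: \code{element_id} (the window key),
#'   \code{n_barcodes}, \code{alpha}, \code{log_alpha},
#'   \code{single_strand}.
#' @export
combine_strands <- function(activity) {
  stopifnot(all(c("window", "strand", "log_alpha", "n_barcodes")
                %in% names(activity)))
  split_idx <- split(seq_len(nrow(activity)), activity$window)
  rows <- lapply(names(split_idx), function(w) {
    idx <- split_idx[[w]]
    la <- mean(activity$log_alpha[idx])
    data.frame(element_id = w,
               n_barcodes = sum(activity$n_barcodes[idx]),
               alpha = exp(la), log_alpha = la,
               single_strand = length(idx) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read an activity table TSV
#'
#' @param activity Activity / test-result table.
#' @param path TSV path.
#' @export
write_activity <- function(activity, path) {
  utils::write.table(activity, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(element_id = "character"))
}
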