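# CRE calling: join overlapping/consecutive significant elements into
# candidate cis-regulatory elements, compare calls across cell types, and
# classify CREs against ENCODE cCRE annotations.

#' Join significant elements into CREs
#'
#' A single left-to-right sweep merges elements whose intervals overlap or
#' whose gap is at most \code{adjacency_gap} bp. With the default gap of 0,
#' consecutive 100 bp bins (which share a boundary) merge into one CRE;
#' 90 bp-step tiles already overlap, so overlap-merging suffices for them.
#'
#' @param significant_elements \code{GRanges} of elements already called
#'   significant (e.g. \code{pval_mad <= 0.05}); optional metadata columns
#'   \code{element_id}, \code{log_alpha}, \code{pval_mad} are summarized
#'   per CRE.
#' @param adjacency_gap Maximum gap (bp) still merged (default 0: abutting
#'   intervals merge, a 1 bp gap does not).
#' @return \code{GRanges} of CREs with metadata \code{cre_id},
#'   \code{n_members}, \code{members} (comma-separated element ids), and,
#'   when available, \code{peak_log_alpha} (max) and \code{min_pval_mad}.
#' @export
call_cres <- function(significant_elements, adjacency_gap = 0L) {
  x <- significant_elements
  if (length(x) == 0) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$cre_id <- character()
    return(out)
  }
  ord <- GenomicRanges::order(x)
  x <- x[ord]
  chrom <- as.character(GenomicRanges::seqnames(x))
  s <- GenomicRanges::start(x)
  e <- GenomicRanges::end(x)
  grp <- integer(length(x))
  grp[1] <- 1L
  cur_end <- e[1]
  cur_chrom <- chrom[1]
  for (i in seq_along(x)[-1]) {
    if (chrom[i] == cur_chrom && s[i] <= cur_end + adjacency_gap + 1L) {
      grp[i] <- grp[i - 1L]
      cur_end <- max(cur_end, e[i])
    } else {
      grp[i] <- grp[i - 1L] + 1L
      cur_end <- e[i]
      cur_chrom <- chrom[i]
    }
  }
  mc <- S4Vectors::mcols(x)
  idx <- split(seq_along(x), grp)
  rows <- lapply(idx, function(ii) {
    r <- data.frame(
      chrom = chrom[ii[1]], start = min(s[ii]), end = max(e[ii]),
      n_members = length(ii), stringsAsFactors = FALSE
    )
    r$members <- if ("element_id" %in% names(mc)) {
      paste(mc$element_id[ii], collapse = ",")
    } else paste(ii, collapse = ",")
    if ("log_alpha" %in% names(mc)) r$peak_log_alpha <- max(mc$log_alpha[ii])
    if ("pval_mad" %in% names(mc)) r$min_pval_mad <- min(mc$pval_mad[ii])
    r
  })
  df <- do.call(rbind, rows)
  out <- genomic_interval(df$chrom, df$start, df$end)
  S4Vectors::mcols(out) <- cbind(
    S4Vectors::DataFrame(cre_id = sprintf("cre_%04d", seq_len(nrow(df)))),
    S4Vectors::DataFrame(df[setdiff(names(df), c("chrom", "start", "end"))])
  )
  out
}

#' Compare element-level calls between two cell types
#'
#' Classifies each element as significant in A only, B only, both
#' (\code{shared}), or neither, at the given \code{pval_mad} threshold.
#'
#' @param results_a,results_b \code{\link{mad_test}} outputs for the two
#'   cell types (joined on \code{element_id}).
#' @param threshold Significance threshold on \code{pval_mad}
#'   (default 0.05).
#' @param labels Length-2 character vector naming the cell types.
#' @return A list: \code{table} (\code{element_id}, \code{class}) and
#'   \code{counts} (named tally over the four classes).
#' @export
compare_cell_types <- function(results_a, results_b, threshold = 0.05,
                               labels = c("A", "B")) {
  ids <- union(results_a$element_id, results_b$element_id)
  sig_a <- ids %in% results_a$element_id[results_a$pval_mad <= threshold]
  sig_b <- ids %in% results_b$element_id[results_b$pval_mad <= threshold]
  cls <- ifelse(sig_a & sig_b, "shared",
         ifelse(sig_a, paste0(labels[1], "_only"),
         ifelse(sig_b, paste0(labels[2], "_only"), "neither")))
  lvls <- c(paste0(labels[1], "_only"), paste0(labels[2], "_only"),
            "shared", "neither")
  tab <- data.frame(element_id = ids, class = cls, stringsAsFactors = FALSE)
  counts <- table(factor(cls, levels = lvls))
  list(table = tab, counts = c(counts))
}

#' cCRE annotation classes in precedence order (promoter-most first).
#' @export
CCRE_PRECEDENCE <- c("PLS", "pELS", "dELS", "CA-H3K4me3", "CA-TF",
                     "CA-CTCF", "CA", "TF")

#' Annotate CREs with ENCODE cCRE classes
#'
#' Any overlap with a cCRE assigns that cCRE's class; CREs overlapping no
#' cCRE are \code{"unannotated"}. When a CRE overlaps cCREs of several
#' classes, the promoter-most class wins by the fixed precedence
#' \code{PLS > pELS > dELS > CA-H3K4me3 > CA-TF > CA-CTCF > CA > TF}
#' (all overlapping classes are retained in \code{overlapping_classes}).
#'
#' @param cres \code{GRanges} of CREs (\code{\link{call_cres}}).
#' @param ccre \code{GRanges} of cCREs with the class in metadata column
#'   \code{name} (as read from a BED file) or \code{class}.
#' @return \code{cres} with metadata columns \code{annotation_class} and
#'   \code{overlapping_classes} added.
#' @export
annotate_cres <- function(cres, ccre) {
  cls_col <- if ("class" %in% names(S4Vectors::mcols(ccre))) "class" else "name"
  ccre_cls <- as.character(S4Vectors::mcols(ccre)[[cls_col]])
  unknown <- setdiff(unique(ccre_cls), CCRE_PRECEDENCE)
  if (length(unknown) > 0) {
    warning("unknown cCRE class(es) ranked last: ",
            paste(unknown, collapse = ", "))
  }
  prec <- c(CCRE_PRECEDENCE, unknown)
  hits <- GenomicRanges::findOverlaps(cres, ccre)
  ann <- rep("unannotated", length(cres))
  all_cls <- rep("", length(cres))
  for (i in unique(S4Vectors::queryHits(hits))) {
    cls <- unique(ccre_cls[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]])
    cls <- cls[order(match(cls, prec))]
    ann[i] <- cls[1]
    all_cls[i] <- paste(cls, collapse = ",")
  }
  S4Vectors::mcols(cres)$annotation_class <- ann
  S4Vectors::mcols(cres)$overlapping_classes <- all_cls
  cres
}
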