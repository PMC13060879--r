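# Barcode-to-element association: locus binning for sheared-fragment
# libraries, exact CIGAR-length matching for designed-oligo libraries, and
# dictionary construction with absolute multi-mapping removal.

#' Divide a locus into fixed-width bins
#'
#' Non-overlapping bins tile the region left to right, each \code{width} bp
#' except a possibly shorter terminal bin; their union is exactly the region.
#'
#' @param region Single-interval \code{GRanges}.
#' @param width Bin width in bp (default 100).
#' @return \code{GRanges} of bins with metadata column \code{bin_id}
#'   (\code{bin_00001}, ... left to right).
#' @export
bin_locus <- function(region, width = 100L) {
  stopifnot(length(region) == 1L, width >= 1L)
  s0 <- GenomicRanges::start(region)
  e0 <- GenomicRanges::end(region)
  starts <- seq.int(s0, e0, by = width)
  ends <- pmin(starts + as.integer(width) - 1L, e0)
  bins <- genomic_interval(as.character(GenomicRanges::seqnames(region)),
                           starts, ends)
  S4Vectors::mcols(bins)$bin_id <- sprintf("bin_%05d", seq_along(bins))
  bins
}

# Fragment midpoint under the lower-central tie-break for even lengths.
fragment_midpoint <- function(start, end) {
  as.integer(floor((as.numeric(start) + as.numeric(end)) / 2))
}

#' Assign fragments to bins by midpoint
#'
#' A sheared fragment is assigned to the bin containing its midpoint; for
#' even-length fragments the midpoint is the lower of the two central
#' coordinates, so assignment is deterministic and strand-free. Fragments
#' whose midpoint falls outside the binned locus are unassigned (\code{NA}).
#'
#' @param frag_iv \code{GRanges} of aligned fragments.
#' @param bins Bins from \code{\link{bin_locus}}.
#' @return Character vector of \code{bin_id} (NA for unassigned).
#' @export
assign_fragment <- function(frag_iv, bins) {
  mid <- fragment_midpoint(GenomicRanges::start(frag_iv),
                           GenomicRanges::end(frag_iv))
  pts <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(frag_iv),
    IRanges::IRanges(start = mid, width = 1L)
  )
  hit <- GenomicRanges::findOverlaps(pts, bins, select = "first")
  S4Vectors::mcols(bins)$bin_id[hit]
}

#' Read association records from a SAM file
#'
#' Reads an association-sequencing alignment (SAM) and returns the
#' simplified record table the dictionary builder consumes. The barcode is
#' taken from the read name (the convention of association libraries where
#' the 15 bp barcode is carried in the qname); secondary and supplementary
#' alignments are ignored. The aligned span is the alignment's reference
#' span (CIGAR reference width).
#'
#' @param path SAM (or BAM) file path.
#' @return \code{data.frame} with columns \code{barcode}, \code{element}
#'   (reference name), \code{start}, \code{end}, \code{cigar}, \code{reads}.
#' @export
read_association_sam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  p <- Rsamtools::ScanBamParam(
    flag = flags, what = c("qname", "rname", "pos", "cigar")
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(rec$pos)
  rwidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
  data.frame(
    barcode = rec$qname[keep],
    element = as.character(rec$rname)[keep],
    start = rec$pos[keep],
    end = rec$pos[keep] + rwidth - 1L,
    cigar = rec$cigar[keep],
    reads = 1L,
    stringsAsFactors = FALSE
  )
}

#' @rdname read_association_sam
#' @details \code{read_association_tsv} reads the simplified TSV dialect
#'   with header \code{barcode, element, start, end, cigar, reads}
#'   (\code{element} is an oligo id in oligo mode or a chromosome in
#'   fragment mode).
#' @export
read_association_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(barcode = "character",
                                   element = "character",
                                   cigar = "character"))
}

# A CIGAR "<L>M" for exactly the designed length L; anything else fails.
cigar_is_perfect <- function(cigar, expected_len) {
  ok <- grepl("^[0-9]+M$", cigar)
  len <- rep(NA_integer_, length(cigar))
  len[ok] <- as.integer(sub("M$", "", cigar[ok]))
  ok & !is.na(expected_len) & len == expected_len
}

#' Build a barcode-to-element dictionary
#'
#' In \code{"oligo"} mode each record's element is a designed oligo id and
#' only records whose CIGAR is a single match run equal to the oligo's
#' designed length (e.g. \code{219M} for a 219 bp oligo) are kept. In
#' \code{"fragment"} mode each record is an aligned sheared fragment,
#' assigned to a locus bin by its midpoint. Barcodes observed for more than
#' one element are removed entirely (no plurality rescue), then barcodes
#' with total read support below \code{min_support} are dropped.
#'
#' Every input record lands in exactly one accounting category, so the
#' report's category counts sum to the input record count.
#'
#' @param records \code{data.frame} of association records (see
#'   \code{\link{read_association_tsv}}).
#' @param mode \code{"oligo"} or \code{"fragment"}.
#' @param oligo_lengths Named integer vector of designed lengths by oligo id
#'   (oligo mode; e.g. \code{setNames(design$length, design$oligo_id)}).
#' @param bins Bins from \code{\link{bin_locus}} (fragment mode).
#' @param min_support Minimum summed read support per kept barcode
#'   (default 1).
#' @return A list: \code{dictionary} (\code{data.frame} of \code{barcode},
#'   \code{element_id}, \code{support}), \code{element_counts} (barcodes per
#'   element), and \code{report} (named counts: \code{kept},
#'   \code{removed_multimap}, \code{removed_cigar}, \code{removed_support},
#'   \code{removed_unassigned}, \code{removed_malformed}).
#' @export
build_dictionary <- function(records, mode = c("oligo", "fragment"),
                             oligo_lengths = NULL, bins = NULL,
                             min_support = 1L) {
  mode <- match.arg(mode)
  n_in <- nrow(records)
  report <- c(kept = 0L, removed_multimap = 0L, removed_cigar = 0L,
              removed_support = 0L, removed_unassigned = 0L,
              removed_malformed = 0L)
  empty <- list(
    dictionary = data.frame(barcode = character(), element_id = character(),
                            support = integer()),
    element_counts = data.frame(element_id = character(),
                                n_barcodes = integer()),
    report = report
  )
  if (n_in == 0) return(empty)
  stopifnot(all(c("barcode", "element", "reads") %in% names(records)))

  if (mode == "oligo") {
    if (is.null(oligo_lengths)) stop("oligo mode requires oligo_lengths")
    malformed <- !grepl("^([0-9]+[MIDNSHP=X])+$", records$cigar)
    expected <- unname(oligo_lengths[records$element])
    pass <- !malformed & cigar_is_perfect(records$cigar, expected)
    report["removed_malformed"] <- sum(malformed)
    report["removed_cigar"] <- sum(!malformed & !pass)
    records <- records[pass, , drop = FALSE]
    records$element_id <- records$element
  } else {
    if (is.null(bins)) stop("fragment mode requires bins")
    frag <- genomic_interval(records$element, records$start, records$end)
    records$element_id <- assign_fragment(frag, bins)
    unassigned <- is.na(records$element_id)
    report["removed_unassigned"] <- sum(unassigned)
    records <- records[!unassigned, , drop = FALSE]
  }

  if (nrow(records) == 0) { empty$report <- report; return(empty) }

  # absolute multi-mapping removal
  n_elements <- tapply(records$element_id, records$barcode,
                       function(x) length(unique(x)))
  multi <- names(n_elements)[n_elements > 1L]
  is_multi <- records$barcode %in% multi
  report["removed_multimap"] <- sum(is_multi)
  records <- records[!is_multi, , drop = FALSE]

  if (nrow(records) == 0) { empty$report <- report; return(empty) }

  agg <- stats::aggregate(reads ~ barcode + element_id, data = records,
                          FUN = sum)
  low <- agg$barcode[agg$reads < min_support]
  is_low <- records$barcode %in% low
  report["removed_support"] <- sum(is_low)
  report["kept"] <- sum(!is_low)
  agg <- agg[!agg$barcode %in% low, , drop = FALSE]
  agg <- agg[order(agg$barcode), , drop = FALSE]
  rownames(agg) <- NULL
  names(agg)[names(agg) == "reads"] <- "support"
  ec <- stats::aggregate(barcode ~ element_id, data = agg, FUN = length)
  names(ec)[names(ec) == "barcode"] <- "n_barcodes"
  ec <- ec[order(ec$element_id), , drop = FALSE]
  rownames(ec) <- NULL
  list(dictionary = agg[, c("barcode", "element_id", "support")],
       element_counts = ec, report = report)
}

#' Write / read a barcode dictionary TSV
#'
#' @param dict Result of \code{\link{build_dictionary}} or its
#'   \code{dictionary} component.
#' @param path Output TSV path.
#' @export
write_dictionary <- function(dict, path) {
  if (is.list(dict) && !is.data.frame(dict)) dict <- dict$dictionary
  utils::write.table(dict, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(barcode = "character",
                                   element_id = "character"))
}
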