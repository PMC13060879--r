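#' Construct a genomic interval
#'
#' Intervals are represented as \link[GenomicRanges]{GRanges} with 1-based
#' inclusive coordinates throughout the package; BED input/output converts to
#' 0-based half-open only at the file boundary. Strand \code{"."} (unstranded)
#' is stored as \code{"*"}.
#'
#' @param chrom Chromosome / contig name(s).
#' @param start 1-based inclusive start position(s); must be >= 1.
#' @param end 1-based inclusive end position(s); must be >= start.
#' @param strand One of \code{"+"}, \code{"-"}, \code{"."} (recycled).
#' @return A \code{GRanges} object.
#' @examples
#' iv <- genomic_interval("chr17", 45893536, 45895535)
#' interval_length(iv)  # 2000
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 1L)) stop("start must be >= 1 (coordinates are 1-based)")
  if (any(end < start)) stop("end must be >= start")
  strand <- ifelse(strand == ".", "*", strand)
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
}

#' Inclusive length of genomic intervals
#'
#' Length under the 1-based inclusive convention: \code{end - start + 1}.
#' A span printed as \code{chr17:45,893,536-45,895,535} therefore has length
#' 2,000 bp. The exclusive width (\code{end - start}) is available via
#' \code{exclusive = TRUE}; both conventions appear in the literature for the
#' same printed span, so neither is treated as canonical.
#'
#' @param iv A \code{GRanges} object.
#' @param exclusive If \code{TRUE}, return \code{end - start} instead.
#' @return Integer vector of lengths.
#' @export
interval_length <- function(iv, exclusive = FALSE) {
  w <- GenomicRanges::width(iv)
  if (exclusive) w - 1L else w
}

#' Load a genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named \link[Biostrings]{DNAStringSet}, names truncated at the
#'   first whitespace (contig names).
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Fetch sequence for genomic intervals
#'
#' Extracts the genome sequence over each interval; minus-strand intervals
#' return the reverse complement.
#'
#' @param genome A named \code{DNAStringSet} (see \code{\link{read_genome}})
#'   or a path to a FASTA file.
#' @param iv A \code{GRanges} of intervals to extract.
#' @return A \code{DNAStringSet}, one entry per interval, named
#'   \code{chrom:start-end(strand)}.
#' @export
fetch_sequence <- function(genome, iv) {
  if (is.character(genome)) genome <- read_genome(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  chrom <- as.character(GenomicRanges::seqnames(iv))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing) > 0) {
    stop("unknown contig(s): ", paste(missing, collapse = ", "))
  }
  clen <- Biostrings::width(genome)[match(chrom, names(genome))]
  s <- GenomicRanges::start(iv)
  e <- GenomicRanges::end(iv)
  bad <- which(s < 1L | e > clen)
  if (length(bad) > 0) {
    stop(sprintf(
      "interval out of contig bounds: %s:%d-%d (contig length %d)",
      chrom[bad[1]], s[bad[1]], e[bad[1]], clen[bad[1]]
    ))
  }
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(iv), function(i) {
    Biostrings::subseq(genome[[chrom[i]]], start = s[i], end = e[i])
  }))
  neg <- as.character(GenomicRanges::strand(iv)) == "-"
  if (any(neg)) seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
  names(seqs) <- sprintf(
    "%s:%d-%d(%s)", chrom, s, e, as.character(GenomicRanges::strand(iv))
  )
  seqs
}

#' Read / write BED intervals
#'
#' Thin wrappers over \link[rtracklayer]{import.bed} /
#' \link[rtracklayer]{export.bed} so all coordinate-convention conversion
#' (BED is 0-based half-open) happens at the file boundary. In-memory
#' intervals are always 1-based inclusive.
#'
#' @param path BED file path.
#' @return \code{read_bed}: a \code{GRanges}.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @param iv \code{GRanges} to write.
#' @export
write_bed <- function(iv, path) {
  rtracklayer::export(iv, path, format = "BED")
  invisible(path)
}

#' Read / write interval tables as TSV
#'
#' Plain TSV with header columns \code{chrom}, \code{start}, \code{end},
#' \code{strand} (1-based inclusive), plus any extra metadata columns.
#'
#' @param path TSV file path.
#' @return \code{read_interval_tsv}: a \code{GRanges} with metadata columns.
#' @export
read_interval_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  iv <- genomic_interval(df$chrom, df$start, df$end,
                         strand = if ("strand" %in% names(df)) df$strand else ".")
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra) > 0) {
    S4Vectors::mcols(iv) <- df[extra]
  }
  iv
}

#' @rdname read_interval_tsv
#' @param iv \code{GRanges} to write.
#' @export
write_interval_tsv <- function(iv, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(iv)),
    start = GenomicRanges::start(iv),
    end = GenomicRanges::end(iv),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(iv))),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(iv)
  if (ncol(mc) > 0) df <- cbind(df, as.data.frame(mc))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a printed coordinate span
#'
#' Accepts the human-readable form \code{"chr17:45,893,536-45,895,535"}
#' (thousands separators and en-dashes tolerated) and returns the interval.
#'
#' @param x Character vector of printed spans.
#' @param strand Strand to assign (default unstranded).
#' @return A \code{GRanges}.
#' @export
parse_span <- function(x, strand = ".") {
  x <- gsub(",", "", x)
  x <- gsub("–|—", "-", x)
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("cannot parse span: ", x[bad][1])
  genomic_interval(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    strand = strand
  )
}
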