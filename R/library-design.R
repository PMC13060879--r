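# Oligo library designers: strand tiling, per-base saturation mutagenesis,
# known-variant (SNV/InDel) pairs with parity-aware centering, and scrambled
# GC-matched negative controls.
#
# All designers are pure functions of (genome, parameters, seed) and emit a
# "design manifest": a data.frame with one row per oligo and columns
#   oligo_id, seq, chrom, start, end, strand, allele_class, focal_pos,
#   variant_key, length, library
# Coordinates (start, end, focal_pos) are 1-based inclusive genomic anchors
# of the *reference* window the oligo was derived from.

manifest_row <- function(oligo_id, seq, chrom, start, end, strand,
                         allele_class, focal_pos = NA_integer_,
                         variant_key = NA_character_, library) {
  data.frame(
    oligo_id = oligo_id, seq = seq, chrom = chrom,
    start = as.integer(start), end = as.integer(end), strand = strand,
    allele_class = allele_class, focal_pos = as.integer(focal_pos),
    variant_key = variant_key, length = nchar(seq), library = library,
    stringsAsFactors = FALSE
  )
}

empty_manifest <- function() {
  manifest_row(character(), character(), character(), integer(), integer(),
               character(), character(), integer(), character(), character())
}

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

contig_string <- function(genome, chrom) {
  if (!chrom %in% names(genome)) {
    stop("unknown contig: ", chrom)
  }
  as.character(genome[[chrom]])
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Design strand-tiled oligos over a region
#'
#' Emits fixed-length oligos starting at \code{region} start and every
#' \code{step} bp thereafter while the window fits inside the region, once per
#' strand (the minus-strand oligo is the reverse complement of the same
#' genomic window). With the defaults (270 bp oligos every 90 bp on both
#' strands) interior bases are covered by \code{2 * tile_len / step = 6}
#' oligos.
#'
#' Windows containing an N base are skipped (alternate-base semantics are
#' undefined for N); skips are reported via a message and recorded in the
#' \code{"skipped"} attribute of the result.
#'
#' @param region A single-interval \code{GRanges}.
#' @param genome Named \code{DNAStringSet} or FASTA path.
#' @param tile_len Oligo length in bp (default 270).
#' @param step Tiling step in bp (default 90).
#' @param strands Character vector of strands to emit (default both).
#' @return Design manifest \code{data.frame}, ordered by (start, strand).
#' @export
design_tiles <- function(region, genome, tile_len = 270L, step = 90L,
                         strands = c("+", "-")) {
  stopifnot(length(region) == 1L, tile_len >= 1L, step >= 1L)
  if (is.character(genome)) genome <- read_genome(genome)
  rlen <- interval_length(region)
  if (rlen < tile_len) {
    stop(sprintf("region length %d is shorter than tile_len %d", rlen, tile_len))
  }
  chrom <- as.character(GenomicRanges::seqnames(region))
  cs <- contig_string(genome, chrom)
  r0 <- GenomicRanges::start(region)
  starts <- seq.int(r0, GenomicRanges::end(region) - tile_len + 1L, by = step)
  windows <- substring(cs, starts, starts + tile_len - 1L)
  has_n <- grepl("N", windows, fixed = TRUE)
  if (any(has_n)) {
    message(sum(has_n), " tile window(s) skipped: contain N")
  }
  keep <- which(!has_n)
  rows <- lapply(keep, function(i) {
    s <- starts[i]
    e <- s + tile_len - 1L
    do.call(rbind, lapply(sort(strands), function(str) {
      seq <- if (str == "-") revcomp_chr(windows[i]) else windows[i]
      manifest_row(
        oligo_id = sprintf("tile:%s:%d-%d:%s", chrom, s, e, str),
        seq = seq, chrom = chrom, start = s, end = e, strand = str,
        allele_class = "ref", library = "tile"
      )
    }))
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty_manifest()
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- data.frame(
    start = starts[has_n], reason = rep("contains_N", sum(has_n))
  )
  out
}

#' Design per-base saturation mutagenesis oligos
#'
#' For every base p of \code{region}: one reference oligo whose window is
#' centered on p (length \code{oligo_len}, odd); three alternate oligos
#' differing from the reference only at the centered base (every base other
#' than the reference base); and one deletion oligo equal to the reference
#' oligo with the \code{del_len} bases centered on p removed (length
#' \code{oligo_len - del_len}). Five oligos per position in total.
#'
#' Positions whose window would leave the contig are skipped (not shifted —
#' shifting would break the centering invariant), as are windows containing
#' N; both are reported via message and the \code{"skipped"} attribute.
#'
#' @param region Single-interval \code{GRanges} of positions to mutate.
#' @param genome Named \code{DNAStringSet} or FASTA path.
#' @param oligo_len Odd oligo length in bp (default 219).
#' @param del_len Odd centered-deletion length in bp (default 5).
#' @return Design manifest \code{data.frame}; \code{focal_pos} is the mutated
#'   genomic base, \code{variant_key} is \code{chrom:pos:ref:alt} (deletions
#'   use the deleted bases as ref and \code{"-"} as alt).
#' @export
design_saturation <- function(region, genome, oligo_len = 219L, del_len = 5L) {
  stopifnot(length(region) == 1L)
  oligo_len <- as.integer(oligo_len)
  del_len <- as.integer(del_len)
  if (oligo_len %% 2L == 0L) stop("oligo_len must be odd")
  if (del_len %% 2L == 0L) stop("del_len must be odd")
  if (is.character(genome)) genome <- read_genome(genome)
  chrom <- as.character(GenomicRanges::seqnames(region))
  cs <- contig_string(genome, chrom)
  clen <- nchar(cs)
  flank <- (oligo_len - 1L) %/% 2L
  dflank <- (del_len - 1L) %/% 2L
  positions <- seq.int(GenomicRanges::start(region), GenomicRanges::end(region))
  in_bounds <- positions - flank >= 1L & positions + flank <= clen
  windows <- rep(NA_character_, length(positions))
  windows[in_bounds] <- substring(
    cs, positions[in_bounds] - flank, positions[in_bounds] + flank
  )
  has_n <- !is.na(windows) & grepl("N", windows, fixed = TRUE)
  skipped <- data.frame(
    pos = positions[!in_bounds | has_n],
    reason = c(rep("window_out_of_bounds", sum(!in_bounds)),
               rep("contains_N", sum(has_n)))
  )
  if (nrow(skipped) > 0) {
    message(nrow(skipped), " saturation position(s) skipped (",
            "out-of-bounds window or N in window)")
  }
  keep <- which(in_bounds & !has_n)
  center <- flank + 1L
  bases <- c("A", "C", "G", "T")
  rows <- lapply(keep, function(i) {
    p <- positions[i]
    w <- windows[i]
    refb <- substr(w, center, center)
    s <- p - flank
    e <- p + flank
    ref_row <- manifest_row(
      oligo_id = sprintf("sat:%s:%d:ref", chrom, p),
      seq = w, chrom = chrom, start = s, end = e, strand = "+",
      allele_class = "ref", focal_pos = p,
      variant_key = sprintf("%s:%d:%s:%s", chrom, p, refb, refb),
      library = "satmut"
    )
    alt_rows <- do.call(rbind, lapply(setdiff(bases, refb), function(b) {
      aw <- w
      substr(aw, center, center) <- b
      manifest_row(
        oligo_id = sprintf("sat:%s:%d:%s", chrom, p, b),
        seq = aw, chrom = chrom, start = s, end = e, strand = "+",
        allele_class = "snv_alt", focal_pos = p,
        variant_key = sprintf("%s:%d:%s:%s", chrom, p, refb, b),
        library = "satmut"
      )
    }))
    deleted <- substr(w, center - dflank, center + dflank)
    del_seq <- paste0(substr(w, 1L, center - dflank - 1L),
                      substr(w, center + dflank + 1L, oligo_len))
    del_row <- manifest_row(
      oligo_id = sprintf("sat:%s:%d:del%d", chrom, p, del_len),
      seq = del_seq, chrom = chrom, start = s, end = e, strand = "+",
      allele_class = "del5", focal_pos = p,
      variant_key = sprintf("%s:%d:%s:-", chrom, p - dflank, deleted),
      library = "satmut"
    )
    rbind(ref_row, alt_rows, del_row)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty_manifest()
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# Strip leading bases shared by ref and alt alleles (VCF anchoring),
# advancing pos accordingly. Returns list(pos, ref, alt).
normalize_variant <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, 1, 1) == substr(alt, 1, 1) &&
         (nchar(ref) > 1 || nchar(alt) > 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

variant_class <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) "snv"
  else if (nchar(alt) == 0L) "deletion"
  else if (nchar(ref) == 0L) "insertion"
  else "complex"
}

#' Design reference/alternate oligo pairs for known variants
#'
#' SNVs get a pair of equal-length oligos (\code{base_len}, default 219 bp)
#' with the variant base centered. Deletions of k bases get a reference oligo
#' of \code{base_len} bp when k is odd and \code{base_len - 1} bp when k is
#' even, so the deleted span is centered with equal flanks; the alternate
#' oligo is the reference minus the deleted span. Insertions mirror the rule:
#' the alternate (carrying the insertion, centered) is \code{base_len} bp for
#' odd k and \code{base_len - 1} bp for even k, and the reference is that
#' length minus k.
#'
#' Variants are filtered before design: indels longer than
#' \code{max_indel} bp are rejected (reason \code{"indel_gt_10"} at the
#' default), as are variants with allele count 0 (\code{"ac_zero"}).
#' VCF-anchored alleles (shared leading base) are normalized internally;
#' \code{variant_key} keeps the input spelling so downstream joins work on
#' the caller's identifiers.
#'
#' @param variants \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} and optionally \code{AC} (allele count) and
#'   \code{AF} (allele frequency).
#' @param genome Named \code{DNAStringSet} or FASTA path.
#' @param base_len Design length for odd-parity windows (default 219).
#' @param max_indel Largest indel size designed (default 10 bp).
#' @return A list with \code{oligos} (manifest, two rows per accepted
#'   variant: \code{allele_class} \code{"ref"} and one of
#'   \code{"snv_alt"}/\code{"deletion"}/\code{"insertion"}) and
#'   \code{rejected} (\code{data.frame} of \code{variant_key},
#'   \code{reason}).
#' @export
design_variant_oligos <- function(variants, genome, base_len = 219L,
                                  max_indel = 10L) {
  if (is.character(genome)) genome <- read_genome(genome)
  base_len <- as.integer(base_len)
  if (base_len %% 2L == 0L) stop("base_len must be odd")
  oligos <- list()
  rejected <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    key <- sprintf("%s:%d:%s:%s", v$chrom, as.integer(v$pos), v$ref, v$alt)
    reject <- function(reason) {
      rejected[[length(rejected) + 1L]] <<- data.frame(
        variant_key = key, reason = reason, stringsAsFactors = FALSE
      )
    }
    if (!is.null(v$AC) && !is.na(v$AC) && v$AC == 0) {
      reject("ac_zero"); next
    }
    nv <- normalize_variant(v$pos, toupper(v$ref), toupper(v$alt))
    cls <- variant_class(nv$ref, nv$alt)
    k <- abs(nchar(nv$ref) - nchar(nv$alt))
    if (cls == "complex") { reject("unsupported_allele"); next }
    if (cls != "snv" && k > max_indel) { reject("indel_gt_10"); next }
    cs <- tryCatch(contig_string(genome, v$chrom), error = function(e) NULL)
    if (is.null(cs)) { reject("unknown_contig"); next }
    pr <- design_one_variant(cs, v$chrom, nv, cls, k, base_len, key)
    if (is.character(pr)) { reject(pr); next }
    oligos[[length(oligos) + 1L]] <- pr
  }
  list(
    oligos = if (length(oligos) > 0) {
      out <- do.call(rbind, oligos); rownames(out) <- NULL; out
    } else empty_manifest(),
    rejected = if (length(rejected) > 0) do.call(rbind, rejected)
      else data.frame(variant_key = character(), reason = character())
  )
}

# Build one ref/alt pair; returns a 2-row manifest or a rejection reason.
design_one_variant <- function(cs, chrom, nv, cls, k, base_len, key) {
  clen <- nchar(cs)
  p <- nv$pos
  if (cls == "snv") {
    flank <- (base_len - 1L) %/% 2L
    s <- p - flank; e <- p + flank
    if (s < 1L || e > clen) return("window_out_of_bounds")
    refw <- substring(cs, s, e)
    if (grepl("N", refw, fixed = TRUE)) return("contains_N")
    if (substr(refw, flank + 1L, flank + 1L) != nv$ref) {
      return("ref_mismatch")
    }
    altw <- refw
    substr(altw, flank + 1L, flank + 1L) <- nv$alt
    alt_class <- "snv_alt"
  } else if (cls == "deletion") {
    ref_len <- if (k %% 2L == 1L) base_len else base_len - 1L
    flank <- (ref_len - k) %/% 2L
    s <- p - flank; e <- p + k - 1L + flank
    if (s < 1L || e > clen) return("window_out_of_bounds")
    refw <- substring(cs, s, e)
    if (grepl("N", refw, fixed = TRUE)) return("contains_N")
    if (substring(cs, p, p + k - 1L) != nv$ref) return("ref_mismatch")
    altw <- paste0(substr(refw, 1L, flank), substr(refw, flank + k + 1L, ref_len))
  } else {  # insertion of k bases between p-1 and p
    alt_len <- if (k %% 2L == 1L) base_len else base_len - 1L
    flank <- (alt_len - k) %/% 2L
    s <- p - flank; e <- p + flank - 1L
    if (s < 1L || e > clen) return("window_out_of_bounds")
    refw <- substring(cs, s, e)
    if (grepl("N", refw, fixed = TRUE)) return("contains_N")
    altw <- paste0(substr(refw, 1L, flank), nv$alt,
                   substr(refw, flank + 1L, nchar(refw)))
  }
  alt_class <- switch(cls, snv = "snv_alt", deletion = "deletion",
                      insertion = "insertion")
  rbind(
    manifest_row(
      oligo_id = sprintf("var:%s:ref:1", key), seq = refw, chrom = chrom,
      start = s, end = e, strand = "+", allele_class = "ref",
      focal_pos = p, variant_key = key, library = "variant"
    ),
    manifest_row(
      oligo_id = sprintf("var:%s:alt:1", key), seq = altw, chrom = chrom,
      start = s, end = e, strand = "+", allele_class = alt_class,
      focal_pos = p, variant_key = key, library = "variant"
    )
  )
}

#' Duplicate oligos of high-frequency variants
#'
#' Variants at or above the allele-frequency threshold have their ref/alt
#' oligo pairs represented twice in the ordered pool, with distinct
#' \code{oligo_id}s (copy suffix). The threshold applies to whatever
#' frequency scale the variant table carries (default 1.0).
#'
#' @param oligos Variant design manifest (from
#'   \code{\link{design_variant_oligos}}).
#' @param variants The variant table used for the design (needs \code{AF}).
#' @param af_threshold Frequency at/above which a variant is duplicated.
#' @return Expanded manifest; duplicated rows carry \code{":2"} id suffix.
#' @export
apply_replicate_rule <- function(oligos, variants, af_threshold = 1.0) {
  if (nrow(oligos) == 0 || is.null(variants$AF)) return(oligos)
  key <- sprintf("%s:%d:%s:%s", variants$chrom, as.integer(variants$pos),
                 variants$ref, variants$alt)
  qualifying <- key[!is.na(variants$AF) & variants$AF >= af_threshold]
  dup <- oligos[oligos$variant_key %in% qualifying, , drop = FALSE]
  if (nrow(dup) > 0) {
    dup$oligo_id <- sub(":1$", ":2", dup$oligo_id)
  }
  out <- rbind(oligos, dup)
  rownames(out) <- NULL
  out
}

#' Generate scrambled GC-matched negative controls
#'
#' Each control is a seeded random permutation of a source oligo's bases, so
#' base composition (and hence GC content) is matched exactly. At least one
#' scramble is emitted for every distinct oligo length present in the source
#' set, matching controls to every tested-region length. For the first
#' \code{n_center_sub} scrambles, three siblings with the middle base
#' substituted to each alternate base are also emitted.
#'
#' @param source_oligos Design manifest to draw sources from.
#' @param n Number of scrambles (excluding center-substituted siblings).
#' @param gc_tolerance Maximum allowed |GC(scramble) - GC(source)|; a
#'   permutation matches composition exactly, so this is asserted, not tuned.
#' @param rng_seed Integer seed; output is byte-identical per seed.
#' @param n_center_sub Number of scrambles that also get 3 center-base
#'   substituted siblings (default 0).
#' @return Design manifest of \code{allele_class} \code{"scramble"} oligos;
#'   column \code{source_id} records each scramble's source oligo.
#' @export
make_scrambles <- function(source_oligos, n, gc_tolerance = 0.02,
                           rng_seed = 1L, n_center_sub = 0L) {
  if (nrow(source_oligos) == 0) stop("no source oligos")
  if (n > nrow(source_oligos)) {
    stop(sprintf("n (%d) exceeds available source oligos (%d)",
                 n, nrow(source_oligos)))
  }
  with_seed(rng_seed, {
    lens <- source_oligos$length
    # one source per distinct length first, then fill at random
    first_per_len <- vapply(unique(lens), function(L) {
      idx <- which(lens == L); idx[sample.int(length(idx), 1L)]
    }, 1L)
    if (length(first_per_len) > n) {
      stop(sprintf("n (%d) too small to cover %d distinct lengths",
                   n, length(first_per_len)))
    }
    rest <- setdiff(seq_len(nrow(source_oligos)), first_per_len)
    chosen <- c(first_per_len,
                if (n > length(first_per_len))
                  sample(rest, n - length(first_per_len)))
    rows <- lapply(seq_along(chosen), function(i) {
      src <- source_oligos[chosen[i], ]
      chars <- strsplit(src$seq, "")[[1]]
      scr <- paste(sample(chars), collapse = "")
      gc <- function(x) {
        mean(strsplit(x, "")[[1]] %in% c("G", "C"))
      }
      stopifnot(abs(gc(scr) - gc(src$seq)) <= gc_tolerance)
      base <- manifest_row(
        oligo_id = sprintf("scramble_%04d", i), seq = scr,
        chrom = src$chrom, start = src$start, end = src$end, strand = ".",
        allele_class = "scramble", library = "control"
      )
      base$source_id <- src$oligo_id
      if (i <= n_center_sub) {
        len <- nchar(scr)
        c_idx <- (len + 1L) %/% 2L
        cb <- substr(scr, c_idx, c_idx)
        sibs <- do.call(rbind, lapply(setdiff(c("A", "C", "G", "T"), cb),
          function(b) {
            s2 <- scr
            substr(s2, c_idx, c_idx) <- b
            r <- manifest_row(
              oligo_id = sprintf("scramble_%04d:alt%s", i, b), seq = s2,
              chrom = src$chrom, start = src$start, end = src$end,
              strand = ".", allele_class = "scramble", library = "control"
            )
            r$source_id <- src$oligo_id
            r
          }))
        base <- rbind(base, sibs)
      }
      base
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a design manifest to FASTA and TSV
#'
#' @param design Design manifest \code{data.frame}.
#' @param fasta_path Output FASTA (ids are \code{oligo_id}); \code{NULL} to
#'   skip.
#' @param tsv_path Output manifest TSV; \code{NULL} to skip.
#' @return Invisibly, the paths written.
#' @export
write_design <- function(design, fasta_path = NULL, tsv_path = NULL) {
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(design$seq)
    names(seqs) <- design$oligo_id
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(design, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(fasta = fasta_path, tsv = tsv_path))
}

#' @rdname write_design
#' @param path Manifest TSV path to read back.
#' @export
read_design_manifest <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(oligo_id = "character"))
}
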