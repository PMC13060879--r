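# Synthetic-data generator: toy genomes, variant tables, and DNA/RNA barcode
# counts drawn from a declared noise model over a known activity landscape.
# Every pipeline stage is testable against the truth tables emitted here.
#
# Noise model (defaults documented in default_noise_model): per-barcode DNA
# abundance is log-normal(0, sigma_d); DNA counts are Poisson around the
# replicate depth times abundance; RNA counts are negative binomial with
# mean = DNA-scale x exp(element activity) x replicate depth factor and
# dispersion phi; barcodes per element are truncated Poisson(lambda_bc,
# min 1).

#' Generate a toy genome
#'
#' Deterministic per seed; realized GC content concentrates at the requested
#' fraction (within about 2 percentage points for lengths >= 10 kb).
#'
#' @param length Contig length in bp.
#' @param gc Target GC fraction (default 0.41, a human-like average).
#' @param seed RNG seed.
#' @param name Contig name.
#' @return A named \code{DNAStringSet} with one contig.
#' @export
make_toy_genome <- function(length, gc = 0.41, seed = 1L, name = "chrS") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- name
    genome
  })
}

#' Default noise model for count simulation
#'
#' @param sigma_d SD of log DNA abundance per barcode (log-normal;
#'   default 0.5).
#' @param phi Negative-binomial dispersion of RNA counts (default 0.1;
#'   \code{size = 1/phi}).
#' @param lambda_bc Mean barcodes per element (truncated Poisson, min 1;
#'   default 10).
#' @param depth Expected total DNA counts per replicate (default 1e6).
#' @param depth_factors Optional per-replicate relative depths (recycled to
#'   the number of replicates; default all 1).
#' @return A \code{list} consumed by \code{\link{simulate_counts}}.
#' @export
default_noise_model <- function(sigma_d = 0.5, phi = 0.1, lambda_bc = 10,
                                depth = 1e6, depth_factors = NULL) {
  stopifnot(sigma_d > 0, phi > 0, lambda_bc > 0, depth > 0)
  list(sigma_d = sigma_d, phi = phi, lambda_bc = lambda_bc, depth = depth,
       depth_factors = depth_factors)
}

#' Define an activity landscape
#'
#' The ground truth the simulator draws counts from: a baseline log
#' activity, planted enhancer intervals adding their effect (log units) to
#' any oligo whose anchor midpoint falls inside them, and planted
#' per-variant logFC values added to non-reference alleles of the matching
#' \code{variant_key}. Scrambled/negative controls always sit at baseline.
#'
#' @param baseline Baseline log activity (default 0).
#' @param enhancers \code{data.frame} with \code{chrom}, \code{start},
#'   \code{end}, \code{effect} (log units), or \code{NULL}.
#' @param variant_logfc Named numeric vector of planted logFC by
#'   \code{variant_key}, or \code{NULL}.
#' @return A \code{list} consumed by \code{\link{simulate_counts}}.
#' @export
activity_landscape <- function(baseline = 0, enhancers = NULL,
                               variant_logfc = NULL) {
  stopifnot(is.null(enhancers) ||
              all(c("chrom", "start", "end", "effect") %in% names(enhancers)))
  if (!is.null(variant_logfc)) stopifnot(all(is.finite(variant_logfc)))
  list(baseline = baseline, enhancers = enhancers,
       variant_logfc = variant_logfc)
}

# True log activity of each manifest oligo under a landscape.
true_activity <- function(design, landscape) {
  act <- rep(landscape$baseline, nrow(design))
  null_class <- design$allele_class %in% c("scramble", "negative")
  if (!is.null(landscape$enhancers) && nrow(landscape$enhancers) > 0) {
    mid <- fragment_midpoint(design$start, design$end)
    for (i in seq_len(nrow(landscape$enhancers))) {
      e <- landscape$enhancers[i, ]
      hit <- !null_class & design$chrom == e$chrom &
        mid >= e$start & mid <= e$end
      act[hit] <- act[hit] + e$effect
    }
  }
  if (!is.null(landscape$variant_logfc)) {
    alt <- !null_class & design$allele_class != "ref" &
      design$variant_key %in% names(landscape$variant_logfc)
    act[alt] <- act[alt] +
      unname(landscape$variant_logfc[design$variant_key[alt]])
  }
  act
}

random_barcodes <- function(n, length = 15L) {
  draw <- function(k) {
    vapply(seq_len(k), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  bc <- draw(n)
  while (anyDuplicated(bc) > 0) {
    dup <- duplicated(bc)
    bc[dup] <- draw(sum(dup))
  }
  bc
}

#' Simulate DNA/RNA barcode counts over a design
#'
#' Draws, per oligo, a truncated-Poisson number of 15 bp barcodes; per
#' barcode, a log-normal DNA abundance; then per replicate, Poisson DNA
#' counts around the replicate depth and negative-binomial RNA counts whose
#' mean is the DNA scale multiplied by \code{exp(true activity)}. The truth
#' table records every planted effect so recovery can be scored without
#' reaching into simulator internals.
#'
#' @param design Design manifest (any of the designers' outputs, possibly
#'   row-bound together).
#' @param landscape \code{\link{activity_landscape}}.
#' @param noise \code{\link{default_noise_model}}.
#' @param n_replicates Number of replicates (default 3).
#' @param seed RNG seed; output is reproducible byte-for-byte per seed.
#' @return List: \code{counts} (\code{barcode}, \code{element_id},
#'   \code{DNA_r}/\code{RNA_r} columns), \code{dictionary}
#'   (\code{barcode}, \code{element_id}), \code{truth}
#'   (\code{element_id}, \code{allele_class}, \code{variant_key},
#'   \code{true_log_activity}, \code{is_null}, \code{n_barcodes}).
#' @export
simulate_counts <- function(design, landscape = activity_landscape(),
                            noise = default_noise_model(),
                            n_replicates = 3L, seed = 1L) {
  stopifnot(nrow(design) > 0, n_replicates >= 1L)
  df <- if (is.null(noise$depth_factors)) rep(1, n_replicates)
        else rep_len(noise$depth_factors, n_replicates)
  if (any(df <= 0)) {
    stop("zero- or negative-depth replicate: depth factor(s) ",
         paste(which(df <= 0), collapse = ", "), " must be > 0")
  }
  act <- true_activity(design, landscape)
  with_seed(seed, {
    n_bc <- pmax(1L, stats::rpois(nrow(design), noise$lambda_bc))
    n_tot <- sum(n_bc)
    element_id <- rep(design$oligo_id, n_bc)
    abundance <- stats::rlnorm(n_tot, 0, noise$sigma_d)
    act_bc <- rep(act, n_bc)
    # per-barcode DNA scale so each replicate's expected total is depth
    base_mu <- noise$depth / (n_tot * exp(noise$sigma_d^2 / 2))
    counts <- data.frame(barcode = random_barcodes(n_tot),
                         element_id = element_id,
                         stringsAsFactors = FALSE)
    for (r in seq_len(n_replicates)) {
      mu_d <- base_mu * df[r] * abundance
      counts[[paste0("DNA_", r)]] <- stats::rpois(n_tot, mu_d)
      counts[[paste0("RNA_", r)]] <- stats::rnbinom(
        n_tot, mu = mu_d * exp(act_bc), size = 1 / noise$phi
      )
    }
    truth <- data.frame(
      element_id = design$oligo_id,
      allele_class = design$allele_class,
      variant_key = design$variant_key,
      true_log_activity = act,
      is_null = design$allele_class %in% c("scramble", "negative"),
      n_barcodes = n_bc,
      stringsAsFactors = FALSE
    )
    list(counts = counts,
         dictionary = counts[c("barcode", "element_id")],
         truth = truth)
  })
}

#' Generate a synthetic variant table
#'
#' SNVs and indels (VCF-anchored ref/alt spellings) at uniform positions in
#' the region, indel sizes uniform on 1..\code{max_indel}, allele
#' frequencies Beta-distributed with counts derived from a nominal cohort.
#' A few records deliberately violate the design filters (allele count 0;
#' indel size \code{max_indel + 2}) so filter accounting can be exercised
#' downstream.
#'
#' @param region Single-interval \code{GRanges} variants fall in.
#' @param genome Named \code{DNAStringSet} or FASTA path.
#' @param n_snv,n_indel Numbers of well-formed SNVs / indels.
#' @param max_indel Largest well-formed indel size (default 10).
#' @param n_ac_zero Planted allele-count-0 SNVs (default 3).
#' @param n_oversize Planted oversized deletions (default 3).
#' @param cohort_n Nominal diploid cohort size for allele counts
#'   (default 5000).
#' @param seed RNG seed.
#' @return \code{data.frame}: \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{AC}, \code{AF}, \code{class}, \code{planted_violation}.
#' @export
make_variant_table <- function(region, genome, n_snv = 100L, n_indel = 20L,
                               max_indel = 10L, n_ac_zero = 3L,
                               n_oversize = 3L, cohort_n = 5000L, seed = 1L) {
  if (is.character(genome)) genome <- read_genome(genome)
  chrom <- as.character(GenomicRanges::seqnames(region))
  cs <- contig_string(genome, chrom)
  lo <- GenomicRanges::start(region)
  hi <- GenomicRanges::end(region)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    snv_at <- function(pos, ac = NULL) {
      ref <- substr(cs, pos, pos)
      alt <- sample(setdiff(bases, ref), 1)
      af <- stats::rbeta(1, 0.3, 3)
      if (is.null(ac)) ac <- max(1L, stats::rbinom(1, 2L * cohort_n, af))
      data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 AC = ac, AF = ac / (2 * cohort_n), class = "snv",
                 stringsAsFactors = FALSE)
    }
    indel_at <- function(pos, k) {
      anchor <- substr(cs, pos, pos)
      af <- stats::rbeta(1, 0.3, 3)
      ac <- max(1L, stats::rbinom(1, 2L * cohort_n, af))
      if (stats::runif(1) < 0.5 && pos + k <= nchar(cs)) {  # deletion
        data.frame(chrom = chrom, pos = pos,
                   ref = substr(cs, pos, pos + k), alt = anchor,
                   AC = ac, AF = ac / (2 * cohort_n), class = "deletion",
                   stringsAsFactors = FALSE)
      } else {  # insertion
        ins <- paste(sample(bases, k, replace = TRUE), collapse = "")
        data.frame(chrom = chrom, pos = pos, ref = anchor,
                   alt = paste0(anchor, ins),
                   AC = ac, AF = ac / (2 * cohort_n), class = "insertion",
                   stringsAsFactors = FALSE)
      }
    }
    rows <- list()
    for (p in sample(lo:hi, n_snv, replace = FALSE)) {
      rows[[length(rows) + 1L]] <- snv_at(p)
    }
    for (i in seq_len(n_indel)) {
      rows[[length(rows) + 1L]] <- indel_at(sample(lo:hi, 1),
                                            sample.int(max_indel, 1))
    }
    ok <- do.call(rbind, rows)
    ok$planted_violation <- "none"
    viol <- list()
    for (i in seq_len(n_ac_zero)) {
      r <- snv_at(sample(lo:hi, 1), ac = 0L)
      r$AF <- 0
      r$planted_violation <- "ac_zero"
      viol[[length(viol) + 1L]] <- r
    }
    for (i in seq_len(n_oversize)) {
      pos <- sample(lo:(hi - max_indel - 2L), 1)
      r <- data.frame(chrom = chrom, pos = pos,
                      ref = substr(cs, pos, pos + max_indel + 2L),
                      alt = substr(cs, pos, pos),
                      AC = 5L, AF = 5 / (2 * cohort_n), class = "deletion",
                      planted_violation = "indel_gt_10",
                      stringsAsFactors = FALSE)
      viol[[length(viol) + 1L]] <- r
    }
    out <- rbind(ok, do.call(rbind, viol))
    out <- out[order(out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write / read variant tables
#'
#' The TSV dialect (\code{chrom}, \code{pos}, \code{ref}, \code{alt},
#' \code{AC}, \code{AF}) is the primary interchange format;
#' \code{write_variant_vcf} emits a minimal VCFv4.2 rendering of the same
#' table (AC/AF in INFO) for tools that expect VCF.
#'
#' @param variants Variant \code{data.frame}.
#' @param path Output path.
#' @export
write_variant_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_tsv
#' @export
read_variant_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(ref = "character", alt = "character"))
}

#' @rdname write_variant_tsv
#' @export
write_variant_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAC=%d;AF=%g",
                     variants$chrom, as.integer(variants$pos), variants$ref,
                     variants$alt, as.integer(variants$AC), variants$AF),
             con)
  invisible(path)
}

#' Read variants from a VCF file
#'
#' Wraps \link[VariantAnnotation]{readVcf}; AC/AF are taken from INFO when
#' present. Multi-allelic records are expanded to one row per alternate
#' allele.
#'
#' @param path VCF path.
#' @param genome Genome label passed to \code{readVcf} (default "toy").
#' @return Variant \code{data.frame} as in \code{\link{read_variant_tsv}}.
#' @export
read_variant_vcf <- function(path, genome = "toy") {
  vcf <- VariantAnnotation::readVcf(path, genome = genome)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  idx <- rep(seq_along(rr), n_alt)
  info <- VariantAnnotation::info(vcf)
  get_num <- function(field) {
    if (!field %in% names(info)) return(rep(NA_real_, sum(n_alt)))
    unlist(info[[field]])
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[idx],
    pos = GenomicRanges::start(rr)[idx],
    ref = as.character(VariantAnnotation::ref(vcf))[idx],
    alt = as.character(unlist(alt)),
    AC = as.integer(get_num("AC")),
    AF = as.numeric(get_num("AF")),
    stringsAsFactors = FALSE
  )
}
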