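test_that("tiling emits one window per strand at the configured step", {
  g <- make_toy_genome(1200, seed = 4)
  # region exactly one tile long: one window, both strands
  one <- design_tiles(genomic_interval("chrS", 101, 370), g)
  expect_equal(nrow(one), 2L)
  expect_setequal(one$strand, c("+", "-"))
  expect_equal(as.character(
    fetch_sequence(g, genomic_interval("chrS", 101, 370, "-"))[[1]]),
    one$seq[one$strand == "-"])
  # 450 bp region: offsets 0, 90, 180 -> 3 per strand
  three <- design_tiles(genomic_interval("chrS", 101, 550), g)
  expect_equal(nrow(three), 6L)
  expect_equal(sort(unique(three$start)), c(101L, 191L, 281L))
  expect_error(design_tiles(genomic_interval("chrS", 1, 100), g), "shorter")
})

test_that("tiling coverage matches a brute-force pileup oracle", {
  g <- make_toy_genome(3000, seed = 5)
  region <- genomic_interval("chrS", 1, 3000)
  tiles <- design_tiles(region, g, tile_len = 120, step = 40)
  cov <- pileup_coverage(tiles$start, tiles$end, 3000)
  interior <- seq(1 + 120, 3000 - 120)
  expect_true(all(cov[interior] == 2 * 120 / 40))
  expect_equal(mean(cov[interior]), 6)
})

test_that("tile windows containing N are skipped and reported", {
  seqs <- strsplit(strrep("ACGT", 250), "")[[1]]
  seqs[500] <- "N"
  g <- toy_genome(paste(seqs, collapse = ""), "chrN")
  expect_message(
    tiles <- design_tiles(genomic_interval("chrN", 1, 1000), g,
                          tile_len = 100, step = 100),
    "skipped")
  expect_false(any(grepl("N", tiles$seq)))
  expect_equal(attr(tiles, "skipped")$start, 401L)
})

test_that("saturation designer emits 5 oligos per position with the stated classes", {
  g <- make_toy_genome(700, seed = 6)
  region <- genomic_interval("chrS", 301, 340)
  d <- design_saturation(region, g)
  L <- interval_length(region)
  expect_equal(nrow(d), 5L * L)
  expect_equal(sum(d$allele_class == "ref"), L)
  expect_equal(sum(d$allele_class == "snv_alt"), 3L * L)
  expect_equal(sum(d$allele_class == "del5"), L)
  # per position: exactly 3 alternates, covering the alphabet complement
  cs <- as.character(g[[1]])
  for (p in c(301L, 320L, 340L)) {
    sub <- d[d$focal_pos == p & d$allele_class == "snv_alt", ]
    expect_equal(nrow(sub), 3L)
    refb <- substr(cs, p, p)
    alts <- substr(sub$seq, 110, 110)
    expect_setequal(alts, setdiff(c("A", "C", "G", "T"), refb))
    expect_false(refb %in% alts)
  }
})

test_that("saturation ref window is a hand-slice of the contig and del5 drops 5 centered bases", {
  g <- make_toy_genome(441, seed = 7)
  cs <- as.character(g[[1]])
  d <- design_saturation(genomic_interval("chrS", 221, 221), g)
  ref <- d$seq[d$allele_class == "ref"]
  expect_equal(ref, substr(cs, 112, 330))
  del <- d$seq[d$allele_class == "del5"]
  expect_equal(nchar(del), 214L)
  # single centered 5-base gap relative to the ref partner
  expect_equal(del, paste0(substr(ref, 1, 107), substr(ref, 113, 219)))
  # every snv_alt differs from ref at exactly one position (the center)
  for (alt in d$seq[d$allele_class == "snv_alt"]) {
    diff <- which(strsplit(alt, "")[[1]] != strsplit(ref, "")[[1]])
    expect_equal(diff, 110L)
  }
})

test_that("saturation positions with out-of-contig windows are skipped, not shifted", {
  g <- make_toy_genome(300, seed = 8)
  expect_message(
    d <- design_saturation(genomic_interval("chrS", 1, 150), g),
    "skipped")
  # windows need 109 bp flanks: positions 1..109 skipped
  expect_equal(min(d$focal_pos), 110L)
  expect_equal(attr(d, "skipped")$pos, 1:109)
  # surviving windows are still centered
  expect_true(all(d$start[d$allele_class == "ref"] ==
                    d$focal_pos[d$allele_class == "ref"] - 109L))
})

test_that("variant oligo parity rules: 219 for odd deletions, 218 for even", {
  g <- make_toy_genome(2000, seed = 9)
  cs <- as.character(g[[1]])
  mkdel <- function(pos, k) {
    data.frame(chrom = "chrS", pos = pos,
               ref = substr(cs, pos, pos + k),   # VCF-anchored
               alt = substr(cs, pos, pos), AC = 5L, AF = 0.01)
  }
  for (k in 1:10) {
    d <- design_variant_oligos(mkdel(900, k), g)
    expect_equal(nrow(d$rejected), 0L)
    ref_len <- d$oligos$length[d$oligos$allele_class == "ref"]
    alt_len <- d$oligos$length[d$oligos$allele_class == "deletion"]
    expect_equal(ref_len, if (k %% 2 == 1) 219L else 218L)
    expect_equal(alt_len, ref_len - k)
    # deleted span centered: equal flanks
    ref_seq <- d$oligos$seq[d$oligos$allele_class == "ref"]
    alt_seq <- d$oligos$seq[d$oligos$allele_class == "deletion"]
    flank <- (ref_len - k) / 2
    expect_equal(alt_seq, paste0(substr(ref_seq, 1, flank),
                                 substr(ref_seq, flank + k + 1, ref_len)))
  }
})

test_that("SNV pairs are equal length with Hamming distance 1 at the center", {
  g <- make_toy_genome(600, seed = 10)
  cs <- as.character(g[[1]])
  refb <- substr(cs, 300, 300)
  v <- data.frame(chrom = "chrS", pos = 300L, ref = refb,
                  alt = setdiff(c("A", "C", "G", "T"), refb)[1],
                  AC = 2L, AF = 0.001)
  d <- design_variant_oligos(v, g)
  expect_equal(d$oligos$length, c(219L, 219L))
  ref_seq <- d$oligos$seq[1]
  alt_seq <- d$oligos$seq[2]
  diff <- which(strsplit(ref_seq, "")[[1]] != strsplit(alt_seq, "")[[1]])
  expect_equal(diff, 110L)
  expect_equal(d$oligos$variant_key[1], d$oligos$variant_key[2])
})

test_that("insertion parity mirrors the deletion rule", {
  g <- make_toy_genome(800, seed = 11)
  cs <- as.character(g[[1]])
  mkins <- function(pos, k) {
    data.frame(chrom = "chrS", pos = pos, ref = substr(cs, pos, pos),
               alt = paste0(substr(cs, pos, pos), strrep("A", k)),
               AC = 5L, AF = 0.01)
  }
  for (k in c(1, 2, 7, 10)) {
    d <- design_variant_oligos(mkins(400, k), g)
    alt_len <- d$oligos$length[d$oligos$allele_class == "insertion"]
    ref_len <- d$oligos$length[d$oligos$allele_class == "ref"]
    expect_equal(alt_len, if (k %% 2 == 1) 219L else 218L)
    expect_equal(ref_len, alt_len - k)
  }
})

test_that("variant filters reject oversized indels and zero allele counts", {
  g <- make_toy_genome(800, seed = 12)
  cs <- as.character(g[[1]])
  v <- rbind(
    data.frame(chrom = "chrS", pos = 400L, ref = substr(cs, 400, 411),
               alt = substr(cs, 400, 400), AC = 5L, AF = 0.01),  # 11 bp del
    data.frame(chrom = "chrS", pos = 420L, ref = substr(cs, 420, 420),
               alt = "T", AC = 0L, AF = 0)                        # AC 0
  )
  v$alt[2] <- setdiff(c("A", "C", "G", "T"), v$ref[2])[1]
  d <- design_variant_oligos(v, g)
  expect_equal(nrow(d$oligos), 0L)
  expect_setequal(d$rejected$reason, c("indel_gt_10", "ac_zero"))
  # boundary: a 10 bp deletion passes
  ok <- design_variant_oligos(
    data.frame(chrom = "chrS", pos = 400L, ref = substr(cs, 400, 410),
               alt = substr(cs, 400, 400), AC = 5L, AF = 0.01), g)
  expect_equal(nrow(ok$oligos), 2L)
})

test_that("high-frequency variants are represented twice", {
  g <- make_toy_genome(2000, seed = 13)
  cs <- as.character(g[[1]])
  mk <- function(pos, af) {
    refb <- substr(cs, pos, pos)
    data.frame(chrom = "chrS", pos = pos, ref = refb,
               alt = setdiff(c("A", "C", "G", "T"), refb)[1],
               AC = 10L, AF = af)
  }
  v <- do.call(rbind, c(lapply(c(500, 600, 700), mk, af = 1.0),
                        lapply(c(800, 900), mk, af = 0.5)))
  d <- design_variant_oligos(v, g)
  expanded <- apply_replicate_rule(d$oligos, v, af_threshold = 1.0)
  # 3 qualifying duplicated + 2 singles = 8 ref/alt pairs
  expect_equal(nrow(expanded) / 2, 8)
  expect_equal(anyDuplicated(expanded$oligo_id), 0L)
  per_key <- table(expanded$variant_key) / 2
  expect_equal(unname(sort(c(per_key))), c(1, 1, 2, 2, 2))
})

test_that("scrambles preserve composition, cover all lengths, and are seed-stable", {
  g <- make_toy_genome(900, seed = 14)
  src <- design_saturation(genomic_interval("chrS", 401, 420), g)
  expect_setequal(unique(src$length), c(219L, 214L))
  scr <- make_scrambles(src, n = 10, rng_seed = 42, n_center_sub = 1)
  base <- scr[!grepl(":alt", scr$oligo_id), ]
  expect_setequal(unique(base$length), c(219L, 214L))
  comp <- function(s) sort(strsplit(s, "")[[1]])
  for (i in seq_len(nrow(base))) {
    src_seq <- src$seq[src$oligo_id == base$source_id[i]]
    expect_equal(comp(base$seq[i]), comp(src_seq))
  }
  # center-substituted siblings: 3, differing only at the middle base
  sibs <- scr[grepl("scramble_0001:alt", scr$oligo_id), ]
  expect_equal(nrow(sibs), 3L)
  first <- scr$seq[scr$oligo_id == "scramble_0001"]
  c_idx <- (nchar(first) + 1) %/% 2
  for (s in sibs$seq) {
    diff <- which(strsplit(s, "")[[1]] != strsplit(first, "")[[1]])
    expect_equal(diff, c_idx)
  }
  # determinism and the n > sources error
  expect_identical(scr, make_scrambles(src, n = 10, rng_seed = 42,
                                       n_center_sub = 1))
  expect_error(make_scrambles(src, n = nrow(src) + 1, rng_seed = 1),
               "exceeds")
})

test_that("designers are pure functions of genome, parameters and seed", {
  g <- make_toy_genome(1500, seed = 15)
  r <- genomic_interval("chrS", 201, 700)
  expect_identical(design_tiles(r, g), design_tiles(r, g))
  expect_identical(design_saturation(genomic_interval("chrS", 301, 320), g),
                   design_saturation(genomic_interval("chrS", 301, 320), g))
})

test_that("design FASTA and manifest round-trip", {
  g <- make_toy_genome(700, seed = 16)
  d <- design_saturation(genomic_interval("chrS", 301, 310), g)
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_design(d, fasta_path = fa, tsv_path = tsv)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(names(seqs), d$oligo_id)
  expect_equal(as.character(seqs), stats::setNames(d$seq, d$oligo_id))
  back <- read_design_manifest(tsv)
  expect_equal(back$oligo_id, d$oligo_id)
  expect_equal(back$seq, d$seq)
})
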