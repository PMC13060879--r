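alpha_table <- function(alphas, keys) {
  # per-variant replicate alpha rows (the paired-activity input shape)
  out <- data.frame(variant_key = keys, stringsAsFactors = FALSE)
  alphas <- as.matrix(alphas)
  for (r in seq_len(ncol(alphas))) out[[paste0("alpha_", r)]] <- alphas[, r]
  out
}

test_that("null variants get logFC 0 and an ns call", {
  a <- alpha_table(cbind(c(1.2, 0.8), c(1.1, 0.9), c(1.3, 0.7)),
                   keys = c("v1", "v2"))
  eff <- variant_logfc(a, a)
  expect_equal(eff$logFC, c(0, 0))
  expect_equal(eff$call, c("ns", "ns"))
})

test_that("swapping ref and alt negates logFC exactly", {
  set.seed(61)
  ref <- alpha_table(matrix(exp(rnorm(30)), 10, 3),
                     keys = sprintf("v%02d", 1:10))
  alt <- alpha_table(matrix(exp(rnorm(30, 0.4)), 10, 3),
                     keys = sprintf("v%02d", 1:10))
  fwd <- variant_logfc(ref, alt)
  rev <- variant_logfc(alt, ref)
  expect_equal(rev$logFC, -fwd$logFC)
  expect_equal(rev$p, fwd$p)
})

test_that("the effect-size gate blocks significant but small logFC", {
  # tight replicates at logFC 0.09: tiny p, but below the 0.1 cutoff
  ref <- alpha_table(cbind(1, 1.001, 0.999), "v1")
  alt <- alpha_table(exp(0.09) * cbind(1.0005, 1, 0.9995), "v1")
  eff <- variant_logfc(ref, alt)
  expect_lt(eff$p, 0.01)
  expect_equal(eff$call, "ns")
  # logFC marginally below the threshold is still ns (strict inequality)
  alt2 <- alpha_table(exp(0.0999) * cbind(1.0005, 1, 0.9995), "v1")
  expect_equal(variant_logfc(ref, alt2)$call, "ns")
  # just above with the same precision is called
  alt3 <- alpha_table(exp(0.2) * cbind(1.0005, 1, 0.9995), "v1")
  expect_equal(variant_logfc(ref, alt3)$call, "gain")
})

test_that("log base switch rescales logFC", {
  ref <- alpha_table(cbind(1, 1.01, 0.99), "v1")
  alt <- alpha_table(2 * cbind(1, 1.01, 0.99), "v1")
  e_nat <- variant_logfc(ref, alt)
  e_log2 <- variant_logfc(ref, alt, log_base = 2)
  expect_equal(e_nat$logFC, log(2))
  expect_equal(e_log2$logFC, 1)
})

test_that("SNVs and InDels form separate BH families", {
  set.seed(62)
  keys <- sprintf("v%02d", 1:20)
  cls <- stats::setNames(rep(c("snv", "indel"), each = 10), keys)
  ref <- alpha_table(matrix(exp(rnorm(60, 0, 0.05)), 20, 3), keys)
  alt <- alpha_table(matrix(exp(rnorm(60, 0.3, 0.05)), 20, 3), keys)
  eff <- variant_logfc(ref, alt, variant_class = cls)
  for (k in c("snv", "indel")) {
    sel <- eff$class == k
    expect_equal(eff$adj_p[sel], bh_oracle(eff$p[sel]))
  }
})

test_that("missing partner oligos are untestable, not fatal", {
  ref <- alpha_table(cbind(1, 1.1, 0.9), "v1")
  alt <- alpha_table(rbind(c(1, 1.1, 0.9), c(2, 2.1, 1.9)), c("v1", "v2"))
  eff <- variant_logfc(ref, alt)
  expect_equal(eff$call[eff$variant_key == "v2"], "untestable")
  expect_equal(eff$call[eff$variant_key == "v1"], "ns")
})

test_that("planted e^0.5 effects are recovered at low noise", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    noise <- matrix(exp(rnorm(3, 0, 0.02)), 1, 3)
    ref <- alpha_table(matrix(exp(rnorm(3, 0, 0.02)), 1, 3), "v1")
    alt <- alpha_table(exp(0.5) * noise, "v1")
    eff <- variant_logfc(ref, alt)
    if (abs(eff$logFC - 0.5) <= 0.1 && eff$call == "gain") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("sharing classification matches the exhaustive 9-case truth table", {
  calls <- c("gain", "loss", "ns")
  grid <- expand.grid(a = calls, b = calls, stringsAsFactors = FALSE)
  want <- with(grid, ifelse(
    a != "ns" & b != "ns" & a == b, "shared",
    ifelse(a != "ns" & b != "ns", "discordant",
    ifelse(a != "ns", "neuron_only",
    ifelse(b != "ns", "hek_only", "none")))))
  expect_equal(classify_sharing(grid$a, grid$b), want)
  expect_equal(classify_sharing("gain", "gain"), "shared")
  expect_equal(classify_sharing("gain", "ns"), "neuron_only")
  expect_equal(classify_sharing("gain", "loss"), "discordant")
})

test_that("window summaries recover planted per-window counts", {
  set.seed(63)
  n <- 200
  eff <- data.frame(
    variant_key = sprintf("v%03d", 1:n),
    chrom = "c",
    focal_pos = sample.int(10000, n),
    call = sample(c("gain", "loss", "ns"), n, replace = TRUE,
                  prob = c(0.2, 0.2, 0.6)),
    stringsAsFactors = FALSE
  )
  win <- genomic_interval("c", 2000, 5000)
  got <- window_summary(eff, win)
  inside <- eff$focal_pos >= 2000 & eff$focal_pos <= 5000
  expect_equal(got$gain, sum(inside & eff$call == "gain"))
  expect_equal(got$loss, sum(inside & eff$call == "loss"))
  expect_equal(got$total_tested, sum(inside))
  # window spanning everything conserves the global call count
  all_w <- window_summary(eff, genomic_interval("c", 1, 10000))
  expect_equal(all_w$total_called, sum(eff$call != "ns"))
  expect_equal(all_w$fraction_of_called, 1)
  # empty window
  none <- window_summary(eff, genomic_interval("c", 99000, 99900))
  expect_equal(none$total_tested, 0L)
  expect_equal(none$gain + none$loss, 0L)
})

test_that("motif delta is zero for identical sequences and uniform PWMs", {
  pwm <- pwm_matrix(matrix(c(
    0.97, 0.01, 0.01, 0.01,
    0.01, 0.97, 0.01, 0.01,
    0.01, 0.01, 0.97, 0.01,
    0.01, 0.01, 0.01, 0.97
  ), nrow = 4), name = "ACGT")
  expect_equal(motif_delta(pwm, "TTACGTTT", "TTACGTTT")$delta, 0)
  unif <- pwm_matrix(matrix(0.25, 4, 4), name = "flat")
  expect_equal(motif_delta(unif, "ACGTACGT", "AAAAAAAA")$delta, 0)
})

test_that("motif delta matches hand-computed log-odds on a consensus-breaking SNV", {
  # columns prefer A, C, G, T with probability 0.91, others 0.03
  p <- matrix(0.03, 4, 4)
  diag(p) <- 0.91
  pwm <- pwm_matrix(p, name = "toy")
  hi <- log2(0.91 / 0.25)
  lo <- log2(0.03 / 0.25)
  ref <- "TTACGTTT"   # contains the consensus ACGT
  alt <- "TTATGTTT"   # center C -> T breaks it
  d <- motif_delta(pwm, ref, alt)
  expect_equal(d$ref_score, 4 * hi)
  # best alt hit: ATGT matches consensus at positions 1, 3, 4
  expect_equal(d$alt_score, 3 * hi + lo)
  expect_equal(d$delta, lo - hi)
  expect_lt(d$delta, 0)
})

test_that("motif scanning considers both strands and delta ignores background shifts", {
  p <- matrix(0.02, 4, 4)
  diag(p) <- 0.94
  pwm <- pwm_matrix(p)
  # ACGT's reverse complement is ACGT-revcomp = ACGT ... use a non-palindrome
  p2 <- matrix(0.02, 4, 5)
  p2[1, ] <- 0.94; p2[cbind(2:4, 2:4)] <- 0.02
  p2 <- sweep(p2, 2, colSums(p2), "/")
  pwm2 <- pwm_matrix(p2)  # consensus AAAAA
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  fwd <- motif_delta(pwm2, "GGAAAAAGG", "GGAATAAGG")$delta
  rcv <- motif_delta(pwm2, rc("GGAAAAAGG"), rc("GGAATAAGG"))$delta
  expect_equal(fwd, rcv)
  # background change shifts both best scores equally
  d1 <- motif_delta(pwm, "TTACGTTT", "TTATGTTT", background = 0.25)
  d2 <- motif_delta(pwm, "TTACGTTT", "TTATGTTT", background = 0.4)
  expect_equal(d1$delta, d2$delta)
})

test_that("score agreement reproduces rank correlations and sign concordance", {
  eff <- data.frame(
    variant_key = sprintf("v%02d", 1:10),
    logFC = c(0.5, -0.3, 0.2, 0.9, -0.7, 0.1, -0.2, 0.4, -0.05, 0.6),
    call = c("gain", "loss", "ns", "gain", "loss", "ns", "loss", "gain",
             "ns", "gain"),
    stringsAsFactors = FALSE
  )
  same <- data.frame(variant_key = eff$variant_key, score = eff$logFC)
  expect_equal(score_agreement(eff, same)$rho, 1)
  flipped <- data.frame(variant_key = eff$variant_key, score = -eff$logFC)
  expect_equal(score_agreement(eff, flipped)$rho, -1)
  set.seed(64)
  ext <- data.frame(variant_key = eff$variant_key, score = rnorm(10))
  got <- score_agreement(eff, ext)
  expect_equal(got$rho, spearman_oracle(eff$logFC, ext$score))
  called <- eff$call != "ns"
  expect_equal(got$sign_concordance,
               mean(sign(eff$logFC[called]) == sign(ext$score[called])))
  # unmatched keys are reported
  ext2 <- rbind(ext, data.frame(variant_key = "v99", score = 1))
  expect_equal(score_agreement(eff, ext2)$unmatched_keys, "v99")
})

test_that("permutation test agrees with the t-test on clear effects", {
  set.seed(65)
  nb <- 12
  mk <- function(mu_rna) {
    cm <- data.frame(barcode = fixture_barcodes(nb, seed = sample.int(1e6, 1)),
                     stringsAsFactors = FALSE)
    for (r in 1:3) {
      cm[[paste0("DNA_", r)]] <- rpois(nb, 200)
      cm[[paste0("RNA_", r)]] <- rpois(nb, mu_rna)
    }
    cm
  }
  ref <- mk(200)
  alt_null <- mk(200)
  alt_up <- mk(200 * exp(1))
  null_res <- permutation_logfc_test(ref, alt_null, n_perm = 500, seed = 1)
  up_res <- permutation_logfc_test(ref, alt_up, n_perm = 500, seed = 1)
  expect_gt(null_res$p, 0.05)
  expect_lt(up_res$p, 0.01)
  expect_gt(up_res$logFC, 0.8)
  # seeded: reproducible
  expect_identical(up_res,
                   permutation_logfc_test(ref, alt_up, n_perm = 500, seed = 1))
})

test_that("no planted effects means few calls (error control on null data)", {
  set.seed(66)
  called_frac <- replicate(3, {
    g <- make_toy_genome(3000, seed = sample.int(1e6, 1))
    cs <- as.character(g[[1]])
    pos <- seq(300, 2690, by = 24)
    v <- data.frame(
      chrom = "chrS", pos = pos, ref = substring(cs, pos, pos),
      alt = vapply(pos, function(p) {
        setdiff(c("A", "C", "G", "T"), substring(cs, p, p))[1]
      }, ""),
      AC = 5L, AF = 0.01
    )
    d <- design_variant_oligos(v, g)
    sim <- simulate_counts(d$oligos, activity_landscape(),
                           default_noise_model(depth = 2e5),
                           seed = sample.int(1e6, 1))
    act <- element_activity(normalize_counts(sim$counts))
    m <- d$oligos[match(act$element_id, d$oligos$oligo_id), ]
    act$variant_key <- m$variant_key
    eff <- variant_logfc(act[m$allele_class == "ref", ],
                         act[m$allele_class != "ref", ])
    mean(eff$call %in% c("gain", "loss"))
  })
  expect_lt(mean(called_frac), 0.05 + 0.03)
})
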