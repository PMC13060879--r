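# Orchestration: one validated config drives simulate -> design ->
# associate -> quantify -> call CREs -> variant effects, writing each
# stage's table plus a summary report recomputed from the stage outputs.

#' Default pipeline configuration
#'
#' All stage parameters in one document. Defaults are the package's standard
#' study conditions: a 12 kb toy genome; 270/90 both-strand tiling over a
#' 4 kb region with two planted enhancers; per-base saturation mutagenesis
#' over a short promoter-like window; a synthetic known-variant table with a
#' planted effect subset; 100 scrambled controls; log-normal/negative-
#' binomial counts at 1e6 depth, 3 replicates, two cell types.
#'
#' @param seed Top-level seed; all stage randomness derives from it.
#' @return Nested configuration list for \code{\link{run_pipeline}}.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(length = 12000L, gc = 0.41),
    tiling = list(start = 1001L, end = 5000L, tile_len = 270L, step = 90L),
    saturation = list(start = 6001L, end = 6060L, oligo_len = 219L,
                      del_len = 5L),
    variants = list(n_snv = 60L, n_indel = 12L, max_indel = 10L,
                    n_ac_zero = 3L, n_oversize = 3L, af_threshold = 1.0,
                    start = 7001L, end = 8000L),
    controls = list(n_scrambles = 100L, n_center_sub = 2L),
    noise = list(sigma_d = 0.5, phi = 0.1, lambda_bc = 10, depth = 1e6),
    replicates = 3L,
    cell_types = list(
      names = c("neuron", "hek"),
      n_enhancers = 2L, enhancer_effect = 1.5, enhancer_width = 400L,
      n_variant_effects = 20L, variant_effect_size = 0.5
    ),
    activity = list(pseudocount = 1, min_barcodes = 1L, alpha = 0.05),
    effects = list(lfc = 0.1, alpha = 0.05),
    cre = list(adjacency_gap = 0L)
  )
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys (at any nesting level, against the default
#' template), fills omitted keys with defaults, and checks threshold
#' sanity (positive logFC cutoff, alpha in (0, 1], positive noise
#' parameters).
#'
#' @param config Possibly partial configuration list.
#' @return The resolved (fully populated) configuration.
#' @export
validate_run_config <- function(config) {
  template <- default_run_config()
  merge_checked <- function(cfg, tpl, path = "") {
    unknown <- setdiff(names(cfg), names(tpl))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    }
    out <- tpl
    for (k in names(cfg)) {
      out[[k]] <- if (is.list(tpl[[k]]) && is.list(cfg[[k]]) &&
                      !is.null(names(tpl[[k]]))) {
        merge_checked(cfg[[k]], tpl[[k]], paste0(path, k, "."))
      } else cfg[[k]]
    }
    out
  }
  cfg <- merge_checked(config, template)
  if (cfg$effects$lfc <= 0) stop("effects.lfc must be > 0")
  for (a in c(cfg$activity$alpha, cfg$effects$alpha)) {
    if (a <= 0 || a > 1) stop("alpha thresholds must lie in (0, 1]")
  }
  with(cfg$noise, {
    if (sigma_d <= 0 || phi <= 0 || lambda_bc <= 0 || depth <= 0) {
      stop("noise parameters must be positive")
    }
  })
  if (cfg$replicates < 2) stop("need >= 2 replicates")
  cfg
}

#' Run the full synthetic MPRA pipeline
#'
#' Executes every stage in dependency order on synthetic data generated
#' from the config, writing per-stage TSV/FASTA/BED outputs plus a JSON
#' summary whose numbers are recomputed from the stage tables (never
#' cached). Reruns with the same config are identical.
#'
#' @param config Configuration (see \code{\link{default_run_config}});
#'   validated before anything runs.
#' @param out_dir Output directory (created; stage files written inside).
#' @return Invisibly, a list of in-memory stage results plus
#'   \code{summary}.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile()) {
  cfg <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  genome <- stage("genome", make_toy_genome(
    cfg$genome$length, cfg$genome$gc, seed = cfg$seed
  ))
  chrom <- names(genome)[1]

  tiles <- stage("design_tiles", {
    region <- genomic_interval(chrom, cfg$tiling$start, cfg$tiling$end)
    design_tiles(region, genome, cfg$tiling$tile_len, cfg$tiling$step)
  })
  satmut <- stage("design_saturation", {
    region <- genomic_interval(chrom, cfg$saturation$start,
                               cfg$saturation$end)
    design_saturation(region, genome, cfg$saturation$oligo_len,
                      cfg$saturation$del_len)
  })
  variants <- stage("variant_table", make_variant_table(
    genomic_interval(chrom, cfg$variants$start, cfg$variants$end), genome,
    n_snv = cfg$variants$n_snv, n_indel = cfg$variants$n_indel,
    max_indel = cfg$variants$max_indel, n_ac_zero = cfg$variants$n_ac_zero,
    n_oversize = cfg$variants$n_oversize, seed = cfg$seed + 11L
  ))
  vdesign <- stage("design_variants", {
    d <- design_variant_oligos(variants, genome,
                               max_indel = cfg$variants$max_indel)
    d$oligos <- apply_replicate_rule(d$oligos, variants,
                                     cfg$variants$af_threshold)
    d
  })
  scrambles <- stage("scrambles", make_scrambles(
    rbind(satmut[satmut$allele_class == "ref", ], vdesign$oligos),
    n = cfg$controls$n_scrambles, rng_seed = cfg$seed + 23L,
    n_center_sub = cfg$controls$n_center_sub
  ))
  design <- rbind(tiles, satmut, vdesign$oligos, scrambles[names(tiles)])
  write_design(design, tsv_path = file.path(out_dir, "design_manifest.tsv"),
               fasta_path = file.path(out_dir, "design.fasta"))
  write_variant_tsv(variants, file.path(out_dir, "variants.tsv"))

  # per-cell-type landscapes: planted enhancers and variant effects
  ct <- cfg$cell_types
  landscapes <- stage("landscapes", with_seed(cfg$seed + 31L, {
    testable <- unique(vdesign$oligos$variant_key)
    lapply(seq_along(ct$names), function(i) {
      es <- sort(sample(seq(cfg$tiling$start,
                            cfg$tiling$end - ct$enhancer_width),
                        ct$n_enhancers))
      vk <- sample(testable, min(ct$n_variant_effects, length(testable)))
      activity_landscape(
        baseline = 0,
        enhancers = data.frame(chrom = chrom, start = es,
                               end = es + ct$enhancer_width - 1L,
                               effect = ct$enhancer_effect),
        variant_logfc = stats::setNames(
          sample(c(-1, 1), length(vk), replace = TRUE) *
            ct$variant_effect_size, vk)
      )
    })
  }))

  noise <- default_noise_model(cfg$noise$sigma_d, cfg$noise$phi,
                               cfg$noise$lambda_bc, cfg$noise$depth)
  per_ct <- lapply(seq_along(ct$names), function(i) {
    name <- ct$names[i]
    sim <- stage(paste0("simulate_", name), simulate_counts(
      design, landscapes[[i]], noise, cfg$replicates,
      seed = cfg$seed + 100L * i
    ))
    cm <- stage(paste0("quantify_", name), {
      norm <- normalize_counts(sim$counts)
      element_activity(norm, pseudocount = cfg$activity$pseudocount,
                       min_barcodes = cfg$activity$min_barcodes)
    })
    is_null <- cm$element_id %in%
      sim$truth$element_id[sim$truth$is_null]
    res <- stage(paste0("mad_test_", name), mad_test(
      cm[!is_null, ], cm[is_null, ], alpha = cfg$activity$alpha
    ))
    write_activity(res, file.path(out_dir,
                                  sprintf("activity_%s.tsv", name)))
    list(sim = sim, activity = res, null = cm[is_null, ])
  })
  names(per_ct) <- ct$names

  # tiled track: combine strands per window, retest, join into CREs
  cre_by_ct <- lapply(ct$names, function(name) {
    res <- per_ct[[name]]$activity
    tr <- merge(res, tiles[c("oligo_id", "chrom", "start", "end", "strand")],
                by.x = "element_id", by.y = "oligo_id")
    tr$window <- sprintf("%s:%d-%d", tr$chrom, tr$start, tr$end)
    comb <- combine_strands(tr)
    comb_res <- mad_test(comb, per_ct[[name]]$null,
                         alpha = cfg$activity$alpha)
    sig <- comb_res[comb_res$active, , drop = FALSE]
    iv <- if (nrow(sig) > 0) parse_span(sig$element_id) else
      GenomicRanges::GRanges()
    if (length(iv) > 0) {
      S4Vectors::mcols(iv) <- S4Vectors::DataFrame(
        element_id = sig$element_id, log_alpha = sig$log_alpha,
        pval_mad = sig$pval_mad
      )
    }
    cres <- call_cres(iv, adjacency_gap = cfg$cre$adjacency_gap)
    if (length(cres) > 0) {
      write_bed(cres, file.path(out_dir, sprintf("cres_%s.bed", name)))
    }
    list(windows = comb_res, cres = cres)
  })
  names(cre_by_ct) <- ct$names

  # variant track: ref/alt pairing, logFC, calls, sharing
  effects_by_ct <- lapply(ct$names, function(name) {
    res <- per_ct[[name]]$activity
    va <- merge(res, vdesign$oligos[c("oligo_id", "variant_key",
                                      "allele_class", "chrom", "focal_pos")],
                by.x = "element_id", by.y = "oligo_id")
    va <- va[!duplicated(va$element_id), , drop = FALSE]
    cls <- ifelse(
      variants$class[match(va$variant_key, sprintf(
        "%s:%d:%s:%s", variants$chrom, variants$pos, variants$ref,
        variants$alt))] == "snv", "snv", "indel")
    # 2X-represented variants: average copies per allele before pairing
    agg_allele <- function(is_ref) {
      sub <- va[(va$allele_class == "ref") == is_ref, , drop = FALSE]
      acol <- grep("^alpha_[0-9]+$", names(sub), value = TRUE)
      out <- stats::aggregate(sub[acol], by = list(variant_key = sub$variant_key),
                              FUN = function(x) exp(mean(log(x))))
      out
    }
    eff <- variant_logfc(
      agg_allele(TRUE), agg_allele(FALSE),
      variant_class = stats::setNames(cls, va$variant_key),
      lfc = cfg$effects$lfc, alpha = cfg$effects$alpha
    )
    eff$chrom <- va$chrom[match(eff$variant_key, va$variant_key)]
    eff$focal_pos <- va$focal_pos[match(eff$variant_key, va$variant_key)]
    utils::write.table(eff, file.path(out_dir,
                                      sprintf("effects_%s.tsv", name)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    eff
  })
  names(effects_by_ct) <- ct$names

  sharing <- stage("sharing", {
    a <- effects_by_ct[[1]]
    b <- effects_by_ct[[2]]
    keys <- union(a$variant_key, b$variant_key)
    data.frame(
      variant_key = keys,
      sharing = classify_sharing(
        a$call[match(keys, a$variant_key)],
        b$call[match(keys, b$variant_key)],
        labels = ct$names
      ),
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(sharing, file.path(out_dir, "sharing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    n_oligos_designed = nrow(design),
    n_variants_rejected = nrow(vdesign$rejected),
    active_windows = lapply(cre_by_ct, function(x) sum(x$windows$active)),
    n_cres = lapply(cre_by_ct, function(x) length(x$cres)),
    variant_calls = lapply(effects_by_ct, function(e) {
      as.list(table(factor(e$call,
                           levels = c("gain", "loss", "ns", "untestable"))))
    }),
    sharing_classes = as.list(table(sharing$sharing))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(config = cfg, design = design, per_cell_type = per_ct,
                 cres = cre_by_ct, effects = effects_by_ct,
                 sharing = sharing, summary = summary, out_dir = out_dir))
}
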