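# End-to-end orchestration: simulate -> rank -> sequence -> call/refine ->
# staged filters -> sample QC -> thinning -> summaries, with deterministic
# sub-seeding and a hash manifest of all written artifacts.

#' Default pipeline configuration
#'
#' Desk-scale defaults: every stochastic step derives its seed from the
#' master seed, filter thresholds follow the staged QC defaults (MAF 25 %
#' in high-coverage samples, MAF 10 % pedigree-wide, 50 % missingness,
#' 5 bp proximity, >=5 Mendel-error units, 0.6 heterozygous fraction, 5 %
#' missing rate, pruning r-squared 0.1/0.9/0.4 with window 50 and
#' shift 20).
#'
#' @param seed Master integer seed.
#' @param ... Named overrides of any configuration entry.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_founders = 12, n_generations = 3, mean_offspring = 2.2,
    n_chrom = 2, sites_per_chrom = 250, chrom_bp = 5e7,
    map_length_cM = 100, anchors_per_chrom = 8,
    maf_range = c(0.05, 0.5),
    n_high = 4, n_medium = 12,
    tier_depths = c(high = 30, medium = 5, low = 1),
    base_error = 0.01,
    n_decoy_multiallelic = 5,
    stage1_maf_min = 0.25, proximity_bp = 5,
    stage2_maf_min = 0.10, stage2_miss_max = 0.5,
    mendel_max = 5, het_max = 0.6,
    ibd_r2 = 0.1, ibd_min_sites = 50,
    discord_threshold = 0.15, min_discordant = 10,
    skip_stage3_exclusions = FALSE,
    stage4_miss_max = 0.05,
    r2_assoc = 0.9, r2_linkage = 0.4, ld_window = 50, ld_shift = 20
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
  }
  cfg[names(override)] <- override
  class(cfg) <- "run_config"
  cfg
}

#' Read a key=value configuration file
#'
#' Plain-text configuration: one `key = value` per line, `#` comments;
#' vector values are comma-separated. Unknown keys are rejected.
#'
#' @param path Configuration file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- lapply(kv, function(x) {
    v <- strsplit(trimws(paste(x[-1], collapse = "=")), ",")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else if (all(v %in% c("TRUE", "FALSE")))
      as.logical(v) else trimws(v)
  })
  names(vals) <- keys
  if ("tier_depths" %in% keys) {
    vals$tier_depths <- stats::setNames(vals$tier_depths,
                                        c("high", "medium", "low"))
  }
  do.call(default_run_config, vals)
}

write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    paste0(k, " = ", paste(cfg[[k]], collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Splice multi-allelic decoy rows (literal records, not modelled
# variation) into a panel so structural filters have input to count.
add_decoy_sites <- function(panel, n, seed) {
  if (n == 0) return(panel)
  set.seed(seed)
  sites <- panel$sites
  rows <- list()
  taken <- site_key(sites)
  for (k in seq_len(n)) {
    ch <- sample(unique(sites$chrom), 1)
    repeat {
      pos <- sample.int(max(sites$pos[sites$chrom == ch]) + 1000L, 1)
      if (!(paste(ch, pos) %in% taken)) break
    }
    taken <- c(taken, paste(ch, pos))
    rows[[k]] <- data.frame(chrom = ch, pos = pos, ref = "A",
                            alt = if (k %% 2 == 0) "C,G" else "CT",
                            stringsAsFactors = FALSE)
  }
  extra <- do.call(rbind, rows)
  all_sites <- rbind(sites[, c("chrom", "pos", "ref", "alt")], extra)
  ord <- order(all_sites$chrom, all_sites$pos)
  m_extra <- nrow(extra)
  pad <- function(mat, fill) {
    if (is.null(mat)) return(NULL)
    rbind(mat, matrix(fill, m_extra, ncol(mat)))[ord, , drop = FALSE]
  }
  med_dp <- if (!is.null(panel$dp)) as.integer(round(mean(panel$dp))) else NULL
  site_panel(all_sites[ord, , drop = FALSE],
             gt = pad(panel$gt, NA_integer_),
             dp = pad(panel$dp, med_dp),
             ad = pad(panel$ad, 0L),
             samples = panel$samples)
}

site_key <- function(sites) paste(sites$chrom, sites$pos)

#' Run the full synthetic design-and-QC pipeline
#'
#' Executes, in order: pedigree and genome simulation; greedy coverage
#' ranking and tier assignment; read simulation at the planned depths;
#' naive calling; the Stage 1 site-discovery cascade on high-coverage
#' samples; unit-wise trio refinement with consensus genotypes and the
#' Stage 2 cascade; Stage 3 sample QC (LD pruning, pairwise IBD,
#' discordance flagging and exclusion); re-refinement and the Stage 4
#' final cascade; LD thinning into nested association and linkage sets
#' with a pedigree-wide Mendelian check; genetic-map interpolation for the
#' linkage set; and per-chromosome summaries. All artifacts are written to
#' `out_dir` together with a manifest of MD5 hashes; reruns with an
#' identical configuration are byte-identical.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list with elements `manifest` (data.frame `stage`, `file`,
#'   `md5`), `ped`, `plan`, `reports` (stage1/2/4 [filter_report]s),
#'   `flags`, `excluded`, `sets`, `summaries`, and `paths`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  cfg <- config
  ped <- simulate_pedigree(cfg$n_founders, cfg$n_generations,
                           cfg$mean_offspring, seed = cfg$seed)
  n_seq <- sum(ped$sequenced)
  if (cfg$n_high + cfg$n_medium > n_seq) {
    stop("validation error: n_high + n_medium (", cfg$n_high + cfg$n_medium,
         ") exceeds the ", n_seq, " sequenced individuals")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  manifest <- list()
  emit <- function(stage, name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, file = name, md5 = unname(tools::md5sum(p)),
      stringsAsFactors = FALSE)
    paths[[name]] <<- p
    p
  }

  sites <- simulate_sites(cfg$n_chrom, cfg$sites_per_chrom, cfg$chrom_bp,
                          cfg$maf_range, seed = cfg$seed + 1L)
  gmap <- simulate_genetic_map(cfg$n_chrom, cfg$chrom_bp, cfg$map_length_cM,
                               cfg$anchors_per_chrom, seed = cfg$seed + 2L)
  truth <- gene_drop(ped, sites, gmap, seed = cfg$seed + 3L)

  ranking <- greedy_rank(ped)
  plan <- assign_tiers(ranking, cfg$n_high, cfg$n_medium, cfg$tier_depths)
  depths <- stats::setNames(plan$target_depth, plan$id)
  reads <- simulate_reads(truth, depths, cfg$base_error,
                          seed = cfg$seed + 4L)

  naive <- call_naive(reads, base_error = cfg$base_error, prior_maf = 0.2)
  panel0 <- truth_to_panel(truth, reads, gt = naive)
  panel0 <- add_decoy_sites(panel0, cfg$n_decoy_multiallelic,
                            seed = cfg$seed + 5L)

  emit("setup", "pedigree.tsv", function(p) write_pedigree(ped, p))
  emit("setup", "genetic_map.tsv", function(p) write_genetic_map(gmap, p))
  emit("setup", "coverage_plan.tsv", function(p) {
    utils::write.table(plan, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  hc_ids <- plan$id[plan$tier == "high"]
  s1 <- stage1_filter(panel0, hc_ids, maf_min = cfg$stage1_maf_min,
                      proximity_bp = cfg$proximity_bp)
  emit("stage1", "stage1.vcf", function(p) write_panel_vcf(s1$panel, p))
  emit("stage1", "stage1_ledger.tsv", function(p) write_report(s1$report, p))

  units <- decompose_units(ped)
  ridx <- match(site_key(s1$panel$sites), site_key(truth$sites))
  reads1 <- list(dp = reads$dp[ridx, , drop = FALSE],
                 ad = reads$ad[ridx, , drop = FALSE])
  afreq <- rowSums(s1$panel$gt, na.rm = TRUE) /
    pmax(2 * rowSums(!is.na(s1$panel$gt)), 1)
  afreq <- pmin(pmax(afreq, 0.01), 0.99)
  refined <- refine_units(reads1, units, base_error = cfg$base_error,
                          pop_maf = afreq)
  panel_ref <- site_panel(s1$panel$sites, gt = refined$gt[, ped$id[ped$sequenced],
                                                          drop = FALSE],
                          dp = reads1$dp, ad = reads1$ad)
  s2 <- stage2_filter(panel_ref, units, maf_min = cfg$stage2_maf_min,
                      miss_max = cfg$stage2_miss_max,
                      mendel_max = cfg$mendel_max, het_max = cfg$het_max)
  emit("stage2", "stage2.vcf", function(p) write_panel_vcf(s2$panel, p))
  emit("stage2", "stage2_ledger.tsv", function(p) write_report(s2$report, p))

  pruned <- ld_prune_for_ibd(s2$panel, r2_threshold = cfg$ibd_r2,
                             window = cfg$ld_window, shift = cfg$ld_shift)
  ibd <- estimate_ibd_all(subset_sites(s2$panel, pruned),
                          min_sites = cfg$ibd_min_sites)
  flags <- flag_sample_issues(ibd, ped,
                              discord_threshold = cfg$discord_threshold,
                              min_discordant = cfg$min_discordant)
  excluded <- if (cfg$skip_stage3_exclusions) character(0) else
    flags$id[flags$flagged]
  emit("stage3", "ibd_pairs.tsv", function(p) write_ibd(ibd, p))
  emit("stage3", "sample_flags.tsv", function(p) {
    utils::write.table(flags, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  ped2 <- ped
  ped2$sequenced[ped2$id %in% excluded] <- FALSE
  analysis_ids <- ped2$id[ped2$sequenced]
  units2 <- decompose_units(ped2)
  ridx2 <- match(site_key(s2$panel$sites), site_key(truth$sites))
  reads2 <- list(dp = reads$dp[ridx2, analysis_ids, drop = FALSE],
                 ad = reads$ad[ridx2, analysis_ids, drop = FALSE])
  afreq2 <- afreq[match(site_key(s2$panel$sites), site_key(s1$panel$sites))]
  refined2 <- refine_units(reads2, units2, base_error = cfg$base_error,
                           pop_maf = afreq2)
  panel4in <- site_panel(s2$panel$sites,
                         gt = refined2$gt[, analysis_ids, drop = FALSE],
                         dp = reads2$dp, ad = reads2$ad)
  s4 <- stage4_final_filter(panel4in, units2, mendel_max = cfg$mendel_max,
                            het_max = cfg$het_max,
                            miss_max = cfg$stage4_miss_max)
  emit("stage4", "stage4.vcf", function(p) write_panel_vcf(s4$panel, p))
  emit("stage4", "stage4_ledger.tsv", function(p) write_report(s4$report, p))

  sets <- build_mapping_sets(s4$panel, ped2, r2_assoc = cfg$r2_assoc,
                             r2_linkage = cfg$r2_linkage,
                             window = cfg$ld_window, shift = cfg$ld_shift)
  emit("stage4", "association_sites.tsv", function(p) {
    write_site_list(s4$panel, sets$association, p)
  })
  emit("stage4", "linkage_sites.tsv", function(p) {
    write_site_list(s4$panel, sets$linkage, p)
  })
  link_map <- interpolate_map(gmap,
                              s4$panel$sites[sets$linkage,
                                             c("chrom", "pos"),
                                             drop = FALSE])
  emit("stage4", "linkage_map.tsv", function(p) {
    utils::write.table(link_map, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  summaries <- list(association = summarize_panel(s4$panel,
                                                  sets$association),
                    linkage = summarize_panel(s4$panel, sets$linkage))
  emit("stage4", "association_summary.tsv", function(p) {
    utils::write.table(summaries$association, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  emit("stage4", "linkage_summary.tsv", function(p) {
    utils::write.table(summaries$linkage, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  emit("setup", "config.txt", function(p) write_run_config(cfg, p))

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(manifest = manifest, ped = ped, plan = plan,
       reports = list(stage1 = s1$report, stage2 = s2$report,
                      stage4 = s4$report),
       flags = flags, excluded = excluded, sets = sets,
       summaries = summaries, analysis_ids = analysis_ids,
       paths = paths)
}
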