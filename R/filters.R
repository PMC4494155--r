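# Staged variant-QC filter cascades with per-filter accounting ledgers.
# Each stage applies its filters in a frozen order and records, per filter,
# the number of sites removed; conservation (start - sum removed = end)
# holds for every computed cascade.

#' Build a filter report
#'
#' The accounting ledger of a filter cascade: an ordered list of steps
#' with removal counts. When a `printed_total` is supplied (transcribing a
#' published ledger whose rows need not sum exactly to its total), the end
#' count is `start - printed_total` and the row-sum discrepancy is kept
#' available via [report_discrepancy()].
#'
#' @param stage Label, e.g. `"stage1"`.
#' @param start_count Number of sites entering the cascade.
#' @param removed Named integer vector: sites removed per step, in cascade
#'   order.
#' @param printed_total Optional externally stated total removal count.
#' @return An object of class `filter_report` with elements `stage`,
#'   `start_count`, `steps` (data.frame `name`, `removed`,
#'   `remaining_after`), `end_count`, `printed_total`.
#' @export
filter_report <- function(stage, start_count, removed,
                          printed_total = NULL) {
  stopifnot(length(names(removed)) == length(removed),
            all(removed >= 0))
  remaining <- start_count - cumsum(as.numeric(removed))
  steps <- data.frame(name = names(removed),
                      removed = as.numeric(removed),
                      remaining_after = remaining,
                      stringsAsFactors = FALSE)
  total <- if (is.null(printed_total)) sum(steps$removed) else printed_total
  rep <- structure(list(stage = stage, start_count = start_count,
                        steps = steps, end_count = start_count - total,
                        printed_total = printed_total),
                   class = "filter_report")
  validate_filter_report(rep)
  rep
}

#' Validate filter-report conservation
#'
#' Asserts `removed >= 0` for every step and the conservation identity
#' `end_count = start_count - total_removed`, where the total is the row
#' sum (or the printed total when one was transcribed).
#'
#' @param report A [filter_report].
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_filter_report <- function(report) {
  if (any(report$steps$removed < 0)) stop("negative removal count")
  total <- if (is.null(report$printed_total)) sum(report$steps$removed)
           else report$printed_total
  if (report$end_count != report$start_count - total) {
    stop("ledger conservation violated: start - total != end")
  }
  invisible(TRUE)
}

#' Total removals of a filter report
#' @param report A [filter_report].
#' @return The total removal count (printed total when present, otherwise
#'   the row sum).
#' @export
report_total <- function(report) {
  if (is.null(report$printed_total)) sum(report$steps$removed)
  else report$printed_total
}

#' Row-sum discrepancy of a transcribed ledger
#'
#' Difference between the sum of per-step removals and the stated total
#' (0 for computed reports).
#'
#' @param report A [filter_report].
#' @return `sum(removed) - total`.
#' @export
report_discrepancy <- function(report) {
  sum(report$steps$removed) - report_total(report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Render a filter report as TSV text
#'
#' Emits a caption line (`# <stage> started with X sites and ended with Y
#' sites`), a `procedure\tremoved` header, one row per step, and a `TOTAL`
#' row.
#'
#' @param report A [filter_report].
#' @return Character vector of lines.
#' @seealso [parse_report()] for the inverse.
#' @export
render_report <- function(report) {
  c(sprintf("# %s started with %.0f sites and ended with %.0f sites",
            report$stage, report$start_count, report$end_count),
    "procedure\tremoved",
    sprintf("%s\t%.0f", report$steps$name, report$steps$removed),
    sprintf("TOTAL\t%.0f", report_total(report)))
}

#' Parse a rendered filter report
#'
#' Inverse of [render_report()]: `parse_report(render_report(x))`
#' reproduces `x`.
#'
#' @param lines Character vector of lines, or a file path.
#' @return A [filter_report].
#' @export
parse_report <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  cap <- regmatches(lines[1],
    regexec("^# (\\S+) started with (\\d+) sites and ended with (\\d+) sites",
            lines[1]))[[1]]
  if (length(cap) != 4) stop("unparseable report caption")
  body <- lines[-(1:2)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1)
  val <- as.numeric(vapply(parts, `[`, "", 2))
  is_total <- nm == "TOTAL"
  removed <- stats::setNames(val[!is_total], nm[!is_total])
  total <- val[is_total][1]
  filter_report(stage = cap[2], start_count = as.numeric(cap[3]),
                removed = removed,
                printed_total = if (isTRUE(all.equal(total, sum(removed))))
                  NULL else total)
}

#' Write a filter report to a file
#' @param report A [filter_report].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  writeLines(render_report(report), path)
  invisible(path)
}

is_multiallelic <- function(sites) {
  grepl(",", sites$alt, fixed = TRUE) | nchar(sites$ref) > 1 |
    nchar(sites$alt) > 1
}

coverage_window_fail <- function(panel, median_ref = NULL) {
  cumdp <- rowSums(panel$dp)
  med <- if (is.null(median_ref)) stats::median(cumdp) else median_ref
  cumdp < med / 2 | cumdp > 2 * med
}

#' Stage 1 filter cascade: unequivocal segregating sites
#'
#' Applies, in order: (1) removal of multi-allelic or multi-nucleotide
#' records; (2) removal of sites whose cumulative depth across samples
#' falls outside the twofold range `[m/2, 2m]` of the global per-site
#' median `m` (boundaries retained); (3) removal of sites with MAF below
#' `maf_min` among the high-coverage samples; (4) removal of sites with
#' any missing call among the high-coverage samples; (5) removal of both
#' members of any surviving pair of sites within `proximity_bp` base pairs
#' on the same chromosome.
#'
#' @param panel A [site_panel] with depth matrices.
#' @param hc_ids High-coverage sample ids (non-empty, all in the panel).
#' @param maf_min MAF threshold (default 0.25; strict `<` removal).
#' @param proximity_bp Proximity threshold in bp (default 5; `<=` removal).
#' @return A list `(panel, report)`: the filtered panel and its
#'   [filter_report].
#' @export
stage1_filter <- function(panel, hc_ids, maf_min = 0.25, proximity_bp = 5) {
  if (length(hc_ids) == 0) stop("hc_ids must be non-empty")
  stopifnot(all(hc_ids %in% panel$samples), !is.null(panel$dp))
  start <- n_sites(panel)
  removed <- c()
  drop_step <- function(p, bad, name) {
    removed[[name]] <<- sum(bad)
    subset_sites(p, !bad)
  }
  panel <- drop_step(panel, is_multiallelic(panel$sites),
                     "multiallelic or multinucleotide")
  panel <- drop_step(panel, coverage_window_fail(panel),
                     "cumulative coverage outside twofold range of median")
  panel <- drop_step(panel, panel_maf(panel, hc_ids) < maf_min,
                     sprintf("MAF in high-coverage samples < %g", maf_min))
  panel <- drop_step(panel,
                     rowSums(is.na(panel$gt[, hc_ids, drop = FALSE])) > 0,
                     "missing data in high-coverage samples")
  near <- proximity_fail(panel$sites, proximity_bp)
  panel <- drop_step(panel, near,
                     sprintf("within %d bp of another site", proximity_bp))
  list(panel = panel,
       report = filter_report("stage1", start, unlist(removed)))
}

# TRUE for sites within `bp` of a neighbouring site on the same chromosome
# (both members of a close pair are flagged).
proximity_fail <- function(sites, bp) {
  bad <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    if (length(i) < 2) next
    gap <- diff(sites$pos[i])
    close_prev <- c(FALSE, gap <= bp)
    close_next <- c(gap <= bp, FALSE)
    bad[i] <- close_prev | close_next
  }
  bad
}

#' Stage 2 filter cascade: pedigree-wide genotype QC
#'
#' Applies, in order: a read-level caller-filter pass-through step
#' (recorded with zero removals: no alignment layer exists for synthetic
#' panels, the ledger row is kept for structural fidelity); the cumulative
#' coverage twofold-median window; MAF below `maf_min` over `maf_ids`
#' (default: all samples); missing-call fraction above `miss_max`; per-site
#' Mendelian errors in `mendel_max` or more nuclear units; heterozygous
#' fraction strictly above `het_max`; and sex-chromosome exclusion.
#'
#' @param panel A [site_panel] (normally the Stage 1 survivors, with
#'   genotypes called in all samples).
#' @param units A `nuclear_units` table for the Mendelian check.
#' @param maf_ids Samples over which the MAF is estimated (default all).
#' @param maf_min MAF threshold (default 0.10).
#' @param miss_max Missingness ceiling (default 0.5; strict `>` removal).
#' @param mendel_max Mendel-error unit count triggering removal (default 5;
#'   `>=` removal).
#' @param het_max Heterozygous-fraction ceiling (default 0.6; strict `>`).
#' @param sex_chroms Chromosome labels treated as sex chromosomes.
#' @return A list `(panel, report)`.
#' @export
stage2_filter <- function(panel, units, maf_ids = NULL, maf_min = 0.10,
                          miss_max = 0.5, mendel_max = 5, het_max = 0.6,
                          sex_chroms = c("X", "Y", "chrX", "chrY")) {
  start <- n_sites(panel)
  removed <- c()
  drop_step <- function(p, bad, name) {
    removed[[name]] <<- sum(bad)
    subset_sites(p, !bad)
  }
  panel <- drop_step(panel, rep(FALSE, n_sites(panel)),
                     "read-level caller filters (pass-through)")
  panel <- drop_step(panel, coverage_window_fail(panel),
                     "cumulative coverage outside twofold range of median")
  panel <- drop_step(panel, panel_maf(panel, maf_ids) < maf_min,
                     sprintf("MAF < %g", maf_min))
  panel <- drop_step(panel, missing_fraction(panel) > miss_max,
                     sprintf("missing > %g%% of calls", 100 * miss_max))
  panel <- drop_step(panel, site_mendel_counts(panel$gt, units) >= mendel_max,
                     sprintf(">=%d Mendel errors in parent-child comparisons",
                             mendel_max))
  hf <- het_fraction(panel)
  hf[is.nan(hf)] <- 0
  panel <- drop_step(panel, hf > het_max,
                     sprintf(">%g%% heterozygous calls", 100 * het_max))
  panel <- drop_step(panel, panel$sites$chrom %in% sex_chroms,
                     "sex chromosome sites")
  list(panel = panel,
       report = filter_report("stage2", start, unlist(removed)))
}

#' Stage 4 final filters before panel thinning
#'
#' Applies, in order: (1) removal of sites with Mendelian errors in
#' `mendel_max` or more nuclear units; (2) removal of sites with
#' heterozygous fraction strictly above `het_max`; (3) masking of the
#' remaining sporadic Mendelian-error genotypes -- the child call (and
#' only the child's) is set missing at each violating unit/site; (4)
#' removal of sites whose missing-call rate then exceeds `miss_max`.
#' Step 3 removes no sites; its ledger row records 0 and the number of
#' masked genotypes is attached to the report as attribute
#' `"masked_genotypes"`.
#'
#' @param panel A [site_panel] of refined genotypes.
#' @param units A `nuclear_units` table.
#' @param mendel_max Mendel-error unit threshold (default 5, `>=`).
#' @param het_max Heterozygous-fraction ceiling (default 0.6, strict `>`).
#' @param miss_max Missing-rate ceiling after masking (default 0.05,
#'   strict `>`).
#' @return A list `(panel, report)`.
#' @export
stage4_final_filter <- function(panel, units, mendel_max = 5, het_max = 0.6,
                                miss_max = 0.05) {
  start <- n_sites(panel)
  removed <- c()
  drop_step <- function(p, bad, name) {
    removed[[name]] <<- sum(bad)
    subset_sites(p, !bad)
  }
  panel <- drop_step(panel, site_mendel_counts(panel$gt, units) >= mendel_max,
                     sprintf(">=%d Mendel errors in parent-child comparisons",
                             mendel_max))
  hf <- het_fraction(panel)
  hf[is.nan(hf)] <- 0
  panel <- drop_step(panel, hf > het_max,
                     sprintf("heterozygous fraction > %g", het_max))
  masked <- 0L
  for (r in seq_len(nrow(units))) {
    if (units$kind[r] == "singleton") next
    fa <- units$father[r]
    mo <- units$mother[r]
    me <- mendel_errors(
      child = panel$gt[, units$child[r]],
      father = if (!is.na(fa)) panel$gt[, fa],
      mother = if (!is.na(mo)) panel$gt[, mo]
    )
    v <- which(me$violation)
    if (length(v) > 0) {
      panel$gt[v, units$child[r]] <- NA_integer_
      masked <- masked + length(v)
    }
  }
  removed[["sporadic Mendel-error genotypes masked (site removals)"]] <- 0L
  panel <- drop_step(panel, missing_fraction(panel) > miss_max,
                     sprintf("missing rate > %g%%", 100 * miss_max))
  report <- filter_report("stage4", start, unlist(removed))
  attr(report, "masked_genotypes") <- masked
  list(panel = panel, report = report)
}
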