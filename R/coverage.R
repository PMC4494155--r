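# Hierarchical sequencing-coverage design: greedy ranking of pedigree
# members by marginal gain in newly covered offspring, tier assignment, and
# the in-silico down-sampling harness that evaluates coverage schemes by
# trio Mendelian error and concordance.

#' Greedy coverage ranking of pedigree members
#'
#' Ranks the sequenced members of a pedigree by the impact their deep
#' sequencing would have on pedigree-wide genotype accuracy. The pedigree
#' graph is first restricted to sequenced individuals. A growing
#' offspring-set of unique child ids is maintained; at each step the
#' individual whose direct (sequenced) children add the most NEW ids to
#' the offspring-set receives the next rank (rank 1 = highest priority).
#' Ties are broken by older birth year first (unknown years sort last),
#' then by id.
#'
#' @param ped A [pedigree].
#' @param sequenced Character vector of sequenced ids; defaults to the
#'   pedigree's `sequenced` flag.
#' @return Character vector: ids in rank order (rank 1 first), with the
#'   per-step marginal gains attached as the `"gain"` attribute.
#' @export
greedy_rank <- function(ped, sequenced = NULL) {
  if (is.null(sequenced)) sequenced <- ped$id[ped$sequenced]
  stopifnot(all(sequenced %in% ped$id))
  kids <- lapply(sequenced, function(id) {
    intersect(direct_children(ped, id), sequenced)
  })
  names(kids) <- sequenced
  byear <- ped$birth_year[match(sequenced, ped$id)]
  names(byear) <- sequenced
  remaining <- sort(sequenced)
  offspring <- character(0)
  ranking <- character(0)
  gains <- integer(0)
  while (length(remaining) > 0) {
    gain <- vapply(remaining, function(id) {
      length(setdiff(kids[[id]], offspring))
    }, integer(1))
    top <- remaining[gain == max(gain)]
    yr <- byear[top]
    yr[is.na(yr)] <- Inf
    pick <- top[order(yr, top)][1]
    ranking <- c(ranking, pick)
    gains <- c(gains, max(gain))
    offspring <- union(offspring, kids[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  attr(ranking, "gain") <- gains
  ranking
}

#' Assign coverage tiers from a ranking
#'
#' The first `n_high` ranked individuals get the high tier, the next
#' `n_medium` the medium tier, and the remainder the low tier.
#'
#' @param ranking Ordered id vector from [greedy_rank()].
#' @param n_high,n_medium Tier sizes (non-negative,
#'   `n_high + n_medium <= length(ranking)`).
#' @param target_depth Named numeric vector of per-tier mean target depths.
#' @return A data.frame of class `coverage_plan` with columns `id`, `rank`,
#'   `tier`, `target_depth`.
#' @export
assign_tiers <- function(ranking, n_high, n_medium,
                         target_depth = c(high = 30, medium = 5, low = 1)) {
  if (n_high < 0 || n_medium < 0) stop("tier sizes must be non-negative")
  n <- length(ranking)
  if (n_high + n_medium > n) {
    stop("n_high + n_medium exceeds the number of ranked individuals")
  }
  tier <- rep("low", n)
  if (n_high > 0) tier[seq_len(n_high)] <- "high"
  if (n_medium > 0) tier[n_high + seq_len(n_medium)] <- "medium"
  plan <- data.frame(id = ranking, rank = seq_len(n), tier = tier,
                     target_depth = unname(target_depth[tier]),
                     stringsAsFactors = FALSE)
  class(plan) <- c("coverage_plan", "data.frame")
  plan
}

#' In-silico down-sampling of one individual's reads
#'
#' Uniformly retains a fraction `target_depth / achieved_depth` of the
#' individual's reads at every site: the kept depth is binomially thinned
#' and the kept alt-read count follows by a hypergeometric draw (reads are
#' exchangeable), leaving the alt fraction unchanged in expectation. Other
#' individuals are untouched.
#'
#' @param reads A `read_data` object.
#' @param id Sample id to down-sample.
#' @param target_depth Target mean depth; must not exceed the achieved
#'   mean depth of `id`.
#' @param seed Integer seed.
#' @return A new `read_data` object.
#' @export
downsample_reads <- function(reads, id, target_depth, seed = 1) {
  stopifnot(id %in% colnames(reads$dp))
  achieved <- mean(reads$dp[, id])
  if (target_depth > achieved) {
    stop("target depth ", target_depth, " exceeds achieved mean depth ",
         round(achieved, 2), " of ", id)
  }
  f <- target_depth / achieved
  set.seed(seed)
  dp <- reads$dp[, id]
  ad <- reads$ad[, id]
  ndp <- stats::rbinom(length(dp), dp, f)
  nad <- stats::rhyper(length(dp), m = ad, n = dp - ad, k = ndp)
  out <- reads
  out$dp[, id] <- ndp
  out$ad[, id] <- nad
  out
}

#' Evaluate a down-sampling scheme on a trio
#'
#' Repeatedly thins the trio members' reads to the per-role target depths,
#' re-calls genotypes, and measures (i) the trio Mendelian inconsistency
#' rate of the re-called genotypes and (ii) per-role concordance of the
#' trio-refined calls against the refined calls from the full-depth data.
#' The Mendelian rate is measured on the single-sample maximum-posterior
#' calls: the trio-constrained refiner enforces Mendelian consistency by
#' construction, so coverage-driven inconsistencies are only visible
#' before the constraint is applied. Reported metrics are means over
#' replicates.
#'
#' @param reads A `read_data` object for the full-depth trio.
#' @param unit One row of a `nuclear_units` table (must be a trio).
#' @param scheme Named numeric vector `c(father=, mother=, child=)` of
#'   target depths; each must not exceed that member's achieved depth.
#' @param replicates Number of down-sampling replicates (default 3).
#' @param base_error Per-read allele miscall probability used in calling.
#' @param pop_maf Alt-allele frequency prior (scalar or per-site).
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @return A list of class `trio_metrics`: `mendelian_inconsistency_rate`
#'   (mean), `baseline_mendel_rate`, `concordance` (named father/mother/
#'   child means), and `per_replicate` (data.frame of per-replicate
#'   values).
#' @export
evaluate_scheme <- function(reads, unit, scheme, replicates = 3,
                            base_error = 0.01, pop_maf = 0.2, seed = 1) {
  if (unit$kind != "trio") {
    stop("down-sampling evaluation requires a trio unit, got ", unit$kind)
  }
  stopifnot(all(c("father", "mother", "child") %in% names(scheme)),
            replicates >= 1)
  roles <- c(father = unit$father, mother = unit$mother, child = unit$child)
  base_ref <- refine_trio(reads, child = roles["child"],
                          father = roles["father"], mother = roles["mother"],
                          base_error = base_error, pop_maf = pop_maf)
  base_naive <- call_naive(
    list(dp = reads$dp[, roles, drop = FALSE],
         ad = reads$ad[, roles, drop = FALSE]),
    base_error = base_error, prior_maf = pop_maf)
  baseline_rate <- mendel_errors(base_naive[, roles["child"]],
                                 base_naive[, roles["father"]],
                                 base_naive[, roles["mother"]])$rate
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    thin <- reads
    for (role in names(roles)) {
      target <- scheme[[role]]
      achieved <- mean(thin$dp[, roles[[role]]])
      if (target < achieved) {
        thin <- downsample_reads(thin, roles[[role]], target,
                                 seed = seed + 7L * r + match(role,
                                                              names(roles)))
      }
    }
    naive <- call_naive(
      list(dp = thin$dp[, roles, drop = FALSE],
           ad = thin$ad[, roles, drop = FALSE]),
      base_error = base_error, prior_maf = pop_maf)
    mend <- mendel_errors(naive[, roles["child"]], naive[, roles["father"]],
                          naive[, roles["mother"]])$rate
    ref <- refine_trio(thin, child = roles["child"], father = roles["father"],
                       mother = roles["mother"], base_error = base_error,
                       pop_maf = pop_maf)
    conc <- vapply(names(roles), function(role) {
      genotype_concordance(ref$gt[[roles[[role]]]],
                           base_ref$gt[[roles[[role]]]])
    }, numeric(1))
    rows[[r]] <- data.frame(replicate = r, mendel_rate = mend,
                            conc_father = conc[["father"]],
                            conc_mother = conc[["mother"]],
                            conc_child = conc[["child"]])
  }
  per_rep <- do.call(rbind, rows)
  structure(list(
    mendelian_inconsistency_rate = mean(per_rep$mendel_rate),
    baseline_mendel_rate = baseline_rate,
    concordance = c(father = mean(per_rep$conc_father),
                    mother = mean(per_rep$conc_mother),
                    child = mean(per_rep$conc_child)),
    per_replicate = per_rep
  ), class = "trio_metrics")
}
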