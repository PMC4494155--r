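# Sample-level QC: sliding-window LD pruning, method-of-moments IBD
# estimation from IBS counts, discordance flagging against pedigree
# kinship, and four-rule parentage assignment.

# One pruning pass: windows of `window` sites (shifted by `shift`) over the
# current retained list; within a window, scanning sites left to right, a
# site is dropped when a still-retained earlier site in the window has
# squared dosage correlation above the threshold. Monomorphic sites yield
# undefined correlations and are never treated as violating.
ld_prune_pass <- function(gt, retained, r2_threshold, window, shift) {
  keep <- rep(TRUE, length(retained))
  starts <- unique(c(seq(1, max(length(retained) - window + 1, 1), by = shift),
                     max(length(retained) - window + 1, 1)))
  for (s in starts) {
    idx <- s:min(s + window - 1, length(retained))
    if (length(idx) < 2) next
    sub <- t(gt[retained[idx], , drop = FALSE])
    r2 <- suppressWarnings(stats::cor(sub,
                                      use = "pairwise.complete.obs"))^2
    for (jj in seq_along(idx)[-1]) {
      if (!keep[idx[jj]]) next
      earlier <- idx[seq_len(jj - 1)]
      earlier <- earlier[keep[earlier]]
      if (length(earlier) == 0) next
      v <- r2[match(earlier, idx), jj]
      if (any(v > r2_threshold, na.rm = TRUE)) keep[idx[jj]] <- FALSE
    }
  }
  retained[keep]
}

#' Sliding-window LD pruning
#'
#' Greedy pruning of sites in linkage disequilibrium, per chromosome:
#' within each window of `window` consecutive retained sites the later
#' member of any pair with squared genotype-dosage correlation above
#' `r2_threshold` is removed; windows shift by `shift` sites and passes
#' repeat until a fixpoint, so no retained within-window pair exceeds the
#' threshold. r-squared is the squared Pearson correlation of dosages over
#' pairwise-complete samples (composite LD); monomorphic sites have
#' undefined correlation and are never removed on its account.
#'
#' @param panel A [site_panel].
#' @param r2_threshold Squared-correlation ceiling in `(0, 1]`.
#' @param window Window size in SNPs.
#' @param shift Window shift in SNPs.
#' @return Integer vector of retained site indices (ascending).
#' @export
ld_prune <- function(panel, r2_threshold, window = 50, shift = 20) {
  if (r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must lie in (0, 1]")
  }
  retained_all <- integer(0)
  for (ch in unique(panel$sites$chrom)) {
    retained <- which(panel$sites$chrom == ch)
    repeat {
      nxt <- ld_prune_pass(panel$gt, retained, r2_threshold, window, shift)
      if (length(nxt) == length(retained)) break
      retained <- nxt
    }
    retained_all <- c(retained_all, retained)
  }
  sort(retained_all)
}

#' LD pruning for IBD estimation
#'
#' Convenience wrapper around [ld_prune()] at the stringent threshold used
#' to obtain a roughly independent SNP set for pairwise IBD estimation
#' (r-squared <= 0.1, window 50, shift 20).
#'
#' @param panel A [site_panel].
#' @param r2_threshold,window,shift See [ld_prune()].
#' @return Integer vector of retained site indices.
#' @export
ld_prune_for_ibd <- function(panel, r2_threshold = 0.1, window = 50,
                             shift = 20) {
  ld_prune(panel, r2_threshold, window, shift)
}

#' Method-of-moments IBD estimation for all sample pairs
#'
#' Estimates, for every pair of samples, the probabilities (Z0, Z1, Z2) of
#' sharing 0/1/2 alleles identical by descent, from observed
#' identity-by-state counts and their allele-frequency expectations:
#' `Z0 = N(IBS0)/E(IBS0|IBD0)`,
#' `Z1 = (N(IBS1) - Z0 E(IBS1|IBD0)) / E(IBS1|IBD1)`, and
#' `Z2` by complement, each expectation summed over the sites the pair
#' jointly calls; estimates are then projected onto the probability
#' simplex. The relatedness summary is `pi_hat = Z1/2 + Z2`. Allele
#' frequencies are sample frequencies from the supplied (pruned) panel;
#' no small-sample bias correction is applied.
#'
#' @param panel A [site_panel], normally restricted to LD-pruned sites.
#' @param min_sites Pairs with fewer jointly called sites are flagged
#'   unreliable (default 100).
#' @return A data.frame with columns `id1`, `id2`, `Z0`, `Z1`, `Z2`,
#'   `PI_HAT`, `n_sites`, `reliable` -- column-compatible with the common
#'   pairwise-IBD tabular layout.
#' @export
estimate_ibd_all <- function(panel, min_sites = 100) {
  g <- panel$gt
  ids <- panel$samples
  p <- rowSums(g, na.rm = TRUE) / pmax(2 * rowSums(!is.na(g)), 1)
  p <- pmin(pmax(p, 1e-3), 1 - 1e-3)
  q <- 1 - p
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e2_ibd1 <- 1 - e1_ibd1
  M <- (!is.na(g)) * 1
  H0 <- (g == 0L & !is.na(g)) * 1
  H1 <- (g == 1L & !is.na(g)) * 1
  H2 <- (g == 2L & !is.na(g)) * 1
  N <- crossprod(M)
  n0 <- crossprod(H0, H2) + crossprod(H2, H0)
  n2 <- crossprod(H0) + crossprod(H1) + crossprod(H2)
  n1 <- N - n0 - n2
  E0 <- crossprod(M * e0_ibd0, M)
  E1 <- crossprod(M * e1_ibd0, M)
  E2 <- crossprod(M * e2_ibd0, M)
  F1 <- crossprod(M * e1_ibd1, M)
  F2 <- crossprod(M * e2_ibd1, M)
  z0 <- n0 / pmax(E0, .Machine$double.eps)
  z1 <- (n1 - z0 * E1) / pmax(F1, .Machine$double.eps)
  z2 <- (n2 - z0 * E2 - z1 * F2) / pmax(N, 1)
  pairs <- which(upper.tri(N) | (row(N) == col(N)), arr.ind = TRUE)
  Z <- cbind(z0[pairs], z1[pairs], z2[pairs])
  Z[Z < 0] <- 0
  Z[Z > 1] <- 1
  Z <- Z / pmax(rowSums(Z), .Machine$double.eps)
  out <- data.frame(
    id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
    Z0 = Z[, 1], Z1 = Z[, 2], Z2 = Z[, 3],
    PI_HAT = pmin(pmax(Z[, 3] + Z[, 2] / 2, 0), 1),
    n_sites = N[pairs],
    reliable = N[pairs] >= min_sites,
    stringsAsFactors = FALSE
  )
  out
}

#' IBD estimate for a single pair
#'
#' @param panel A [site_panel] (LD-pruned).
#' @param id1,id2 Sample ids (a sample may be paired with itself).
#' @param min_sites Reliability floor on jointly called sites.
#' @return One-row data.frame as in [estimate_ibd_all()].
#' @export
estimate_ibd <- function(panel, id1, id2, min_sites = 100) {
  all_est <- estimate_ibd_all(panel, min_sites = min_sites)
  hit <- (all_est$id1 == id1 & all_est$id2 == id2) |
    (all_est$id1 == id2 & all_est$id2 == id1)
  all_est[which(hit)[1], , drop = FALSE]
}

#' Flag samples with pedigree-discordant relatedness
#'
#' Compares each pair's estimated `PI_HAT` with twice the pedigree kinship
#' coefficient; a pair is discordant when the absolute difference exceeds
#' `discord_threshold`. Samples in the top tail of discordant-pair counts
#' -- at least `min_discordant` discordant pairs in excess of the cohort
#' median count, which absorbs any panel-wide miscalibration of the moment
#' estimator -- are flagged as suspected contamination or mislabeling, as
#' are samples whose external genotype concordance falls below
#' `concordance_floor`.
#'
#' @param ibd Pairwise estimates from [estimate_ibd_all()].
#' @param ped The [pedigree] providing expected kinship.
#' @param discord_threshold Absolute `|PI_HAT - 2 phi|` threshold
#'   (default 0.15).
#' @param min_discordant Discordant-pair count, in excess of the cohort
#'   median, that triggers a flag (default 10).
#' @param external_concordance Optional named per-sample concordance rates
#'   against an independent genotype set.
#' @param concordance_floor Concordance below this adds a flag
#'   (default 0.9).
#' @return A data.frame `id`, `n_discordant`, `flag_ibd`,
#'   `flag_concordance`, `flagged`, one row per sample appearing in `ibd`.
#' @export
flag_sample_issues <- function(ibd, ped, discord_threshold = 0.15,
                               min_discordant = 10,
                               external_concordance = NULL,
                               concordance_floor = 0.9) {
  phi <- kinship_matrix(ped)
  off <- ibd[ibd$id1 != ibd$id2 & ibd$reliable, , drop = FALSE]
  expected <- 2 * phi[cbind(off$id1, off$id2)]
  discord <- abs(off$PI_HAT - expected) > discord_threshold
  ids <- sort(unique(c(ibd$id1, ibd$id2)))
  n_disc <- vapply(ids, function(id) {
    sum(discord[off$id1 == id | off$id2 == id])
  }, integer(1))
  flag_ibd <- n_disc - stats::median(n_disc) >= min_discordant
  flag_conc <- rep(FALSE, length(ids))
  if (!is.null(external_concordance)) {
    hit <- ids %in% names(external_concordance)
    flag_conc[hit] <- external_concordance[ids[hit]] < concordance_floor
  }
  data.frame(id = ids, n_discordant = n_disc, flag_ibd = flag_ibd,
             flag_concordance = flag_conc,
             flagged = flag_ibd | flag_conc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rule-based parentage assignment from pairwise IBD
#'
#' For each individual of unknown parentage, candidate parents must show
#' parent-offspring-level IBD sharing (`PI_HAT` within `pihat_window` and
#' `Z0` below `z0_max`); candidate mothers additionally require a
#' behavioral record match and candidate fathers a housing record match
#' (when a records table is supplied -- otherwise these rules are skipped
#' and the call is marked provisional); and the candidate must be older
#' than the child by an age difference within `age_range` years. If more
#' than one same-sex candidate survives all rules, that parent is left
#' unresolved. A candidate not older than the child is never assigned,
#' regardless of genetic evidence.
#'
#' @param children Ids whose parentage is to be assigned.
#' @param ibd Pairwise estimates from [estimate_ibd_all()].
#' @param ped The [pedigree] (provides sex and birth year of candidates).
#' @param records Optional data.frame with columns `child`, `candidate`,
#'   `type` (`"behavior"` or `"housing"`); a row means the record is
#'   compatible with that candidate parenting that child.
#' @param pihat_window Parent-offspring `PI_HAT` acceptance window.
#' @param z0_max Ceiling on `Z0` for a parent-offspring pair.
#' @param age_range Allowed parent-minus-child age difference in years.
#' @return A data.frame of class `parentage_calls` with columns `child`,
#'   `mother`, `father` (NA when unresolved), `mother_n_candidates`,
#'   `father_n_candidates`, `provisional`.
#' @export
assign_parentage <- function(children, ibd, ped, records = NULL,
                             pihat_window = c(0.35, 0.65), z0_max = 0.1,
                             age_range = c(4, 15)) {
  if (is.null(records)) {
    warning("no records table supplied; behavioral/housing rules skipped, ",
            "assignments are provisional")
  }
  off <- ibd[ibd$id1 != ibd$id2 & ibd$reliable, , drop = FALSE]
  rows <- lapply(children, function(ch) {
    hit <- off$id1 == ch | off$id2 == ch
    cand <- ifelse(off$id1[hit] == ch, off$id2[hit], off$id1[hit])
    po <- off$PI_HAT[hit] >= pihat_window[1] &
      off$PI_HAT[hit] <= pihat_window[2] & off$Z0[hit] < z0_max
    cand <- cand[po]
    info <- match(cand, ped$id)
    by_child <- ped$birth_year[match(ch, ped$id)]
    agediff <- by_child - ped$birth_year[info]
    age_ok <- !is.na(agediff) & agediff >= age_range[1] &
      agediff <= age_range[2]
    # hard guard: a candidate not strictly older is never assignable
    age_ok <- age_ok & (!is.na(agediff) & agediff > 0)
    pick <- function(sex, rec_type) {
      k <- cand[ped$sex[info] == sex & age_ok]
      if (!is.null(records)) {
        ok <- records$child == ch & records$type == rec_type
        k <- k[k %in% records$candidate[ok]]
      }
      k
    }
    moms <- pick("F", "behavior")
    dads <- pick("M", "housing")
    data.frame(
      child = ch,
      mother = if (length(moms) == 1) moms else NA_character_,
      father = if (length(dads) == 1) dads else NA_character_,
      mother_n_candidates = length(moms),
      father_n_candidates = length(dads),
      provisional = is.null(records),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("parentage_calls", "data.frame")
  out
}

#' Write pairwise IBD estimates as TSV
#' @param ibd Data.frame from [estimate_ibd_all()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ibd <- function(ibd, path) {
  utils::write.table(ibd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
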