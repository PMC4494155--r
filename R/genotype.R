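# Genotype calling from read counts, trio-constrained refinement over the
# 27 joint genotype configurations, consensus haplotypes from replicated
# units, and Mendelian-error accounting.

# Per-site log-likelihood matrix (sites x 3) for genotypes 0/1/2 given
# depth/alt-read vectors. Depth 0 yields a flat likelihood.
genotype_loglik <- function(dp, ad, base_error) {
  p <- c(base_error, 0.5, 1 - base_error)
  out <- sapply(p, function(pp) stats::dbinom(ad, dp, pp, log = TRUE))
  if (!is.matrix(out)) out <- matrix(out, ncol = 3)
  out
}

hw_logprior <- function(maf, m) {
  q <- rep_len(maf, m)
  log(cbind((1 - q)^2, 2 * q * (1 - q), q^2))
}

#' Naive single-sample genotype calling
#'
#' Maximum-posterior calls per sample per site: binomial read-count
#' likelihoods for alt-allele dosage 0/1/2 with per-read error
#' `base_error`, combined with a Hardy-Weinberg prior at `prior_maf`.
#' Sites with zero depth are missing. Posterior ties resolve to the lower
#' dosage.
#'
#' @param reads A `read_data` object (or a list with matrices `dp`, `ad`).
#' @param base_error Per-read allele miscall probability in `(0, 0.5)`.
#' @param prior_maf Alt-allele frequency for the prior: a scalar or a
#'   per-site vector.
#' @return Integer genotype matrix (sites x samples), values 0/1/2/NA.
#' @export
call_naive <- function(reads, base_error = 0.01, prior_maf = 0.2) {
  stopifnot(base_error > 0, base_error < 0.5)
  dp <- reads$dp
  ad <- reads$ad
  m <- nrow(dp)
  lp <- hw_logprior(prior_maf, m)
  gt <- matrix(NA_integer_, m, ncol(dp), dimnames = dimnames(dp))
  for (j in seq_len(ncol(dp))) {
    post <- genotype_loglik(dp[, j], ad[, j], base_error) + lp
    gt[, j] <- max.col(post, ties.method = "first") - 1L
  }
  gt[dp == 0L] <- NA_integer_
  gt
}

# Enumeration order of the 27 trio configurations: index = 9 gf + 3 gm + gc
# (0-based); ties in the joint posterior resolve to the smallest index.
trio_configs <- local({
  cfg <- expand.grid(gc = 0:2, gm = 0:2, gf = 0:2)[, c("gf", "gm", "gc")]
  t_alt <- function(g) g / 2
  tf <- t_alt(cfg$gf)
  tm <- t_alt(cfg$gm)
  trans <- cbind((1 - tf) * (1 - tm),
                 tf * (1 - tm) + (1 - tf) * tm,
                 tf * tm)
  cfg$log_trans <- log(trans[cbind(seq_len(27), cfg$gc + 1L)])
  cfg
})

#' Trio-constrained genotype refinement
#'
#' Refines the calls of a nuclear unit by exact maximization of the joint
#' posterior over the 27 (trio) genotype configurations: Hardy-Weinberg
#' priors on parental genotypes, Mendelian transmission probabilities for
#' the child, and binomial read-count likelihoods for every member. A
#' missing parent (duo or singleton unit) is marginalized as an unrelated
#' population member, which reduces the model to the 9-configuration duo
#' (or single-sample) posterior. Members with zero depth at a site
#' contribute a flat likelihood there, so their refined call is imputed
#' from the other members and the prior -- refinement returns a complete
#' call set, mirroring pedigree-aware imputation.
#'
#' At sites where all members have reads, the refined configuration has
#' non-zero transmission probability, so refinement never introduces a
#' Mendelian inconsistency.
#'
#' @param reads A `read_data` object covering the unit members.
#' @param child Child sample id.
#' @param father,mother Parent sample ids, or `NA` when absent from the
#'   unit.
#' @param base_error Per-read allele miscall probability.
#' @param pop_maf Population alt-allele frequency (scalar or per-site).
#' @return A list with `gt` (named list of refined dosage vectors for the
#'   members present) and `haps` (named list of two-column 0/1 haplotype
#'   matrices; column 1 is the paternal/transmitted slot). Child phase is
#'   taken from the transmitted alleles where determinable; an unresolvable
#'   heterozygote deterministically places the alt allele in the paternal
#'   slot.
#' @export
refine_trio <- function(reads, child, father = NA, mother = NA,
                        base_error = 0.01, pop_maf = 0.2) {
  dp <- reads$dp
  ad <- reads$ad
  m <- nrow(dp)
  ll_of <- function(id) {
    if (is.na(id)) matrix(0, m, 3) else genotype_loglik(dp[, id], ad[, id],
                                                        base_error)
  }
  llf <- ll_of(father)
  llm <- ll_of(mother)
  llc <- ll_of(child)
  lp <- hw_logprior(pop_maf, m)
  score <- matrix(0, m, 27)
  for (k in seq_len(27)) {
    gf <- trio_configs$gf[k]
    gm <- trio_configs$gm[k]
    gc_ <- trio_configs$gc[k]
    score[, k] <- lp[, gf + 1L] + lp[, gm + 1L] + trio_configs$log_trans[k] +
      llf[, gf + 1L] + llm[, gm + 1L] + llc[, gc_ + 1L]
  }
  best <- max.col(score, ties.method = "first")
  gf <- trio_configs$gf[best]
  gm <- trio_configs$gm[best]
  gc_ <- trio_configs$gc[best]

  # child phase: paternal slot first; alleles transmitted from each parent
  pat <- integer(m)
  mat <- integer(m)
  pat[gc_ == 2L] <- 1L
  mat[gc_ == 2L] <- 1L
  het <- gc_ == 1L
  # determinable when a parent is homozygous; tie rule: alt to paternal slot
  pat[het] <- ifelse(gf[het] == 0L, 0L,
              ifelse(gf[het] == 2L, 1L,
              ifelse(gm[het] == 2L, 0L,
              ifelse(gm[het] == 0L, 1L, 1L))))
  mat[het] <- 1L - pat[het]

  # parent phase: transmitted allele in slot 1, untransmitted in slot 2;
  # ambiguous transmission from a het parent puts alt in the transmitted slot
  parent_haps <- function(gp, transmitted_known, trans_allele) {
    h1 <- ifelse(gp == 0L, 0L, ifelse(gp == 2L, 1L,
          ifelse(transmitted_known, trans_allele, 1L)))
    h2 <- gp - h1
    cbind(h1, h2)
  }
  out_gt <- list()
  out_haps <- list()
  if (!is.na(father)) {
    out_gt[[father]] <- gf
    out_haps[[father]] <- parent_haps(gf, TRUE, pat)
  }
  if (!is.na(mother)) {
    out_gt[[mother]] <- gm
    out_haps[[mother]] <- parent_haps(gm, TRUE, mat)
  }
  out_gt[[child]] <- gc_
  out_haps[[child]] <- cbind(h1 = pat, h2 = mat)
  list(gt = out_gt, haps = out_haps)
}

# Hamming distance between haplotypes over jointly observed loci.
hamming <- function(a, b) sum(a != b, na.rm = TRUE)

consensus_of <- function(hap_mat) {
  # hap_mat: loci x replicates (0/1/NA); majority call, ties/missing -> NA
  n1 <- rowSums(hap_mat == 1L, na.rm = TRUE)
  n0 <- rowSums(hap_mat == 0L, na.rm = TRUE)
  out <- rep(NA_integer_, nrow(hap_mat))
  out[n1 > n0] <- 1L
  out[n0 > n1] <- 0L
  out
}

#' Consensus haplotypes from replicated haplotype pairs
#'
#' An individual appearing in several nuclear units carries one estimated
#' haplotype pair per unit. The 2k replicated haplotypes are split into two
#' clusters -- one per chromosome copy -- constrained so that the two
#' haplotypes of a pair land in different clusters, minimizing the total
#' within-cluster pairwise Hamming distance. For k <= `exact_k` pairs the
#' optimal constrained bipartition is found by enumeration; beyond that a
#' greedy pass seeded by the first pair orients each subsequent pair to
#' minimize its added within-cluster distance. Within each cluster the
#' consensus is the majority allele per locus; ties (and all-missing loci)
#' are reported missing.
#'
#' @param replicates List of two-column 0/1 haplotype matrices, all with
#'   the same number of loci.
#' @param exact_k Largest replicate count solved by exact enumeration.
#' @return A list with `consensus` (two-column matrix: the two consensus
#'   haplotypes), `orientation` (0/1 vector: whether each pair was
#'   swapped), and `objective` (the achieved within-cluster distance).
#' @export
build_consensus <- function(replicates, exact_k = 6) {
  k <- length(replicates)
  stopifnot(k >= 1)
  m <- nrow(replicates[[1]])
  for (r in replicates) {
    if (nrow(r) != m || ncol(r) != 2) {
      stop("replicate haplotypes have mismatched dimensions")
    }
  }
  if (k == 1) {
    cons <- replicates[[1]]
    colnames(cons) <- c("h1", "h2")
    return(list(consensus = cons, orientation = 0L, objective = 0))
  }
  pick <- function(orient, side) {
    out <- sapply(seq_len(k), function(i) {
      replicates[[i]][, if (side == 1) 1 + orient[i] else 2 - orient[i]]
    })
    if (!is.matrix(out)) out <- matrix(out, nrow = m)
    out
  }
  objective <- function(orient) {
    a <- pick(orient, 1)
    b <- pick(orient, 2)
    within <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        within <- within + hamming(a[, i], a[, j]) + hamming(b[, i], b[, j])
      }
    }
    within
  }
  if (k <= exact_k) {
    grid <- as.matrix(expand.grid(rep(list(0:1), k - 1)))
    best <- NULL
    best_obj <- Inf
    for (r in seq_len(nrow(grid))) {
      orient <- c(0L, as.integer(grid[r, ]))
      obj <- objective(orient)
      if (obj < best_obj) {
        best_obj <- obj
        best <- orient
      }
    }
    orient <- best
  } else {
    orient <- integer(k)
    a_mem <- replicates[[1]][, 1, drop = FALSE]
    b_mem <- replicates[[1]][, 2, drop = FALSE]
    for (i in 2:k) {
      d_keep <- sum(apply(a_mem, 2, hamming, b = replicates[[i]][, 1])) +
        sum(apply(b_mem, 2, hamming, b = replicates[[i]][, 2]))
      d_swap <- sum(apply(a_mem, 2, hamming, b = replicates[[i]][, 2])) +
        sum(apply(b_mem, 2, hamming, b = replicates[[i]][, 1]))
      orient[i] <- as.integer(d_swap < d_keep)
      a_mem <- cbind(a_mem, replicates[[i]][, 1 + orient[i]])
      b_mem <- cbind(b_mem, replicates[[i]][, 2 - orient[i]])
    }
    best_obj <- objective(orient)
  }
  a <- pick(orient, 1)
  b <- pick(orient, 2)
  cons <- cbind(h1 = consensus_of(a), h2 = consensus_of(b))
  list(consensus = cons, orientation = orient, objective = best_obj)
}

#' Mendelian inconsistency count for a trio or duo
#'
#' A site is inconsistent when the child genotype is impossible given the
#' parental genotypes under Mendelian transmission (for a duo: when the
#' child shares no allele with the single parent). Only sites where all
#' unit members are called enter the comparison.
#'
#' @param child Integer dosage vector for the child.
#' @param father,mother Integer dosage vectors for the parents (`NULL` for
#'   an absent parent; at least one required).
#' @return A list with `count`, `n_comparable`, `rate` and the logical
#'   per-site vector `violation` (`NA` at non-comparable sites).
#' @export
mendel_errors <- function(child, father = NULL, mother = NULL) {
  if (is.null(father) && is.null(mother)) {
    stop("at least one parent genotype vector is required")
  }
  duo_bad <- function(p, c_) (p == 0L & c_ == 2L) | (p == 2L & c_ == 0L)
  if (!is.null(father) && !is.null(mother)) {
    comparable <- !is.na(child) & !is.na(father) & !is.na(mother)
    bad <- duo_bad(father, child) | duo_bad(mother, child) |
      (father == 0L & mother == 0L & child != 0L) |
      (father == 2L & mother == 2L & child != 2L) |
      (father == 0L & mother == 2L & child != 1L) |
      (father == 2L & mother == 0L & child != 1L)
  } else {
    p <- if (is.null(father)) mother else father
    comparable <- !is.na(child) & !is.na(p)
    bad <- duo_bad(p, child)
  }
  violation <- ifelse(comparable, bad, NA)
  count <- sum(violation, na.rm = TRUE)
  n <- sum(comparable)
  list(count = count, n_comparable = n,
       rate = if (n > 0) count / n else NA_real_,
       violation = violation)
}

#' Per-site Mendelian error counts across nuclear units
#'
#' Counts, for each site, how many trio/duo units show a Mendelian
#' inconsistency, given a genotype matrix.
#'
#' @param gt Genotype dosage matrix (sites x samples).
#' @param units A `nuclear_units` table from [decompose_units()].
#' @return Integer vector: per-site count of inconsistent units.
#' @export
site_mendel_counts <- function(gt, units) {
  counts <- integer(nrow(gt))
  for (r in seq_len(nrow(units))) {
    if (units$kind[r] == "singleton") next
    fa <- units$father[r]
    mo <- units$mother[r]
    me <- mendel_errors(
      child = gt[, units$child[r]],
      father = if (!is.na(fa)) gt[, fa],
      mother = if (!is.na(mo)) gt[, mo]
    )
    v <- me$violation
    v[is.na(v)] <- FALSE
    counts <- counts + v
  }
  counts
}

#' Genotype concordance between two call sets
#'
#' Fraction of agreeing calls over sites where both vectors are
#' non-missing. Symmetric in its arguments; 1 on identical call sets.
#'
#' @param a,b Integer dosage vectors of equal length.
#' @return Proportion in `[0, 1]` (`NA` if no jointly called sites).
#' @export
genotype_concordance <- function(a, b) {
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) return(NA_real_)
  mean(a[both] == b[both])
}

#' Refine all nuclear units and build per-individual consensus genotypes
#'
#' Runs [refine_trio()] over every unit of a decomposition, pools each
#' individual's replicated haplotypes from all units containing it (as
#' child or as parent), derives the two consensus haplotypes via
#' [build_consensus()], and returns the implied consensus genotypes.
#'
#' @param reads A `read_data` object covering all unit members.
#' @param units A `nuclear_units` table.
#' @param base_error Per-read allele miscall probability.
#' @param pop_maf Population alt-allele frequency (scalar or per-site).
#' @return A list with `gt` (consensus dosage matrix, sites x individuals;
#'   NA where either consensus haplotype is undecided) and `bundles`
#'   (per-individual list of replicate haplotype matrices).
#' @export
refine_units <- function(reads, units, base_error = 0.01, pop_maf = 0.2) {
  bundles <- list()
  for (r in seq_len(nrow(units))) {
    res <- refine_trio(
      reads, child = units$child[r],
      father = units$father[r], mother = units$mother[r],
      base_error = base_error, pop_maf = pop_maf
    )
    for (id in names(res$haps)) {
      bundles[[id]] <- c(bundles[[id]], list(res$haps[[id]]))
    }
  }
  ids <- names(bundles)
  m <- nrow(reads$dp)
  gt <- matrix(NA_integer_, m, length(ids), dimnames = list(NULL, ids))
  for (id in ids) {
    cons <- build_consensus(bundles[[id]])$consensus
    gt[, id] <- cons[, 1] + cons[, 2]
  }
  list(gt = gt, bundles = bundles)
}
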