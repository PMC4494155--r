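# Independent oracles used to cross-check package implementations.
# Everything here is deliberately written from first principles, without
# reusing the package's internal code paths.

# Monte-Carlo kinship via single-locus gene dropping with uniquely
# labelled founder alleles: phi = P(one random allele from each individual
# is identical by descent), averaged over the four allele pairings.
mc_kinship <- function(ped, id1, id2, n_drops = 1e5, seed = 1) {
  set.seed(seed)
  ids <- ped$id
  fi <- match(ped$father, ids)
  mi <- match(ped$mother, ids)
  depth <- rep(NA_integer_, length(ids))
  depth[is.na(fi) & is.na(mi)] <- 0L
  repeat {
    fd <- ifelse(is.na(fi), -1L, depth[fi])
    md <- ifelse(is.na(mi), -1L, depth[mi])
    newd <- pmax(fd, md) + 1L
    ready <- is.na(depth) & !is.na(newd)
    if (!any(ready)) break
    depth[ready] <- newd[ready]
  }
  ord <- order(depth)
  pat <- matrix(0L, n_drops, length(ids))
  mat <- matrix(0L, n_drops, length(ids))
  lab <- 0L
  for (i in ord) {
    if (is.na(fi[i]) && is.na(mi[i])) {
      pat[, i] <- lab + 1L
      mat[, i] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick <- stats::rbinom(n_drops, 1L, 0.5)
      pat[, i] <- ifelse(pick == 1L, pat[, fi[i]], mat[, fi[i]])
      pick <- stats::rbinom(n_drops, 1L, 0.5)
      mat[, i] <- ifelse(pick == 1L, pat[, mi[i]], mat[, mi[i]])
    }
  }
  a <- match(id1, ids)
  b <- match(id2, ids)
  per_drop <- (
    (pat[, a] == pat[, b]) + (pat[, a] == mat[, b]) +
    (mat[, a] == pat[, b]) + (mat[, a] == mat[, b])
  ) / 4
  list(phi = mean(per_drop),
       se = stats::sd(per_drop) / sqrt(n_drops))
}

# Exhaustive marginal-gain ranking by direct edge scans; reimplements the
# greedy selection rule (gain in new offspring-set ids; ties by older
# birth year then id) independently of greedy_rank()'s bookkeeping.
oracle_rank <- function(ped, sequenced = NULL) {
  if (is.null(sequenced)) sequenced <- ped$id[ped$sequenced]
  offspring <- character(0)
  remaining <- sort(sequenced)
  ranking <- character(0)
  while (length(remaining) > 0) {
    gains <- vapply(remaining, function(cand) {
      kids <- ped$id[(!is.na(ped$father) & ped$father == cand) |
                     (!is.na(ped$mother) & ped$mother == cand)]
      kids <- intersect(kids, sequenced)
      length(union(offspring, kids)) - length(offspring)
    }, integer(1))
    top <- remaining[gains == max(gains)]
    yr <- ped$birth_year[match(top, ped$id)]
    yr[is.na(yr)] <- Inf
    pick <- top[order(yr, top)][1]
    ranking <- c(ranking, pick)
    kids <- ped$id[(!is.na(ped$father) & ped$father == pick) |
                   (!is.na(ped$mother) & ped$mother == pick)]
    offspring <- union(offspring, intersect(kids, sequenced))
    remaining <- setdiff(remaining, pick)
  }
  ranking
}

# Exhaustive optimal pair-constrained bipartition of replicated haplotype
# pairs: minimises total within-cluster pairwise Hamming distance over all
# 2^k orientations.
oracle_bipartition <- function(replicates) {
  k <- length(replicates)
  ham <- function(a, b) sum(a != b, na.rm = TRUE)
  best <- Inf
  for (code in 0:(2^k - 1)) {
    orient <- as.integer(intToBits(code))[seq_len(k)]
    a <- lapply(seq_len(k), function(i) replicates[[i]][, 1 + orient[i]])
    b <- lapply(seq_len(k), function(i) replicates[[i]][, 2 - orient[i]])
    tot <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        tot <- tot + ham(a[[i]], a[[j]]) + ham(b[[i]], b[[j]])
      }
    }
    if (tot < best) best <- tot
  }
  best
}

# Mendelian legality by enumeration of transmissible alleles.
oracle_mendel_legal <- function(gf, gm, gc) {
  alleles <- function(g) switch(as.character(g), "0" = 0L, "1" = 0:1,
                                "2" = 1L)
  sums <- outer(alleles(gf), alleles(gm), "+")
  gc %in% sums
}

# Joint trio posterior by direct enumeration from first principles.
oracle_trio_posterior <- function(dpf, adf, dpm, adm, dpc, adc,
                                  base_error, q) {
  lik <- function(dp, ad, g) {
    p <- c(base_error, 0.5, 1 - base_error)[g + 1]
    stats::dbinom(ad, dp, p)
  }
  prior <- function(g) c((1 - q)^2, 2 * q * (1 - q), q^2)[g + 1]
  trans <- function(gf, gm, gc) {
    tf <- gf / 2
    tm <- gm / 2
    c((1 - tf) * (1 - tm), tf * (1 - tm) + (1 - tf) * tm, tf * tm)[gc + 1]
  }
  best <- NULL
  best_p <- -1
  for (gf in 0:2) for (gm in 0:2) for (gc in 0:2) {
    p <- prior(gf) * prior(gm) * trans(gf, gm, gc) *
      lik(dpf, adf, gf) * lik(dpm, adm, gm) * lik(dpc, adc, gc)
    if (p > best_p) {
      best_p <- p
      best <- c(gf = gf, gm = gm, gc = gc)
    }
  }
  best
}

# Random small pedigree for ranking/kinship property tests: sequential
# construction with parents drawn from earlier individuals, duplicate
# birth years to exercise tie-breaking, and a random sequenced subset.
random_small_pedigree <- function(n, seed, p_parents = 0.7,
                                  seq_frac = 0.9) {
  set.seed(seed)
  id <- sprintf("i%02d", seq_len(n))
  sex <- sample(rep(c("M", "F"), length.out = n))
  father <- mother <- rep(NA_character_, n)
  byear <- 1980 + (seq_len(n) %/% 2)
  for (i in 3:n) {
    males <- id[seq_len(i - 1)][sex[seq_len(i - 1)] == "M"]
    females <- id[seq_len(i - 1)][sex[seq_len(i - 1)] == "F"]
    if (length(males) > 0 && length(females) > 0 &&
        stats::runif(1) < p_parents) {
      father[i] <- sample(males, 1)
      mother[i] <- sample(females, 1)
      byear[i] <- max(byear[match(c(father[i], mother[i]), id)]) + 1
    }
  }
  seqd <- stats::runif(n) < seq_frac
  if (!any(seqd)) seqd[1] <- TRUE
  pedigree(id = id, father = father, mother = mother, sex = sex,
           birth_year = byear, sequenced = seqd)
}

# Random haplotype-pair bundles: k noisy replicates of a template pair
# with per-locus flips, some replicates stored swapped.
random_bundle <- function(k, n_loci, flip_rate, seed) {
  set.seed(seed)
  t1 <- stats::rbinom(n_loci, 1L, 0.5)
  t2 <- stats::rbinom(n_loci, 1L, 0.5)
  lapply(seq_len(k), function(i) {
    a <- abs(t1 - stats::rbinom(n_loci, 1L, flip_rate))
    b <- abs(t2 - stats::rbinom(n_loci, 1L, flip_rate))
    if (stats::runif(1) < 0.5) cbind(a, b) else cbind(b, a)
  })
}
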