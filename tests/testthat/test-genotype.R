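test_that("naive calls follow the hand-computed posterior table", {
  mk <- function(dp, ad) list(dp = matrix(as.integer(dp), ncol = 1,
                                          dimnames = list(NULL, "x")),
                              ad = matrix(as.integer(ad), ncol = 1,
                                          dimnames = list(NULL, "x")))
  # depth 30, no alt reads, e=0.01 -> hom ref; depth 0 -> missing
  gt <- call_naive(mk(c(30, 0), c(0, 0)), base_error = 0.01,
                   prior_maf = 0.2)
  expect_equal(gt[, 1], c(0L, NA))
  # single alt read, e=0.01:
  #   prior q=0.2: posterior scores (0.64*0.01, 0.32*0.5, 0.04*0.99)
  #     = (0.0064, 0.160, 0.0396)            -> het
  #   prior q=0.9: (0.01*0.01, 0.18*0.5, 0.81*0.99)
  #     = (1e-4, 0.090, 0.802)               -> hom alt
  expect_equal(unname(call_naive(mk(1, 1), 0.01, prior_maf = 0.2)[1, 1]), 1L)
  expect_equal(unname(call_naive(mk(1, 1), 0.01, prior_maf = 0.9)[1, 1]), 2L)
  # single ref read at q=0.2: (0.64*0.99, 0.32*0.5, 0.04*0.01) -> hom ref
  expect_equal(unname(call_naive(mk(1, 0), 0.01, prior_maf = 0.2)[1, 1]), 0L)
  expect_error(call_naive(mk(1, 0), base_error = 0), "base_error")
})

test_that("trio refinement obeys Mendelian constraints and the joint oracle", {
  mk_reads <- function(dpf, adf, dpm, adm, dpc, adc) {
    list(dp = cbind(fa = as.integer(dpf), mo = as.integer(dpm),
                    ch = as.integer(dpc)),
         ad = cbind(fa = as.integer(adf), mo = as.integer(adm),
                    ch = as.integer(adc)))
  }
  # confident hom-ref parents override a single alt read in the child
  r <- refine_trio(mk_reads(30, 0, 30, 0, 1, 1), child = "ch",
                   father = "fa", mother = "mo", base_error = 0.01,
                   pop_maf = 0.2)
  expect_equal(r$gt$ch, 0L)
  # hom-alt parents pull a noisy low-depth child to hom alt
  r2 <- refine_trio(mk_reads(30, 30, 30, 30, 2, 1), child = "ch",
                    father = "fa", mother = "mo", base_error = 0.01,
                    pop_maf = 0.2)
  expect_equal(r2$gt$ch, 2L)
  # random read configurations match the brute-force joint posterior
  set.seed(123)
  for (i in 1:60) {
    dps <- rpois(3, 6)
    tg <- sample(0:2, 3, replace = TRUE)
    ads <- rbinom(3, dps, c(0.02, 0.5, 0.98)[tg + 1])
    q <- runif(1, 0.1, 0.9)
    got <- refine_trio(mk_reads(dps[1], ads[1], dps[2], ads[2],
                                dps[3], ads[3]),
                       child = "ch", father = "fa", mother = "mo",
                       base_error = 0.02, pop_maf = q)
    want <- oracle_trio_posterior(dps[1], ads[1], dps[2], ads[2],
                                  dps[3], ads[3], 0.02, q)
    expect_equal(c(got$gt$fa, got$gt$mo, got$gt$ch), unname(want))
  }
})

test_that("refined trios are Mendelian-consistent and recover deep truth", {
  w <- trio_world(sites_per_chrom = 1000, depths = c(fa = 30, mo = 30,
                                                     ch = 30),
                  base_error = 0.001, seed = 501)
  r <- refine_trio(w$reads, child = "ch", father = "fa", mother = "mo",
                   base_error = 0.001, pop_maf = 0.3)
  me <- mendel_errors(r$gt$ch, r$gt$fa, r$gt$mo)
  expect_equal(me$count, 0)
  acc <- mean(cbind(r$gt$fa, r$gt$mo, r$gt$ch) ==
                w$truth$geno[, c("fa", "mo", "ch")])
  expect_gte(acc, 0.999)
  # haplotypes imply the genotypes
  expect_equal(r$haps$ch[, 1] + r$haps$ch[, 2], r$gt$ch)
  # uninformative all-het site phases deterministically (alt to paternal)
  u <- refine_trio(list(dp = cbind(fa = 40L, mo = 40L, ch = 40L),
                        ad = cbind(fa = 20L, mo = 20L, ch = 20L)),
                   child = "ch", father = "fa", mother = "mo",
                   base_error = 0.01, pop_maf = 0.5)
  expect_equal(unname(u$haps$ch[1, ]), c(1L, 0L))
})

test_that("duo refinement marginalizes the absent parent", {
  reads <- list(dp = cbind(mo = 30L, ch = 30L),
                ad = cbind(mo = 30L, ch = 0L))
  r <- refine_trio(reads, child = "ch", mother = "mo", base_error = 0.01,
                   pop_maf = 0.2)
  # hom-alt mother forces at least one alt allele in a truly observed
  # child... unless reads overwhelmingly say otherwise; with 30 ref reads
  # the child is called het (one maternal alt, one paternal ref)?  No:
  # 30 ref reads at e=0.01 make het vastly unlikely; the argmax resolves
  # the conflict by the likelihood -- assert only legality wrt duo rule
  expect_false((r$gt$mo == 2L && r$gt$ch == 0L) ||
                 (r$gt$mo == 0L && r$gt$ch == 2L))
  expect_named(r$gt, c("mo", "ch"))
})

test_that("consensus haplotypes are majority votes over optimal bipartitions", {
  # k = 1: identity
  one <- list(cbind(c(0L, 1L, 0L), c(1L, 1L, 0L)))
  expect_equal(unname(build_consensus(one)$consensus), unname(one[[1]]))
  # k = 3 identical pairs with one flipped allele: majority restores it
  base <- cbind(rep(0L, 6), rep(1L, 6))
  flipped <- base
  flipped[2, 1] <- 1L
  cons <- build_consensus(list(base, base, flipped))$consensus
  expect_equal(unname(cons), unname(base))
  # noisy replicates of two templates: consensus beats every replicate
  set.seed(9)
  t1 <- rbinom(200, 1L, 0.5)
  t2 <- rbinom(200, 1L, 0.5)
  reps <- lapply(1:4, function(i) {
    a <- abs(t1 - rbinom(200, 1L, 0.05))
    b <- abs(t2 - rbinom(200, 1L, 0.05))
    if (i %% 2 == 0) cbind(b, a) else cbind(a, b)
  })
  res <- build_consensus(reps)
  d_cons <- min(sum(res$consensus[, 1] != t1, na.rm = TRUE) +
                  sum(res$consensus[, 2] != t2, na.rm = TRUE),
                sum(res$consensus[, 1] != t2, na.rm = TRUE) +
                  sum(res$consensus[, 2] != t1, na.rm = TRUE))
  d_reps <- vapply(reps, function(r) {
    min(sum(r[, 1] != t1) + sum(r[, 2] != t2),
        sum(r[, 1] != t2) + sum(r[, 2] != t1))
  }, numeric(1))
  expect_lt(d_cons, min(d_reps))
  # and the clustering objective matches the exhaustive oracle
  expect_equal(res$objective, oracle_bipartition(reps))
})

test_that("consensus clustering is invariant to replicate order", {
  set.seed(31)
  reps <- random_bundle(5, 80, 0.05, seed = 31)
  ref <- build_consensus(reps)$consensus
  for (perm_seed in 1:5) {
    set.seed(perm_seed)
    perm <- sample(length(reps))
    got <- build_consensus(reps[perm])$consensus
    same <- identical(unname(got), unname(ref))
    swapped <- identical(unname(got[, 2:1]), unname(ref))
    expect_true(same || swapped)
  }
})

test_that("greedy consensus handles many replicates and length mismatches", {
  reps <- random_bundle(8, 60, 0.03, seed = 41)
  res <- build_consensus(reps)  # k > exact cutoff: greedy path
  expect_equal(dim(res$consensus), c(60L, 2L))
  expect_error(build_consensus(list(cbind(0L, 1L), cbind(c(0L, 1L),
                                                         c(1L, 0L)))),
               "mismatched")
})

test_that("Mendelian error detection matches the legality enumeration", {
  expect_equal(mendel_errors(child = 1L, father = 0L, mother = 0L)$count, 1)
  expect_equal(mendel_errors(child = 1L, father = 0L, mother = 2L)$count, 0)
  expect_equal(mendel_errors(child = 2L, mother = 0L)$count, 1)  # duo
  set.seed(55)
  gf <- sample(c(0:2, NA), 300, replace = TRUE)
  gm <- sample(c(0:2, NA), 300, replace = TRUE)
  gc_ <- sample(c(0:2, NA), 300, replace = TRUE)
  got <- mendel_errors(gc_, gf, gm)
  want <- mapply(function(f, m, c_) {
    if (anyNA(c(f, m, c_))) NA else !oracle_mendel_legal(f, m, c_)
  }, gf, gm, gc_)
  expect_equal(got$violation, unname(want))
  expect_equal(got$count, sum(want, na.rm = TRUE))
  expect_equal(got$n_comparable, sum(!is.na(want)))
})

test_that("concordance is symmetric and unit on identical calls", {
  a <- c(0L, 1L, 2L, NA, 1L)
  b <- c(0L, 2L, 2L, 1L, NA)
  expect_equal(genotype_concordance(a, a), 1)
  expect_equal(genotype_concordance(a, b), genotype_concordance(b, a))
  expect_equal(genotype_concordance(a, b), 2 / 3)
})

test_that("unit-wise refinement yields near-complete consensus genotypes", {
  ped <- simulate_pedigree(8, 2, 2, seed = 61)
  sites <- simulate_sites(n_chrom = 1, sites_per_chrom = 200, seed = 62)
  gmap <- simulate_genetic_map(n_chrom = 1, seed = 63)
  truth <- gene_drop(ped, sites, gmap, seed = 64)
  reads <- simulate_reads(truth, 15, base_error = 0.01, seed = 65)
  units <- decompose_units(ped)
  res <- refine_units(reads, units, base_error = 0.01, pop_maf = 0.3)
  expect_setequal(colnames(res$gt), ped$id)
  expect_gt(mean(res$gt == truth$geno[, colnames(res$gt)], na.rm = TRUE),
            0.95)
  # replicate counts: each appearance as child or parent contributes one
  n_appear <- vapply(ped$id, function(id) {
    sum(units$child == id) +
      sum(units$father == id, na.rm = TRUE) +
      sum(units$mother == id, na.rm = TRUE)
  }, integer(1))
  expect_equal(vapply(res$bundles[ped$id], length, integer(1)),
               n_appear[ped$id])
})
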