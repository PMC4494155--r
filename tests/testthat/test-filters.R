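test_that("filter reports enforce conservation and round-trip as text", {
  rep1 <- filter_report("stage1", 1000,
                        c(alpha = 100, beta = 50, gamma = 0))
  expect_equal(rep1$end_count, 850)
  expect_equal(report_total(rep1), 150)
  expect_equal(report_discrepancy(rep1), 0)
  expect_true(validate_filter_report(rep1))
  expect_error(filter_report("s", 10, c(a = -1)), "removed")
  # empty cascade: TOTAL 0, end = start
  rep0 <- filter_report("empty", 500, setNames(numeric(0), character(0)))
  expect_equal(rep0$end_count, 500)
  expect_equal(report_total(rep0), 0)
  # round trip, including a transcribed ledger whose rows disagree with
  # its stated total
  for (r in list(rep1, rep0,
                 filter_report("stage2", 1000, c(a = 40, b = 10),
                               printed_total = 45))) {
    expect_equal(parse_report(render_report(r)), r)
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep1, path)
  expect_equal(parse_report(path), rep1)
})

test_that("stage 1 MAF threshold arithmetic at 17 diploid samples", {
  samples <- sprintf("hc%02d", 1:17)
  rows <- list(
    c(rep(1L, 4), rep(2L, 2), rep(0L, 11)),  # 8/34 = 0.235  -> removed
    c(rep(1L, 9), rep(0L, 8)),               # 9/34 = 0.265  -> retained
    rep(1L, 17)                              # 17/34 = 0.5   -> retained
  )
  panel <- panel_from_rows(rows, samples)
  res <- stage1_filter(panel, hc_ids = samples)
  maf_row <- res$report$steps[grepl("MAF", res$report$steps$name), ]
  expect_equal(maf_row$removed, 1)
  expect_equal(n_sites(res$panel), 2)
  expect_error(stage1_filter(panel, character(0)), "non-empty")
})

test_that("proximity removal keeps both members of distant pairs only", {
  samples <- sprintf("s%02d", 1:17)
  mk <- function(positions) {
    rows <- replicate(length(positions), rep(1L, 17), simplify = FALSE)
    p <- panel_from_rows(rows, samples)
    p$sites$pos <- positions
    p
  }
  # distance 4 <= 5: both removed
  res <- stage1_filter(mk(c(100L, 104L)), samples)
  expect_equal(n_sites(res$panel), 0)
  # distance 6 > 5: both kept
  res2 <- stage1_filter(mk(c(100L, 106L)), samples)
  expect_equal(n_sites(res2$panel), 2)
  # boundary: distance exactly 5 removed
  res3 <- stage1_filter(mk(c(100L, 105L)), samples)
  expect_equal(n_sites(res3$panel), 0)
})

test_that("stage 1 ledger counts match a panel with planted violations", {
  samples <- sprintf("hc%02d", 1:10)
  common <- function() rep(c(0L, 1L, 2L, 1L, 0L), 2)  # MAF 0.4, complete
  rows <- replicate(30, common(), simplify = FALSE)
  panel <- panel_from_rows(rows, samples, step = 1000, depth = 20)
  # plant 3 multiallelic, 2 low-coverage, 2 high-coverage, 4 low-MAF,
  # 3 with missing, one close pair
  panel$sites$alt[c(2, 11, 25)] <- c("G,T", "GA", "G,C")
  panel$dp[4, ] <- 1L   # cumulative 10 vs median 200 -> below m/2
  panel$dp[5, ] <- 2L
  panel$dp[17, ] <- 50L # cumulative 500 -> above 2m
  panel$dp[18, ] <- 45L
  low_maf <- c(7, 8, 20, 28)
  for (i in low_maf) panel$gt[i, ] <- c(1L, rep(0L, 9))  # 1/20 = 0.05
  miss <- c(9, 21, 29)
  for (i in miss) panel$gt[i, 1] <- NA_integer_
  panel$sites$pos[13] <- panel$sites$pos[12] + 3L
  res <- stage1_filter(panel, samples)
  expect_equal(res$report$steps$removed, c(3, 4, 4, 3, 2))
  expect_equal(res$report$end_count, 30 - 16)
  validate_filter_report(res$report)
})

test_that("stage 2 thresholds act at their printed boundaries", {
  samples <- sprintf("s%03d", 1:100)
  units <- decompose_units(pedigree(samples, sex = "U"))  # singletons only
  het_rows <- function(k) c(rep(1L, k), rep(c(0L, 2L), length.out = 100 - k))
  rows <- list(het_rows(61),  # het fraction 0.61 -> removed
               het_rows(60),  # exactly 0.60     -> retained
               rep(c(0L, 1L), 50))
  panel <- panel_from_rows(rows, samples)
  res <- stage2_filter(panel, units)
  het_row <- res$report$steps[grepl("heterozygous",
                                    res$report$steps$name), ]
  expect_equal(het_row$removed, 1)
  expect_equal(n_sites(res$panel), 2)
})

test_that("stage 2 Mendel-error and missingness filters count planted sites", {
  # 6 trio units; one site violates in 5 units (removed), one in 4 (kept)
  n_fam <- 6
  ids <- as.vector(vapply(seq_len(n_fam), function(i) {
    sprintf(c("f%02d", "m%02d", "c%02d"), i)
  }, character(3)))
  ped <- pedigree(
    id = ids,
    father = as.vector(vapply(seq_len(n_fam), function(i) {
      c(NA, NA, sprintf("f%02d", i))
    }, character(3))),
    mother = as.vector(vapply(seq_len(n_fam), function(i) {
      c(NA, NA, sprintf("m%02d", i))
    }, character(3))),
    sex = rep(c("M", "F", "U"), n_fam),
    birth_year = rep(c(1990, 1990, 2000), n_fam))
  units <- decompose_units(ped)
  ok <- rep(c(0L, 0L, 0L), n_fam)
  viol5 <- ok; viol4 <- ok
  viol5[3 * (1:5)] <- 2L        # child hom-alt under hom-ref parents
  viol4[3 * (1:4)] <- 2L
  half_missing <- rep(c(1L, NA, 0L), n_fam)
  over_missing <- c(rep(NA, 10), rep(1L, 8))
  rows <- list(ok, viol5, viol4, half_missing, over_missing)
  panel <- panel_from_rows(rows, ids)
  res <- stage2_filter(panel, units, maf_min = 0)
  steps <- res$report$steps
  expect_equal(steps$removed[grepl("Mendel", steps$name)], 1)
  expect_equal(steps$removed[grepl("missing", steps$name)], 1)
  validate_filter_report(res$report)
  # exactly 5 violating units trip the >= 5 rule; 4 do not
  counts <- site_mendel_counts(panel$gt, units)
  expect_equal(counts[2:3], c(5L, 4L))
})

test_that("stage 4 masks sporadic errors then applies the missing-rate gate", {
  ids <- c("f1", "m1", "c1", paste0("x", 1:16))
  ped <- pedigree(
    id = ids,
    father = c(NA, NA, "f1", rep(NA, 16)),
    mother = c(NA, NA, "m1", rep(NA, 16)),
    sex = c("M", "F", "U", rep("U", 16)),
    birth_year = c(1990, 1990, 2000, rep(2000, 16)))
  units <- decompose_units(ped)
  clean <- rep(c(0L, 1L), length.out = 19)
  sporadic <- c(0L, 0L, 2L, rep(c(0L, 1L), length.out = 16))
  rows <- list(clean, sporadic)
  panel <- panel_from_rows(rows, ids)
  res <- stage4_final_filter(panel, units)
  # masking the child genotype pushes missingness to 1/19 > 5% -> removed
  expect_equal(n_sites(res$panel), 1)
  expect_equal(attr(res$report, "masked_genotypes"), 1L)
  expect_equal(res$report$steps$removed, c(0, 0, 0, 1))
  # a clean panel passes untouched
  res2 <- stage4_final_filter(panel_from_rows(list(clean), ids), units)
  expect_equal(n_sites(res2$panel), 1)
  expect_equal(sum(res2$report$steps$removed), 0)
})

test_that("cascades are deterministic and idempotent on well-behaved panels", {
  ped <- simulate_pedigree(10, 2, 2, seed = 91)
  sites <- simulate_sites(n_chrom = 2, sites_per_chrom = 150, seed = 92)
  gmap <- simulate_genetic_map(n_chrom = 2, seed = 93)
  truth <- gene_drop(ped, sites, gmap, seed = 94)
  reads <- simulate_reads(truth, 20, base_error = 0.01, seed = 95)
  panel <- truth_to_panel(truth, reads,
                          gt = call_naive(reads, 0.01, 0.2))
  hc <- ped$id[1:5]
  once <- stage1_filter(panel, hc)
  twice <- stage1_filter(once$panel, hc)
  expect_equal(sum(twice$report$steps$removed), 0)
  expect_equal(twice$panel$sites, once$panel$sites)
  units <- decompose_units(ped)
  s2a <- stage2_filter(once$panel, units)
  s2b <- stage2_filter(s2a$panel, units)
  expect_equal(sum(s2b$report$steps$removed), 0)
})

test_that("filter order matters: proximity versus missingness", {
  samples <- sprintf("hc%02d", 1:8)
  rows <- list(rep(1L, 8), c(NA, rep(1L, 7)))
  panel <- panel_from_rows(rows, samples)
  panel$sites$pos <- c(100L, 103L)
  # printed order: the missing-data step removes site 2 first, so site 1
  # no longer has a close neighbour and survives
  res <- stage1_filter(panel, samples)
  expect_equal(n_sites(res$panel), 1)
  expect_equal(res$panel$sites$pos, 100L)
  # reversed order (proximity first) would remove both sites
  prox_first <- pedpanel:::proximity_fail(panel$sites, 5)
  expect_true(all(prox_first))
})
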