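# Gene-dropping simulator: synthetic pedigrees, biallelic site maps,
# recombination-aware transmission of founder alleles, and depth-dependent
# read counts. All functions are deterministic under a fixed seed.

#' Simulate a multi-generation pedigree
#'
#' Generates a pedigree descended from a founder set by mating within
#' adjacent generations. Sexes are balanced within each generation; each
#' female of a generation receives a Poisson number of offspring, fathered
#' primarily by one mate with occasional extra-pair paternity so that the
#' pedigree contains full sibs, maternal half sibs and paternal half sibs.
#' Birth years increase by a fixed generation gap (default 8 years) with a
#' jitter of +/-2 years, so parent-offspring age differences fall in
#' 4-12 years.
#'
#' @param n_founders Number of founders (>= 2).
#' @param n_generations Number of descendant generations (>= 1).
#' @param mean_offspring Mean offspring per female per generation.
#' @param seed Integer seed; identical seeds give identical pedigrees.
#' @param base_year Birth-year origin for founders.
#' @param generation_gap Years between successive generations.
#' @param extra_pair_prob Probability a child's father is not its mother's
#'   primary mate.
#' @return A [pedigree] with all members flagged `sequenced = TRUE`.
#' @export
simulate_pedigree <- function(n_founders, n_generations, mean_offspring = 2,
                              seed = 1, base_year = 2000, generation_gap = 8,
                              extra_pair_prob = 0.3) {
  stopifnot(n_founders >= 2, n_generations >= 1, mean_offspring > 0)
  set.seed(seed)
  balanced_sex <- function(n) sample(rep(c("M", "F"), length.out = n))
  id <- sprintf("G0_%03d", seq_len(n_founders))
  sex <- balanced_sex(n_founders)
  byear <- base_year + sample(-2:2, n_founders, replace = TRUE)
  father <- mother <- rep(NA_character_, n_founders)
  gen <- rep(0L, n_founders)
  for (g in seq_len(n_generations)) {
    prev <- which(gen == g - 1L)
    males <- id[prev][sex[prev] == "M"]
    females <- id[prev][sex[prev] == "F"]
    if (length(males) == 0 || length(females) == 0) {
      stop("generation error: no opposite-sex pairs in generation ", g - 1L)
    }
    kid_f <- character(0)
    kid_m <- character(0)
    for (mo in females) {
      nk <- stats::rpois(1, mean_offspring)
      if (nk == 0) next
      mate <- sample(males, 1)
      for (k in seq_len(nk)) {
        fa <- if (stats::runif(1) < extra_pair_prob) sample(males, 1) else mate
        kid_f <- c(kid_f, fa)
        kid_m <- c(kid_m, mo)
      }
    }
    if (length(kid_f) == 0) {
      # guarantee the generation is non-empty so the pedigree reaches depth
      kid_f <- sample(males, 1)
      kid_m <- sample(females, 1)
    }
    nk <- length(kid_f)
    kid_id <- sprintf("G%d_%03d", g, seq_len(nk))
    id <- c(id, kid_id)
    sex <- c(sex, balanced_sex(nk))
    byear <- c(byear, base_year + g * generation_gap +
                 sample(-2:2, nk, replace = TRUE))
    father <- c(father, kid_f)
    mother <- c(mother, kid_m)
    gen <- c(gen, rep(g, nk))
  }
  pedigree(id = id, father = father, mother = mother, sex = sex,
           birth_year = byear, sequenced = TRUE)
}

#' Simulate biallelic site definitions
#'
#' Draws sorted site positions on each autosome with founder minor allele
#' frequencies uniform on a range and random ref/alt bases.
#'
#' @param n_chrom Number of autosomes.
#' @param sites_per_chrom Sites per chromosome.
#' @param chrom_bp Chromosome length in bp.
#' @param maf_range Range of founder minor allele frequencies (max 0.5).
#' @param seed Integer seed.
#' @return Data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `founder_maf`.
#' @export
simulate_sites <- function(n_chrom = 4, sites_per_chrom = 5000,
                           chrom_bp = 5e7, maf_range = c(0.05, 0.5),
                           seed = 1) {
  stopifnot(maf_range[2] <= 0.5, maf_range[1] > 0)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(n_chrom), function(ch) {
    pos <- sort(sample.int(chrom_bp, sites_per_chrom))
    ref <- sample(bases, sites_per_chrom, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    data.frame(chrom = paste0("chr", ch), pos = pos, ref = ref, alt = alt,
               founder_maf = stats::runif(sites_per_chrom, maf_range[1],
                                          maf_range[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate an STR-style genetic map anchor table
#'
#' Produces evenly spread anchor markers per chromosome with centimorgan
#' positions increasing linearly (plus jitter) to a total map length.
#'
#' @param n_chrom Number of autosomes.
#' @param chrom_bp Chromosome length in bp.
#' @param map_length_cM Genetic length per chromosome in centimorgans.
#' @param anchors_per_chrom Anchor markers per chromosome (>= 2).
#' @param seed Integer seed.
#' @return Data.frame with columns `marker_id`, `chrom`, `pos_bp`, `pos_cM`
#'   (non-decreasing in `pos_bp` within chromosome).
#' @export
simulate_genetic_map <- function(n_chrom = 4, chrom_bp = 5e7,
                                 map_length_cM = 100,
                                 anchors_per_chrom = 10, seed = 1) {
  stopifnot(anchors_per_chrom >= 2)
  set.seed(seed)
  out <- lapply(seq_len(n_chrom), function(ch) {
    bp <- round(seq(1, chrom_bp, length.out = anchors_per_chrom))
    cm <- seq(0, map_length_cM, length.out = anchors_per_chrom)
    if (anchors_per_chrom > 2) {
      mid <- 2:(anchors_per_chrom - 1)
      step <- map_length_cM / (anchors_per_chrom - 1)
      cm[mid] <- cm[mid] + stats::runif(length(mid), -0.3, 0.3) * step
      cm <- cummax(cm)
    }
    data.frame(marker_id = sprintf("STR_%d_%02d", ch,
                                   seq_len(anchors_per_chrom)),
               chrom = paste0("chr", ch), pos_bp = bp, pos_cM = cm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write/read a genetic map anchor table as TSV
#' @param map Anchor data.frame (`marker_id`, `chrom`, `pos_bp`, `pos_cM`).
#' @param path File path.
#' @return `write_genetic_map()` returns `path` invisibly;
#'   `read_genetic_map()` returns the anchor data.frame.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# Haldane map function: cM distance -> recombination fraction.
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# Draw n gametes over sites with given per-site cM positions and chromosome
# labels. Returns a 0/1 matrix (sites x n): which parental haplotype each
# gamete carries at each site. Independent chromosomes (r = 0.5 at starts).
sample_gamete_origins <- function(n, chrom, pos_cM) {
  m <- length(pos_cM)
  r <- rep(0.5, m)
  if (m > 1) {
    same <- chrom[-1] == chrom[-m]
    d <- pos_cM[-1] - pos_cM[-m]
    r[-1] <- ifelse(same, haldane_r(d), 0.5)
  }
  sw <- matrix(stats::rbinom(m * n, 1L, rep(r, n)), nrow = m)
  out <- apply(sw, 2, function(s) cumsum(s) %% 2L)
  if (!is.matrix(out)) out <- matrix(out, nrow = m)
  out
}

#' Drop founder alleles through a pedigree
#'
#' Gene dropping: founder haplotype alleles are drawn independently per
#' site with probability `founder_maf` for the alt allele; each meiosis
#' transmits a recombinant gamete, with recombination between adjacent
#' sites given by Haldane's map function
#' `r = (1 - exp(-2 d / 100)) / 2` applied to the interpolated cM distance
#' `d`. The output is Mendelian-consistent by construction.
#'
#' @param ped A [pedigree].
#' @param sites Site definitions from [simulate_sites()] (requires a
#'   `founder_maf` column).
#' @param map Genetic-map anchors (as from [simulate_genetic_map()]); each
#'   chromosome in `sites` needs at least two anchors.
#' @param seed Integer seed.
#' @return A list of class `gene_drop` with elements `ped`, `sites`
#'   (including interpolated `pos_cM`), `hap_pat`, `hap_mat` (0/1 matrices,
#'   sites x individuals) and `geno` (`hap_pat + hap_mat`).
#' @export
gene_drop <- function(ped, sites, map, seed = 1) {
  missing_chr <- setdiff(unique(sites$chrom), unique(map$chrom))
  if (length(missing_chr) > 0) {
    stop("map error: no anchors for chromosome ", missing_chr[1])
  }
  imap <- interpolate_map(map, sites)
  set.seed(seed)
  n <- nrow(ped)
  m <- nrow(sites)
  hap_pat <- matrix(0L, m, n, dimnames = list(NULL, ped$id))
  hap_mat <- matrix(0L, m, n, dimnames = list(NULL, ped$id))
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  ord <- order(ped_depth(ped), ped$id)
  for (i in ord) {
    if (is.na(fi[i]) && is.na(mi[i])) {
      hap_pat[, i] <- stats::rbinom(m, 1L, sites$founder_maf)
      hap_mat[, i] <- stats::rbinom(m, 1L, sites$founder_maf)
    } else {
      # unknown single parents are modelled as unrelated population founders
      transmit <- function(pidx) {
        if (is.na(pidx)) return(stats::rbinom(m, 1L, sites$founder_maf))
        o <- sample_gamete_origins(1, sites$chrom, imap$pos_cM)[, 1]
        ifelse(o == 0L, hap_pat[, pidx], hap_mat[, pidx])
      }
      hap_pat[, i] <- transmit(fi[i])
      hap_mat[, i] <- transmit(mi[i])
    }
  }
  structure(list(ped = ped, sites = cbind(sites, pos_cM = imap$pos_cM),
                 hap_pat = hap_pat, hap_mat = hap_mat,
                 geno = hap_pat + hap_mat),
            class = "gene_drop")
}

#' Simulate per-site read counts from true genotypes
#'
#' Sequencing depth at each site of each individual is Poisson with the
#' individual's mean depth; each read reports the allele of a uniformly
#' chosen haplotype, flipped with probability `base_error`. Equivalently,
#' the alt-read count is binomial with success probability
#' `(g/2) (1 - base_error) + (1 - g/2) base_error` for dosage `g`.
#'
#' @param truth A `gene_drop` object (or a dosage matrix sites x samples).
#' @param mean_depth Named numeric vector of per-individual mean depths
#'   (a scalar is recycled to all samples).
#' @param base_error Per-read allele miscall probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return A list of class `read_data` with integer matrices `dp` and `ad`
#'   (sites x samples) and the scalar `base_error`.
#' @export
simulate_reads <- function(truth, mean_depth, base_error = 0.01, seed = 1) {
  stopifnot(base_error >= 0, base_error < 0.5)
  geno <- if (inherits(truth, "gene_drop")) truth$geno else truth
  ids <- colnames(geno)
  if (length(mean_depth) == 1 && is.null(names(mean_depth))) {
    mean_depth <- stats::setNames(rep(mean_depth, length(ids)), ids)
  }
  stopifnot(all(ids %in% names(mean_depth)))
  set.seed(seed)
  m <- nrow(geno)
  dp <- vapply(ids, function(id) stats::rpois(m, mean_depth[[id]]),
               integer(m))
  p_alt <- (geno / 2) * (1 - 2 * base_error) + base_error
  ad <- matrix(stats::rbinom(length(dp), as.vector(dp), as.vector(p_alt)),
               m, length(ids))
  dimnames(dp) <- dimnames(ad) <- list(NULL, ids)
  structure(list(dp = dp, ad = ad, base_error = base_error),
            class = "read_data")
}

#' Assemble a site panel from simulated truth and reads
#'
#' Combines site definitions, genotype calls (by default the true dosages)
#' and read matrices into a [site_panel].
#'
#' @param truth A `gene_drop` object.
#' @param reads Optional `read_data` from [simulate_reads()].
#' @param gt Optional genotype matrix overriding the true dosages (e.g.
#'   naive or refined calls).
#' @return A [site_panel].
#' @export
truth_to_panel <- function(truth, reads = NULL, gt = NULL) {
  g <- if (is.null(gt)) truth$geno else gt
  site_panel(truth$sites[, c("chrom", "pos", "ref", "alt")],
             gt = g,
             dp = if (!is.null(reads)) reads$dp,
             ad = if (!is.null(reads)) reads$ad,
             samples = colnames(truth$geno))
}
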