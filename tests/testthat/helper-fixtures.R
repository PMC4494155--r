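# Shared fixtures built in code.

trio_ped <- function() {
  pedigree(id = c("fa", "mo", "ch"),
           father = c(NA, NA, "fa"), mother = c(NA, NA, "mo"),
           sex = c("M", "F", "F"), birth_year = c(1990, 1991, 2000))
}

# A trio with simulated genome, truth and reads at the given depths.
trio_world <- function(sites_per_chrom = 1250, depths = c(fa = 30, mo = 6,
                                                          ch = 6),
                       base_error = 0.0075, seed = 11) {
  ped <- trio_ped()
  sites <- simulate_sites(n_chrom = 2, sites_per_chrom = sites_per_chrom,
                          chrom_bp = 5e7, seed = seed)
  gmap <- simulate_genetic_map(n_chrom = 2, chrom_bp = 5e7, seed = seed + 1)
  truth <- gene_drop(ped, sites, gmap, seed = seed + 2)
  reads <- simulate_reads(truth, depths, base_error, seed = seed + 3)
  units <- decompose_units(ped)
  list(ped = ped, truth = truth, reads = reads,
       unit = units[units$kind == "trio", ][1, ], base_error = base_error)
}

# Small uniform-depth panel with explicit genotype rows (one list element
# per site: integer dosage vector over samples).
panel_from_rows <- function(rows, samples, chrom = "chr1", start = 1000,
                            step = 100, depth = 20) {
  gt <- do.call(rbind, rows)
  colnames(gt) <- samples
  m <- nrow(gt)
  sites <- data.frame(chrom = chrom, pos = seq(start, by = step,
                                               length.out = m),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  dp <- matrix(depth, m, length(samples))
  ad <- matrix(0L, m, length(samples))
  site_panel(sites, gt, dp = dp, ad = ad, samples = samples)
}
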