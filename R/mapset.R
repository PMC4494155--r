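# Final panel construction: LD thinning to association/linkage marker
# sets, pedigree-wide Mendelian checks, genetic-map interpolation from STR
# anchors, and per-chromosome panel summaries.

#' LD thinning of a site panel
#'
#' Sliding-window greedy pruning at the given r-squared threshold (window
#' and shift counted in SNPs), identical to the engine behind
#' [ld_prune_for_ibd()]. The retained set is free of within-window pairs
#' exceeding the threshold.
#'
#' @param panel A [site_panel].
#' @param r2_threshold Squared-correlation ceiling in `(0, 1]`.
#' @param window,shift Window size and shift in SNPs.
#' @return Integer vector of retained site indices (ascending).
#' @export
ld_thin <- function(panel, r2_threshold, window = 50, shift = 20) {
  ld_prune(panel, r2_threshold, window, shift)
}

#' Exhaustive post-check of a thinned set
#'
#' Enumerates, per chromosome, every sliding window of the retained list
#' (the same window/shift grid the pruner uses) and exhaustively checks
#' all pairs inside each window, reporting pairs whose squared dosage
#' correlation exceeds the threshold. An empty result certifies the
#' thinning. Pairs that never share a window -- possible when their
#' spacing exceeds the window overlap -- are outside the windowed design
#' and are not constrained.
#'
#' @param panel The [site_panel] the thinning was computed on.
#' @param retained Integer site indices returned by [ld_thin()].
#' @param r2_threshold The threshold used.
#' @param window,shift Window size and shift in SNPs, matching the
#'   thinning call.
#' @return Data.frame of violating pairs (`i`, `j`, `r2`), empty when the
#'   thinning is valid.
#' @export
verify_ld_thinning <- function(panel, retained, r2_threshold, window = 50,
                               shift = 20) {
  viol <- list()
  sites <- panel$sites
  for (ch in unique(sites$chrom[retained])) {
    idx <- retained[sites$chrom[retained] == ch]
    if (length(idx) < 2) next
    starts <- unique(c(seq(1, max(length(idx) - window + 1, 1), by = shift),
                       max(length(idx) - window + 1, 1)))
    seen <- matrix(FALSE, length(idx), length(idx))
    for (s in starts) {
      win <- s:min(s + window - 1, length(idx))
      for (a in win[-length(win)]) {
        for (b in win[win > a]) {
          if (seen[a, b]) next
          seen[a, b] <- TRUE
          r2 <- suppressWarnings(
            stats::cor(panel$gt[idx[a], ], panel$gt[idx[b], ],
                       use = "pairwise.complete.obs"))^2
          if (!is.na(r2) && r2 > r2_threshold) {
            viol[[length(viol) + 1]] <- data.frame(i = idx[a], j = idx[b],
                                                   r2 = r2)
          }
        }
      }
    }
  }
  if (length(viol) == 0) {
    data.frame(i = integer(0), j = integer(0), r2 = numeric(0))
  } else {
    do.call(rbind, viol)
  }
}

#' Build nested association and linkage marker sets
#'
#' Thins a QC-passed panel at the association threshold (default
#' r-squared <= 0.9), then thins the association set further at the
#' linkage threshold (default r-squared <= 0.4) so the linkage set is
#' nested within the association set by construction. Sites failing the
#' pedigree-wide Mendelian check are removed from both sets.
#'
#' @param panel A [site_panel] of refined, QC-passed genotypes.
#' @param ped A [pedigree] for the Mendelian check (`NULL` to skip).
#' @param r2_assoc,r2_linkage Thinning thresholds.
#' @param window,shift Pruning window and shift in SNPs.
#' @return A list with integer index vectors `association` and `linkage`
#'   (indices into `panel`), and `mendel_removed` (indices removed by the
#'   pedigree-wide check).
#' @export
build_mapping_sets <- function(panel, ped = NULL, r2_assoc = 0.9,
                               r2_linkage = 0.4, window = 50, shift = 20) {
  assoc <- ld_thin(panel, r2_assoc, window, shift)
  sub <- subset_sites(panel, assoc)
  linkage <- assoc[ld_thin(sub, r2_linkage, window, shift)]
  mendel_removed <- integer(0)
  if (!is.null(ped)) {
    units <- decompose_units(ped, sequenced_only = FALSE)
    units <- units[units$child %in% panel$samples &
                     (is.na(units$father) | units$father %in% panel$samples) &
                     (is.na(units$mother) | units$mother %in% panel$samples),
                   , drop = FALSE]
    bad <- pedigree_mendel_check(panel, units)
    mendel_removed <- intersect(assoc, bad)
    assoc <- setdiff(assoc, bad)
    linkage <- setdiff(linkage, bad)
  }
  list(association = assoc, linkage = linkage,
       mendel_removed = mendel_removed)
}

#' Pedigree-wide Mendelian check
#'
#' Nuclear-family consistency: returns the sites at which at least one
#' trio or duo unit anywhere in the pedigree carries a Mendelianly
#' impossible genotype configuration.
#'
#' @param panel A [site_panel].
#' @param units A `nuclear_units` table restricted to samples present in
#'   the panel.
#' @return Integer vector of violating site indices (possibly empty).
#' @export
pedigree_mendel_check <- function(panel, units) {
  which(site_mendel_counts(panel$gt, units) >= 1L)
}

#' Interpolate a genetic map from anchor markers
#'
#' Piecewise-linear interpolation of centimorgan positions from physical
#' positions, per chromosome, using STR-style anchors. Beyond the terminal
#' anchors the terminal segment's slope extrapolates, floored at 0 cM;
#' monotonicity along each chromosome is enforced.
#'
#' @param anchors Data.frame with columns `chrom`, `pos_bp`, `pos_cM`
#'   (each chromosome needs at least two anchors).
#' @param snps Data.frame with columns `chrom` and `pos`.
#' @return `snps` with an added numeric column `pos_cM`.
#' @export
interpolate_map <- function(anchors, snps) {
  out_cm <- rep(NA_real_, nrow(snps))
  for (ch in unique(snps$chrom)) {
    a <- anchors[anchors$chrom == ch, , drop = FALSE]
    if (nrow(a) < 2) {
      stop("fewer than 2 genetic-map anchors on chromosome ", ch)
    }
    a <- a[order(a$pos_bp), , drop = FALSE]
    sel <- snps$chrom == ch
    x <- snps$pos[sel]
    cm <- stats::approx(a$pos_bp, a$pos_cM, xout = x, rule = 1, ties = "ordered")$y
    n <- nrow(a)
    lo <- x < a$pos_bp[1]
    hi <- x > a$pos_bp[n]
    slope_lo <- (a$pos_cM[2] - a$pos_cM[1]) / (a$pos_bp[2] - a$pos_bp[1])
    slope_hi <- (a$pos_cM[n] - a$pos_cM[n - 1]) /
      (a$pos_bp[n] - a$pos_bp[n - 1])
    cm[lo] <- a$pos_cM[1] + (x[lo] - a$pos_bp[1]) * slope_lo
    cm[hi] <- a$pos_cM[n] + (x[hi] - a$pos_bp[n]) * slope_hi
    cm <- pmax(cm, 0)
    cm[order(x)] <- cummax(cm[order(x)])
    out_cm[sel] <- cm
  }
  cbind(snps, pos_cM = out_cm)
}

#' Per-chromosome summary of a marker panel
#'
#' For each chromosome: marker count, density per Mb (count over the span
#' from first to last retained marker), maximum and mean gap between
#' consecutive markers, mean pairwise r-squared within consecutive
#' non-overlapping 5-marker windows, and mean heterozygosity.
#'
#' @param panel A [site_panel].
#' @param retained Optional integer index vector of retained sites
#'   (default: all).
#' @return A data.frame, one row per chromosome, columns `chrom`,
#'   `n_snps`, `snps_per_mb`, `max_gap_bp`, `mean_gap_bp`, `mean_r2_5win`,
#'   `mean_heterozygosity`. Gap and density columns are `NA` on
#'   single-marker chromosomes.
#' @export
summarize_panel <- function(panel, retained = NULL) {
  if (is.null(retained)) retained <- seq_len(n_sites(panel))
  hf <- het_fraction(panel)
  rows <- lapply(unique(panel$sites$chrom[retained]), function(ch) {
    idx <- retained[panel$sites$chrom[retained] == ch]
    pos <- panel$sites$pos[idx]
    n <- length(idx)
    if (n >= 2) {
      gaps <- diff(pos)
      span_mb <- (max(pos) - min(pos)) / 1e6
      dens <- n / span_mb
      max_gap <- max(gaps)
      mean_gap <- mean(gaps)
    } else {
      dens <- max_gap <- mean_gap <- NA_real_
    }
    r2s <- c()
    if (n >= 5) {
      for (s in seq(1, n - 4, by = 5)) {
        w <- idx[s:(s + 4)]
        cc <- suppressWarnings(
          stats::cor(t(panel$gt[w, , drop = FALSE]),
                     use = "pairwise.complete.obs"))^2
        r2s <- c(r2s, mean(cc[upper.tri(cc)], na.rm = TRUE))
      }
    }
    data.frame(chrom = ch, n_snps = n, snps_per_mb = dens,
               max_gap_bp = max_gap, mean_gap_bp = mean_gap,
               mean_r2_5win = if (length(r2s)) mean(r2s) else NA_real_,
               mean_heterozygosity = mean(hf[idx], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a site list as TSV
#' @param panel A [site_panel].
#' @param retained Integer index vector of retained sites.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_site_list <- function(panel, retained, path) {
  utils::write.table(panel$sites[retained, c("chrom", "pos", "ref", "alt")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
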