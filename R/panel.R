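# SitePanel: ordered biallelic sites with per-sample genotypes, depths and
# alt-read counts. Genotypes are alt-allele dosages 0/1/2 with NA = missing.

#' Construct a site panel
#'
#' The central container for variant data: a site table plus aligned
#' per-sample matrices of genotype dosage (`gt`), total read depth (`dp`)
#' and alt-supporting read count (`ad`).
#'
#' @param sites Data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (positions strictly increasing within a chromosome).
#' @param gt Integer matrix, sites x samples, values 0/1/2/NA.
#' @param dp,ad Optional integer matrices of the same shape: total depth
#'   and alt read count, with `ad <= dp`.
#' @param samples Character vector of sample ids; defaults to
#'   `colnames(gt)`.
#' @return An object of class `site_panel`: a list with elements `sites`,
#'   `gt`, `dp`, `ad`, `samples`.
#' @export
site_panel <- function(sites, gt, dp = NULL, ad = NULL,
                       samples = colnames(gt)) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(sites) == nrow(gt))
  if (is.null(samples)) stop("sample names required")
  colnames(gt) <- samples
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  if (!is.null(dp)) {
    stopifnot(all(dim(dp) == dim(gt)))
    colnames(dp) <- samples
  }
  if (!is.null(ad)) {
    stopifnot(!is.null(dp), all(dim(ad) == dim(gt)),
              all(ad <= dp, na.rm = TRUE))
    colnames(ad) <- samples
  }
  rownames(sites) <- NULL
  structure(list(sites = sites, gt = gt, dp = dp, ad = ad,
                 samples = samples),
            class = "site_panel")
}

#' @export
print.site_panel <- function(x, ...) {
  cat("site_panel:", nrow(x$sites), "sites x", length(x$samples),
      "samples on", length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Number of sites in a panel
#' @param panel A [site_panel].
#' @return Integer site count.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' Subset a panel by site index
#'
#' @param panel A [site_panel].
#' @param idx Logical or integer index over sites (order-preserving).
#' @return A [site_panel] restricted to the selected sites.
#' @export
subset_sites <- function(panel, idx) {
  site_panel(
    sites = panel$sites[idx, , drop = FALSE],
    gt = panel$gt[idx, , drop = FALSE],
    dp = if (!is.null(panel$dp)) panel$dp[idx, , drop = FALSE],
    ad = if (!is.null(panel$ad)) panel$ad[idx, , drop = FALSE],
    samples = panel$samples
  )
}

#' Per-site minor allele frequency
#'
#' MAF is computed from called genotypes: allele counts over non-missing
#' calls, folded to the rarer allele.
#'
#' @param panel A [site_panel].
#' @param ids Optional sample subset over which to count alleles.
#' @return Numeric vector of MAF per site; 0 where no calls are available.
#' @export
panel_maf <- function(panel, ids = NULL) {
  g <- if (is.null(ids)) panel$gt else panel$gt[, ids, drop = FALSE]
  ac <- rowSums(g, na.rm = TRUE)
  an <- 2 * rowSums(!is.na(g))
  p <- ifelse(an > 0, ac / an, 0)
  pmin(p, 1 - p)
}

#' Per-site heterozygous fraction
#'
#' Fraction of heterozygous calls among non-missing calls at each site.
#'
#' @param panel A [site_panel].
#' @return Numeric vector per site; `NaN` where all calls are missing.
#' @export
het_fraction <- function(panel) {
  nhet <- rowSums(panel$gt == 1L, na.rm = TRUE)
  ncall <- rowSums(!is.na(panel$gt))
  nhet / ncall
}

#' Per-site missing-call fraction
#' @param panel A [site_panel].
#' @return Numeric vector per site in `[0, 1]`.
#' @export
missing_fraction <- function(panel) rowMeans(is.na(panel$gt))

#' Write a panel as VCF text
#'
#' Emits an uncompressed VCFv4.2 file with `GT:AD:DP` genotype fields
#' (unphased calls; `AD` lists ref,alt supporting reads). Output is
#' byte-deterministic for identical panels.
#'
#' @param panel A [site_panel].
#' @param path Output path (`.vcf`).
#' @return Invisibly, `path`.
#' @seealso [read_panel_vcf()]
#' @export
write_panel_vcf <- function(panel, path) {
  gt_chr <- matrix("./.", nrow = n_sites(panel), ncol = length(panel$samples))
  gt_chr[which(panel$gt == 0L)] <- "0/0"
  gt_chr[which(panel$gt == 1L)] <- "0/1"
  gt_chr[which(panel$gt == 2L)] <- "1/1"
  if (!is.null(panel$dp)) {
    dp <- panel$dp
    ad <- if (!is.null(panel$ad)) panel$ad else matrix(0L, nrow(dp), ncol(dp))
    fld <- paste0(gt_chr, ":", dp - ad, ",", ad, ":", dp)
    fld[is.na(dp)] <- gt_chr[is.na(dp)]
    fmt <- "GT:AD:DP"
  } else {
    fld <- gt_chr
    fmt <- "GT"
  }
  dim(fld) <- dim(gt_chr)
  body <- paste(panel$sites$chrom, panel$sites$pos,
                paste0(panel$sites$chrom, "_", panel$sites$pos),
                panel$sites$ref, panel$sites$alt, ".", "PASS", ".", fmt,
                apply(fld, 1, paste, collapse = "\t"),
                sep = "\t")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pedpanel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a panel from a VCF file
#'
#' Parses a VCF via the vcfR package into a [site_panel]. Multi-allelic or
#' multi-nucleotide records are retained with `gt = NA` so that downstream
#' structural filters can count and remove them.
#'
#' @param path Path to a `.vcf` (or `.vcf.gz`) file.
#' @return A [site_panel].
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  gtc <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(NA_integer_, nrow(gtc), ncol(gtc))
  core <- gsub("\\|", "/", gtc)
  gt[core == "0/0"] <- 0L
  gt[core %in% c("0/1", "1/0")] <- 1L
  gt[core == "1/1"] <- 2L
  dp <- ad <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    mode(dp) <- "integer"
    adc <- vcfR::extract.gt(v, element = "AD")
    if (!all(is.na(adc))) {
      ad <- suppressWarnings(
        matrix(as.integer(sub("^[0-9]+,", "", adc)), nrow(adc), ncol(adc))
      )
      ad[is.na(dp)] <- NA_integer_
    }
    dimnames(dp) <- NULL
    if (!is.null(ad)) dimnames(ad) <- NULL
  }
  dimnames(gt) <- NULL
  site_panel(sites, gt, dp = dp, ad = ad, samples = colnames(gtc))
}
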