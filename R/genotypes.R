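# Donor genotype loading and variant filtering.
#
# The likelihood only uses the alternate-allele frequency gamma[v, i] of
# each retained variant in each donor, so loading reduces a VCF to a
# variants x donors matrix plus coordinates. Retained sites are biallelic
# SNPs, fully genotyped in the requested donors, and polymorphic across
# them (a monomorphic site carries no demultiplexing information).

#' Load donor genotypes from a VCF
#'
#' Reads a VCF (plain or gzipped), restricts it to the requested donors in
#' the requested order, and applies the model's variant filters: keep
#' biallelic SNPs, drop sites with any missing genotype among the retained
#' donors, and drop sites monomorphic across them. Genotypes are encoded as
#' alternate-allele frequencies: 0/0 -> 0, 0/1 -> 0.5, 1/1 -> 1. With
#' `use_dosage = TRUE` the DS FORMAT field is used instead where present
#' (values clipped to \[0, 2\] and halved).
#'
#' @param vcf_path path to a VCF or VCF.gz with a GT FORMAT field.
#' @param donor_ids character vector of sample names to retain; default all
#'   samples in file order.
#' @param use_dosage prefer the DS field over GT when present.
#' @return A [GenotypeMatrix-class].
#' @examples
#' vcf <- system.file("extdata", "toy_donors.vcf", package = "demuxamb")
#' gm <- readGenotypes(vcf)
#' gammaMatrix(gm)
#' @export
readGenotypes <- function(vcf_path, donor_ids = NULL, use_dosage = FALSE) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (ncol(v@gt) < 2L)
    stop("VCF has no sample columns: ", vcf_path)
  samples <- colnames(v@gt)[-1L]
  if (is.null(donor_ids)) donor_ids <- samples
  missing <- setdiff(donor_ids, samples)
  if (length(missing))
    stop("donor(s) not present in VCF: ", paste(missing, collapse = ", "))
  fmt <- v@gt[, 1L]
  if (!any(grepl("(^|:)GT(:|$)", fmt)))
    stop("VCF FORMAT has no GT field: ", vcf_path)

  fix <- v@fix
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[, donor_ids, drop = FALSE]
  enc <- .encode_gt(gt)
  if (use_dosage && any(grepl("(^|:)DS(:|$)", fmt))) {
    ds <- suppressWarnings(
      matrix(as.numeric(vcfR::extract.gt(v, element = "DS")[, donor_ids,
                                                            drop = FALSE]),
             nrow = nrow(gt)))
    keep_ds <- !is.na(ds)
    enc[keep_ds] <- pmin(pmax(ds[keep_ds], 0), 2) / 2
  }
  complete <- !apply(is.na(enc), 1L, any)
  keep <- snp & complete
  enc <- enc[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
               sep = ":")
  if (anyDuplicated(ids)) {
    warning(sum(duplicated(ids)), " duplicated variant record(s) dropped")
    first <- !duplicated(ids)
    enc <- enc[first, , drop = FALSE]; fix <- fix[first, , drop = FALSE]
    ids <- ids[first]
  }
  rownames(enc) <- ids
  colnames(enc) <- donor_ids
  gr <- GRanges(fix[, "CHROM"],
                IRanges(as.integer(fix[, "POS"]), width = 1L),
                ref = fix[, "REF"], alt = fix[, "ALT"])
  names(gr) <- ids
  dropMonomorphic(GenotypeMatrix(enc, gr))
}

.encode_gt <- function(gt) {
  # strip phase, tolerate extra fields already removed by extract.gt
  g <- gsub("|", "/", gt, fixed = TRUE)
  out <- matrix(NA_real_, nrow(gt), ncol(gt))
  out[g %in% c("0/0", "0")] <- 0
  out[g %in% c("0/1", "1/0")] <- 0.5
  out[g %in% c("1/1", "1")] <- 1
  out
}

#' Drop variants monomorphic across the retained donors
#'
#' A variant where all donors share the same genotype cannot distinguish
#' donors and is removed. With a single donor every variant is trivially
#' monomorphic; the matrix is returned unchanged in that degenerate case.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return A [GenotypeMatrix-class] without monomorphic variants.
#' @export
dropMonomorphic <- function(gm) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (nDonors(gm) < 2L || nVariants(gm) == 0L) return(gm)
  g <- gm@gamma
  poly <- matrixStats_rowMax(g) != matrixStats_rowMin(g)
  GenotypeMatrix(g[poly, , drop = FALSE], gm@ranges[poly])
}

# small row-extrema helpers (avoid a matrixStats dependency)
matrixStats_rowMax <- function(m) do.call(pmax, as.data.frame(m))
matrixStats_rowMin <- function(m) do.call(pmin, as.data.frame(m))

#' Subset variants by genomic intervals
#'
#' Keeps variants overlapping `region_mask` (any-overlap), preserving donor
#' order. Intended for restricting inference to peak regions or chromosomes.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param region_mask `GRanges` of intervals to keep, or `NULL` for no
#'   filtering. BED input should be converted upstream (BED is 0-based
#'   half-open; [rtracklayer::import()] performs the conversion).
#' @return A [GenotypeMatrix-class] restricted to overlapping variants.
#' @export
filterVariants <- function(gm, region_mask = NULL) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (is.null(region_mask)) return(gm)
  # disjoint seqlevels are a legitimate empty result, not a user warning
  keep <- suppressWarnings(overlapsAny(gm@ranges, region_mask))
  if (!any(keep)) warning("no variants overlap the region mask")
  GenotypeMatrix(gm@gamma[keep, , drop = FALSE], gm@ranges[keep])
}

#' Subset donors of a GenotypeMatrix
#'
#' Restricts the matrix to the given donors (in the given order) and, by
#' default, re-applies the monomorphic filter, since a site polymorphic in
#' the full pool can be monomorphic in a subset.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param donors character vector of donor names to keep.
#' @param drop_monomorphic re-filter monomorphic sites (default `TRUE`).
#' @return A [GenotypeMatrix-class].
#' @export
subsetDonors <- function(gm, donors, drop_monomorphic = TRUE) {
  stopifnot(is(gm, "GenotypeMatrix"))
  missing <- setdiff(donors, donorNames(gm))
  if (length(missing))
    stop("donor(s) not present: ", paste(missing, collapse = ", "))
  out <- GenotypeMatrix(gm@gamma[, donors, drop = FALSE], gm@ranges)
  if (drop_monomorphic) out <- dropMonomorphic(out)
  out
}

#' Write a GenotypeMatrix back to VCF (gzipped)
#'
#' Writes the retained variants and donors as a minimal VCF with a GT field
#' (and a DS field when fractional dosages are present), for provenance.
#' Output is gzip-compressed; a `.gz` suffix is appended if absent.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path (`.vcf.gz`).
#' @return The path written, invisibly.
#' @export
writeGenotypesVcf <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  g <- gm@gamma
  hard <- all(g %in% c(0, 0.5, 1))
  gt_chr <- matrix("./.", nrow(g), ncol(g))
  gt_chr[g == 0] <- "0/0"
  gt_chr[g == 0.5] <- "0/1"
  gt_chr[g == 1] <- "1/1"
  if (!hard) {
    frac <- !(g %in% c(0, 0.5, 1))
    gt_chr[frac] <- ifelse(round(2 * g[frac]) == 0, "0/0",
                           ifelse(round(2 * g[frac]) == 1, "0/1", "1/1"))
    gt_chr[] <- paste0(gt_chr, ":", format(2 * g, trim = TRUE, digits = 6))
  }
  fmt <- if (hard) "GT" else "GT:DS"
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!hard)
    meta <- c(meta, paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
                           "Description=\"Dosage\">"))
  r <- gm@ranges
  fix <- cbind(CHROM = as.character(seqnames(r)),
               POS = as.character(start(r)),
               ID = names(r), REF = mcols(r)$ref, ALT = mcols(r)$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  gt <- cbind(FORMAT = rep(fmt, nrow(g)), gt_chr)
  colnames(gt) <- c("FORMAT", colnames(g))
  v <- methods::new(methods::getClass("vcfR",
                                      where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
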