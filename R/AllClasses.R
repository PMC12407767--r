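setOldClass(c("data.table", "data.frame"))

#' GenotypeMatrix: donor genotypes at biallelic SNPs
#'
#' Stores the alternate-allele frequency gamma[v, i] of each variant v
#' (rows) in each pooled donor i (columns). Hard diploid genotypes are
#' encoded 0 (hom ref), 0.5 (het), and 1 (hom alt); fractional dosages are
#' permitted. Variant coordinates are 1-based and carried as a
#' [GenomicRanges::GRanges] with `ref` and `alt` metadata columns; variant
#' identifiers are `chrom:pos:ref:alt`.
#'
#' @slot gamma numeric matrix, variants x donors, values in \[0, 1\].
#' @slot ranges `GRanges` of variant positions, names = variant ids,
#'   mcols `ref` and `alt` (single bases).
#'
#' @seealso [readGenotypes()], [filterVariants()], [dropMonomorphic()]
#' @export
setClass("GenotypeMatrix",
  representation(gamma = "matrix", ranges = "GRanges"))

setValidity("GenotypeMatrix", function(object) {
  g <- object@gamma
  r <- object@ranges
  msg <- character()
  if (nrow(g) != length(r))
    msg <- c(msg, "nrow(gamma) must equal length(ranges)")
  if (is.null(colnames(g)) || anyDuplicated(colnames(g)))
    msg <- c(msg, "donor names (colnames of gamma) must be unique and non-NULL")
  if (nrow(g) > 0) {
    if (is.null(rownames(g)) || anyDuplicated(rownames(g)))
      msg <- c(msg, "variant ids (rownames of gamma) must be unique")
    if (!is.null(names(r)) && !identical(rownames(g), names(r)))
      msg <- c(msg, "rownames(gamma) must match names(ranges)")
    if (anyNA(g) || any(g < 0) || any(g > 1))
      msg <- c(msg, "gamma values must be in [0, 1] with no NAs")
    refs <- mcols(r)$ref; alts <- mcols(r)$alt
    if (is.null(refs) || is.null(alts))
      msg <- c(msg, "ranges must carry 'ref' and 'alt' metadata columns")
    else if (any(nchar(refs) != 1L) || any(nchar(alts) != 1L) ||
             any(refs == alts))
      msg <- c(msg, "all variants must be biallelic SNPs (single, distinct bases)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param gamma variants x donors matrix of alternate-allele frequencies,
#'   rownames variant ids, colnames donor ids.
#' @param ranges `GRanges` of the variants (names matching rownames of
#'   `gamma`), with `ref`/`alt` mcols.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(gamma, ranges) {
  if (is.null(names(ranges))) names(ranges) <- rownames(gamma)
  new("GenotypeMatrix", gamma = gamma, ranges = ranges)
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@gamma), "variants x",
      ncol(object@gamma), "donors\n")
  cat("  donors:", paste(head(colnames(object@gamma), 8), collapse = ", "),
      if (ncol(object@gamma) > 8) "..." else "", "\n")
})

#' MoleculeTable: deduplicated molecules and their variant base calls
#'
#' Per-droplet molecule evidence for inference. A molecule is a deduplicated
#' unit: an RNA UMI group or an ATAC fragment. Molecules overlapping
#' genotyped SNPs ("informative" molecules) are listed in `calls` with one
#' row per (molecule, variant) base call. Molecules with no variant overlap
#' carry no likelihood terms and are kept only as counts in `coverage`;
#' they still count toward per-droplet coverage and the test-droplet rule.
#'
#' @slot calls data.table with columns `barcode`, `modality` ("RNA"/"ATAC"),
#'   `molecule` (id, unique within barcode x modality), `region` ("intra",
#'   "inter" for ATAC; "na" for RNA), `variant` (variant id), `allele`
#'   (0 = ref, 1 = alt), `qual` (Phred).
#' @slot coverage data.table with columns `barcode`, `modality`, `region`,
#'   `n_molecules` (all molecules, informative or not).
#'
#' @seealso [pileupBam()], [readMoleculeTable()], [selectMolecules()]
#' @export
setClass("MoleculeTable",
  representation(calls = "data.table", coverage = "data.table"))

.mt_call_cols <- c("barcode", "modality", "molecule", "region",
                   "variant", "allele", "qual")
.mt_cov_cols  <- c("barcode", "modality", "region", "n_molecules")

setValidity("MoleculeTable", function(object) {
  msg <- character()
  cl <- object@calls; cv <- object@coverage
  if (!all(.mt_call_cols %in% names(cl)))
    msg <- c(msg, paste("calls must have columns:",
                        paste(.mt_call_cols, collapse = ", ")))
  if (!all(.mt_cov_cols %in% names(cv)))
    msg <- c(msg, paste("coverage must have columns:",
                        paste(.mt_cov_cols, collapse = ", ")))
  if (!length(msg) && nrow(cl)) {
    if (!all(cl$allele %in% c(0L, 1L)))
      msg <- c(msg, "allele must be 0 or 1")
    if (any(cl$qual < 0))
      msg <- c(msg, "qual must be >= 0")
    if (!all(cl$modality %in% c("RNA", "ATAC")))
      msg <- c(msg, "modality must be 'RNA' or 'ATAC'")
    bad <- cl$modality == "RNA" & cl$region != "na"
    if (any(bad)) msg <- c(msg, "RNA molecules must have region 'na'")
    if (anyDuplicated(cl[, c("barcode", "modality", "molecule", "variant")]))
      msg <- c(msg, "duplicate (barcode, modality, molecule, variant) base call")
  }
  if (!length(msg) && nrow(cv)) {
    if (anyDuplicated(cv[, c("barcode", "modality", "region")]))
      msg <- c(msg, "coverage rows must be unique per (barcode, modality, region)")
    if (any(cv$n_molecules < 0))
      msg <- c(msg, "n_molecules must be >= 0")
    # coverage must account for at least the informative molecules
    if (nrow(cl)) {
      ninf <- cl[, .(n_inf = data.table::uniqueN(molecule)),
                 by = c("barcode", "modality", "region")]
      m <- merge(ninf, cv, by = c("barcode", "modality", "region"),
                 all.x = TRUE)
      if (anyNA(m$n_molecules) || any(m$n_molecules < m$n_inf))
        msg <- c(msg, "coverage n_molecules must be >= informative molecules")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MoleculeTable
#'
#' @param calls data.table of base calls (see [MoleculeTable-class]). May
#'   have zero rows.
#' @param coverage data.table of per (barcode, modality, region) molecule
#'   counts. If `NULL`, derived from `calls` (every molecule informative).
#' @return A [MoleculeTable-class] object.
#' @export
MoleculeTable <- function(calls, coverage = NULL) {
  calls <- as.data.table(calls)
  if (nrow(calls)) {
    calls[, allele := as.integer(allele)]
    calls[, qual := as.numeric(qual)]
  } else {
    calls <- data.table(barcode = character(), modality = character(),
                        molecule = character(), region = character(),
                        variant = character(), allele = integer(),
                        qual = numeric())
  }
  if (is.null(coverage)) {
    coverage <- calls[, .(n_molecules = data.table::uniqueN(molecule)),
                      by = c("barcode", "modality", "region")]
  }
  coverage <- as.data.table(coverage)
  if (!nrow(coverage))
    coverage <- data.table(barcode = character(), modality = character(),
                           region = character(), n_molecules = integer())
  new("MoleculeTable", calls = calls, coverage = coverage)
}

setMethod("show", "MoleculeTable", function(object) {
  cv <- object@coverage
  nb <- data.table::uniqueN(cv$barcode)
  cat("MoleculeTable:", nb, "barcodes,",
      sum(cv$n_molecules), "molecules,",
      nrow(object@calls), "base calls\n")
  if (nrow(cv)) {
    tab <- cv[, .(n = sum(n_molecules)), by = "modality"]
    cat("  molecules by modality:",
        paste(sprintf("%s=%d", tab$modality, tab$n), collapse = ", "), "\n")
  }
})

#' SimTruth: ground truth emitted by the droplet simulator
#'
#' @slot droplets data.table, one row per simulated barcode: `barcode`,
#'   `n_nuclei` (0/1/2), `donor1`, `donor2`, `cell_type1`, `cell_type2`,
#'   `alpha_true` (drawn ambient fraction; 1 for empty droplets),
#'   `p_peak` (droplet intra-peak probability), `m_rna`, `m_atac`
#'   (molecule counts), `inf_rna`, `inf_atac` (informative molecules),
#'   `amb_frac_rna`, `amb_frac_atac` (realized ambient molecule fractions).
#' @slot origins data.table of per-informative-molecule origin labels:
#'   `barcode`, `modality`, `molecule`, `origin` (0 = ambient, otherwise
#'   donor index), plus RNA `spliced` flag and sampled `feature`.
#' @slot params list: the generating configuration (resolved) and the true
#'   ambient donor proportions.
#' @export
setClass("SimTruth",
  representation(droplets = "data.table", origins = "data.table",
                 params = "list"))

setMethod("show", "SimTruth", function(object) {
  d <- object@droplets
  cat("SimTruth:", nrow(d), "droplets (",
      sum(d$n_nuclei == 0), "empty,", sum(d$n_nuclei == 1), "singlet,",
      sum(d$n_nuclei == 2), "doublet )\n")
})

#' DemuxFit: fitted droplet model
#'
#' Result of [demuxFit()]. Holds, for every test droplet, the log-likelihood
#' of each (droplet type, donor composition) hypothesis at its fitted
#' ambient fractions, plus the fitted global parameters.
#'
#' @slot barcodes character, test droplet barcodes (row order of matrices).
#' @slot fixed_empty character, barcodes below the coverage threshold,
#'   treated as empty (posterior 1 on empty).
#' @slot hyp data.frame enumerating hypotheses: `h` (0/1/2), `i`, `j`
#'   (donor indices, NA where absent), `label`.
#' @slot loglik droplets x hypotheses log-likelihood matrix (at fitted
#'   alpha, including hypothesis priors).
#' @slot alpha_rna,alpha_atac droplets x hypotheses fitted ambient
#'   fractions per modality (1 for the empty hypothesis).
#' @slot coverage data.table: per barcode and modality, `n_molecules` and
#'   `n_informative` (all barcodes, including fixed-empty).
#' @slot params list: fitted `lambda`, `pi_c`, `pi_a`, `beta` (per
#'   modality), `donors`, and the configuration used.
#' @slot converged logical; `n_iter` integer; `trace` data.table of
#'   per-iteration parameter deltas.
#' @export
setClass("DemuxFit",
  representation(barcodes = "character", fixed_empty = "character",
                 hyp = "data.frame", loglik = "matrix",
                 alpha_rna = "matrix", alpha_atac = "matrix",
                 coverage = "data.table", params = "list",
                 converged = "logical", n_iter = "integer",
                 trace = "data.table"))

setMethod("show", "DemuxFit", function(object) {
  cat("DemuxFit:", length(object@barcodes), "test droplets,",
      length(object@fixed_empty), "fixed-empty,",
      nrow(object@hyp), "hypotheses,",
      length(object@params$donors), "donors\n")
  cat("  converged:", object@converged, "after", object@n_iter,
      "iterations\n")
  cat("  lambda:", paste(sprintf("%.4f", object@params$lambda),
                         collapse = ", "), "\n")
})
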