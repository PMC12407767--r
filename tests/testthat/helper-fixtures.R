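# Small fixtures built in code.

library(data.table)

# two-donor genotype matrix with hand-picked genotypes
toy_gm2 <- function() {
  g <- matrix(c(0, 0.5, 1, 0,
                1, 0.5, 0, 0.5), 4, 2,
              dimnames = list(NULL, c("dA", "dB")))
  pos <- c(100L, 200L, 300L, 400L)
  ref <- c("A", "C", "G", "T"); alt <- c("G", "T", "A", "C")
  ids <- paste("c1", pos, ref, alt, sep = ":")
  rownames(g) <- ids
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(pos, width = 1L),
                               ref = ref, alt = alt)
  names(gr) <- ids
  GenotypeMatrix(g, gr)
}

# three-donor matrix (donor C distinct everywhere possible)
toy_gm3 <- function() {
  g <- matrix(c(0, 0, 1, 0.5, 1,
                1, 0.5, 0, 0.5, 0,
                0.5, 1, 0.5, 0, 1), 5, 3,
              dimnames = list(NULL, c("dA", "dB", "dC")))
  pos <- seq(100L, 500L, by = 100L)
  ref <- rep("A", 5); alt <- rep("T", 5)
  ids <- paste("c1", pos, ref, alt, sep = ":")
  rownames(g) <- ids
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(pos, width = 1L),
                               ref = ref, alt = alt)
  names(gr) <- ids
  GenotypeMatrix(g, gr)
}

# molecule table from a compact spec: list of molecules, each
# list(barcode, modality, molecule, region, calls = data.frame(variant,
# allele, qual))
toy_mt <- function(mols, extra_cov = NULL) {
  calls <- rbindlist(lapply(mols, function(m) {
    if (is.null(m$calls) || !NROW(m$calls)) return(NULL)
    data.table(barcode = m$barcode, modality = m$modality,
               molecule = m$molecule,
               region = m$region %||% if (m$modality == "RNA") "na"
               else "intra",
               variant = m$calls$variant,
               allele = as.integer(m$calls$allele),
               qual = as.numeric(m$calls$qual))
  }))
  cov <- rbindlist(lapply(mols, function(m)
    data.table(barcode = m$barcode, modality = m$modality,
               region = m$region %||% if (m$modality == "RNA") "na"
               else "intra")))
  cov <- cov[, .(n_molecules = .N), by = c("barcode", "modality",
                                           "region")]
  if (!is.null(extra_cov)) {
    cov <- rbindlist(list(cov, as.data.table(extra_cov)))
    cov <- cov[, .(n_molecules = sum(n_molecules)),
               by = c("barcode", "modality", "region")]
  }
  MoleculeTable(calls = if (is.null(calls)) data.table() else calls,
                coverage = cov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small but realistic simulated experiment for integration-style unit
# tests (cheap: ~30k molecules)
small_sim <- function(seed = 101, n_donors = 4, ambient = "low",
                      n_cellular = 120, n_empty = 400,
                      coverage_mean = 400, ...) {
  cfg <- simConfig(n_cellular = n_cellular, n_empty = n_empty,
                   n_donors = n_donors, n_variants = 3000,
                   coverage_mean = coverage_mean, ambient = ambient, ...)
  simulateExperiment(cfg, seed = seed)
}

# hand-built fit with controlled log-likelihoods
mini_fit <- function(ll, donors = c("d1", "d2"), fixed_empty = character(),
                     alpha = NULL, n_inf = 20L) {
  hyp <- hypothesisSpace(donors)
  stopifnot(ncol(ll) == nrow(hyp))
  colnames(ll) <- hyp$label
  if (is.null(rownames(ll)))
    rownames(ll) <- sprintf("b%02d", seq_len(nrow(ll)))
  a <- if (is.null(alpha))
    matrix(0.2, nrow(ll), ncol(ll), dimnames = dimnames(ll)) else alpha
  a[, hyp$h == 0] <- 1
  cov <- CJ(barcode = c(rownames(ll), fixed_empty),
            modality = c("RNA", "ATAC"))
  cov[, `:=`(n_molecules = 200L,
             n_informative = rep(as.integer(n_inf),
                                 length.out = .N))]
  new("DemuxFit", barcodes = rownames(ll), fixed_empty = fixed_empty,
      hyp = hyp, loglik = ll, alpha_rna = a, alpha_atac = a,
      coverage = cov,
      params = list(lambda = c(0.3, 0.6, 0.1),
                    pi_c = setNames(rep(1 / length(donors),
                                        length(donors)), donors),
                    pi_a = setNames(rep(1 / length(donors),
                                        length(donors)), donors),
                    beta = c(RNA = 0.1, ATAC = 0.1), donors = donors,
                    config = list()),
      converged = TRUE, n_iter = 3L,
      trace = data.table(iter = 1:3, delta = 0))
}

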