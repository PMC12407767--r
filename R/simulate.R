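# Droplet simulator (abstract mode).
#
# Generates multiome droplets with known donor composition and ambient
# fractions, for benchmarking demultiplexing and ambient estimation with
# ground truth. Two droplet sets are produced: cellular droplets (90%
# singlets / 10% doublets by default) with per-modality molecule counts
# from a negative binomial (mean 5,000, size 1.5, clipped to
# [200, 100,000]) and a per-droplet ambient fraction from a Beta whose
# shapes set the contamination level (low (2,18), medium (4,16), high
# (6,14)); and empty droplets whose molecules are all ambient and whose
# counts follow NB(mean 2, size 0.1). Molecules carry cell-type-sampled
# features, splice states (spliced with probability 0.4 for cellular
# molecules, 0.6 for ambient), ATAC intra-peak indicators (droplet-level
# peak probability Beta(4,6) cellular / Beta(1,9) empty), and base calls
# at overlapping SNPs drawn from the origin's allele frequency with a 1%
# uniform sequencing error. In abstract mode the number of SNPs a
# molecule overlaps is Poisson(overlap_rate) instead of arising from read
# placement on a genome.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration
#'
#' Builds and validates the configuration of [simulateExperiment()]. The
#' defaults are the standard simulated experiment: 10,000 cellular
#' droplets with a 10% doublet rate, eight donors pooled uniformly,
#' 20,000 empty droplets, NB(5,000, 1.5) coverage clipped to
#' \[200, 100,000\] per modality, and one ambient-fraction draw per
#' droplet applied to both modalities.
#'
#' @param n_cellular cellular droplet count (default 10,000).
#' @param doublet_rate doublet probability among cellular droplets
#'   (default 0.10). Doublet donors are drawn independently, so
#'   self-doublets occur in truth; evaluation treats them as singlets.
#' @param n_donors pooled donor count (default 8).
#' @param donor_cell_props donor proportions among nuclei (default
#'   uniform).
#' @param donor_ambient_props donor proportions in the ambient pool
#'   (default uniform).
#' @param ambient contamination level: `"low"`, `"medium"`, `"high"`
#'   (Beta shapes (2,18), (4,16), (6,14); means 0.1/0.2/0.3), `"mixed"`
#'   (equal mixture of the three), or a list `list(type = "beta",
#'   shape1 =, shape2 =)` / `list(type = "uniform", min =, max =)`.
#' @param n_empty empty droplet count (default 20,000).
#' @param empty_coverage_mean,empty_coverage_size NB parameters of empty
#'   droplet molecule counts (default mean 2, size 0.1).
#' @param coverage_mean,coverage_size,coverage_min,coverage_max cellular
#'   molecule-count NB parameters and clipping bounds per modality.
#' @param n_cell_types,n_genes,n_peaks cell-type count and feature space
#'   sizes for the multinomial profiles.
#' @param spliced_prob_cell,spliced_prob_amb probability an RNA molecule
#'   is spliced, by origin (nuclear RNA is enriched for unspliced).
#' @param peak_beta_cell,peak_beta_empty Beta shapes of the droplet-level
#'   intra-peak probability for cellular / empty droplets.
#' @param insert_range ATAC insert size range, sampled uniformly
#'   (sequence mode).
#' @param error_rate per-base sequencing error probability (default
#'   0.01); an erroneous base is replaced by any of the four nucleotides
#'   equally, so half of the errors at a SNP fall outside ref/alt and the
#'   call is dropped, mirroring pileup behavior.
#' @param qual constant Phred quality attached to abstract-mode base
#'   calls (default 30).
#' @param overlap_rate abstract-mode Poisson rate of SNP overlaps per
#'   molecule (default 0.12, the realistic regime of roughly one SNP per
#'   750 bp seen through a ~90 bp window).
#' @param n_variants,maf_range synthetic SNP panel size and the uniform
#'   population allele-frequency range used for Hardy-Weinberg genotype
#'   draws.
#' @param read_len,n_chrom,chrom_len,snp_spacing,gene_len,n_isoforms_max,
#'   peak_len sequence-mode geometry (synthetic genome).
#' @return A validated `SimConfig` (named list).
#' @export
simConfig <- function(n_cellular = 10000, doublet_rate = 0.10,
                      n_donors = 8, donor_cell_props = NULL,
                      donor_ambient_props = NULL, ambient = "low",
                      n_empty = 20000, empty_coverage_mean = 2,
                      empty_coverage_size = 0.1, coverage_mean = 5000,
                      coverage_size = 1.5, coverage_min = 200,
                      coverage_max = 100000, n_cell_types = 9,
                      n_genes = 1000, n_peaks = 2000,
                      spliced_prob_cell = 0.4, spliced_prob_amb = 0.6,
                      peak_beta_cell = c(4, 6), peak_beta_empty = c(1, 9),
                      insert_range = c(0, 150), error_rate = 0.01,
                      qual = 30, overlap_rate = 0.12, n_variants = 100000,
                      maf_range = c(0.05, 0.5), read_len = 90,
                      n_chrom = 2, chrom_len = 1e6, snp_spacing = 750,
                      gene_len = 2000, n_isoforms_max = 3,
                      peak_len = 400) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_cellular >= 1, cfg$n_donors >= 1,
            cfg$doublet_rate >= 0, cfg$doublet_rate < 1,
            cfg$n_empty >= 0, cfg$coverage_min <= cfg$coverage_max,
            cfg$n_cell_types >= 1, cfg$error_rate >= 0,
            cfg$error_rate <= 1, cfg$overlap_rate > 0,
            all(cfg$peak_beta_cell > 0), all(cfg$peak_beta_empty > 0))
  for (nm in c("donor_cell_props", "donor_ambient_props")) {
    p <- cfg[[nm]]
    if (!is.null(p)) {
      stopifnot(length(p) == cfg$n_donors, all(p >= 0), sum(p) > 0)
      cfg[[nm]] <- p / sum(p)
    }
  }
  cfg$ambient <- .resolve_ambient(cfg$ambient)
  structure(cfg, class = "SimConfig")
}

.ambient_shapes <- list(low = c(2, 18), medium = c(4, 16),
                        high = c(6, 14))

.resolve_ambient <- function(a) {
  if (is.character(a) && length(a) == 1L) {
    if (a == "mixed") return(list(type = "mixed"))
    if (!a %in% names(.ambient_shapes))
      stop("unknown ambient level: ", a)
    sh <- .ambient_shapes[[a]]
    return(list(type = "beta", shape1 = sh[1], shape2 = sh[2], level = a))
  }
  stopifnot(is.list(a), a$type %in% c("beta", "uniform", "mixed"))
  if (a$type == "beta") stopifnot(a$shape1 > 0, a$shape2 > 0)
  if (a$type == "uniform")
    stopifnot(a$min >= 0, a$max <= 1, a$min < a$max)
  a
}

.sample_ambient <- function(n, a) {
  switch(a$type,
    beta = rbeta(n, a$shape1, a$shape2),
    uniform = runif(n, a$min, a$max),
    mixed = {
      lvl <- sample.int(3L, n, replace = TRUE)
      sh <- matrix(unlist(.ambient_shapes), nrow = 2L)
      rbeta(n, sh[1L, lvl], sh[2L, lvl])
    })
}

#' Generate a synthetic donor pool (genotypes and cell-type profiles)
#'
#' SNP population alternate-allele frequencies are uniform on `maf_range`
#' and donor genotypes are drawn under Hardy-Weinberg equilibrium
#' (Binomial(2, p)/2); sites monomorphic across the pool are redrawn so
#' the returned matrix satisfies the genotype-matrix invariants.
#' Cell-type multinomial feature profiles (genes for RNA, peaks for ATAC)
#' are drawn from a symmetric Dirichlet.
#'
#' @param n_donors,n_variants pool dimensions.
#' @param maf_range uniform range of population allele frequencies.
#' @param n_cell_types,n_genes,n_peaks profile dimensions.
#' @param concentration symmetric Dirichlet concentration (default 1).
#' @param donor_names optional donor names (default `donor01`, ...).
#' @return list: `genotypes` ([GenotypeMatrix-class]), `profiles`
#'   (list `rna`, `atac`: cell types x features probability matrices).
#' @export
makeSyntheticPool <- function(n_donors, n_variants = 100000,
                              maf_range = c(0.05, 0.5), n_cell_types = 9,
                              n_genes = 1000, n_peaks = 2000,
                              concentration = 1, donor_names = NULL) {
  if (n_variants < 100)
    warning("fewer than 100 variants: donor identifiability will be weak")
  donor_names <- donor_names %||% sprintf("donor%02d", seq_len(n_donors))
  p <- runif(n_variants, maf_range[1], maf_range[2])
  g <- matrix(rbinom(n_variants * n_donors, 2L, rep(p, n_donors)) / 2,
              n_variants, n_donors)
  if (n_donors >= 2L) {
    for (k in 1:100) {
      mono <- matrixStats_rowMax(g) == matrixStats_rowMin(g)
      if (!any(mono)) break
      n_m <- sum(mono)
      g[mono, ] <- matrix(rbinom(n_m * n_donors, 2L, rep(p[mono],
                                                         n_donors)) / 2,
                          n_m, n_donors)
    }
    stopifnot(!any(matrixStats_rowMax(g) == matrixStats_rowMin(g)))
  }
  colnames(g) <- donor_names
  pos <- seq_len(n_variants) * 750L
  ba <- c("A", "C", "G", "T")
  ref <- sample(ba, n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(ba, r), 1L), character(1))
  ids <- paste("sim1", pos, ref, alt, sep = ":")
  rownames(g) <- ids
  gr <- GRanges("sim1", IRanges(pos, width = 1L), ref = ref, alt = alt)
  names(gr) <- ids
  rdir <- function(k, n) {
    m <- matrix(rgamma(k * n, concentration), k, n)
    m / rowSums(m)
  }
  list(genotypes = GenotypeMatrix(g, gr),
       profiles = list(rna = rdir(n_cell_types, n_genes),
                       atac = rdir(n_cell_types, n_peaks)))
}

#' Sample the droplet-level structure of a simulated experiment
#'
#' Draws, per droplet: type (singlet/doublet by `doublet_rate`; empty for
#' the empty set), donors (independent draws from `donor_cell_props`, so
#' self-doublets can occur), one cell type per nucleus (uniform), the
#' ambient fraction (configured Beta/uniform; 1 for empty droplets), the
#' droplet intra-peak probability, and per-modality molecule counts
#' (clipped NB for cellular, NB(2, 0.1) for empty droplets).
#'
#' @param cfg a [simConfig()].
#' @param donors donor names.
#' @return data.table, one row per droplet (cellular first).
#' @export
sampleDropletStructure <- function(cfg, donors) {
  stopifnot(inherits(cfg, "SimConfig"), length(donors) == cfg$n_donors)
  nc <- cfg$n_cellular; ne <- cfg$n_empty
  cp <- cfg$donor_cell_props %||% rep(1 / cfg$n_donors, cfg$n_donors)
  nn <- 1L + (runif(nc) < cfg$doublet_rate)
  d1 <- sample.int(cfg$n_donors, nc, replace = TRUE, prob = cp)
  d2 <- ifelse(nn == 2L,
               sample.int(cfg$n_donors, nc, replace = TRUE, prob = cp),
               NA_integer_)
  ct1 <- sample.int(cfg$n_cell_types, nc, replace = TRUE)
  ct2 <- ifelse(nn == 2L,
                sample.int(cfg$n_cell_types, nc, replace = TRUE),
                NA_integer_)
  alpha <- .sample_ambient(nc, cfg$ambient)
  clip <- function(x) pmin(pmax(x, cfg$coverage_min), cfg$coverage_max)
  cell <- data.table(
    barcode = sprintf("BC%07d", seq_len(nc)), n_nuclei = nn,
    donor1 = donors[d1], donor2 = donors[d2],
    cell_type1 = ct1, cell_type2 = ct2, alpha_true = alpha,
    p_peak = rbeta(nc, cfg$peak_beta_cell[1], cfg$peak_beta_cell[2]),
    m_rna = clip(rnbinom(nc, mu = cfg$coverage_mean,
                         size = cfg$coverage_size)),
    m_atac = clip(rnbinom(nc, mu = cfg$coverage_mean,
                          size = cfg$coverage_size)))
  if (ne > 0) {
    emp <- data.table(
      barcode = sprintf("BC%07d", nc + seq_len(ne)), n_nuclei = 0L,
      donor1 = NA_character_, donor2 = NA_character_,
      cell_type1 = NA_integer_, cell_type2 = NA_integer_,
      alpha_true = 1,
      p_peak = rbeta(ne, cfg$peak_beta_empty[1], cfg$peak_beta_empty[2]),
      m_rna = rnbinom(ne, mu = cfg$empty_coverage_mean,
                      size = cfg$empty_coverage_size),
      m_atac = rnbinom(ne, mu = cfg$empty_coverage_mean,
                       size = cfg$empty_coverage_size))
    cell <- rbindlist(list(cell, emp))
  }
  cell
}

#' Simulate a multiome experiment with ground truth
#'
#' End-to-end generator: donor pool (unless supplied), droplet structure,
#' and per-molecule sampling of origin (ambient vs donor, by the
#' droplet's true ambient fraction), cell-type feature, splice state,
#' ATAC peak region, SNP overlaps (Poisson(`overlap_rate`) in abstract
#' mode), origin-driven alleles, and uniform sequencing error. Fully
#' reproducible from (config, seed). Sequence mode additionally writes
#' reads against a synthetic genome (see [writeSimulation()] /
#' [simulateReads()]).
#'
#' @param cfg a [simConfig()].
#' @param seed integer RNG seed (optional; the caller may also seed).
#' @param pool optional pool from [makeSyntheticPool()] (reused across
#'   experiments, e.g. to fit with a genotype subset).
#' @return list: `molecules` ([MoleculeTable-class]), `truth`
#'   ([SimTruth-class]), `pool`, `config`.
#' @examples
#' sim <- simulateExperiment(simConfig(n_cellular = 50, n_empty = 100,
#'   n_donors = 2, n_variants = 300, coverage_mean = 200), seed = 7)
#' sim$truth
#' @export
simulateExperiment <- function(cfg, seed = NULL, pool = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (!is.null(seed)) set.seed(seed)
  pool <- pool %||% makeSyntheticPool(
    cfg$n_donors, cfg$n_variants, cfg$maf_range, cfg$n_cell_types,
    cfg$n_genes, cfg$n_peaks)
  gm <- pool$genotypes
  donors <- donorNames(gm)
  truth <- sampleDropletStructure(cfg, donors)
  ap <- cfg$donor_ambient_props %||% rep(1 / cfg$n_donors, cfg$n_donors)
  g <- gammaMatrix(gm)
  ga_true <- as.vector(g %*% ap)

  # droplet x modality expansion
  truth[, droplet := .I]
  dm <- rbindlist(list(
    truth[, .(droplet, barcode, modality = "RNA", M = m_rna, alpha_true,
              p_peak, n_nuclei, donor1, donor2, cell_type1, cell_type2)],
    truth[, .(droplet, barcode, modality = "ATAC", M = m_atac, alpha_true,
              p_peak, n_nuclei, donor1, donor2, cell_type1, cell_type2)]))
  p_informative <- 1 - exp(-cfg$overlap_rate)
  dm[, n_inf := rbinom(.N, M, p_informative)]

  inf <- dm[rep(seq_len(.N), n_inf)]
  inf[, molecule := seq_len(.N), by = c("barcode", "modality")]
  n_i <- nrow(inf)
  if (n_i) {
    amb <- runif(n_i) < inf$alpha_true
    pick2 <- runif(n_i) < 0.5
    don <- ifelse(amb, NA_character_,
                  ifelse(inf$n_nuclei == 2L & pick2, inf$donor2,
                         inf$donor1))
    inf[, origin := ifelse(amb, 0L, match(don, donors))]
    inf[, cell_type := ifelse(amb, 0L,
                              ifelse(inf$n_nuclei == 2L & pick2,
                                     cell_type2, cell_type1))]
    inf[, region := ifelse(modality == "RNA", "na",
                           ifelse(runif(n_i) < p_peak, "intra", "inter"))]
    inf[, spliced := ifelse(modality == "RNA",
                            runif(n_i) < ifelse(origin == 0L,
                                                cfg$spliced_prob_amb,
                                                cfg$spliced_prob_cell),
                            NA)]
    # feature from the origin cell type's profile; ambient molecules use
    # the cell-type-frequency-weighted average profile (uniform weights)
    inf[, feature := {
      prof <- if (modality[1L] == "RNA") pool$profiles$rna else
        pool$profiles$atac
      pv <- if (cell_type[1L] == 0L) colMeans(prof) else
        prof[cell_type[1L], ]
      sample.int(length(pv), .N, replace = TRUE, prob = pv)
    }, by = c("modality", "cell_type")]
    inf[, n_calls := qpois(runif(n_i, ppois(0L, cfg$overlap_rate), 1),
                           cfg$overlap_rate)]
  } else {
    inf[, `:=`(origin = integer(), cell_type = integer(),
               region = character(), spliced = logical(),
               feature = integer(), n_calls = integer())]
  }

  calls <- inf[rep(seq_len(.N), n_calls),
               .(barcode, modality, molecule, region, origin)]
  if (nrow(calls)) {
    calls[, variant_idx := sample.int(nrow(g), .N, replace = TRUE)]
    calls <- unique(calls,
                    by = c("barcode", "modality", "molecule",
                           "variant_idx"))
    # a 0 (ambient) origin must not enter the matrix index: zero indices
    # would be dropped and misalign the vector
    p_don <- g[cbind(calls$variant_idx, pmax(calls$origin, 1L))]
    p_alt <- ifelse(calls$origin == 0L, ga_true[calls$variant_idx],
                    p_don)
    b <- as.integer(runif(nrow(calls)) < p_alt)
    err <- runif(nrow(calls)) < cfg$error_rate
    u2 <- runif(nrow(calls))
    b[err & u2 < 0.25] <- 0L
    b[err & u2 >= 0.25 & u2 < 0.5] <- 1L
    drop <- err & u2 >= 0.5
    calls[, `:=`(allele = b, variant = rownames(g)[variant_idx],
                 qual = as.numeric(cfg$qual))]
    calls <- calls[!drop]
  }
  calls_out <- if (nrow(calls)) {
    calls[, .(barcode, modality, molecule = as.character(molecule),
              region, variant, allele, qual)]
  } else data.table()

  # coverage per (barcode, modality, region): split the uninformative
  # molecules of ATAC droplets between intra and inter by p_peak
  cov_list <- list()
  rna <- dm[modality == "RNA" & M > 0]
  cov_list$rna <- rna[, .(barcode, modality, region = "na",
                          n_molecules = M)]
  atac <- dm[modality == "ATAC" & M > 0]
  if (nrow(atac)) {
    inf_reg <- inf[modality == "ATAC",
                   .(n_intra_inf = sum(region == "intra")),
                   by = "barcode"]
    atac <- merge(atac, inf_reg, by = "barcode", all.x = TRUE)
    atac[is.na(n_intra_inf), n_intra_inf := 0L]
    atac[, n_intra := n_intra_inf + rbinom(.N, M - n_inf, p_peak)]
    cov_list$atac <- rbindlist(list(
      atac[n_intra > 0, .(barcode, modality, region = "intra",
                          n_molecules = n_intra)],
      atac[M - n_intra > 0, .(barcode, modality, region = "inter",
                              n_molecules = M - n_intra)]))
  }
  coverage <- rbindlist(cov_list)
  mt <- MoleculeTable(calls = calls_out, coverage = coverage)

  # realized ambient molecule fractions (informative molecules observed,
  # uninformative drawn from the same Bernoulli(alpha))
  amb_inf <- inf[, .(n_amb_inf = sum(origin == 0L)),
                 by = c("droplet", "modality")]
  dm2 <- merge(dm, amb_inf, by = c("droplet", "modality"), all.x = TRUE)
  dm2[is.na(n_amb_inf), n_amb_inf := 0L]
  dm2[, n_amb := n_amb_inf + rbinom(.N, M - n_inf, alpha_true)]
  dm2[, frac := ifelse(M > 0, n_amb / M, NA_real_)]
  wide <- data.table::dcast(dm2, droplet ~ modality,
                            value.var = c("frac", "n_inf"))
  setnames(wide, c("droplet", "amb_frac_atac", "amb_frac_rna",
                   "inf_atac", "inf_rna"))
  truth <- merge(truth, wide, by = "droplet")
  truth[, droplet := NULL]
  setorder(truth, barcode)

  origins <- if (n_i) inf[, .(barcode, modality,
                              molecule = as.character(molecule),
                              origin, spliced, feature)] else
    data.table(barcode = character(), modality = character(),
               molecule = character(), origin = integer(),
               spliced = logical(), feature = integer())

  st <- new("SimTruth", droplets = truth, origins = origins,
            params = list(config = cfg, donors = donors,
                          pi_a_true = setNames(ap, donors)))
  list(molecules = mt, truth = st, pool = pool, config = cfg)
}

#' Write a simulated experiment to disk
#'
#' Abstract-mode outputs: `molecules.tsv.gz` (the molecule-table
#' interchange format), `truth.tsv`, `donors.vcf.gz`, and
#' `config.lock.json` (the resolved configuration, for reproducibility).
#'
#' @param sim result of [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- c(
    molecules = file.path(dir, "molecules.tsv.gz"),
    truth = file.path(dir, "truth.tsv"),
    vcf = file.path(dir, "donors.vcf.gz"),
    config = file.path(dir, "config.lock.json"))
  writeMoleculeTable(sim$molecules, paths[["molecules"]])
  fwrite(truthDroplets(sim$truth), paths[["truth"]], sep = "\t")
  writeGenotypesVcf(sim$pool$genotypes, paths[["vcf"]])
  jsonlite::write_json(unclass(sim$config), paths[["config"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(paths)
}
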