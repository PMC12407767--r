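# Likelihood core.
#
# A droplet with H nuclei (0/1/2) and donor composition S generates
# molecules that originate either from the ambient pool (with probability
# alpha, the droplet's per-modality ambient fraction; alpha = 1 for empty
# droplets) or from the encapsulated donor(s) (a doublet's donors
# contribute equally). A molecule from origin i emits, at each overlapping
# SNP v, a base call b in {0 = ref, 1 = alt} that is Bernoulli(gamma[v, i])
# unless a sequencing error occurred (probability tau from the Phred
# quality), in which case any of the four bases is equally likely. The
# ambient "genotype" is the pi_a-weighted average of donor genotypes.
#
# The functions here are the plain-R reference implementation; demuxFit()
# uses an equivalent compiled kernel over pre-computed per-molecule caches.

#' Enumerate the droplet hypothesis space
#'
#' Hypotheses are (h, s): the empty droplet (0, {}); singlets (1, {i}) for
#' each donor; and doublets (2, {i, j}) over unordered distinct pairs
#' (self-doublets are excluded). Size: 1 + N + N(N-1)/2.
#'
#' @param donors character vector of donor names.
#' @return data.frame with columns `h`, `i`, `j` (donor indices, NA where
#'   absent), and `label`.
#' @export
hypothesisSpace <- function(donors) {
  n <- length(donors)
  hyp <- data.frame(h = 0L, i = NA_integer_, j = NA_integer_,
                    label = "empty", stringsAsFactors = FALSE)
  if (n >= 1L)
    hyp <- rbind(hyp, data.frame(h = 1L, i = seq_len(n), j = NA_integer_,
                                 label = paste0("sng:", donors)))
  if (n >= 2L) {
    pr <- utils::combn(n, 2L)
    hyp <- rbind(hyp, data.frame(
      h = 2L, i = pr[1L, ], j = pr[2L, ],
      label = paste0("dbl:", donors[pr[1L, ]], ",", donors[pr[2L, ]])))
  }
  hyp
}

#' Log-probability of one base call given its origin's allele frequency
#'
#' `log[(1 - tau) * Bern(b; gamma) + tau / 4]` with
#' `tau = 10^(-qual / 10)`. The error term spreads mass equally over the
#' four nucleotides, so the retained ref/alt calls are deliberately
#' sub-normalized; the deficit is identical across hypotheses and cancels
#' in posteriors. Qualities are capped (default Phred 60) so every term
#' stays finite.
#'
#' @param b allele (0 = ref, 1 = alt); vectorized.
#' @param qual Phred quality; vectorized.
#' @param gamma_v origin alternate-allele frequency in \[0, 1\]; vectorized.
#' @param max_qual quality cap (default 60, i.e. tau >= 1e-6).
#' @return log-probability (vector).
#' @export
baseCallLoglik <- function(b, qual, gamma_v, max_qual = 60) {
  stopifnot(all(b %in% c(0, 1)), all(gamma_v >= 0 & gamma_v <= 1))
  tau <- 10^(-pmin(qual, max_qual) / 10)
  p <- ifelse(b == 1, gamma_v, 1 - gamma_v)
  log((1 - tau) * p + tau / 4)
}

#' Log-likelihood of a molecule under a single origin
#'
#' Sum of [baseCallLoglik()] over the molecule's base calls, under a donor
#' origin or the ambient pool (whose allele frequency at each SNP is
#' `sum_i pi_a[i] * gamma[v, i]`). A molecule with no base calls has
#' log-likelihood 0 under every origin.
#'
#' @param calls data.frame with columns `variant`, `allele`, `qual` (may
#'   have zero rows).
#' @param source a donor name, donor index, or `"ambient"`.
#' @param gm a [GenotypeMatrix-class].
#' @param pi_a ambient donor proportions (needed when `source = "ambient"`).
#' @param max_qual quality cap.
#' @return A single log-likelihood.
#' @export
moleculeSourceLoglik <- function(calls, source, gm, pi_a = NULL,
                                 max_qual = 60) {
  if (NROW(calls) == 0L) return(0)
  bad <- setdiff(calls$variant, variantIds(gm))
  if (length(bad))
    stop("variant(s) absent from genotype matrix: ",
         paste(head(bad, 3), collapse = ", "))
  g <- gammaMatrix(gm)
  if (identical(source, "ambient")) {
    stopifnot(!is.null(pi_a), length(pi_a) == nDonors(gm))
    gv <- as.vector(g %*% pi_a)[match(calls$variant, rownames(g))]
  } else {
    gv <- g[match(calls$variant, rownames(g)), source]
  }
  sum(baseCallLoglik(calls$allele, calls$qual, gv, max_qual))
}

#' Log-likelihood of a molecule under a droplet hypothesis
#'
#' Marginalizes the molecule's latent origin: with probability `alpha` the
#' molecule is ambient; otherwise it comes from the hypothesis' donor
#' (singlet) or from either donor with equal probability (doublet). For the
#' empty hypothesis `alpha` must be 1. Computed with log-sum-exp stability.
#'
#' @param calls molecule base calls as in [moleculeSourceLoglik()].
#' @param h droplet type (0, 1, 2).
#' @param s donor name(s): none for h = 0, one for h = 1, two for h = 2.
#' @param alpha ambient fraction in \[0, 1\].
#' @param gm a [GenotypeMatrix-class].
#' @param pi_a ambient donor proportions.
#' @param max_qual quality cap.
#' @return A single log-likelihood.
#' @export
moleculeMixtureLoglik <- function(calls, h, s, alpha, gm, pi_a,
                                  max_qual = 60) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  la <- moleculeSourceLoglik(calls, "ambient", gm, pi_a, max_qual)
  if (h == 0) {
    if (alpha != 1) stop("empty hypothesis requires alpha = 1")
    return(la)
  }
  ld <- if (h == 1) {
    moleculeSourceLoglik(calls, s[[1L]], gm, pi_a, max_qual)
  } else {
    .logsumexp(c(moleculeSourceLoglik(calls, s[[1L]], gm, pi_a, max_qual),
                 moleculeSourceLoglik(calls, s[[2L]], gm, pi_a, max_qual))) -
      log(2)
  }
  if (alpha == 0) return(ld)
  if (alpha == 1) return(la)
  .logsumexp(c(log(alpha) + la, log1p(-alpha) + ld))
}

#' Log-likelihood of a droplet under a hypothesis (reference implementation)
#'
#' `log lambda_h + log p(s | h; pi_c) + sum over molecules of the mixture
#' log-likelihood`, with the per-modality ambient fraction applied to that
#' modality's molecules. The composition prior `p(s | h)` is 1 for empty,
#' `pi_c[i]` for a singlet, and `pi_c[i] pi_c[j]` normalized over unordered
#' distinct pairs for a doublet.
#'
#' This direct implementation is quadratic-ish in bookkeeping and meant for
#' small inputs and testing; [demuxFit()] computes the same quantity from
#' cached per-molecule source likelihoods.
#'
#' @param mt a [MoleculeTable-class] (a single barcode's molecules).
#' @param barcode the barcode to evaluate.
#' @param h,s hypothesis as in [moleculeMixtureLoglik()].
#' @param alpha_rna,alpha_atac per-modality ambient fractions.
#' @param gm a [GenotypeMatrix-class].
#' @param lambda length-3 droplet-type proportions.
#' @param pi_c donor proportions among cells.
#' @param pi_a ambient donor proportions.
#' @param max_qual quality cap.
#' @return A single log-likelihood.
#' @export
dropletLoglik <- function(mt, barcode, h, s, alpha_rna, alpha_atac, gm,
                          lambda, pi_c, pi_a, max_qual = 60) {
  stopifnot(is(mt, "MoleculeTable"), h %in% 0:2)
  donors <- donorNames(gm)
  lp <- log(lambda[h + 1L])
  if (h == 1L) {
    lp <- lp + log(pi_c[match(s[[1L]], donors)])
  } else if (h == 2L) {
    i <- match(s[[1L]], donors); j <- match(s[[2L]], donors)
    z <- (1 - sum(pi_c^2)) / 2
    lp <- lp + log(pi_c[i]) + log(pi_c[j]) - log(z)
  }
  bc <- barcode
  cl <- mt@calls[barcode == bc]
  if (nrow(cl)) {
    for (key in split(seq_len(nrow(cl)),
                      paste(cl$modality, cl$molecule))) {
      mod <- cl$modality[key[1L]]
      a <- if (mod == "RNA") alpha_rna else alpha_atac
      if (h == 0L) a <- 1
      lp <- lp + moleculeMixtureLoglik(cl[key], h, s, a, gm, pi_a,
                                       max_qual)
    }
  }
  lp
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# ---- per-molecule likelihood caches -----------------------------------

# Build, for every informative molecule of the given barcodes, the source
# log-likelihood under each donor and under the ambient pool, then the
# scaled natural-scale likelihoods used by the fitting kernel.
#
# Returns a list:
#   mol   data.table (barcode, modality, molecule, droplet, row) sorted by
#         droplet then modality ("RNA" before "ATAC")
#   E     n_mol x (N + 1) matrix exp(S - c), last column = ambient
#   cshift per-molecule scaling constants c (rowMax of S)
#   bounds n_droplet x 4 integer matrix: RNA start/end, ATAC start/end
#         (0-based, end exclusive) into the rows of E
#   csum  n_droplet x 2 matrix: sum of cshift per modality (additive
#         constant of every hypothesis log-likelihood)
.build_cache <- function(mt, gm, pi_a, barcodes, max_qual = 60) {
  cl <- mt@calls[barcode %in% barcodes]
  g <- gammaMatrix(gm)
  nd <- ncol(g)
  bad <- setdiff(unique(cl$variant), rownames(g))
  if (length(bad))
    stop("variant(s) in molecule table absent from genotype matrix: ",
         paste(head(bad, 3), collapse = ", "))
  drop_idx <- data.table(barcode = barcodes,
                         droplet = seq_along(barcodes))
  if (nrow(cl) == 0L) {
    bounds <- matrix(0L, length(barcodes), 4L)
    return(list(mol = data.table(), E = matrix(0, 0, nd + 1L),
                cshift = numeric(0), bounds = bounds,
                csum = matrix(0, length(barcodes), 2L)))
  }
  cl <- merge(cl, drop_idx, by = "barcode")
  vidx <- match(cl$variant, rownames(g))
  ga_all <- as.vector(g %*% pi_a)                      # ambient frequency
  cl[, mol_id := .GRP, by = c("droplet", "modality", "molecule")]
  n_mol <- max(cl$mol_id)
  alt <- cl$allele == 1L
  tau_all <- 10^(-pmin(cl$qual, max_qual) / 10)

  # accumulate per-molecule source log-likelihoods in chunks to bound
  # peak memory (the call-level matrix is calls x (N+1))
  S <- matrix(0, n_mol, nd + 1L)
  chunk <- max(1L, min(nrow(cl), 500000L))
  starts <- seq(1L, nrow(cl), by = chunk)
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1L, nrow(cl))
    p <- cbind(g[vidx[idx], , drop = FALSE], ga_all[vidx[idx]])
    na <- !alt[idx]
    p[na, ] <- 1 - p[na, , drop = FALSE]
    tau <- tau_all[idx]
    p <- log((1 - tau) * p + tau / 4)
    part <- rowsum(p, cl$mol_id[idx], reorder = FALSE)
    rows <- as.integer(rownames(part))
    S[rows, ] <- S[rows, , drop = FALSE] + part
  }

  mol <- unique(cl[, .(barcode, modality, molecule, droplet, mol_id)])
  setorder(mol, mol_id)
  # order molecules by droplet, RNA before ATAC
  mol[, mod_ord := ifelse(modality == "RNA", 0L, 1L)]
  ord <- order(mol$droplet, mol$mod_ord)
  mol <- mol[ord]
  S <- S[ord, , drop = FALSE]
  cshift <- matrixStats_rowMax(S)
  E <- exp(S - cshift)
  rm(S)

  nD <- length(barcodes)
  bounds <- matrix(0L, nD, 4L)
  csum <- matrix(0, nD, 2L)
  grp <- mol[, .(start = min(.I) - 1L, end = max(.I)),
             by = c("droplet", "mod_ord")]
  for (r in seq_len(nrow(grp))) {
    d <- grp$droplet[r]
    off <- if (grp$mod_ord[r] == 0L) 1L else 3L
    bounds[d, off] <- grp$start[r]
    bounds[d, off + 1L] <- grp$end[r]
  }
  cs <- mol[, .(cs = sum(cshift[.I])), by = c("droplet", "mod_ord")]
  csum[cbind(cs$droplet, cs$mod_ord + 1L)] <- cs$cs
  list(mol = mol, E = E, cshift = cshift, bounds = bounds, csum = csum)
}
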