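# Parameter estimation.
#
# Fitting proceeds in two phases. First the ambient donor proportions pi_a
# are estimated once, by projected gradient ascent on the base calls of
# the fixed-empty droplets (all of whose molecules are ambient), and
# frozen. Then, for the test droplets, the algorithm iterates: (1) fit the
# per-droplet, per-hypothesis, per-modality ambient fractions alpha by
# safeguarded Newton-Raphson on the penalized profile likelihood; (2)
# update the global droplet-type proportions lambda and cellular donor
# proportions pi_c by EM; (3) reset the prior center beta to the weighted
# average of the fitted singlet alphas. Iterations stop when the mean
# absolute change of (lambda, pi_c) falls below the tolerance.

#' Split barcodes into test droplets and fixed-empty droplets
#'
#' A barcode is a test droplet when it has at least `min_molecules`
#' molecules in either modality (in the single modality, for
#' single-modality data); all other barcodes are treated as empty and
#' excluded from per-droplet fitting.
#'
#' @param mt a [MoleculeTable-class].
#' @param min_molecules coverage threshold U (default 100).
#' @param modality "both", "RNA", or "ATAC".
#' @return list with character vectors `test` and `empty`.
#' @export
splitDroplets <- function(mt, min_molecules = 100,
                          modality = c("both", "RNA", "ATAC")) {
  modality <- match.arg(modality)
  stopifnot(is(mt, "MoleculeTable"))
  cv <- mt@coverage
  if (modality != "both") {
    sel <- cv$modality == modality   # avoid column-name masking in [i]
    cv <- cv[sel]
  }
  m <- cv[, .(n = sum(n_molecules)), by = c("barcode", "modality")]
  test <- unique(m[n >= min_molecules]$barcode)
  all_bc <- unique(mt@coverage$barcode)
  list(test = sort(test), empty = sort(setdiff(all_bc, test)))
}

#' Euclidean projection onto the probability simplex
#'
#' Sort-based algorithm: the projection of v is `pmax(v - theta, 0)` with
#' the threshold theta chosen so the result sums to 1.
#'
#' @param v a finite numeric vector.
#' @return Non-negative vector of the same length summing to 1.
#' @export
projectToSimplex <- function(v) {
  stopifnot(all(is.finite(v)), length(v) >= 1L)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  k <- seq_along(u)
  rho <- max(which(u + (1 - css) / k > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

#' Estimate ambient donor proportions from fixed-empty droplets
#'
#' Maximizes the log-likelihood of the empty-droplet base calls over the
#' ambient donor proportions pi_a, with the ambient allele frequency of
#' SNP v modeled as `sum_i pi_a[i] gamma[v, i]`. Optimization is projected
#' gradient ascent (Euclidean simplex projection) with backtracking line
#' search (Armijo). The estimate is computed once and kept constant during
#' droplet fitting.
#'
#' @param mt a [MoleculeTable-class].
#' @param gm a [GenotypeMatrix-class].
#' @param barcodes the fixed-empty barcodes to use.
#' @param eps convergence tolerance on the mean absolute step (default
#'   1e-6).
#' @param max_iter maximum gradient iterations (default 500).
#' @param max_qual Phred cap.
#' @return Named vector pi_a on the simplex. Uniform, with a warning, when
#'   the empty droplets carry no base calls.
#' @export
estimateAmbientProfile <- function(mt, gm, barcodes, eps = 1e-6,
                                   max_iter = 500, max_qual = 60) {
  stopifnot(is(mt, "MoleculeTable"), is(gm, "GenotypeMatrix"))
  donors <- donorNames(gm)
  n <- length(donors)
  pa <- rep(1 / n, n)
  names(pa) <- donors
  cl <- mt@calls[barcode %in% barcodes]
  if (nrow(cl) == 0L) {
    warning("no informative empty droplets; ambient donor proportions ",
            "left uniform")
    return(pa)
  }
  if (n == 1L) return(pa)
  g <- gammaMatrix(gm)
  Gv <- g[match(cl$variant, rownames(g)), , drop = FALSE]
  tau <- 10^(-pmin(cl$qual, max_qual) / 10)
  alt <- cl$allele == 1L
  sgn <- ifelse(alt, 1, -1)
  obj_grad <- function(p) {
    ga <- as.vector(Gv %*% p)
    pr <- ifelse(alt, ga, 1 - ga)
    lik <- (1 - tau) * pr + tau / 4
    coef <- sgn * (1 - tau) / lik
    list(obj = sum(log(lik)), grad = as.vector(crossprod(Gv, coef)))
  }
  cur <- obj_grad(pa)
  step <- 1 / nrow(cl)
  for (it in seq_len(max_iter)) {
    accepted <- FALSE
    for (bt in 1:40) {
      cand <- projectToSimplex(pa + step * cur$grad)
      move <- cand - pa
      nxt <- obj_grad(cand)
      if (nxt$obj >= cur$obj + 1e-4 * sum(cur$grad * move)) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    delta <- mean(abs(cand - pa))
    pa <- cand
    cur <- nxt
    step <- step * 2
    if (delta < eps) break
  }
  names(pa) <- donors
  pa
}

#' Fit one droplet's ambient fraction (reference implementation)
#'
#' Maximizes `sum_m log[alpha exp(la_m) + (1 - alpha) exp(ld_m)] +
#' kappa (beta log alpha + (1 - beta) log(1 - alpha))` over alpha in
#' (0, 1) by safeguarded Newton-Raphson, given the per-molecule ambient
#' (`la`) and donor-mix (`ld`) log-likelihoods of one droplet's molecules
#' in one modality. The Beta-like penalty (strength `kappa`, one
#' pseudo-molecule by default) keeps the optimum away from the boundary;
#' with no molecules the prior center `beta` is returned, flagged.
#'
#' This is the plain-R counterpart of the compiled kernel used by
#' [demuxFit()]; both maximize the same objective.
#'
#' @param la,ld numeric vectors: per-molecule ambient and donor-mix
#'   log-likelihoods.
#' @param beta prior center in (0, 1).
#' @param kappa prior strength (pseudo-molecule count, default 1).
#' @param tol convergence tolerance on alpha (default 1e-6).
#' @param max_iter maximum Newton iterations (default 100).
#' @return list: `alpha`, `objective` (at the optimum, penalty included),
#'   `flag` (`TRUE` when no molecules were available).
#' @export
fitAlpha <- function(la, ld, beta, kappa = 1, tol = 1e-6, max_iter = 100) {
  stopifnot(length(la) == length(ld), beta > 0, beta < 1)
  if (length(la) == 0L)
    return(list(alpha = beta, objective = NA_real_, flag = TRUE))
  cs <- pmax(la, ld)
  a <- exp(la - cs)
  d <- exp(ld - cs)
  pen <- function(x) kappa * (beta * log(x) + (1 - beta) * log1p(-x))
  obj <- function(x) sum(log(pmax(d + x * (a - d), 1e-300))) + pen(x)
  alpha <- 0.5
  lo <- 1e-9; hi <- 1 - 1e-9
  for (it in seq_len(max_iter)) {
    t <- pmax(d + alpha * (a - d), 1e-300)
    r <- (a - d) / t
    g1 <- sum(r) + kappa * (beta / alpha - (1 - beta) / (1 - alpha))
    g2 <- -sum(r^2) - kappa * (beta / alpha^2 +
                                 (1 - beta) / (1 - alpha)^2)
    if (g1 > 0) lo <- alpha else hi <- alpha
    step <- alpha - g1 / g2
    if (!is.finite(step) || step <= lo || step >= hi)
      step <- (lo + hi) / 2
    delta <- abs(step - alpha)
    alpha <- step
    if (delta < tol) break
  }
  list(alpha = alpha, objective = obj(alpha) + sum(cs), flag = FALSE)
}

#' EM update of the global droplet-type and donor proportions
#'
#' M-step given per-droplet posteriors over the hypothesis space:
#' `lambda[h]` is the posterior-expected count of type-h droplets (the
#' fixed-empty droplets contribute wholly to h = 0) over all droplets;
#' `pi_c[i]` is proportional to the expected singlet count of donor i plus
#' half the expected count of doublets containing i (each member donor of
#' a doublet carries half a droplet's weight).
#'
#' @param post n_droplets x n_hypotheses posterior matrix (rows sum to 1).
#' @param hyp hypothesis table from [hypothesisSpace()].
#' @param n_fixed_empty number of fixed-empty droplets.
#' @param n_donors number of donors.
#' @return list with simplex vectors `lambda` (length 3) and `pi_c`
#'   (length `n_donors`).
#' @export
emUpdateGlobal <- function(post, hyp, n_fixed_empty, n_donors) {
  D <- nrow(post) + n_fixed_empty
  ch <- vapply(0:2, function(h) {
    cols <- which(hyp$h == h)
    if (length(cols)) sum(post[, cols]) else 0
  }, numeric(1))
  lambda <- (ch + c(n_fixed_empty, 0, 0)) / D
  w <- numeric(n_donors)
  sng <- which(hyp$h == 1L)
  for (k in sng) w[hyp$i[k]] <- w[hyp$i[k]] + sum(post[, k])
  dbl <- which(hyp$h == 2L)
  for (k in dbl) {
    m <- 0.5 * sum(post[, k])
    w[hyp$i[k]] <- w[hyp$i[k]] + m
    w[hyp$j[k]] <- w[hyp$j[k]] + m
  }
  pi_c <- if (sum(w) > 0) w / sum(w) else rep(1 / n_donors, n_donors)
  list(lambda = lambda, pi_c = pi_c)
}

#' Weighted update of the ambient-fraction prior center
#'
#' `beta` is set to the weighted average of the fitted singlet ambient
#' fractions; the caller supplies weights (posterior singlet mass times
#' informative-molecule count). The result is clamped to
#' \[1e-3, 1 - 1e-3\] so the Beta-like penalty stays proper.
#'
#' @param alpha fitted ambient fractions of the (posterior) singlets.
#' @param weights non-negative weights.
#' @param fallback value returned when all weights are zero.
#' @return Updated beta.
#' @export
updateBeta <- function(alpha, weights, fallback) {
  stopifnot(length(alpha) == length(weights), all(weights >= 0))
  if (!length(weights) || sum(weights) <= 0) return(fallback)
  min(max(sum(alpha * weights) / sum(weights), 1e-3), 1 - 1e-3)
}

.softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

# hypothesis log prior: log lambda_h + log p(s | h; pi_c)
.hyp_log_prior <- function(hyp, lambda, pi_c) {
  lp <- log(lambda[hyp$h + 1L])
  sng <- hyp$h == 1L
  lp[sng] <- lp[sng] + log(pi_c[hyp$i[sng]])
  dbl <- hyp$h == 2L
  if (any(dbl)) {
    z <- (1 - sum(pi_c^2)) / 2
    lp[dbl] <- lp[dbl] + log(pi_c[hyp$i[dbl]]) + log(pi_c[hyp$j[dbl]]) -
      log(z)
  }
  lp
}

#' Fit the droplet model
#'
#' Full estimation pipeline: region and modality selection, the coverage
#' split into test and fixed-empty droplets, ambient donor proportions
#' from the empty droplets, then iterated per-droplet ambient-fraction
#' fitting (Newton-Raphson) and EM updates of the droplet-type and donor
#' proportions until the mean absolute change of (lambda, pi_c) drops
#' below `tol`. Inference is deterministic: identical inputs produce
#' identical fits.
#'
#' Initialization follows the coverage split: `lambda` starts at (share of
#' fixed-empty, 0.9 x share of test, 0.1 x share of test); `pi_c` and
#' `pi_a` start uniform; every droplet's alpha starts at 0.5 and is warm-
#' started across iterations; `beta` starts at `beta_init`.
#'
#' @param mt a [MoleculeTable-class].
#' @param gm a [GenotypeMatrix-class].
#' @param min_molecules test-droplet coverage threshold U (default 100).
#' @param region_mode ATAC peak-region filter, "all" or "intra" (see
#'   [selectMolecules()]).
#' @param modality "both" (joint RNA+ATAC), "RNA", or "ATAC".
#' @param tol convergence tolerance on (lambda, pi_c) (default 1e-6).
#' @param max_iter maximum outer iterations (default 100).
#' @param kappa strength of the Beta-like alpha penalty (pseudo-molecules,
#'   default 1).
#' @param beta_init initial prior center for alpha (default 0.1).
#' @param alpha_tol,max_newton Newton-Raphson controls for alpha.
#' @param lazy_tol hypotheses whose posterior mass stays below this keep
#'   their cached alpha and likelihood between iterations (0 disables).
#' @param max_qual Phred cap (default 60).
#' @param pi_a optional fixed ambient donor proportions (skips their
#'   estimation).
#' @param verbose print per-iteration deltas.
#' @return A [DemuxFit-class].
#' @examples
#' sim <- simulateExperiment(simConfig(n_cellular = 80, n_empty = 150,
#'   n_donors = 3, n_variants = 400, coverage_mean = 300), seed = 1)
#' fit <- demuxFit(sim$molecules, sim$pool$genotypes)
#' fit
#' @export
demuxFit <- function(mt, gm, min_molecules = 100,
                     region_mode = c("all", "intra"),
                     modality = c("both", "RNA", "ATAC"),
                     tol = 1e-6, max_iter = 100, kappa = 1,
                     beta_init = 0.1, alpha_tol = 1e-6, max_newton = 100,
                     lazy_tol = 1e-8, max_qual = 60, pi_a = NULL,
                     verbose = FALSE) {
  region_mode <- match.arg(region_mode)
  modality <- match.arg(modality)
  stopifnot(is(mt, "MoleculeTable"), is(gm, "GenotypeMatrix"))
  mt <- selectMolecules(mt, region_mode)
  if (modality != "both") {
    sel_cl <- mt@calls$modality == modality
    sel_cv <- mt@coverage$modality == modality
    mt <- MoleculeTable(calls = mt@calls[sel_cl],
                        coverage = mt@coverage[sel_cv])
  }

  donors <- donorNames(gm)
  nd <- length(donors)
  split <- splitDroplets(mt, min_molecules, modality)
  test_bc <- split$test
  empty_bc <- split$empty
  if (length(test_bc) == 0L)
    stop("no droplet reaches ", min_molecules, " molecules in any used ",
         "modality; nothing to fit")

  if (is.null(pi_a)) {
    pi_a <- estimateAmbientProfile(mt, gm, empty_bc)
  } else {
    stopifnot(length(pi_a) == nd, all(pi_a >= 0),
              abs(sum(pi_a) - 1) < 1e-8)
    names(pi_a) <- donors
  }

  cache <- .build_cache(mt, gm, pi_a, test_bc, max_qual)
  hyp <- hypothesisSpace(donors)
  nH <- nrow(hyp)
  nT <- length(test_bc)
  nE <- length(empty_bc)

  # per-droplet informative molecule counts by modality
  n_inf <- matrix(0L, nT, 2L)
  if (nrow(cache$mol)) {
    im <- cache$mol[, .(n = .N), by = c("droplet", "mod_ord")]
    n_inf[cbind(im$droplet, im$mod_ord + 1L)] <- im$n
  }

  D <- nT + nE
  lambda <- c(nE / D, 0.9 * nT / D, 0.1 * nT / D)
  # degenerate but possible: no empty droplets at all
  if (lambda[1L] == 0) lambda <- lambda + 1e-12
  lambda <- lambda / sum(lambda)
  pi_c <- rep(1 / nd, nd)
  beta <- c(RNA = beta_init, ATAC = beta_init)

  hyp_i0 <- ifelse(is.na(hyp$i), -1L, hyp$i - 1L)
  hyp_j0 <- ifelse(is.na(hyp$j), -1L, hyp$j - 1L)
  alpha_rna <- matrix(0.5, nT, nH)
  alpha_atac <- matrix(0.5, nT, nH)
  molsum_rna <- matrix(0, nT, nH)
  molsum_atac <- matrix(0, nT, nH)
  active <- matrix(TRUE, nT, nH)

  trace <- vector("list", max_iter)
  converged <- FALSE
  it <- 0L
  post <- NULL
  repeat {
    it <- it + 1L
    .fit_droplets_kernel(cache$E, cache$bounds, hyp$h, hyp_i0, hyp_j0,
                         active, alpha_rna, alpha_atac, molsum_rna,
                         molsum_atac, kappa, unname(beta), alpha_tol,
                         max_newton)
    lp <- .hyp_log_prior(hyp, lambda, pi_c)
    ll <- sweep(molsum_rna + molsum_atac, 2L, lp, "+")
    post <- .softmax_rows(ll)

    upd <- emUpdateGlobal(post, hyp, nE, nd)
    delta <- mean(abs(c(upd$lambda, upd$pi_c) - c(lambda, pi_c)))
    lambda <- upd$lambda
    pi_c <- upd$pi_c

    sng_cols <- which(hyp$h == 1L)
    sng_mass <- rowSums(post[, sng_cols, drop = FALSE])
    best_sng <- sng_cols[max.col(post[, sng_cols, drop = FALSE],
                                 ties.method = "first")]
    idx <- cbind(seq_len(nT), best_sng)
    beta <- c(
      RNA = updateBeta(alpha_rna[idx], sng_mass * n_inf[, 1L], beta[1L]),
      ATAC = updateBeta(alpha_atac[idx], sng_mass * n_inf[, 2L],
                        beta[2L]))

    trace[[it]] <- data.table(iter = it, delta = delta,
                              lambda0 = lambda[1L], lambda1 = lambda[2L],
                              lambda2 = lambda[3L],
                              beta_rna = beta[[1L]], beta_atac = beta[[2L]])
    if (verbose)
      message(sprintf("iter %d: delta = %.3g", it, delta))
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    # lazy refitting: keep cached alpha/likelihood for hypotheses with
    # negligible posterior mass (empty hypothesis is alpha-free after
    # the first pass)
    if (it >= 2L && lazy_tol > 0) {
      active <- post > lazy_tol
      active[, hyp$h == 0L] <- FALSE
    } else if (it >= 1L) {
      active[, hyp$h == 0L] <- FALSE
    }
  }
  if (!converged)
    warning("demuxFit did not converge in ", max_iter, " iterations")

  # final log-likelihoods at the fitted parameters (scaling constants
  # restored so values are absolute)
  lp <- .hyp_log_prior(hyp, lambda, pi_c)
  ll <- sweep(molsum_rna + molsum_atac, 2L, lp, "+") +
    cache$csum[, 1L] + cache$csum[, 2L]
  rownames(ll) <- test_bc
  colnames(ll) <- hyp$label
  dimnames(alpha_rna) <- dimnames(alpha_atac) <- dimnames(ll)

  cov <- mt@coverage[, .(n_molecules = sum(n_molecules)),
                     by = c("barcode", "modality")]
  ninf_tab <- mt@calls[, .(n_informative = data.table::uniqueN(molecule)),
                       by = c("barcode", "modality")]
  cov <- merge(cov, ninf_tab, by = c("barcode", "modality"), all.x = TRUE)
  cov[is.na(n_informative), n_informative := 0L]

  names(pi_c) <- donors
  new("DemuxFit",
      barcodes = test_bc, fixed_empty = empty_bc, hyp = hyp,
      loglik = ll, alpha_rna = alpha_rna, alpha_atac = alpha_atac,
      coverage = cov,
      params = list(lambda = lambda, pi_c = pi_c, pi_a = pi_a,
                    beta = beta, donors = donors,
                    config = list(min_molecules = min_molecules,
                                  region_mode = region_mode,
                                  modality = modality, tol = tol,
                                  max_iter = max_iter, kappa = kappa,
                                  beta_init = beta_init,
                                  lazy_tol = lazy_tol,
                                  max_qual = max_qual)),
      converged = converged, n_iter = it,
      trace = rbindlist(trace[seq_len(it)]))
}
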