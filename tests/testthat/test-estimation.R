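library(data.table)

test_that("test/empty split follows the either-modality coverage rule", {
  cov <- data.table(
    barcode = c("a", "a", "b", "b", "c", "c", "d"),
    modality = c("RNA", "ATAC", "RNA", "ATAC", "RNA", "ATAC", "ATAC"),
    region = c("na", "intra", "na", "intra", "na", "intra", "intra"),
    n_molecules = c(100L, 0L, 99L, 99L, 0L, 100L, 250L))
  mt <- MoleculeTable(calls = data.table(), coverage = cov)
  sp <- splitDroplets(mt, 100)
  expect_setequal(sp$test, c("a", "c", "d"))   # strict at 100
  expect_setequal(sp$empty, "b")               # 99 + 99 is not enough
  # single-modality runs ignore the other modality entirely
  sp_rna <- splitDroplets(mt, 100, modality = "RNA")
  expect_setequal(sp_rna$test, "a")
  expect_setequal(sp_rna$empty, c("b", "c", "d"))
})

test_that("simplex projection: known points and optimality property", {
  expect_equal(projectToSimplex(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  expect_equal(projectToSimplex(c(0.6, 0.6)), c(0.5, 0.5))
  expect_equal(projectToSimplex(c(2, 0, 0)), c(1, 0, 0))
  set.seed(42)
  for (rep in 1:20) {
    v <- rnorm(5, sd = 2)
    p <- projectToSimplex(v)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # no random simplex point is closer to v than the projection
    q <- matrix(rgamma(5 * 50, 1), 50, 5)
    q <- q / rowSums(q)
    d_p <- sum((v - p)^2)
    d_q <- apply(q, 1, function(r) sum((v - r)^2))
    expect_true(all(d_q >= d_p - 1e-12))
  }
})

test_that("ambient profile estimation agrees with oracles", {
  gm <- toy_gm2()
  vids <- variantIds(gm)
  # closed form: a single alt call at a site with gamma (0, 1) is
  # maximized by putting all ambient mass on the alt-carrying donor
  mols <- list(list(barcode = "e1", modality = "RNA", molecule = "m1",
                    region = "na",
                    calls = data.frame(variant = vids[3], allele = 1L,
                                       qual = 60)))
  mt <- toy_mt(mols)
  pa <- estimateAmbientProfile(mt, gm, "e1")
  expect_equal(unname(pa), c(1, 0), tolerance = 1e-4)

  # grid-search oracle on a random two-donor instance
  set.seed(9)
  n <- 400
  vs <- sample(vids, n, replace = TRUE)
  g <- gammaMatrix(gm)
  truth_pa <- c(0.8, 0.2)
  ga <- as.vector(g %*% truth_pa)[match(vs, rownames(g))]
  calls <- data.table(barcode = "e1", modality = "RNA",
                      molecule = as.character(seq_len(n)), region = "na",
                      variant = vs,
                      allele = as.integer(runif(n) < ga), qual = 30)
  mt2 <- MoleculeTable(calls = calls)
  pa2 <- estimateAmbientProfile(mt2, gm, "e1")
  oracle <- grid_pi_a2(calls, gm)
  expect_equal(unname(pa2[1]), oracle, tolerance = 2e-3)

  # unidentifiable case: identical donors leave the uniform start
  g_flat <- gammaMatrix(gm)
  g_flat[, 2] <- g_flat[, 1]
  gm_flat <- GenotypeMatrix(g_flat, variantRanges(gm))
  pa3 <- estimateAmbientProfile(mt2, gm_flat, "e1")
  expect_equal(unname(pa3), c(0.5, 0.5), tolerance = 1e-8)

  # no informative empty droplets: warning, uniform
  mt0 <- MoleculeTable(calls = data.table(),
                       coverage = data.table(barcode = "e1",
                                             modality = "RNA",
                                             region = "na",
                                             n_molecules = 3L))
  expect_warning(pa4 <- estimateAmbientProfile(mt0, gm, "e1"),
                 "uniform")
  expect_equal(unname(pa4), c(0.5, 0.5))
})

test_that("alpha fitting matches a fine grid search and its limits", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    la <- rnorm(n, -1, 1.2)
    ld <- rnorm(n, -1, 1.2)
    beta <- runif(1, 0.05, 0.3)
    r <- fitAlpha(la, ld, beta)
    expect_lt(abs(r$alpha - grid_alpha(la, ld, beta)), 2e-4)
  }
  # likelihood flat in alpha: the prior center is the exact optimum
  flat <- fitAlpha(rep(-1, 30), rep(-1, 30), beta = 0.13)
  expect_equal(flat$alpha, 0.13, tolerance = 1e-6)
  # perfectly discriminating molecules, vanishing prior: alpha tends to
  # the ambient-consistent fraction
  k <- 7; n <- 20
  la <- c(rep(0, k), rep(-25, n - k))
  ld <- c(rep(-25, k), rep(0, n - k))
  r0 <- fitAlpha(la, ld, beta = 0.5, kappa = 1e-8)
  expect_equal(r0$alpha, k / n, tolerance = 1e-3)
  # no molecules: prior center returned, flagged
  e <- fitAlpha(numeric(0), numeric(0), beta = 0.2)
  expect_true(e$flag)
  expect_equal(e$alpha, 0.2)
})

test_that("compiled kernel and R reference maximize the same objective", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(c(5, 30, 80), 1)
    la <- rnorm(n, -1, 1)
    ld <- rnorm(n, -0.5, 1)
    beta <- runif(1, 0.05, 0.4)
    ref <- fitAlpha(la, ld, beta)
    cs <- pmax(la, ld)
    E <- cbind(exp(ld - cs), exp(la - cs))
    bounds <- matrix(c(0L, n, 0L, 0L), 1)
    ar <- matrix(0.5, 1, 1); aa <- matrix(0.5, 1, 1)
    mr <- matrix(0, 1, 1); ma <- matrix(0, 1, 1)
    demuxamb:::.fit_droplets_kernel(E, bounds, 1L, 0L, -1L,
                                    matrix(TRUE, 1, 1), ar, aa, mr, ma,
                                    1, c(beta, beta), 1e-8, 100L)
    expect_equal(ar[1, 1], ref$alpha, tolerance = 1e-6)
    expect_equal(mr[1, 1] + sum(cs),
                 sum(log(ref$alpha * exp(la) +
                           (1 - ref$alpha) * exp(ld))),
                 tolerance = 1e-8)
  }
})

test_that("EM updates match hand-derived maximizers on toys", {
  hyp <- hypothesisSpace(c("d1", "d2"))
  # all posterior mass on singlet d2
  post <- matrix(0, 3, nrow(hyp))
  post[, which(hyp$label == "sng:d2")] <- 1
  up <- emUpdateGlobal(post, hyp, n_fixed_empty = 7, n_donors = 2)
  expect_equal(up$lambda, c(7, 3, 0) / 10)
  expect_equal(up$pi_c, c(0, 1))
  # uniform over singlets only -> uniform pi_c
  post2 <- matrix(0, 4, nrow(hyp))
  post2[, hyp$h == 1] <- 0.5
  up2 <- emUpdateGlobal(post2, hyp, 0, 2)
  expect_equal(up2$pi_c, c(0.5, 0.5))
  expect_equal(up2$lambda, c(0, 1, 0))
  # mixed toy: compare with a 1-D numeric maximizer of the weighted
  # surrogate objective (N = 2, D = 3)
  post3 <- rbind(c(0.1, 0.6, 0.2, 0.1),
                 c(0.0, 0.1, 0.8, 0.1),
                 c(0.3, 0.3, 0.2, 0.2))
  up3 <- emUpdateGlobal(post3, hyp, n_fixed_empty = 1, n_donors = 2)
  w1 <- sum(post3[, 2]) + 0.5 * sum(post3[, 4])
  w2 <- sum(post3[, 3]) + 0.5 * sum(post3[, 4])
  opt <- optimize(function(p) w1 * log(p) + w2 * log(1 - p),
                  c(1e-6, 1 - 1e-6), maximum = TRUE)$maximum
  expect_equal(up3$pi_c[1], opt, tolerance = 1e-5)
  expect_equal(up3$pi_c[1], w1 / (w1 + w2))
  # M-step does not decrease the surrogate expected log-likelihood
  before <- surrogate_em_obj(post3, hyp, 1, c(1, 1, 1) / 3, c(0.5, 0.5))
  after <- surrogate_em_obj(post3, hyp, 1, up3$lambda, up3$pi_c)
  expect_gte(after, before)
})

test_that("beta update is the clamped weighted mean", {
  expect_equal(updateBeta(c(0.1, 0.1), c(2, 5), 0.3), 0.1)
  expect_equal(updateBeta(c(0, 0.2), c(1, 1), 0.3), 0.1)
  expect_equal(updateBeta(c(0, 0.2), c(1, 3), 0.3), 0.15)
  expect_equal(updateBeta(numeric(0), numeric(0), 0.3), 0.3)
  expect_equal(updateBeta(c(0, 0), c(1, 1), 0.3), 1e-3)  # clamped
})

test_that("demuxFit is deterministic and keeps simplex invariants", {
  sim <- small_sim(seed = 31)
  f1 <- demuxFit(sim$molecules, sim$pool$genotypes)
  f2 <- demuxFit(sim$molecules, sim$pool$genotypes)
  expect_identical(f1@loglik, f2@loglik)
  expect_identical(f1@alpha_rna, f2@alpha_rna)
  expect_identical(f1@params$lambda, f2@params$lambda)
  p <- f1@params
  expect_equal(sum(p$lambda), 1, tolerance = 1e-12)
  expect_true(all(p$lambda >= 0))
  expect_equal(sum(p$pi_c), 1, tolerance = 1e-12)
  expect_true(all(p$pi_c >= 0))
  expect_equal(sum(p$pi_a), 1, tolerance = 1e-12)
  expect_true(all(p$pi_a >= -1e-15))
  expect_true(all(f1@alpha_rna >= 0 & f1@alpha_rna <= 1))
  expect_true(all(f1@alpha_atac >= 0 & f1@alpha_atac <= 1))
  # empty hypothesis alpha is identically 1
  expect_equal(unname(f1@alpha_rna[, "empty"]),
               rep(1, length(f1@barcodes)))
  # trace records every iteration
  expect_equal(nrow(f1@trace), f1@n_iter)
})

test_that("demuxFit recovers the generating global parameters", {
  sim <- small_sim(seed = 55, n_donors = 4, n_cellular = 500,
                   n_empty = 4000, coverage_mean = 1200)
  fit <- demuxFit(sim$molecules, sim$pool$genotypes)
  td <- truthDroplets(sim$truth)
  present <- c(fit@barcodes, fit@fixed_empty)
  tdp <- td[barcode %in% present]
  lam_true <- c(mean(tdp$n_nuclei == 0), mean(tdp$n_nuclei == 1),
                mean(tdp$n_nuclei == 2))
  expect_true(all(abs(fit@params$lambda - lam_true) < 0.02))
  nuclei <- stats::na.omit(c(td$donor1, td[n_nuclei == 2]$donor2))
  pic_true <- as.vector(table(factor(nuclei,
                                     donorNames(sim$pool$genotypes))) /
                          length(nuclei))
  expect_lt(mean(abs(fit@params$pi_c - pic_true)), 0.02)
  # ambient donor proportions were uniform in truth
  expect_lt(mean(abs(fit@params$pi_a - 0.25)), 0.05)
})

test_that("demuxFit degenerate inputs", {
  sim <- small_sim(seed = 77, n_donors = 2, n_cellular = 40, n_empty = 80,
                   coverage_mean = 300)
  gm1 <- subsetDonors(sim$pool$genotypes, "donor01",
                      drop_monomorphic = FALSE)
  mt1 <- restrictToVariants(sim$molecules, gm1)
  fit1 <- demuxFit(mt1, gm1)
  calls1 <- callDroplets(fit1)
  expect_true(all(calls1$call %in% c("SNG", "EMPTY", "AMB")))
  expect_equal(unname(fit1@params$pi_c), 1)
  # no droplet reaches the threshold -> clear fatal error
  expect_error(demuxFit(sim$molecules, sim$pool$genotypes,
                        min_molecules = 1e7), "nothing to fit")
})

test_that("lazy hypothesis refitting does not change the calls", {
  sim <- small_sim(seed = 91)
  f_lazy <- demuxFit(sim$molecules, sim$pool$genotypes)
  f_full <- demuxFit(sim$molecules, sim$pool$genotypes, lazy_tol = 0)
  c1 <- callDroplets(f_lazy); c2 <- callDroplets(f_full)
  expect_identical(c1$call, c2$call)
  expect_identical(c1$donor1, c2$donor1)
  expect_equal(c1$alpha_rna, c2$alpha_rna, tolerance = 1e-4)
  expect_equal(f_lazy@params$lambda, f_full@params$lambda,
               tolerance = 1e-6)
})

test_that("single-modality fits ignore the other modality", {
  sim <- small_sim(seed = 13)
  f_rna <- demuxFit(sim$molecules, sim$pool$genotypes, modality = "RNA")
  cov <- f_rna@coverage
  expect_false("ATAC" %in% cov$modality)
  calls <- callDroplets(f_rna)
  expect_true(all(calls$n_atac == 0))
})
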