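library(data.table)

test_that("hypothesis space enumerates empty, singlets, unordered pairs", {
  hyp <- hypothesisSpace(c("a", "b", "c", "d"))
  expect_equal(nrow(hyp), 1 + 4 + 6)
  expect_equal(sum(hyp$h == 0), 1)
  expect_equal(sum(hyp$h == 1), 4)
  expect_equal(sum(hyp$h == 2), 6)
  pairs <- hyp[hyp$h == 2, c("i", "j")]
  expect_true(all(pairs$i < pairs$j))        # no self-doublets
  expect_false(anyDuplicated(hyp$label) > 0)
  expect_equal(nrow(hypothesisSpace("solo")), 2)
})

test_that("base-call log-likelihood follows the error-mixture form", {
  # tau = 0.01 at Phred 20; mixture (1 - tau) * Bern + tau / 4
  expect_equal(baseCallLoglik(1, 20, 0), log(0.0025))
  expect_equal(baseCallLoglik(0, 20, 0.5), log(0.4975))
  expect_equal(baseCallLoglik(1, 20, 1), log(0.9925))
  # perfect match at an uncapped-quality limit approaches 0
  expect_lt(abs(baseCallLoglik(1, 1000, 1)), 1e-5)
  # the quality cap keeps everything finite even for impossible calls
  expect_true(is.finite(baseCallLoglik(1, 1000, 0)))
  # vectorized
  expect_equal(baseCallLoglik(c(1, 0), c(20, 20), c(0, 0.5)),
               c(log(0.0025), log(0.4975)))
})

test_that("molecule source log-likelihood sums calls; empty product is 0", {
  gm <- toy_gm2()
  vids <- variantIds(gm)
  calls <- data.frame(variant = vids[1:2], allele = c(1L, 0L), qual = 20)
  # dA: gamma = (0, 0.5): log(0.0025) + log(0.4975)
  expect_equal(moleculeSourceLoglik(calls, "dA", gm),
               log(0.0025) + log(0.4975))
  expect_equal(moleculeSourceLoglik(calls[0, ], "dA", gm), 0)
  # ambient with uniform pi_a over gamma (0, 1) -> 0.5
  one <- data.frame(variant = vids[1], allele = 1L, qual = 20)
  expect_equal(moleculeSourceLoglik(one, "ambient", gm,
                                    pi_a = c(0.5, 0.5)),
               log(0.99 * 0.5 + 0.0025))
  expect_error(moleculeSourceLoglik(
    data.frame(variant = "nope", allele = 1L, qual = 20), "dA", gm),
    "absent")
})

test_that("mixture log-likelihood collapses at the alpha extremes", {
  gm <- toy_gm2()
  pi_a <- c(0.3, 0.7)
  calls <- data.frame(variant = variantIds(gm)[c(1, 3)],
                      allele = c(1L, 1L), qual = c(20, 30))
  ld <- moleculeSourceLoglik(calls, "dB", gm)
  la <- moleculeSourceLoglik(calls, "ambient", gm, pi_a)
  expect_equal(moleculeMixtureLoglik(calls, 1, "dB", 0, gm, pi_a), ld)
  expect_equal(moleculeMixtureLoglik(calls, 1, "dB", 1, gm, pi_a), la)
  expect_equal(moleculeMixtureLoglik(calls, 0, character(), 1, gm, pi_a),
               la)
  mid <- moleculeMixtureLoglik(calls, 1, "dB", 0.5, gm, pi_a)
  expect_equal(mid, log(0.5 * exp(la) + 0.5 * exp(ld)))
  # doublet: equal contribution of the two donors
  dd <- moleculeMixtureLoglik(calls, 2, c("dA", "dB"), 0, gm, pi_a)
  expect_equal(dd, log(0.5 * exp(moleculeSourceLoglik(calls, "dA", gm)) +
                         0.5 * exp(ld)))
  expect_error(moleculeMixtureLoglik(calls, 1, "dB", 1.2, gm, pi_a),
               "alpha")
  expect_error(moleculeMixtureLoglik(calls, 0, character(), 0.5, gm,
                                     pi_a), "alpha = 1")
})

test_that("molecule likelihood is affine in alpha", {
  gm <- toy_gm2()
  pi_a <- c(0.5, 0.5)
  calls <- data.frame(variant = variantIds(gm)[1:3],
                      allele = c(1L, 0L, 1L), qual = 25)
  f <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(a)
    exp(moleculeMixtureLoglik(calls, 1, "dA", a, gm, pi_a)), numeric(1))
  # second differences vanish for an affine function
  expect_equal(diff(diff(f)), rep(0, 3), tolerance = 1e-12)
})

test_that("brute-force enumeration reproduces the droplet likelihood", {
  gm <- toy_gm3()
  vids <- variantIds(gm)
  pi_a <- c(0.2, 0.5, 0.3)
  lambda <- c(0.3, 0.6, 0.1)
  pi_c <- c(0.5, 0.3, 0.2)
  mols <- list(
    list(barcode = "b1", modality = "RNA", molecule = "m1",
         region = "na",
         calls = data.frame(variant = vids[1:2], allele = c(1L, 0L),
                            qual = c(20, 30))),
    list(barcode = "b1", modality = "RNA", molecule = "m2",
         region = "na",
         calls = data.frame(variant = vids[3], allele = 1L, qual = 25)),
    list(barcode = "b1", modality = "ATAC", molecule = "m3",
         region = "intra",
         calls = data.frame(variant = vids[c(4, 5)], allele = c(0L, 1L),
                            qual = c(35, 20))))
  mt <- toy_mt(mols)
  cases <- list(list(h = 0, s = character()),
                list(h = 1, s = "dA"), list(h = 1, s = "dC"),
                list(h = 2, s = c("dA", "dB")),
                list(h = 2, s = c("dB", "dC")))
  for (cs in cases) {
    for (al in list(c(1, 1), c(0.3, 0.8), c(0.05, 0.6))) {
      if (cs$h == 0 && !all(al == 1)) next
      got <- dropletLoglik(mt, "b1", cs$h, cs$s, al[1], al[2], gm,
                           lambda, pi_c, pi_a)
      want <- bf_droplet_loglik(mols, cs$h, cs$s, al[1], al[2], gm,
                                lambda, pi_c, pi_a)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("droplet log-likelihood degenerate cases", {
  gm <- toy_gm2()
  lambda <- c(0.25, 0.65, 0.10)
  # droplet with zero molecules under the empty hypothesis -> log lambda0
  mt0 <- MoleculeTable(
    calls = data.table(),
    coverage = data.table(barcode = "bX", modality = "RNA",
                          region = "na", n_molecules = 5L))
  expect_equal(dropletLoglik(mt0, "bX", 0, character(), 1, 1, gm, lambda,
                             c(0.5, 0.5), c(0.5, 0.5)), log(lambda[1]))
  # equal molecule terms across s: ranking within h is set by pi_c alone
  pi_c <- c(0.8, 0.2)
  mols <- list(list(barcode = "b", modality = "RNA", molecule = "m",
                    region = "na",
                    calls = data.frame(variant = variantIds(gm)[2],
                                       allele = 1L, qual = 20)))
  mt <- toy_mt(mols)   # site 2 is gamma 0.5 for both donors
  lA <- dropletLoglik(mt, "b", 1, "dA", 0.2, 0.2, gm, lambda, pi_c,
                      c(0.5, 0.5))
  lB <- dropletLoglik(mt, "b", 1, "dB", 0.2, 0.2, gm, lambda, pi_c,
                      c(0.5, 0.5))
  expect_equal(lA - lB, log(pi_c[1]) - log(pi_c[2]))
})

test_that("singlet likelihood is non-increasing in alpha for a perfect match", {
  # donor with gamma in {0, 1} matching every call: ambient can only
  # dilute the match
  g <- matrix(c(1, 1, 0, 0, 0, 1), 3, 2,
              dimnames = list(paste0("c1:", 1:3 * 100, ":A:T"),
                              c("dA", "dB")))
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(1:3 * 100,
                                                      width = 1),
                               ref = "A", alt = "T")
  names(gr) <- rownames(g)
  gm <- GenotypeMatrix(g, gr)
  calls <- data.frame(variant = rownames(g), allele = c(1L, 1L, 0L),
                      qual = 30)
  vals <- vapply(seq(0, 1, by = 0.1), function(a)
    moleculeMixtureLoglik(calls, 1, "dA", a, gm, c(0.5, 0.5)),
    numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("posterior normalization over the hypothesis space", {
  sim <- small_sim(seed = 7)
  fit <- demuxFit(sim$molecules, sim$pool$genotypes)
  post <- dropletPosteriors(fit)
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)),
               tolerance = 1e-12)
  expect_true(all(post >= 0))
})
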