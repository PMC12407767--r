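# Independent oracles, structurally different from the implementation.

# Brute-force droplet likelihood: enumerate the full joint configuration
# space of per-molecule origins T and per-call error indicators E, and
# sum the joint probabilities. Exponential in the number of molecules
# and calls; only for tiny instances.
bf_droplet_loglik <- function(mols, h, s, alpha_rna, alpha_atac, gm,
                              lambda, pi_c, pi_a, max_qual = 60) {
  donors <- donorNames(gm)
  g <- gammaMatrix(gm)
  ga <- as.vector(g %*% pi_a)
  names(ga) <- rownames(g)
  # hypothesis prior
  pr <- lambda[h + 1]
  if (h == 1) pr <- pr * pi_c[match(s[[1]], donors)]
  if (h == 2) {
    z <- 0
    for (i in seq_along(donors)) for (j in seq_along(donors))
      if (i < j) z <- z + pi_c[i] * pi_c[j]
    pr <- pr * pi_c[match(s[[1]], donors)] * pi_c[match(s[[2]], donors)] / z
  }
  M <- length(mols)
  origin_sets <- lapply(mols, function(m) {
    a <- if (m$modality == "RNA") alpha_rna else alpha_atac
    if (h == 0) {
      list(list(p = 1, src = 0L))
    } else if (h == 1) {
      list(list(p = a, src = 0L),
           list(p = 1 - a, src = match(s[[1]], donors)))
    } else {
      list(list(p = a, src = 0L),
           list(p = (1 - a) / 2, src = match(s[[1]], donors)),
           list(p = (1 - a) / 2, src = match(s[[2]], donors)))
    }
  })
  idx <- lapply(origin_sets, seq_along)
  grid <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
  total <- 0
  for (r in seq_len(max(nrow(grid), 1))) {
    p_cfg <- 1
    for (m in seq_len(M)) {
      o <- origin_sets[[m]][[grid[r, m]]]
      p_cfg <- p_cfg * o$p
      cl <- mols[[m]]$calls
      if (NROW(cl)) for (k in seq_len(nrow(cl))) {
        tau <- 10^(-min(cl$qual[k], max_qual) / 10)
        gv <- if (o$src == 0L) ga[cl$variant[k]] else
          g[cl$variant[k], o$src]
        bern <- if (cl$allele[k] == 1) gv else 1 - gv
        # enumerate the error indicator explicitly
        p_call <- (1 - tau) * bern + tau * 0.25
        p_cfg <- p_cfg * p_call
      }
    }
    total <- total + p_cfg
  }
  unname(log(pr) + log(total))
}

# 1-D grid maximizer of the penalized alpha objective
grid_alpha <- function(la, ld, beta, kappa = 1, step = 1e-4) {
  grid <- seq(step, 1 - step, by = step)
  f <- vapply(grid, function(a)
    sum(log(a * exp(la) + (1 - a) * exp(ld))) +
      kappa * (beta * log(a) + (1 - beta) * log(1 - a)), numeric(1))
  grid[which.max(f)]
}

# grid search over the 2-simplex for the ambient profile objective
grid_pi_a2 <- function(calls, gm, step = 1e-3, max_qual = 60) {
  g <- gammaMatrix(gm)
  grid <- seq(0, 1, by = step)
  obj <- vapply(grid, function(p1) {
    pa <- c(p1, 1 - p1)
    ga <- as.vector(g %*% pa)[match(calls$variant, rownames(g))]
    tau <- 10^(-pmin(calls$qual, max_qual) / 10)
    pr <- ifelse(calls$allele == 1, ga, 1 - ga)
    sum(log((1 - tau) * pr + tau / 4))
  }, numeric(1))
  grid[which.max(obj)]
}

# expected complete-data log-likelihood of the global parameters given
# fixed posteriors (the quantity the EM M-step should not decrease),
# using the spec's half-weight doublet membership surrogate
surrogate_em_obj <- function(post, hyp, n_fixed_empty, lambda, pi_c) {
  ch <- vapply(0:2, function(h) {
    cols <- which(hyp$h == h)
    if (length(cols)) sum(post[, cols, drop = FALSE]) else 0
  }, numeric(1))
  ch[1] <- ch[1] + n_fixed_empty
  w <- numeric(length(pi_c))
  for (k in which(hyp$h == 1)) w[hyp$i[k]] <- w[hyp$i[k]] + sum(post[, k])
  for (k in which(hyp$h == 2)) {
    m <- 0.5 * sum(post[, k])
    w[hyp$i[k]] <- w[hyp$i[k]] + m
    w[hyp$j[k]] <- w[hyp$j[k]] + m
  }
  sum(ch * log(lambda)) + sum(w * log(pi_c))
}
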