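# Droplet calls.
#
# Posterior probabilities over the hypothesis space are a softmax of the
# per-hypothesis log-likelihoods at the fitted parameters. A droplet type
# (EMPTY / SNG / DBL) is called when the summed posterior mass of that
# type's hypotheses reaches the threshold (default 0.90); otherwise the
# droplet is ambiguous (AMB). Fixed-empty droplets (below the coverage
# threshold) have posterior 1 on empty by construction.

#' Posterior probabilities over the hypothesis space
#'
#' @param fit a [DemuxFit-class].
#' @return Matrix (test droplets x hypotheses) of posteriors; rows sum
#'   to 1. Fixed-empty droplets are not included (their posterior is 1 on
#'   the empty hypothesis; see [callDroplets()]).
#' @export
dropletPosteriors <- function(fit) {
  stopifnot(is(fit, "DemuxFit"))
  .softmax_rows(fit@loglik)
}

#' Call droplets from posterior probabilities
#'
#' Computes the per-type posterior mass (empty, singlet, doublet) for each
#' droplet and calls the type whose mass reaches `threshold`; droplets
#' where no type qualifies are AMB (ambiguous). Called singlets are
#' assigned to the donor of the highest-posterior singlet hypothesis
#' (ties broken deterministically by donor input order and flagged);
#' doublets to the best pair. Fixed-empty droplets are EMPTY with
#' posterior 1.
#'
#' @param fit a [DemuxFit-class].
#' @param threshold posterior mass required to call a type; must be in
#'   (0.5, 1\] (below 0.5 two types could qualify at once). Default 0.90.
#' @return A data.table, one row per barcode (sorted): `barcode`, `call`
#'   (EMPTY/SNG/DBL/AMB), `donor1`, `donor2`, type masses `p_empty`,
#'   `p_sng`, `p_dbl`, best-hypothesis masses `p_best_sng`, `p_best_dbl`,
#'   fitted `alpha_rna`, `alpha_atac` at the reported hypothesis (1 for
#'   EMPTY), `tie` flag, and per-modality coverage (`n_rna`, `n_atac`,
#'   `inf_rna`, `inf_atac`).
#' @export
callDroplets <- function(fit, threshold = 0.90) {
  stopifnot(is(fit, "DemuxFit"))
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must be in (0.5, 1]")
  hyp <- fit@hyp
  donors <- fit@params$donors
  post <- dropletPosteriors(fit)
  nT <- nrow(post)

  sng_cols <- which(hyp$h == 1L)
  dbl_cols <- which(hyp$h == 2L)
  emp_col <- which(hyp$h == 0L)
  p_empty <- post[, emp_col]
  p_sng <- rowSums(post[, sng_cols, drop = FALSE])
  p_dbl <- if (length(dbl_cols))
    rowSums(post[, dbl_cols, drop = FALSE]) else rep(0, nT)

  best_sng <- sng_cols[max.col(post[, sng_cols, drop = FALSE],
                               ties.method = "first")]
  best_dbl <- if (length(dbl_cols))
    dbl_cols[max.col(post[, dbl_cols, drop = FALSE],
                     ties.method = "first")] else rep(NA_integer_, nT)

  # exact likelihood ties among singlet hypotheses (flagged)
  ll_sng <- fit@loglik[, sng_cols, drop = FALSE]
  tie <- rowSums(ll_sng == ll_sng[cbind(seq_len(nT),
                                        max.col(ll_sng, "first"))]) > 1L

  call <- rep("AMB", nT)
  call[p_empty >= threshold] <- "EMPTY"
  call[p_sng >= threshold] <- "SNG"
  call[p_dbl >= threshold] <- "DBL"

  # reported hypothesis: called type's best hypothesis; AMB -> best
  # non-empty; EMPTY -> alpha = 1 by definition
  rep_hyp <- ifelse(call == "SNG", best_sng,
                    ifelse(call == "DBL", best_dbl, NA_integer_))
  amb_idx <- which(is.na(rep_hyp) & call != "EMPTY")
  if (length(amb_idx)) {
    ne <- c(sng_cols, dbl_cols)
    rep_hyp[amb_idx] <- ne[max.col(post[amb_idx, ne, drop = FALSE],
                                   ties.method = "first")]
  }
  a_rna <- a_atac <- rep(1, nT)
  ok <- !is.na(rep_hyp)
  a_rna[ok] <- fit@alpha_rna[cbind(which(ok), rep_hyp[ok])]
  a_atac[ok] <- fit@alpha_atac[cbind(which(ok), rep_hyp[ok])]

  donor1 <- ifelse(call == "SNG", donors[hyp$i[best_sng]],
                   ifelse(call == "DBL", donors[hyp$i[best_dbl]],
                          NA_character_))
  donor2 <- ifelse(call == "DBL", donors[hyp$j[best_dbl]], NA_character_)

  out <- data.table(
    barcode = fit@barcodes, call = call, donor1 = donor1, donor2 = donor2,
    p_empty = p_empty, p_sng = p_sng, p_dbl = p_dbl,
    p_best_sng = post[cbind(seq_len(nT), best_sng)],
    p_best_dbl = if (length(dbl_cols))
      post[cbind(seq_len(nT), best_dbl)] else 0,
    alpha_rna = a_rna, alpha_atac = a_atac, tie = tie)

  if (length(fit@fixed_empty)) {
    out <- rbindlist(list(out, data.table(
      barcode = fit@fixed_empty, call = "EMPTY", donor1 = NA_character_,
      donor2 = NA_character_, p_empty = 1, p_sng = 0, p_dbl = 0,
      p_best_sng = 0, p_best_dbl = 0, alpha_rna = 1, alpha_atac = 1,
      tie = FALSE)))
  }

  cov <- fit@coverage
  wide <- data.table::dcast(cov, barcode ~ modality,
                            value.var = c("n_molecules", "n_informative"),
                            fill = 0L)
  for (col in c("n_molecules_RNA", "n_molecules_ATAC",
                "n_informative_RNA", "n_informative_ATAC"))
    if (!col %in% names(wide)) wide[, (col) := 0L]
  setnames(wide,
           c("n_molecules_RNA", "n_molecules_ATAC", "n_informative_RNA",
             "n_informative_ATAC"),
           c("n_rna", "n_atac", "inf_rna", "inf_atac"))
  out <- merge(out, wide, by = "barcode", all.x = TRUE)
  for (col in c("n_rna", "n_atac", "inf_rna", "inf_atac"))
    out[is.na(get(col)), (col) := 0L]
  setorder(out, barcode)
  out[]
}

#' Write droplet calls and a fit summary
#'
#' Writes `assignments.tsv` (one row per barcode, barcode-sorted, the
#' columns of [callDroplets()]) and a `summary.json` sidecar with call
#' counts and the fitted global parameters.
#'
#' @param calls data.table from [callDroplets()].
#' @param dir output directory (created if needed).
#' @param fit the [DemuxFit-class] the calls came from (optional; enables
#'   the parameter section of the summary).
#' @return Invisibly, the paths written.
#' @export
writeAssignments <- function(calls, dir, fit = NULL) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  tsv <- file.path(dir, "assignments.tsv")
  fwrite(data.table::setorder(copy(calls), barcode), tsv, sep = "\t")
  smry <- list(
    n_barcodes = nrow(calls),
    calls = as.list(table(calls$call)))
  if (!is.null(fit)) {
    stopifnot(is(fit, "DemuxFit"))
    p <- fit@params
    smry <- c(smry, list(
      lambda = unname(p$lambda),
      pi_c = as.list(p$pi_c),
      pi_a = as.list(p$pi_a),
      beta = as.list(p$beta),
      converged = fit@converged,
      n_iter = fit@n_iter,
      config = p$config))
  }
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(smry, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(assignments = tsv, summary = js))
}

#' Read droplet calls written by [writeAssignments()]
#'
#' @param path the `assignments.tsv` file (or the directory holding it).
#' @return A data.table of calls.
#' @export
readAssignments <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "assignments.tsv")
  if (!file.exists(path)) stop("assignments file not found: ", path)
  fread(path, sep = "\t", na.strings = "",
        colClasses = list(character = c("call", "donor1", "donor2")))
}
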