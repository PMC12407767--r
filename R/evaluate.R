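# Evaluation against simulation ground truth.
#
# Precision = correctly assigned called singlets / all called singlets;
# recall = correctly assigned called singlets / all true singlets. A true
# self-doublet (both independent donor draws hit the same donor) is
# evaluated as a singlet of that donor. Ambient-fraction accuracy is the
# mean absolute error |alpha_hat - alpha_true| per modality, by default
# over correctly assigned called singlets; its dependence on coverage is
# summarized by a loess fit of the per-droplet absolute error against the
# informative molecule count.

# effective truth type/donor: self-doublets count as singlets
.truth_effective <- function(truth) {
  td <- if (is(truth, "SimTruth")) truthDroplets(truth) else
    as.data.table(truth)
  td[, true_singlet := n_nuclei == 1L |
       (n_nuclei == 2L & donor1 == donor2)]
  td[, true_donor := ifelse(true_singlet, donor1, NA_character_)]
  td[, true_type := ifelse(n_nuclei == 0L, "empty",
                           ifelse(true_singlet, "singlet", "doublet"))]
  td
}

#' Precision and recall of singlet assignment across posterior thresholds
#'
#' Re-calls droplets at each threshold from the fit's posteriors and
#' computes precision (correct-donor singlets over called singlets; NA
#' when nothing is called) and recall (correct-donor singlets over all
#' true singlets, including true singlets below the coverage threshold,
#' which can never be called).
#'
#' @param fit a [DemuxFit-class].
#' @param truth a [SimTruth-class] (or its droplet table).
#' @param thresholds posterior thresholds to sweep (default
#'   `seq(0.5, 0.99, by = 0.01)` plus 0.90).
#' @return data.table: `threshold`, `n_called`, `n_correct`, `precision`,
#'   `recall`.
#' @export
precisionRecall <- function(fit, truth,
                            thresholds = sort(unique(c(
                              seq(0.5, 0.99, by = 0.01), 0.9)))) {
  stopifnot(is(fit, "DemuxFit"))
  td <- .truth_effective(truth)
  all_fit <- c(fit@barcodes, fit@fixed_empty)
  missing <- setdiff(td$barcode, all_fit)
  if (length(missing)) {
    # droplets without a single molecule never enter the fit; they are
    # implicitly empty. A cellular truth barcode missing from the fit is
    # an input mismatch.
    bad <- td[barcode %in% missing & n_nuclei > 0L]
    if (nrow(bad))
      stop(nrow(bad), " cellular truth barcode(s) absent from the fit")
  }
  n_true_sng <- sum(td$true_singlet)

  post <- dropletPosteriors(fit)
  hyp <- fit@hyp
  sng_cols <- which(hyp$h == 1L)
  p_sng <- rowSums(post[, sng_cols, drop = FALSE])
  best <- sng_cols[max.col(post[, sng_cols, drop = FALSE],
                           ties.method = "first")]
  assigned <- fit@params$donors[hyp$i[best]]
  tdx <- td[match(fit@barcodes, barcode)]
  correct_donor <- !is.na(tdx$true_donor) & assigned == tdx$true_donor

  out <- lapply(thresholds, function(t) {
    called <- p_sng >= t
    n_called <- sum(called)
    n_correct <- sum(called & correct_donor)
    data.table(threshold = t, n_called = n_called, n_correct = n_correct,
               precision = if (n_called > 0) n_correct / n_called else
                 NA_real_,
               recall = n_correct / n_true_sng)
  })
  rbindlist(out)
}

#' Mean absolute error of the ambient-fraction estimates
#'
#' Compares the fitted per-droplet ambient fractions with the simulated
#' truth, per modality. The default subset is the correctly assigned
#' called singlets (their reported alpha is the fitted value at the
#' assigned singlet hypothesis); `"all-cellular"` scores every cellular
#' truth droplet present in the fit, using the best non-empty hypothesis.
#'
#' @param fit a [DemuxFit-class].
#' @param truth a [SimTruth-class].
#' @param subset `"correct-singlets"` (default) or `"all-cellular"`.
#' @param threshold posterior threshold for the singlet calls (default
#'   0.90).
#' @return list: `mae` named vector (RNA, ATAC), `n` droplets scored,
#'   `per_droplet` data.table with per-droplet absolute errors and
#'   informative counts.
#' @export
ambientMae <- function(fit, truth,
                       subset = c("correct-singlets", "all-cellular"),
                       threshold = 0.90) {
  subset <- match.arg(subset)
  stopifnot(is(fit, "DemuxFit"))
  td <- .truth_effective(truth)
  calls <- callDroplets(fit, threshold)
  dt <- merge(calls, td[, .(barcode, true_type, true_donor, alpha_true)],
              by = "barcode")
  if (subset == "correct-singlets") {
    dt <- dt[call == "SNG" & true_type == "singlet" &
               donor1 == true_donor]
  } else {
    dt <- dt[true_type %in% c("singlet", "doublet") &
               barcode %in% fit@barcodes]
  }
  if (nrow(dt) == 0L)
    return(list(mae = c(RNA = NA_real_, ATAC = NA_real_), n = 0L,
                per_droplet = dt))
  dt[, `:=`(abs_err_rna = abs(alpha_rna - alpha_true),
            abs_err_atac = abs(alpha_atac - alpha_true))]
  list(mae = c(RNA = mean(dt$abs_err_rna), ATAC = mean(dt$abs_err_atac)),
       n = nrow(dt),
       per_droplet = dt[, .(barcode, alpha_true, alpha_rna, alpha_atac,
                            abs_err_rna, abs_err_atac, inf_rna,
                            inf_atac)])
}

#' Ambient-estimate error as a function of informative coverage
#'
#' Fits a loess curve (span 0.75, degree 1 by default) of the per-droplet
#' absolute ambient-fraction error on log10(informative molecule count),
#' per modality, over the [ambientMae()] subset, and evaluates it on a
#' grid that always contains 100 and 1,000 informative molecules.
#' Decile-binned mean errors are returned as a smoother-free fallback;
#' with fewer than 30 droplets only the bins are returned.
#'
#' @param fit a [DemuxFit-class].
#' @param truth a [SimTruth-class].
#' @param modality "RNA" or "ATAC".
#' @param span,degree loess controls.
#' @param grid informative-count evaluation grid.
#' @param subset,threshold passed to [ambientMae()].
#' @return list: `curve` (data.table `n_informative`, `abs_err`; NULL
#'   when too few droplets), `bins` (decile means), `n`.
#' @export
errorByCoverage <- function(fit, truth, modality = c("RNA", "ATAC"),
                            span = 0.75, degree = 1,
                            grid = c(50, 100, 200, 500, 1000, 2000),
                            subset = "correct-singlets",
                            threshold = 0.90) {
  modality <- match.arg(modality)
  mae <- ambientMae(fit, truth, subset, threshold)
  pd <- mae$per_droplet
  if (!nrow(pd)) return(list(curve = NULL, bins = NULL, n = 0L))
  err <- if (modality == "RNA") pd$abs_err_rna else pd$abs_err_atac
  cnt <- if (modality == "RNA") pd$inf_rna else pd$inf_atac
  keep <- cnt > 0
  err <- err[keep]; cnt <- cnt[keep]
  grid <- sort(unique(c(grid, 100, 1000)))
  dt <- data.table(n_informative = cnt, abs_err = err)
  dt[, bin := cut(n_informative,
                  breaks = unique(stats::quantile(n_informative,
                                           probs = seq(0, 1, 0.1))),
                  include.lowest = TRUE)]
  bins <- dt[, .(mean_n = mean(n_informative), mean_err = mean(abs_err),
                 n = .N), by = "bin"][order(mean_n)]
  curve <- NULL
  if (length(err) >= 30) {
    fitl <- loess(abs_err ~ lx, data = data.frame(abs_err = err,
                                                  lx = log10(cnt)),
                  span = span, degree = degree,
                  control = loess.control(surface = "direct"))
    curve <- data.table(n_informative = grid,
                        abs_err = predict(fitl,
                                          data.frame(lx = log10(grid))))
  }
  list(curve = curve, bins = bins, n = length(err))
}

#' Full evaluation report for a fitted simulation
#'
#' Precision/recall curves, a confusion matrix of calls against truth
#' (EMPTY / SNG-correct / SNG-wrong / DBL / AMB by true type), ambient
#' MAE under both subsets, and the error-vs-coverage summaries.
#'
#' @param fit a [DemuxFit-class].
#' @param truth a [SimTruth-class].
#' @param threshold calling threshold (default 0.90).
#' @return list (`EvalReport`): `pr`, `confusion`, `mae_correct_singlets`,
#'   `mae_all_cellular`, `error_by_coverage` (per modality), `counts`.
#' @export
evaluateCalls <- function(fit, truth, threshold = 0.90) {
  stopifnot(is(fit, "DemuxFit"))
  td <- .truth_effective(truth)
  calls <- callDroplets(fit, threshold)
  dt <- merge(td[, .(barcode, true_type, true_donor)], calls,
              by = "barcode", all.x = TRUE)
  dt[is.na(call), call := "EMPTY"]   # no molecules at all -> never fit
  dt[, call_cat := ifelse(
    call == "SNG", ifelse(!is.na(true_donor) & donor1 == true_donor,
                          "SNG-correct", "SNG-wrong"), call)]
  confusion <- data.table::dcast(
    dt[, .N, by = c("true_type", "call_cat")],
    true_type ~ call_cat, value.var = "N", fill = 0L)
  mae_cs <- ambientMae(fit, truth, "correct-singlets", threshold)
  mae_ac <- ambientMae(fit, truth, "all-cellular", threshold)
  list(pr = precisionRecall(fit, truth),
       confusion = confusion,
       mae_correct_singlets = mae_cs$mae,
       mae_all_cellular = mae_ac$mae,
       error_by_coverage = list(
         RNA = errorByCoverage(fit, truth, "RNA", threshold = threshold),
         ATAC = errorByCoverage(fit, truth, "ATAC",
                                threshold = threshold)),
       counts = as.list(table(dt$call)))
}
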