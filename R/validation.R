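#' @title Cross-validation of patient-specific models
#' @description Leave-one-metabolite-out validation: for each measured
#' exchange the patient model is rebuilt with that exchange relaxed to
#' its baseline bounds, the relaxed model is sampled, and the sampled
#' flux population for the exchange is compared against the constrained
#' population with a Welch t-test; p-values are FDR-adjusted across the
#' run. A prediction counts as correct when the constrained flux is
#' statistically indistinguishable from the relaxed one (adjusted
#' p >= alpha); the opposite convention is available by flag.
#' @name validation-module
NULL

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `p(i) * m / i` with monotone enforcement,
#' clipped to `[0, 1]`.
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0) return(numeric())
  o <- order(pvalues)
  adj <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Enumerate the cross-validation test grid
#'
#' One test per (patient, measured metabolite) pair; the driver runs
#' exactly `length(patients) * length(metabolites)` tests.
#' @param patients patient ids.
#' @param metabolites measured metabolite (or exchange) ids.
#' @return data.frame with columns `patient`, `metabolite`.
#' @export
cv_test_grid <- function(patients, metabolites) {
  expand.grid(patient = patients, metabolite = metabolites,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Leave-one-exchange-out cross-validation of one patient model
#'
#' @param patient_model constrained patient [metabolic_model].
#' @param profile `baseline_profile` providing the relaxed bounds.
#' @param samples_constrained [flux_sample_set] from `patient_model`.
#' @param measured_exchanges exchange reaction ids under test.
#' @param alpha significance level (default 0.01).
#' @param subsample_n draws per population entering the t-test.
#' @param seed RNG seed (subsampling and relaxed-model sampling).
#' @param n_points samples drawn from each relaxed model.
#' @param correct_if_nonsignificant verdict convention (default TRUE:
#'   non-significant difference = correct prediction).
#' @return a `validation_report`: data.frame `table` (exchange, p_raw,
#'   p_adj, verdict) and `summary` (fraction_correct, n_error, alpha).
#' @export
crossvalidate_exchanges <- function(patient_model, profile,
                                    samples_constrained,
                                    measured_exchanges,
                                    alpha = 0.01, subsample_n = 100L,
                                    seed = 1L, n_points = 500L,
                                    correct_if_nonsignificant = TRUE) {
  stopifnot(all(measured_exchanges %in% patient_model$reactions$id))
  set.seed(seed)
  pr <- rep(NA_real_, length(measured_exchanges))
  verdict <- character(length(measured_exchanges))
  pb <- profile$bounds
  for (k in seq_along(measured_exchanges)) {
    ex <- measured_exchanges[k]
    relaxed <- patient_model
    i <- reaction_index(relaxed, ex)
    j <- match(ex, pb$id)
    relaxed$reactions$lower_bound[i] <- pb$lower[j]
    relaxed$reactions$upper_bound[i] <- pb$upper[j]
    su <- tryCatch(sample_fluxes(relaxed, n_points,
                                 seed = seed + k),
                   error = function(e) NULL)
    if (is.null(su)) { verdict[k] <- "error"; next }
    a <- samples_constrained$matrix[, ex]
    b <- su$matrix[, ex]
    a <- a[sample.int(length(a), min(subsample_n, length(a)))]
    b <- b[sample.int(length(b), min(subsample_n, length(b)))]
    if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
      ## both populations numerically constant: indistinguishable iff equal
      pr[k] <- if (abs(mean(a) - mean(b)) < 1e-9) 1 else 0
    } else {
      pr[k] <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    }
    verdict[k] <- "pending"
  }
  ok <- verdict == "pending"
  padj <- rep(NA_real_, length(pr))
  padj[ok] <- fdr_adjust(pr[ok])
  sig <- !is.na(padj) & padj < alpha
  verdict[ok] <- if (correct_if_nonsignificant)
    ifelse(sig[ok], "incorrect", "correct")
  else ifelse(sig[ok], "correct", "incorrect")
  tab <- data.frame(exchange = measured_exchanges, p_raw = pr,
                    p_adj = padj, verdict = verdict,
                    stringsAsFactors = FALSE)
  structure(list(
    table = tab,
    summary = list(
      fraction_correct = if (any(ok)) mean(tab$verdict[ok] == "correct")
                         else NA_real_,
      n_error = sum(verdict == "error"), alpha = alpha)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", nrow(x$table), "tests;",
      format(100 * x$summary$fraction_correct, digits = 4),
      "% correct at alpha", x$summary$alpha, "(",
      x$summary$n_error, "errors )\n")
  invisible(x)
}

#' Write a validation report (TSV table + JSON summary)
#' @param report a `validation_report`.
#' @param path TSV path; summary goes to `<path>.json`.
#' @export
write_validation_report <- function(report, path) {
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report$summary, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
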