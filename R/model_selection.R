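#' Akaike Information Criterion corrected for small samples
#'
#' AICc = -2 logL + 2K + 2K(K+1)/(n - K - 1). The correction is undefined
#' when n <= K + 1 and such calls error; \code{\link{buildSelectionTable}}
#' surfaces that case as a skipped model with a warning.
#'
#' @param logL maximized log-likelihood
#' @param K number of estimated parameters
#' @param n sample size (sites entering the fit)
#' @return AICc value
#' @examples
#' aicc(0, 1, 10)  # 2.5
#' @export
aicc <- function(logL, K, n) {
  if (n <= K + 1)
    stop("AICc undefined: need n > K + 1 (n = ", n, ", K = ", K, ")")
  -2 * logL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights
#'
#' w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2) with
#' Delta_i = AICc_i - min(AICc); computed shift-stabilized so large AICc
#' values cannot underflow the normalization.
#'
#' @param aicc_values numeric vector of AICc values (>= 1 finite)
#' @return weights summing to 1
#' @export
akaikeWeights <- function(aicc_values) {
  if (!length(aicc_values) || all(!is.finite(aicc_values)))
    stop("need at least one finite AICc")
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Build an AICc model-selection table
#'
#' Ranks a set of fitted candidate models by AICc: rows carry the model id,
#' K, logL, AICc, delta AICc to the best model, Akaike weight and the
#' plausibility flag (delta AICc strictly < 2), sorted ascending by AICc with
#' ties broken lexicographically by model id. Non-converged fits, and fits
#' whose sample size does not support the small-sample correction
#' (n <= K + 1), are excluded with a warning.
#'
#' @param fits list of \linkS4class{FittedModel}
#' @return data.frame(model_id, K, logL, AICc, deltaAICc, weight, plausible)
#' @export
buildSelectionTable <- function(fits) {
  keep <- vapply(fits, function(f) f@converged, logical(1))
  if (any(!keep))
    warning("excluding non-converged fit(s): ",
            paste(vapply(fits[!keep], function(f) f@model@model_id,
                         character(1)), collapse = ", "))
  fits <- fits[keep]
  if (!length(fits)) stop("no converged fits to rank")
  rows <- lapply(fits, function(f) {
    a <- tryCatch(aicc(f@logL, f@K, f@n), error = function(e) NA_real_)
    data.frame(model_id = f@model@model_id, K = f@K, logL = f@logL,
               AICc = a, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (anyNA(tab$AICc)) {
    warning("skipping model(s) with n <= K + 1: ",
            paste(tab$model_id[is.na(tab$AICc)], collapse = ", "))
    tab <- tab[!is.na(tab$AICc), , drop = FALSE]
  }
  if (!nrow(tab)) stop("no models with a defined AICc")
  tab <- tab[order(tab$AICc, tab$model_id), , drop = FALSE]
  tab$deltaAICc <- tab$AICc - tab$AICc[1]
  tab$weight <- akaikeWeights(tab$AICc)
  tab$plausible <- tab$deltaAICc < 2
  rownames(tab) <- NULL
  tab
}

#' Write a selection table in the report dialect
#'
#' Tab-separated with columns M, K, logL, AICc, dAICc, Wi.
#'
#' @param tab data.frame from \code{\link{buildSelectionTable}}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeSelectionTable <- function(tab, path) {
  out <- data.frame(M = tab$model_id, K = tab$K,
                    logL = sprintf("%.3f", tab$logL),
                    AICc = sprintf("%.3f", tab$AICc),
                    dAICc = sprintf("%.3f", tab$deltaAICc),
                    Wi = sprintf("%.4f", tab$weight))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
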