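#' Accuracy of predicted breeding values
#'
#' Pearson correlation between true and predicted breeding values over the
#' same animals.
#'
#' @param true_bv,pred_bv Aligned numeric vectors (>= 3 animals, both with
#'   nonzero variance).
#' @return Correlation in `[-1, 1]`.
#' @export
accuracy <- function(true_bv, pred_bv) {
  check_metric_input(true_bv, pred_bv, both = TRUE)
  stats::cor(true_bv, pred_bv)
}

#' Regression of true on predicted breeding values
#'
#' OLS slope `cov(true, pred) / var(pred)`. A slope near 1 indicates
#' dispersion-unbiased predictions; below 1, inflated (over-dispersed)
#' predictions.
#'
#' @inheritParams accuracy
#' @return Regression slope.
#' @export
regression_true_on_pred <- function(true_bv, pred_bv) {
  check_metric_input(true_bv, pred_bv, both = FALSE)
  stats::cov(true_bv, pred_bv) / stats::var(pred_bv)
}

check_metric_input <- function(true_bv, pred_bv, both) {
  if (length(true_bv) != length(pred_bv)) {
    stop("true and predicted vectors must be aligned", call. = FALSE)
  }
  if (length(true_bv) < 3) stop("at least 3 animals required", call. = FALSE)
  if (stats::var(pred_bv) == 0 || (both && stats::var(true_bv) == 0)) {
    stop("metric undefined: zero variance", call. = FALSE)
  }
  invisible(NULL)
}

#' Overlap of top-N animals between true and predicted rankings
#'
#' Percentage of the true top-N animals that also appear in the predicted
#' top-N. Ties are broken by descending value then ascending id.
#'
#' @param true_bv,pred_bv Aligned numeric vectors.
#' @param ids Animal identifiers aligned with the vectors.
#' @param n Size of the selected group (default 20).
#' @return Percentage in `[0, 100]`.
#' @export
topn_overlap <- function(true_bv, pred_bv, ids = seq_along(true_bv),
                         n = 20) {
  if (n > length(true_bv)) {
    stop("n (", n, ") exceeds the number of animals (", length(true_bv),
         ")", call. = FALSE)
  }
  top <- function(v) {
    ord <- order(-v, as.character(ids))
    ids[ord[seq_len(n)]]
  }
  100 * length(intersect(top(true_bv), top(pred_bv))) / n
}

#' Correlations of breeding values across time points
#'
#' Pearson correlation matrix of EBVs between the fitted time points,
#' computed over animals.
#'
#' @param ebv Long-format data frame with columns `id`, `time`, `ebv`.
#' @return Symmetric correlation matrix with unit diagonal, one row/column
#'   per time point.
#' @export
ebv_correlations <- function(ebv) {
  times <- sort(unique(ebv$time))
  if (length(times) < 2) {
    stop("at least 2 time points are required", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(ebv[, c("id", "time", "ebv")],
                             names_from = "time", values_from = "ebv")
  Y <- as.matrix(wide[, as.character(times)])
  sds <- apply(Y, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance time point: ",
         paste(times[sds == 0], collapse = ", "), call. = FALSE)
  }
  stats::cor(Y)
}

#' Within-full-sib-family spread of predicted breeding values
#'
#' Groups animals into full-sib families (same sire and dam, both known) and
#' reports the count, mean and standard deviation of their predicted
#' breeding values. Animals with an unknown parent are excluded; families of
#' one are flagged as singletons with `sd` reported as 0.
#'
#' @param predictions Data frame with columns `id` and `pred_bv`.
#' @param ped Pedigree covering the predicted animals.
#' @return Tibble with columns `sire`, `dam`, `n`, `mean_bv`, `sd_bv`,
#'   `singleton`.
#' @export
family_spread <- function(predictions, ped) {
  fam <- dplyr::inner_join(
    tibble::as_tibble(predictions[, c("id", "pred_bv")]),
    tibble::as_tibble(ped)[, c("id", "sire", "dam")],
    by = "id"
  )
  fam <- dplyr::filter(fam, !is.na(.data$sire), !is.na(.data$dam))
  out <- dplyr::summarise(
    dplyr::group_by(fam, .data$sire, .data$dam),
    n = dplyr::n(),
    mean_bv = mean(.data$pred_bv),
    sd_bv = stats::sd(.data$pred_bv),
    .groups = "drop"
  )
  out$singleton <- out$n == 1L
  out$sd_bv[out$singleton] <- 0
  out
}

#' Evaluate predictions against true breeding values
#'
#' Computes the comparison metrics for one method over the validation
#' (non-phenotyped) animals: accuracy, regression of true on predicted,
#' top-N overlap and the variance of predictions.
#'
#' @param predictions Tibble with columns `id`, `pred_bv` (validation
#'   animals).
#' @param true_bv Tibble with columns `id`, `true_bv` at the same time
#'   point.
#' @param top_n Size of the selected group for the overlap metric.
#' @return One-row tibble: `n`, `accuracy`, `regression`, `topn_overlap_pct`,
#'   `pred_variance`.
#' @export
evaluate_predictions <- function(predictions, true_bv, top_n = 20) {
  joined <- dplyr::inner_join(tibble::as_tibble(predictions),
                              tibble::as_tibble(true_bv), by = "id")
  if (nrow(joined) < nrow(predictions)) {
    stop("true breeding values missing for some predicted animals",
         call. = FALSE)
  }
  tibble::tibble(
    n = nrow(joined),
    accuracy = accuracy(joined$true_bv, joined$pred_bv),
    regression = regression_true_on_pred(joined$true_bv, joined$pred_bv),
    topn_overlap_pct = topn_overlap(joined$true_bv, joined$pred_bv,
                                    ids = joined$id, n = top_n),
    pred_variance = stats::var(joined$pred_bv)
  )
}
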