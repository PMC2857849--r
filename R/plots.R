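#' Plot predicted breeding values within full-sib families
#'
#' Dot plot of predicted breeding values for a few full-sib families,
#' contrasting how pedigree-based predictions collapse to the family mean
#' while marker-based predictions spread within a family (Mendelian
#' sampling).
#'
#' @param report A `snpblup_report` from [run_pipeline()].
#' @param n_families Number of (largest) validation families to show.
#' @return A ggplot object.
#' @export
plot_family_spread <- function(report, n_families = 4) {
  preds <- report$predictions[
    report$predictions$id %in% report$validation_ids, ]
  ped <- tibble::as_tibble(report$population$pedigree)
  df <- dplyr::inner_join(preds, ped[, c("id", "sire", "dam")], by = "id")
  df$family <- paste(df$sire, df$dam, sep = " x ")
  fam_sizes <- sort(table(df$family[df$method == df$method[1]]),
                    decreasing = TRUE)
  keep <- names(fam_sizes)[seq_len(min(n_families, length(fam_sizes)))]
  df <- df[df$family %in% keep, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$pred_bv,
                                   colour = .data$method)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        alpha = 0.7) +
    ggplot2::labs(x = "full-sib family (sire x dam)",
                  y = "predicted breeding value",
                  colour = "method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot estimated breeding-value trajectories
#'
#' EBV against time for a sample of animals, with the fitted quadratic
#' extrapolation to the target time shown as the end point.
#'
#' @param report A `snpblup_report`.
#' @param method Which method's EBVs to show.
#' @param n_animals Number of validation animals to draw.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(report, method = report$config$methods[1],
                              n_animals = 12) {
  ids <- utils::head(report$validation_ids, n_animals)
  ebv <- report$ebv[report$ebv$method == method & report$ebv$id %in% ids, ]
  pred <- report$predictions[
    report$predictions$method == method & report$predictions$id %in% ids, ]
  pred_pts <- tibble::tibble(id = pred$id, time = pred$time,
                             ebv = pred$pred_bv)
  ggplot2::ggplot(ebv, ggplot2::aes(x = .data$time, y = .data$ebv,
                                    group = .data$id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_point(data = pred_pts, colour = "red", size = 1.2) +
    ggplot2::labs(x = "time", y = "estimated breeding value",
                  title = paste0(method,
                                 ": EBV trajectories with extrapolation")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname run_pipeline
#' @param object A `snpblup_report`.
#' @param ... Unused.
#' @method autoplot snpblup_report
#' @export
autoplot.snpblup_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$metrics[, c("method", "accuracy", "regression",
                       "topn_overlap_pct")],
    cols = -"method", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "prediction quality at the extrapolated time") +
    ggplot2::theme_minimal()
}
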