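#' Plot a reliability (calibration) curve
#'
#' Observed active fraction per prediction bin against the bin center; a
#' calibrated probabilistic scorer follows the diagonal.
#'
#' @param curve A tibble from [reliability_curve()].
#' @param min_count Hide bins with fewer members than this (default 1).
#' @return A ggplot object.
#' @export
plot_reliability <- function(curve, min_count = 1L) {
  stopifnot(all(c("bin_center", "fraction", "count") %in% names(curve)))
  shown <- curve[!is.na(curve$fraction) & curve$count >= min_count, , drop = FALSE]
  ggplot2::ggplot(shown, ggplot2::aes(x = .data$bin_center, y = .data$fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$count)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "predicted probability (bin center)",
      y = "observed active fraction",
      size = "predictions"
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve of a screen result
#'
#' @param object A `screen_result` from [cross_validate()] or
#'   [simulated_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, ...) {
  preds <- object$predictions
  ord <- order(-preds$score, preds$molecule_id)
  lab <- preds$label[ord]
  roc <- tibble::tibble(
    fpr = c(0, cumsum(lab == 0) / max(sum(lab == 0), 1)),
    tpr = c(0, cumsum(lab == 1) / max(sum(lab == 1), 1))
  )
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = paste0(
        object$method, " on ", object$target_id,
        " (AUC = ", round(object$auc, 3), ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Loss trace of an IRV fit
#'
#' @param object A fitted [irv()] model.
#' @param ... Unused.
#' @return A ggplot object showing the summed cross-entropy per epoch.
#' @method autoplot irv
#' @export
autoplot.irv <- function(object, ...) {
  trace <- tibble::tibble(epoch = seq_along(object$loss), loss = object$loss)
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "summed cross-entropy") +
    ggplot2::theme_minimal()
}

#' Per-neighbor influence chart for one prediction
#'
#' Visualizes how each training neighbor pushes one query's prediction up or
#' down: signed influence bars, ordered by magnitude, annotated with the
#' neighbor's similarity.
#'
#' @param explanation A tibble from [irv_explain()].
#' @param molecule_id Which query molecule to show (default: the first).
#' @return A ggplot object.
#' @export
plot_influences <- function(explanation, molecule_id = NULL) {
  stopifnot(all(c("molecule_id", "neighbor_id", "influence") %in% names(explanation)))
  if (is.null(molecule_id)) molecule_id <- explanation$molecule_id[1]
  one <- explanation[explanation$molecule_id == molecule_id, , drop = FALSE]
  if (nrow(one) == 0L) stop("molecule_id not found in explanation", call. = FALSE)
  one$neighbor_id <- factor(one$neighbor_id, levels = rev(one$neighbor_id))
  ggplot2::ggplot(one, ggplot2::aes(
    x = .data$influence, y = .data$neighbor_id,
    fill = .data$influence > 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, color = "grey40") +
    ggplot2::labs(
      x = "influence", y = "neighbor",
      title = paste0(
        molecule_id, ": score = ", round(one$score[1], 4)
      ),
      subtitle = "bar sign = direction of the neighbor's vote"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
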