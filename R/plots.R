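#' @export
autoplot.recovery_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$rank, y = .data$recovered)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(
      intercept = 0, slope = 1 / object$depth,
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::labs(
      x = "rank", y = "fraction of target set recovered",
      subtitle = sprintf("AUC over first %d ranks: %.4f", object$depth, object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Candidate-TF summary plot
#'
#' Differential-footprint AUC per TF with point size showing TF expression
#' and color its subset log2 fold change (the layout of the screen's
#' headline figure).
#'
#' @param candidates A [candidate_screen()] result (or a `tec_screen`).
#' @return A ggplot object.
#' @export
plot_candidates <- function(candidates) {
  if (inherits(candidates, "tec_screen")) candidates <- candidates$candidates
  d <- as_tibble(candidates)
  d$tf <- factor(d$tf, levels = rev(d$tf[order(d$rank)]))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$fp_auc, y = .data$tf,
      size = .data$tf_expr_log2tpm, colour = .data$tf_log2fc, shape = .data$pass
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey80", high = "red") +
    ggplot2::labs(
      x = "differential footprint AUC (TRA promoters)", y = NULL,
      size = "TF log2(TPM+1)", colour = "TF log2FC", shape = "passes criteria"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.candidate_screen <- function(object, ...) plot_candidates(object)

#' @export
autoplot.tec_screen <- function(object, ...) plot_candidates(object)

#' @export
autoplot.diversity_result <- function(object, ...) {
  ggplot2::ggplot(
    object$values,
    ggplot2::aes(x = .data$category, y = .data$inv_simpson, colour = .data$group)
  ) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::labs(y = "inverse Simpson (effective gene number)", x = NULL) +
    ggplot2::theme_minimal()
}

#' Cut-site profile around a genomic window
#'
#' @param profile A [cut_sites()] profile.
#' @param contig Contig name.
#' @param start,end Window (0-based half-open).
#' @param normalized Plot insertions per million.
#' @return A ggplot object.
#' @export
plot_footprint_profile <- function(profile, contig, start, end, normalized = TRUE) {
  stopifnot(inherits(profile, "cut_profile"))
  v <- profile$counts[[contig]][(start + 1L):end]
  if (normalized) v <- v * profile$norm_factor
  d <- tibble(position = start:(end - 1L), insertions = v)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$insertions)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(
      y = if (normalized) "insertions per million" else "insertions",
      x = sprintf("%s position", contig)
    ) +
    ggplot2::theme_minimal()
}
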