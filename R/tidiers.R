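#' Tidiers and plots for orthopotts result objects
#'
#' broom-style `tidy()`/`glance()` methods and `autoplot()` methods so the
#' main result types drop straight into dplyr/ggplot2 pipelines.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name orthopotts-tidiers
NULL

#' @rdname orthopotts-tidiers
#' @export
tidy.potts_fit <- function(x, ...) x$log

#' @rdname orthopotts-tidiers
#' @export
glance.potts_fit <- function(x, ...) {
  tibble::tibble(
    L = x$model$L, q = x$model$q, boundary = x$model$boundary,
    n_steps = x$config$n_steps, lambda_reg = x$config$lambda_reg,
    eta = x$config$eta,
    final_moment_gap = utils::tail(x$log$max_moment_gap, 1)
  )
}

#' @rdname orthopotts-tidiers
#' @export
tidy.ois_classifier_report <- function(x, ...) x$coefficients

#' @rdname orthopotts-tidiers
#' @export
glance.ois_classifier_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auc = x$auc, n_repeats = x$n_repeats)
}

#' @rdname orthopotts-tidiers
#' @export
tidy.ois_selection <- function(x, ...) x$selected

#' @rdname orthopotts-tidiers
#' @export
glance.ois_selection <- function(x, ...) {
  tibble::tibble(
    e1 = x$thresholds[["e1"]], e2 = x$thresholds[["e2"]],
    target_fraction = x$target_fraction,
    achieved_fraction = x$achieved_fraction,
    n_selected = nrow(x$selected)
  )
}

#' @rdname orthopotts-tidiers
#' @export
tidy.ois_embedding <- function(x, ...) x$coords

#' @rdname orthopotts-tidiers
#' @export
glance.ois_embedding <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$coords),
    n_components = length(x$explained_variance),
    explained_variance = sum(x$explained_variance),
    k_clusters = x$k_clusters %||% NA_integer_,
    inertia = x$inertia
  )
}

#' @rdname orthopotts-tidiers
#' @param object A result object.
#' @export
autoplot.ois_repertoire <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$d_inter_astar_b, .data$d_inter_a_bstar)) +
    ggplot2::geom_bin2d(bins = 60) +
    ggplot2::labs(
      x = expression(Delta * E[inter] * "(A*, B)"),
      y = expression(Delta * E[inter] * "(A, B*)"),
      fill = "mutants",
      title = "Cross-talk score plane of the generated repertoire"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname orthopotts-tidiers
#' @export
autoplot.ois_selection <- function(object, ...) {
  sel <- object$selected
  ggplot2::ggplot(sel,
                  ggplot2::aes(.data$d_inter_astar_b, .data$d_inter_a_bstar)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$thresholds[["e1"]],
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$thresholds[["e2"]],
                        linetype = "dashed") +
    ggplot2::labs(
      x = expression(Delta * E[inter] * "(A*, B)"),
      y = expression(Delta * E[inter] * "(A, B*)"),
      title = sprintf("Selected orthogonal candidates (F = %.2f)",
                      object$target_fraction)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname orthopotts-tidiers
#' @export
autoplot.ois_embedding <- function(object, ...) {
  p <- ggplot2::ggplot(object$coords, ggplot2::aes(.data$pc1, .data$pc2))
  p <- if (!is.null(object$coords$cluster)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster),
                            alpha = 0.5, size = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.5, size = 0.8)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2]),
    title = "Mutant sequence space (one-hot PCA)"
  ) + ggplot2::theme_minimal()
}

#' @rdname orthopotts-tidiers
#' @export
autoplot.ois_enrichment <- function(object, ...) {
  if ("from_aa" %in% names(object)) {
    ggplot2::ggplot(object, ggplot2::aes(.data$to_aa, .data$from_aa)) +
      ggplot2::geom_point(ggplot2::aes(size = .data$background,
                                       colour = .data$ratio)) +
      ggplot2::scale_colour_gradient2(midpoint = 1) +
      ggplot2::labs(x = "introduced residue", y = "wild-type residue",
                    title = "Substitution enrichment") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$aa, .data$ratio)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
      ggplot2::labs(x = "introduced residue", y = "selected / background",
                    title = "Amino acid usage enrichment") +
      ggplot2::theme_minimal()
  }
}

#' Mutation-frequency logo data plot
#'
#' Stacked per-position bars whose total height is the mutation frequency of
#' the position, split by introduced residue.
#'
#' @param profile Output of [mutation_frequency_profile()].
#' @return A ggplot object.
#' @export
plot_mutation_profile <- function(profile) {
  dat <- dplyr::filter(profile, .data$frequency > 0)
  ggplot2::ggplot(dat, ggplot2::aes(.data$position, .data$frequency,
                                    fill = .data$aa)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~protein, scales = "free_x", ncol = 1) +
    ggplot2::labs(x = "position (protein-local)",
                  y = "mutation frequency", fill = "residue") +
    ggplot2::theme_minimal()
}
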