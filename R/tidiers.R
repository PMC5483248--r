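# broom-style tidiers and plot methods.

#' Tidy a count matrix
#'
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @return Long tibble: `position`, `base`, `count`.
#' @method tidy count_matrix
#' @export
tidy.count_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(position = rep(seq_len(ncol(m)), each = 4),
         base = rep(DNA_BASES, ncol(m)),
         count = as.vector(m))
}

#' Tidy a frequency matrix
#'
#' @param x A `frequency_matrix`.
#' @param ... Unused.
#' @return Long tibble: `position`, `base`, `frequency`.
#' @method tidy frequency_matrix
#' @export
tidy.frequency_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(position = rep(seq_len(ncol(m)), each = 4),
         base = rep(DNA_BASES, ncol(m)),
         frequency = as.vector(m))
}

#' Tidy a PSSM
#'
#' @param x A `pssm`.
#' @param ... Unused.
#' @return Long tibble: `position`, `base`, `score` (bits), plus
#'   `frequency` when the training frequencies are stored.
#' @method tidy pssm
#' @export
tidy.pssm <- function(x, ...) {
  out <- tibble(position = rep(seq_len(x$k), each = 4),
                base = rep(DNA_BASES, x$k),
                score = as.vector(x$w))
  if (!is.null(x$freq)) out$frequency <- as.vector(unclass(x$freq))
  out
}

#' One-row summary of a PSSM
#'
#' @param x A `pssm`.
#' @param ... Unused.
#' @return Tibble with `width`, `n_sites`, `pseudocount`, `consensus`,
#'   `consensus_score`, `max_score` (column-wise maxima summed) and
#'   `total_ic` when frequencies are stored.
#' @method glance pssm
#' @export
glance.pssm <- function(x, ...) {
  cons <- consensus_sequence(x)
  tibble(width = x$k,
         n_sites = x$n_sites %||% NA_integer_,
         pseudocount = x$pseudocount %||% NA_real_,
         consensus = cons$sequence,
         consensus_score = cons$score,
         max_score = sum(apply(x$w, 2, max)),
         total_ic = if (!is.null(x$freq) && !is.null(x$background))
           sum(information_content(x$freq, x$background)) else NA_real_)
}

#' Scan summary as a one-row tibble
#'
#' @param x A `scan_result`.
#' @param ... Unused.
#' @return The [scan_summary()] tibble.
#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) scan_summary(x)

#' ROC curve as a plain tibble
#'
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @return Tibble with `threshold`, `tp`, `fp`, `tpr`, `fpr`.
#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) as_tibble(x)

#' One-row summary of a ROC analysis
#'
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @return Tibble with `n_pos`, `n_neg`, `n_thresholds`, `auroc`.
#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble(n_pos = attr(x, "n_pos"), n_neg = attr(x, "n_neg"),
         n_thresholds = nrow(x), auroc = attr(x, "auroc"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot: FPR vs TPR with the chance diagonal, threshold
#'   points labeled.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUROC = %.3f)", attr(object, "auroc"))) +
    ggplot2::theme_minimal()
}

#' Plot a PSSM as per-position information and score heatmap
#'
#' @param object A `pssm` built from frequencies (for the information
#'   panel) or any `pssm` (score heatmap only).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pssm
#' @export
autoplot.pssm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$base,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "bits") +
    ggplot2::scale_x_continuous(breaks = seq_len(object$k)) +
    ggplot2::labs(x = "Motif position", y = NULL,
                  title = "Position-specific scores (bits)") +
    ggplot2::theme_minimal()
}

#' Histogram of scan scores
#'
#' @param x A `scan_result`.
#' @param threshold Optional threshold to mark.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(x, threshold = NULL, bins = 80) {
  p <- ggplot2::ggplot(as_tibble(x), ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::labs(x = "Window score (bits)", y = "Windows") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, colour = "firebrick",
                                 linetype = "dashed")
  }
  p
}
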