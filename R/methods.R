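# Tidiers and autoplot methods for the package's result objects.

#' Tidy a depletion logo into long format
#'
#' @param x A `depletion_logo` from [depletion_logo()].
#' @param ... Unused.
#' @return Tibble with `position`, `base`, `freq`, `log2fc`.
#' @export
tidy.depletion_logo <- function(x, ...) {
  long <- as_tibble(as.data.frame(as.table(x$pfm)))
  names(long) <- c("position", "base", "freq")
  long$position <- as.integer(as.character(long$position))
  long$base <- as.character(long$base)
  long$log2fc <- log2(long$freq / 0.25)
  arrange(long, position, base)
}

#' One-row summary of a depletion logo
#'
#' @param x A `depletion_logo`.
#' @param ... Unused.
#' @return Tibble: `n_pams`, `n_positions`, `max_log2fc`,
#'   `max_position`, `max_base`.
#' @export
glance.depletion_logo <- function(x, ...) {
  idx <- which(x$log2fc == max(x$log2fc), arr.ind = TRUE)[1, ]
  tibble(
    n_pams = x$n_pams, n_positions = nrow(x$pfm),
    max_log2fc = max(x$log2fc),
    max_position = as.integer(idx[["position"]]),
    max_base = colnames(x$pfm)[idx[["base"]]]
  )
}

#' Per-gap tidy view of a spacing summary
#'
#' @param x A `spacing_summary`.
#' @param ... Unused.
#' @return Tibble with one row per inter-anchor gap (`distance`).
#' @export
tidy.spacing_summary <- function(x, ...) {
  tibble(distance = x$distances)
}

#' One-row summary of a spacing summary
#'
#' @param x A `spacing_summary`.
#' @param ... Unused.
#' @return Tibble: `n_anchors`, `n_gaps`, `mean`, `median`, `undefined`,
#'   `circular`, `genome_len`.
#' @export
glance.spacing_summary <- function(x, ...) {
  tibble(
    n_anchors = x$n_anchors, n_gaps = length(x$distances),
    mean = x$mean, median = x$median, undefined = x$undefined,
    circular = x$circular, genome_len = x$genome_len
  )
}

#' One-row summary of a PPDV table
#'
#' @param x A `ppdv_tbl` from [compute_ppdv()].
#' @param ... Unused.
#' @return Tibble: `n_pams`, `n_undefined`, `n_depleted` (PPDV < 1),
#'   `min_ppdv`, `median_ppdv`.
#' @export
glance.ppdv_tbl <- function(x, ...) {
  ok <- !x$undefined
  tibble(
    n_pams = nrow(x), n_undefined = sum(x$undefined),
    n_depleted = sum(x$ppdv[ok] < 1),
    min_ppdv = if (any(ok)) min(x$ppdv[ok]) else NA_real_,
    median_ppdv = if (any(ok)) stats::median(x$ppdv[ok]) else NA_real_
  )
}

#' Plot a depletion logo as per-position log2 enrichment
#'
#' @param object A `depletion_logo`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depletion_logo <- function(object, ...) {
  df <- tidy(object)
  df$log2fc[!is.finite(df$log2fc)] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(position), y = log2fc, fill = base
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "PAM position", y = "log2(freq / 0.25)",
      title = sprintf("Depletion logo (%d PAMs)", object$n_pams)
    )
}

#' Plot a PAM wheel as a polar weight chart
#'
#' @param object A `pam_wheel_tbl` from [pam_wheel()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pam_wheel_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = "", y = weight, fill = trimer)) +
    ggplot2::geom_col(width = 1, colour = "white", linewidth = 0.2) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::theme_void() +
    ggplot2::labs(title = "PAM wheel (relative depletion by nucleotide triple)")
}

#' Plot the inter-anchor distance distribution
#'
#' @param object A `spacing_summary`.
#' @param binwidth Histogram bin width in bp (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spacing_summary <- function(object, binwidth = 1, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$mean, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(
      x = "distance (bp)", y = "gaps",
      title = sprintf("Anchor spacing: mean %.2f bp, median %.0f bp",
                      object$mean, object$median)
    )
}

#' Plot the PPDV distribution
#'
#' @param object A `ppdv_tbl`.
#' @param bins Histogram bins (default 60).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ppdv_tbl <- function(object, bins = 60, ...) {
  df <- object[!object$undefined, ]
  ggplot2::ggplot(df, ggplot2::aes(x = ppdv)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 1, colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "PPDV", y = "PAMs",
                  title = "Post-selection PAM depletion values")
}
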