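#' Plot cleavage curves and fitted sigmoids
#'
#' Observed fraction-cleaved points per replicate with the fitted Hill
#' curve overlaid (per guide, faceted), on a log10 concentration axis. A
#' dashed vertical line marks each guide's fitted EC(1/2max); censored
#' guides are drawn without a curve.
#'
#' @param object An `ec50_fit` from [fit_ec50()].
#' @param n_grid Points in the prediction grid.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ec50_fit
#' @export
autoplot.ec50_fit <- function(object, n_grid = 100, ...) {
  dat <- object$data
  rng <- range(dat$concentration_nM)
  grid <- tidyr::expand_grid(
    guide_id = unique(dat$guide_id),
    concentration_nM = exp(seq(log(rng[1] / 2), log(rng[2] * 2),
                               length.out = n_grid))
  ) |>
    left_join(object$summary, by = "guide_id") |>
    filter(!.data$censored, !is.na(.data$ec50)) |>
    mutate(fraction = .data$f_max * .data$concentration_nM^.data$hill /
             (.data$concentration_nM^.data$hill + .data$ec50^.data$hill))
  marks <- object$summary |> filter(!.data$censored)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$concentration_nM,
                                    y = .data$fraction)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$ec50),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$replicate))) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~guide_id) +
    ggplot2::labs(x = "Cas9 concentration (nM)", y = "Fraction cleaved",
                  shape = "Replicate") +
    ggplot2::theme_bw()
}

#' Map predicted duplex hits along screened spacers
#'
#' One horizontal track per guide: the spacer arm of every reported hit is
#' drawn as a segment over spacer coordinates 1-20 (position 1 = 5',
#' PAM-distal), coloured by hit kind and shaded by stem stability. Clean
#' guides show an empty track.
#'
#' @param object A `guide_screen` tibble from [screen_guides()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot guide_screen
#' @export
autoplot.guide_screen <- function(object, ...) {
  hits <- object |>
    select(all_of(c("id", "hits"))) |>
    tidyr::unnest("hits")
  base <- tibble(id = factor(object$id, levels = rev(object$id)))
  p <- ggplot2::ggplot(base, ggplot2::aes(y = .data$id)) +
    ggplot2::geom_blank() +
    ggplot2::scale_x_continuous(limits = c(1, 20),
                                breaks = c(1, 5, 10, 15, 20)) +
    ggplot2::labs(x = "Spacer position (5' to 3', PAM-proximal = 20)",
                  y = NULL, colour = "Interaction", alpha = "Stability") +
    ggplot2::theme_bw()
  if (nrow(hits) > 0) {
    hits$id <- factor(hits$id, levels = rev(object$id))
    p <- p + ggplot2::geom_segment(
      data = hits,
      ggplot2::aes(x = .data$spacer_start, xend = .data$spacer_end,
                   yend = .data$id, colour = .data$kind,
                   alpha = .data$stability),
      linewidth = 3
    )
  }
  p
}

#' Arc diagram of a predicted fold
#'
#' Draws the sequence along the x axis with an arc for every base pair of
#' the maximum-pairing structure.
#'
#' @param object A `fold_result` from [max_pair_fold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fold_result
#' @export
autoplot.fold_result <- function(object, ...) {
  b <- rna_chars(object$sequence)
  letters_df <- tibble(pos = seq_along(b), base = b)
  p <- ggplot2::ggplot(letters_df, ggplot2::aes(x = .data$pos, y = 0)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$base), size = 3) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("score %g", object$score)) +
    ggplot2::theme_void()
  if (nrow(object$pair_list) > 0) {
    arcs <- as_tibble(object$pair_list)
    p <- p + ggplot2::geom_curve(
      data = arcs,
      ggplot2::aes(x = .data$i, xend = .data$j, y = 0.05, yend = 0.05),
      curvature = -0.5, colour = "grey40"
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
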