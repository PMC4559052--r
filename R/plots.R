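#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map of sPCA colony scores
#'
#' The classic sPCA map: each colony drawn at its coordinates, square area
#' proportional to the absolute score on the chosen axis, fill encoding the
#' sign, so spatial genetic structure reads directly off the map.
#'
#' @param object An [spca()] fit.
#' @param geo Colony metadata tibble aligned with the sPCA rows.
#' @param axis Axis to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spca
#' @export
autoplot.spca <- function(object, geo, axis = 1, ...) {
  sc <- object$scores[, axis]
  d <- tibble::tibble(x = geo$x, y = geo$y, score = sc,
                      sign = ifelse(sc >= 0, "positive", "negative"))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$score),
                                     fill = .data$sign),
                        shape = 22, colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(positive = "black",
                                          negative = "white")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", size = "|score|",
                  title = sprintf("sPCA axis %d (lambda = %.3g)",
                                  axis, object$eigenvalues[axis]))
}

#' Isolation-by-distance scatter with kernel density
#'
#' @param density Output of [ibd_density()].
#' @return A ggplot object: pairwise genetic vs geographic distance with
#'   filled density contours.
#' @export
plot_ibd <- function(density) {
  grid <- expand.grid(geo = density$x, gen = density$y)
  grid$z <- as.vector(density$z)
  ggplot2::ggplot() +
    ggplot2::geom_contour_filled(data = grid,
                                 ggplot2::aes(.data$geo, .data$gen,
                                              z = .data$z),
                                 show.legend = FALSE) +
    ggplot2::geom_point(data = density$points,
                        ggplot2::aes(.data$geo, .data$gen),
                        size = 0.6, colour = "white", alpha = 0.6) +
    ggplot2::labs(x = "geographic distance (m)",
                  y = "Edwards' genetic distance")
}

#' Admixture barplot
#'
#' One stacked bar per individual showing its posterior admixture
#' proportions, the standard visual summary of a clustering run.
#'
#' @param object A [gibbs_admixture()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot admix_fit
#' @export
autoplot.admix_fit <- function(object, ...) {
  d <- tidy(object)
  d$individual_id <- factor(d$individual_id, levels = rownames(object$q))
  ggplot2::ggplot(d, ggplot2::aes(.data$individual_id, .data$q,
                                  fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "individual (one per colony)",
                  y = "admixture proportion q")
}

#' Delta-K curve
#'
#' @param object An [evanno_deltak()] object.
#' @param ... Unused.
#' @return A ggplot object of Delta-K against K.
#' @method autoplot deltak
#' @export
autoplot.deltak <- function(object, ...) {
  d <- object$table[!is.na(object$table$delta_k), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$k, .data$delta_k)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "K", y = expression(Delta * K))
}

#' sPCA allele-loading barplot
#'
#' @param report Output of [loading_report()].
#' @return A ggplot object, faceted by axis.
#' @export
plot_loadings <- function(report) {
  report$allele <- factor(report$allele, levels = unique(report$allele))
  ggplot2::ggplot(report, ggplot2::aes(.data$allele, .data$loading)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~axis, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)) +
    ggplot2::labs(x = "allele (locus.code)", y = "squared loading")
}
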