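#' Principal coordinates analysis of a distance matrix
#'
#' Classical (Torgerson) scaling: eigendecomposition of the double-centred
#' squared-distance matrix, as implemented by [stats::cmdscale()].
#' Coordinates are returned for the leading positive-eigenvalue axes; the
#' full eigenvalue spectrum, including any negative eigenvalues arising from
#' non-Euclidean distances, is retained and reported. Variance proportions
#' are relative to the sum of positive eigenvalues.
#'
#' @param dm Symmetric distance matrix with zero diagonal and dimnames.
#' @param n_axes Number of axes requested (default 2); truncated with a
#'   warning if it exceeds the rank of the embedding.
#' @return An object of class `pcoa_ord` with elements `coordinates`
#'   (entities x axes), `eigenvalues`, `prop_variance` and `entity_ids`.
#' @export
pcoa_ordination <- function(dm, n_axes = 2) {
  check_distance_matrix(dm)
  n <- nrow(dm)
  stopifnot(n_axes >= 1)
  k <- min(n_axes, n - 1)
  res <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k, eig = TRUE))
  eig <- res$eig
  pos <- sum(eig > 1e-12)
  coords <- res$points
  if (ncol(coords) < n_axes) {
    warn(sprintf("requested %d axes but embedding rank is %d; returning %d",
                 n_axes, pos, ncol(coords)))
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  prop <- ifelse(rep(sum(eig[eig > 0]) > 0, length(eig)),
                 eig / sum(eig[eig > 0]), 0)
  structure(list(coordinates = coords, eigenvalues = eig,
                 prop_variance = prop, entity_ids = rownames(dm)),
            class = "pcoa_ord")
}

#' @method print pcoa_ord
#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("PCoA: %d entities, %d axes returned\n", nrow(x$coordinates),
              ncol(x$coordinates)))
  cat("Variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$prop_variance[seq_len(ncol(x$coordinates))]),
             collapse = ", "), "\n")
  invisible(x)
}

#' Tidy PCoA coordinates
#'
#' @param x A `pcoa_ord` object.
#' @param ... Unused.
#' @return Tibble with `entity_id` and one column per axis.
#' @method tidy pcoa_ord
#' @export
tidy.pcoa_ord <- function(x, ...) {
  dplyr::bind_cols(tibble(entity_id = x$entity_ids),
                   as_tibble(as.data.frame(x$coordinates)))
}

#' One-row-per-axis eigenvalue summary
#'
#' @inheritParams tidy.pcoa_ord
#' @method glance pcoa_ord
#' @export
glance.pcoa_ord <- function(x, ...) {
  tibble(axis = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
         prop_variance = x$prop_variance)
}

#' Scatter plot of the first two principal coordinates
#'
#' @param object A `pcoa_ord` object.
#' @param colour_by Optional vector (aligned with entities) to colour points.
#' @param ... Unused.
#' @method autoplot pcoa_ord
#' @export
autoplot.pcoa_ord <- function(object, colour_by = NULL, ...) {
  df <- tidy(object)
  if (ncol(object$coordinates) < 2) abort("need at least 2 axes to plot")
  if (!is.null(colour_by)) df$colour_by <- colour_by
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$prop_variance[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$prop_variance[2])) +
    ggplot2::theme_classic()
  if (is.null(colour_by)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour_by)) +
    ggplot2::labs(colour = NULL)
}
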