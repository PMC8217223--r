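#' Microelectrode array geometry
#'
#' Describes the rectangular grid of a penetrating microelectrode array (MEA).
#' The default is the 4-by-8 arrangement with 400 um inter-electrode pitch used
#' to record evoked responses in the nodose ganglion. Channels are numbered
#' 1..n_rows*n_cols in row-major order; only relative geometry matters to the
#' analysis, so the anatomical orientation of the grid is metadata.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param pitch_um Inter-electrode pitch in micrometres (> 0).
#' @return An object of class `mea_geometry` with fields `n_rows`, `n_cols`,
#'   `pitch_um`, `n_channels`, and per-channel `row`/`col` index vectors.
#' @examples
#' g <- mea_geometry()
#' channel_distance(g, 1, 2)   # one pitch apart
#' @export
mea_geometry <- function(n_rows = 4L, n_cols = 8L, pitch_um = 400) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch_um > 0)
  n <- as.integer(n_rows) * as.integer(n_cols)
  ch <- seq_len(n)
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      pitch_um = pitch_um, n_channels = n,
      row = (ch - 1L) %/% as.integer(n_cols) + 1L,
      col = (ch - 1L) %% as.integer(n_cols) + 1L
    ),
    class = "mea_geometry"
  )
}

#' @export
print.mea_geometry <- function(x, ...) {
  cat(sprintf("MEA geometry: %d x %d grid, %g um pitch (%d channels)\n",
              x$n_rows, x$n_cols, x$pitch_um, x$n_channels))
  invisible(x)
}

.check_channels <- function(geom, ch) {
  if (any(ch < 1L | ch > geom$n_channels | ch != round(ch)))
    stop("invalid channel index: must be in 1..", geom$n_channels)
  as.integer(ch)
}

#' Planar positions of MEA channels
#'
#' @param geom An [mea_geometry()].
#' @param channels Channel indices (default all).
#' @return A two-column matrix of (x, y) positions in micrometres, x along
#'   columns and y along rows.
#' @export
channel_position <- function(geom, channels = seq_len(geom$n_channels)) {
  channels <- .check_channels(geom, channels)
  cbind(x = (geom$col[channels] - 1L) * geom$pitch_um,
        y = (geom$row[channels] - 1L) * geom$pitch_um)
}

#' Euclidean distance between two MEA channels
#'
#' @param geom An [mea_geometry()].
#' @param a,b Channel indices.
#' @return Distance in micrometres; symmetric, and zero iff `a == b`.
#' @export
channel_distance <- function(geom, a, b) {
  pa <- channel_position(geom, a)
  pb <- channel_position(geom, b)
  unname(sqrt((pa[, 1] - pb[, 1])^2 + (pa[, 2] - pb[, 2])^2))
}
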