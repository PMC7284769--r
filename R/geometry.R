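#' Square-lattice nanopost array
#'
#' Describes an array of infinitely long parallel cylindrical posts whose
#' axes (along x) pierce a square lattice of spacing \code{S_p} in the (y, z)
#' plane, and derives the confinement descriptors used throughout:
#' the effective post diameter \code{d_p = D_p + w} (geometric diameter plus
#' bead width), the passage width \code{w_p = S_p - d_p} (closest wall-wall
#' gap, the quasi-slit height), the quasi-channel diameter
#' \code{d_c = sqrt(2) S_p - d_p} (gauge of the interstitial volume bounded
#' by four posts), the confinement ratio \code{d_c/w_p}, and the post volume
#' fraction \code{F = pi d_p^2 / (4 S_p^2)}.
#'
#' @param S_p Post-axis separation, units sigma. Must satisfy
#'   \code{S_p >= D_p} (posts must not overlap).
#' @param D_p Geometric post diameter, units sigma.
#' @param w Effective bead width used to build \code{d_p}, units sigma.
#' @return An object of class \code{"post_array"} with fields \code{S_p},
#'   \code{D_p}, \code{d_p}, \code{w_p}, \code{d_c}, \code{ratio}
#'   (= d_c/w_p) and \code{F}.
#' @examples
#' post_array(4.0, 3.0)   # strongly confining: d_c/w_p = 17.569
#' post_array(12, 3.0)
#' @export
post_array <- function(S_p, D_p, w = 0.9) {
  stopifnot(length(S_p) == 1, length(D_p) == 1, w > 0, D_p >= 0)
  if (S_p < D_p) stop("overlapping posts: S_p must be >= D_p")
  d_p <- D_p + w
  structure(list(S_p = S_p, D_p = D_p, d_p = d_p,
                 w_p = S_p - d_p,
                 d_c = sqrt(2) * S_p - d_p,
                 ratio = (sqrt(2) * S_p - d_p) / (S_p - d_p),
                 F = pi * d_p^2 / (4 * S_p^2)),
            class = "post_array")
}

#' @export
print.post_array <- function(x, ...) {
  cat("Square-lattice nanopost array\n")
  cat(sprintf("  S_p = %g, D_p = %g, d_p = %g\n", x$S_p, x$D_p, x$d_p))
  cat(sprintf("  w_p = %.3f (quasi-slit), d_c = %.3f (quasi-channel)\n",
              x$w_p, x$d_c))
  cat(sprintf("  d_c/w_p = %.3f, volume fraction F = %.3f\n", x$ratio, x$F))
  invisible(x)
}

#' Four lattice posts bounding a point's interstitial cell
#'
#' For a point (y, z), returns the coordinates of the four posts at the
#' corners of its cell, i.e. at \code{(floor(y/S_p) + {0,1}) S_p} crossed with
#' \code{(floor(z/S_p) + {0,1}) S_p}. A bead can interact with at most these
#' four posts whenever \code{S_p} exceeds the interaction reach.
#'
#' @param y,z Coordinates in the lattice plane, units sigma.
#' @param array A \code{\link{post_array}}.
#' @return 4 x 2 matrix with columns \code{y}, \code{z}.
#' @export
nearest_posts <- function(y, z, array) {
  iy <- floor(y / array$S_p); iz <- floor(z / array$S_p)
  g <- expand.grid(dy = c(0, 1), dz = c(0, 1))
  m <- cbind(y = (iy + g$dy) * array$S_p, z = (iz + g$dz) * array$S_p)
  m
}

#' Interstitial cell label of a point
#'
#' Cells tile the (y, z) plane with the half-open convention
#' \code{[i S_p, (i+1) S_p)}; a point exactly on a lattice line belongs to the
#' higher-index cell.
#'
#' @inheritParams nearest_posts
#' @return Integer vector \code{c(i, j)} (or a 2-column matrix for vector
#'   input).
#' @export
cell_index <- function(y, z, array) {
  i <- floor(y / array$S_p); j <- floor(z / array$S_p)
  if (length(y) == 1) c(i = i, j = j) else cbind(i = i, j = j)
}

#' Energy barrier at the passage aperture
#'
#' Potential energy (in k_B T) of a single bead at the midpoint between two
#' adjacent post surfaces -- axis distance \code{S_p/2} from each flanking
#' post -- summed over every lattice post within the interaction cutoff.
#' This is the barrier a monomer must cross to translocate between
#' neighbouring interstitial volumes; it decreases steeply with \code{S_p}
#' and vanishes once the midpoint clears the cutoff of both posts.
#'
#' @param array A \code{\link{post_array}}.
#' @param ff A \code{\link{force_field}}.
#' @return Barrier height, units k_B T.
#' @examples
#' passage_barrier(post_array(3.9, 3.0))   # ~ 1.15e5: impassable
#' passage_barrier(post_array(4.8, 3.0))   # ~ 15.3:   rarely passable
#' @export
passage_barrier <- function(array, ff = force_field()) {
  if (array$S_p / 2 <= array$D_p / 2)
    stop("bead inside post: midpoint lies within the post core")
  # bead at (S_p/2, 0); sum shifted WCA over a post patch large enough to
  # cover the cutoff
  rc <- array$D_p / 2 + 2^(1 / 6) * ff$sigma
  k <- ceiling(rc / array$S_p) + 1
  g <- expand.grid(m = -k:k, n = -k:k)
  d <- sqrt((array$S_p / 2 - g$m * array$S_p)^2 + (g$n * array$S_p)^2)
  within <- d - array$D_p / 2 < 2^(1 / 6) * ff$sigma
  if (!any(within)) return(0)
  sum(post_energy(d[within], array$D_p, ff))
}

#' Smallest post separation allowing chain translocation
#'
#' Threshold \code{S_p} at which the passage width equals the bead width,
#' i.e. \code{d_p + w = D_p + 2w}; beyond it a chain fragment can slip
#' between adjacent posts into the neighbouring interstitial volume.
#'
#' @param D_p Geometric post diameter, units sigma.
#' @param w Bead width, units sigma.
#' @return Threshold separation, units sigma.
#' @export
min_translocation_separation <- function(D_p, w = 0.9) {
  stopifnot(D_p >= 0, w > 0)
  D_p + 2 * w
}

#' Tabulate geometry descriptors for a series of arrays
#'
#' @param arrays A list of \code{\link{post_array}} objects.
#' @param file Optional path; when given the table is written as CSV.
#' @return A data.frame with columns \code{S_p}, \code{D_p}, \code{d_p},
#'   \code{w_p}, \code{d_c}, \code{ratio} (d_c/w_p) and \code{F}.
#' @export
geometry_table <- function(arrays, file = NULL) {
  df <- do.call(rbind, lapply(arrays, function(a)
    data.frame(S_p = a$S_p, D_p = a$D_p, d_p = a$d_p, w_p = a$w_p,
               d_c = a$d_c, ratio = a$ratio, F = a$F)))
  rownames(df) <- NULL
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
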