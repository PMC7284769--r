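#' Straight-rod fixture
#'
#' Collinear beads at fixed spacing along a coordinate axis; the span along
#' that axis is exactly \code{(N - 1) l} and the structure factor shows the
#' rod-like -1 slope between \code{2 pi/((N-1) l)} and \code{2 pi/l}.
#'
#' @param N Bead count (>= 2).
#' @param l Bond length, units sigma, in (0, R_o).
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}.
#' @param origin Length-3 offset added to every bead.
#' @param ff A \code{\link{force_field}} (validates l against R_o).
#' @return A \code{\link{chain_state}}.
#' @export
make_rod <- function(N, l = 0.97, axis = c("x", "y", "z"),
                     origin = c(0, 0, 0), ff = force_field()) {
  axis <- match.arg(axis)
  stopifnot(N >= 2, l > 0, l < ff$r_max)
  pos <- matrix(rep(origin, each = N), N, 3)
  pos[, match(axis, c("x", "y", "z"))] <-
    pos[, match(axis, c("x", "y", "z"))] + (seq_len(N) - 1) * l
  chain_state(pos, ff)
}

#' Helical fixture
#'
#' Beads on a helix of given radius and pitch around the x axis, with equal
#' arc spacing close to \code{l}. Exercises gyration components and S(q) on
#' a curved but deterministic backbone.
#'
#' @param N Bead count.
#' @param l Bond spacing along the helix (chord), units sigma.
#' @param radius Helix radius, units sigma.
#' @param pitch Axial rise per turn, units sigma.
#' @param ff A \code{\link{force_field}}.
#' @return A \code{\link{chain_state}}.
#' @export
make_helix <- function(N, l = 0.97, radius = 3, pitch = 2,
                       ff = force_field()) {
  stopifnot(N >= 2, radius > 0, pitch >= 0)
  # choose the turn angle per bead so the chord length equals l
  rise <- pitch / (2 * pi)
  f <- function(th) sqrt(2 * radius^2 * (1 - cos(th)) + (rise * th)^2) - l
  th <- stats::uniroot(f, c(1e-8, pi), tol = 1e-12)$root
  k <- seq_len(N) - 1
  pos <- cbind(x = rise * th * k,
               y = radius * cos(th * k),
               z = radius * sin(th * k))
  chain_state(pos, ff)
}

#' U-turn fixture: two parallel strands around one post
#'
#' Two antiparallel x-aligned strands, one at each of two adjacent cell
#' centres, joined by a semicircular hairpin threading the shared passage
#' aperture. By construction the occupation number is exactly 2 and the
#' strand separation is exactly \code{S_p}, the geometry responsible for the
#' inter-strand correlation hump in S(q) near \code{q = 2 pi / S_p}.
#'
#' @param array A \code{\link{post_array}}.
#' @param cells 2 x 2 integer matrix (rows: the two adjacent cell indices
#'   (i, j)); default cells (0,0) and (1,0).
#' @param N Total bead count (even).
#' @param l Bond spacing, units sigma.
#' @param ff A \code{\link{force_field}}.
#' @return A \code{\link{chain_state}} with attributes \code{occupation}
#'   (= 2) and \code{strand_separation} (= S_p).
#' @export
make_u_turn <- function(array, cells = rbind(c(0, 0), c(1, 0)), N = 40,
                        l = 0.97, ff = force_field()) {
  cells <- as.matrix(cells)
  if (!all(dim(cells) == c(2, 2)) || sum(abs(cells[1, ] - cells[2, ])) != 1)
    stop("cells must be two adjacent lattice cells")
  if (N %% 2 != 0) stop("N must be even")
  Sp <- array$S_p
  # cell centres; the two strands run along x
  cA <- (cells[1, ] + 0.5) * Sp
  cB <- (cells[2, ] + 0.5) * Sp
  R <- Sp / 2
  n_arc <- max(1, ceiling(pi * R / l) - 1)
  if ((N - n_arc) %% 2 != 0) n_arc <- n_arc + 1
  n_s <- (N - n_arc) / 2
  if (n_s < 1) stop("N too small for this post separation")
  x_t <- (n_s - 1) * l
  # strand A (towards +x), arc, strand B (back towards -x)
  A <- cbind((seq_len(n_s) - 1) * l, cA[1], cA[2])
  phi <- seq_len(n_arc) * pi / (n_arc + 1)
  ctr <- (cA + cB) / 2     # aperture midpoint in (y, z)
  dirv <- (cB - cA) / sqrt(sum((cB - cA)^2))
  arc_lat <- ctr[1] - dirv[1] * R * cos(phi)  # y of arc beads
  arc_lat2 <- ctr[2] - dirv[2] * R * cos(phi) # z of arc beads
  ARC <- cbind(x_t + R * sin(phi), arc_lat, arc_lat2)
  B <- cbind(rev((seq_len(n_s) - 1) * l), cB[1], cB[2])
  st <- chain_state(rbind(A, ARC, B), ff)
  attr(st, "occupation") <- 2L
  attr(st, "strand_separation") <- Sp
  st
}

#' Random-cell point-cloud fixture
#'
#' Scatters beads uniformly over a stated set of interstitial cells to test
#' occupation counting. Deliberately non-physical: bead order is arbitrary
#' and bond-length invariants are not enforced.
#'
#' @param array A \code{\link{post_array}}.
#' @param cells k x 2 integer matrix of cell indices to populate (each cell
#'   receives at least one bead).
#' @param N Total bead count (>= number of cells).
#' @param seed RNG seed.
#' @return A \code{\link{chain_state}} (unvalidated) with attribute
#'   \code{occupation} set to the number of distinct cells.
#' @export
make_lattice_random <- function(array, cells, N = 50, seed = 1) {
  cells <- unique(as.matrix(cells))
  k <- nrow(cells)
  stopifnot(N >= k)
  set.seed(seed)
  assign_cell <- c(seq_len(k), sample(seq_len(k), N - k, replace = TRUE))
  u <- matrix(stats::runif(2 * N), N, 2)
  yz <- (cells[assign_cell, , drop = FALSE] + u) * array$S_p
  st <- chain_state(cbind(stats::runif(N, 0, 5), yz), validate = FALSE)
  attr(st, "occupation") <- k
  st
}

#' Synthetic structure-factor curve with a known hump
#'
#' A rod-like \code{q^-1} background multiplied by \code{1 + amplitude *
#' Gaussian(q; bump_q, bump_width)}: ground truth for
#' \code{\link{hump_detect}}, which must return \code{bump_q}.
#'
#' @param bump_q Hump position (1/sigma); must lie inside the grid.
#' @param bump_width Gaussian width of the hump (1/sigma).
#' @param amplitude Relative hump height (0 = no hump).
#' @param q Wavevector grid (default 300 log-spaced points on [0.05, 6.3]).
#' @return An \code{"sq_curve"}.
#' @export
make_synthetic_sq <- function(bump_q, bump_width = 0.08, amplitude = 0.2,
                              q = exp(seq(log(0.05), log(6.3), length.out = 300))) {
  if (bump_q < min(q) || bump_q > max(q)) stop("bump_q outside the grid")
  S <- (min(q) / q) * (1 + amplitude * exp(-(q - bump_q)^2 / (2 * bump_width^2)))
  structure(data.frame(q = q, S = pmin(S, 1)),
            class = c("sq_curve", "data.frame"), n_frames = 0L, N = NA_integer_)
}
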