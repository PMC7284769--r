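#' Force-field parameters for the bead-spring chain
#'
#' Bundles the interaction constants of the coarse-grained touching-bead
#' model in reduced units: purely repulsive (WCA) excluded volume between all
#' bead pairs (bonded neighbours included), FENE bond springs, and a discrete
#' worm-like-chain bending term. With the defaults (\code{epsilon = sigma = 1},
#' \code{kappa = 30}, \code{r_max = 1.5}) the equilibrium bond length is
#' approximately \code{0.97 sigma} and the effective bead width approximately
#' \code{0.9 sigma}, so bond length and bead width nearly coincide.
#'
#' @param epsilon Lennard-Jones energy unit (sets \code{k_B T = epsilon} at
#'   the reference temperature \code{T = 1}).
#' @param sigma Lennard-Jones length unit (bead diameter).
#' @param kappa FENE spring constant, units \code{epsilon/sigma^2}.
#' @param r_max FENE maximal bond extension \code{R_o}, units \code{sigma}.
#' @param stiffness Dimensionless bending parameter \code{b = B/(l k_B T)};
#'   0 gives a fully flexible chain, 20 maps a DNA-like chain whose
#'   persistence length is about 20 bond lengths.
#' @param bead_width Effective bead width \code{w}, a model constant
#'   (enters the effective post diameter and the confinement theory), not a
#'   recomputed quantity.
#' @param mean_bond Effective mean bond length \code{<l>}, a model constant.
#' @return An object of class \code{"force_field"}.
#' @examples
#' ff <- force_field(stiffness = 20)
#' wca_energy(1, ff)          # epsilon at r = sigma
#' fene_energy(0.97, ff)
#' @export
force_field <- function(epsilon = 1, sigma = 1, kappa = 30, r_max = 1.5,
                        stiffness = 0, bead_width = 0.9, mean_bond = 0.97) {
  stopifnot(epsilon > 0, sigma > 0, kappa > 0, r_max > sigma, stiffness >= 0)
  if (bead_width <= 0 || bead_width >= sigma * 2^(1 / 6))
    stop("bead_width must lie in (0, sigma * 2^(1/6))")
  if (mean_bond <= bead_width || mean_bond >= r_max)
    stop("mean_bond must lie in (bead_width, r_max)")
  structure(list(epsilon = epsilon, sigma = sigma, kappa = kappa,
                 r_max = r_max, stiffness = stiffness,
                 bead_width = bead_width, mean_bond = mean_bond),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat("Bead-spring force field (reduced units)\n")
  cat(sprintf("  WCA: epsilon = %g, sigma = %g (cutoff 2^(1/6) sigma)\n",
              x$epsilon, x$sigma))
  cat(sprintf("  FENE: kappa = %g, R_o = %g\n", x$kappa, x$r_max))
  cat(sprintf("  bending: b = %g (%s)\n", x$stiffness,
              if (x$stiffness == 0) "flexible" else "semiflexible"))
  cat(sprintf("  model constants: w = %g, <l> = %g\n", x$bead_width, x$mean_bond))
  invisible(x)
}

#' WCA pair energy
#'
#' Purely repulsive Weeks-Chandler-Andersen interaction between two beads:
#' \code{4 eps [(sigma/r)^12 - (sigma/r)^6] + eps} for \code{r < 2^(1/6) sigma},
#' exactly zero beyond the cutoff.
#'
#' @param r Bead-bead distance(s), units sigma. Must be positive.
#' @param ff A \code{\link{force_field}}.
#' @return Energy in units of epsilon (vectorised over \code{r}).
#' @export
wca_energy <- function(r, ff = force_field()) {
  if (any(r <= 0)) stop("r must be positive")
  rc <- 2^(1 / 6) * ff$sigma
  s6 <- (ff$sigma / r)^6
  ifelse(r < rc, 4 * ff$epsilon * (s6^2 - s6) + ff$epsilon, 0)
}

#' Monomer-post interaction energy
#'
#' The WCA repulsion applied to the distance between a bead and the surface
#' of a cylindrical post of geometric diameter \code{D_p}: the pair formula is
#' evaluated at the shifted distance \code{r_axis - D_p/2}, same cutoff.
#'
#' @param r_axis Distance(s) from the bead centre to the post axis.
#' @param D_p Geometric post diameter, units sigma.
#' @param ff A \code{\link{force_field}}.
#' @return Energy in units of epsilon.
#' @export
post_energy <- function(r_axis, D_p, ff = force_field()) {
  s <- r_axis - D_p / 2
  if (any(s <= 0))
    stop("bead inside post core: r_axis must exceed D_p/2 (divergent overlap)")
  wca_energy(s, ff)
}

#' FENE bond energy
#'
#' Finitely extensible nonlinear elastic spring,
#' \code{-(kappa/2) R_o^2 log(1 - (l/R_o)^2)}; zero at \code{l = 0} and
#' divergent as \code{l} approaches \code{R_o}.
#'
#' @param l Bond length(s), units sigma, in \code{[0, R_o)}.
#' @param ff A \code{\link{force_field}}.
#' @return Energy in units of epsilon.
#' @export
fene_energy <- function(l, ff = force_field()) {
  if (any(l < 0)) stop("bond length must be non-negative")
  if (any(l >= ff$r_max))
    stop("bond overstretch: bond length reached R_o (integrator blow-up)")
  -0.5 * ff$kappa * ff$r_max^2 * log(1 - (l / ff$r_max)^2)
}

#' Bending energy of a valence angle
#'
#' Discrete worm-like-chain bending term \code{b k_B T (1 + cos theta)} where
#' \code{theta} is the valence angle between consecutive bonds. The convention
#' is fixed so a straight chain (theta = pi, consecutive bond vectors
#' parallel) costs zero and a full fold-back costs \code{2 b k_B T}.
#'
#' @param theta Valence angle(s) in radians, in \code{[0, pi]}.
#' @param ff A \code{\link{force_field}}; uses \code{ff$stiffness}.
#' @return Energy in units of k_B T (= epsilon at T = 1).
#' @export
bending_energy <- function(theta, ff = force_field()) {
  ct <- pmin(1, pmax(-1, cos(theta)))
  ff$stiffness * (1 + ct)
}

#' Chain conformation container
#'
#' A chain state is an N x 3 matrix of bead coordinates (columns x, y, z) in
#' sigma units; the x axis is collinear with the post axes. Validation checks
#' finiteness and that no bond reaches the FENE divergence \code{R_o}.
#'
#' @param positions Numeric N x 3 matrix (N >= 2).
#' @param ff A \code{\link{force_field}} supplying \code{R_o}.
#' @param validate Set \code{FALSE} to skip the bond-length check (used by
#'   non-physical point-cloud fixtures).
#' @return The matrix with class \code{"chain_state"}.
#' @export
chain_state <- function(positions, ff = force_field(), validate = TRUE) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || nrow(positions) < 2)
    stop("positions must be an N x 3 matrix with N >= 2")
  if (!all(is.finite(positions))) stop("non-finite coordinates")
  if (validate) {
    bl <- bond_lengths(positions)
    if (any(bl >= ff$r_max))
      stop(sprintf("bond overstretch: max bond length %.4f >= R_o = %g",
                   max(bl), ff$r_max))
  }
  colnames(positions) <- c("x", "y", "z")
  class(positions) <- c("chain_state", class(positions))
  positions
}

# consecutive bead distances
bond_lengths <- function(pos) {
  d <- diff(unclass(pos)[, 1:3, drop = FALSE])
  sqrt(rowSums(d^2))
}

#' Total energy of a chain, by term
#'
#' Sums all pairwise WCA repulsions (bonded neighbours included), FENE bonds,
#' bending angles, and -- when a post array is given -- the monomer-post
#' repulsions over every lattice post within the interaction cutoff. The
#' lattice is treated as infinite: posts are looked up around each bead, so
#' no periodic box is needed.
#'
#' @param state A \code{\link{chain_state}} (or plain N x 3 matrix).
#' @param array A \code{\link{post_array}}, or NULL for a free chain.
#' @param ff A \code{\link{force_field}}.
#' @return A list with components \code{wca}, \code{fene}, \code{bend},
#'   \code{post} and \code{total} (epsilon units).
#' @export
chain_energy <- function(state, array = NULL, ff = force_field()) {
  pos <- unclass(state)[, 1:3, drop = FALSE]
  use <- !is.null(array)
  .chain_energy_cpp(pos, ff$epsilon, ff$sigma, ff$kappa, ff$r_max,
                    ff$stiffness, use,
                    if (use) array$S_p else 1, if (use) array$D_p else 0)
}

#' Forces on every bead
#'
#' Negative gradient of \code{\link{chain_energy}} with respect to the bead
#' coordinates, evaluated analytically.
#'
#' @inheritParams chain_energy
#' @return N x 3 matrix of force components (epsilon/sigma units).
#' @export
chain_forces <- function(state, array = NULL, ff = force_field()) {
  pos <- unclass(state)[, 1:3, drop = FALSE]
  use <- !is.null(array)
  f <- .chain_forces_cpp(pos, ff$epsilon, ff$sigma, ff$kappa, ff$r_max,
                         ff$stiffness, use,
                         if (use) array$S_p else 1, if (use) array$D_p else 0)
  colnames(f) <- c("x", "y", "z")
  f
}
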