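#' Simulation configuration
#'
#' Collects the parameters of an NVT run in reduced time units
#' (tau = sigma sqrt(m/epsilon), unit bead mass).
#'
#' @param dt Integration time step, units tau.
#' @param thermostat One of \code{"nose-hoover"} (default, matches the
#'   reference protocol), \code{"langevin"} (identical stationary ensemble,
#'   better sampling for strongly confined starts) or \code{"none"} (NVE).
#' @param thermostat_tau Thermostat relaxation time (Nose-Hoover coupling
#'   time, or inverse Langevin friction), units tau.
#' @param temperature Target temperature in epsilon/k_B.
#' @param n_equil Equilibration steps, discarded.
#' @param n_prod Production steps.
#' @param sample_stride Steps between stored frames.
#' @param seed RNG seed, recorded in the trajectory provenance.
#' @param init_orientation \code{"parallel"} (chain along the post axes) or
#'   \code{"perpendicular"} (chain across the lattice).
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(dt = 0.005, thermostat = c("nose-hoover", "langevin", "none"),
                       thermostat_tau = 0.1, temperature = 1,
                       n_equil = 50000L, n_prod = 200000L,
                       sample_stride = 10000L, seed = 1L,
                       init_orientation = c("parallel", "perpendicular")) {
  thermostat <- match.arg(thermostat)
  init_orientation <- match.arg(init_orientation)
  stopifnot(dt > 0, thermostat_tau > dt, temperature > 0,
            n_equil >= 0, n_prod >= 1, sample_stride >= 1)
  structure(list(dt = dt, thermostat = thermostat,
                 thermostat_tau = thermostat_tau, temperature = temperature,
                 n_equil = as.double(n_equil), n_prod = as.double(n_prod),
                 sample_stride = as.double(sample_stride),
                 seed = as.integer(seed), init_orientation = init_orientation),
            class = "sim_config")
}

#' Straight initial conformation
#'
#' Beads collinear at spacing \code{<l>}. With \code{orientation =
#' "parallel"} the chain lies along x at the centre of cell (0, 0); with
#' \code{"perpendicular"} it lies along y at \code{z = S_p/2}, \code{x = 0},
#' threading the passage apertures. A perpendicular start close to the posts
#' is relaxed by a capped-force (soft push-off) descent before dynamics.
#'
#' @param N Bead count (>= 2).
#' @param array A \code{\link{post_array}} or NULL for a free chain.
#' @param orientation \code{"parallel"} or \code{"perpendicular"}.
#' @param ff A \code{\link{force_field}}.
#' @return A \code{\link{chain_state}}.
#' @export
init_conformation <- function(N, array = NULL,
                              orientation = c("parallel", "perpendicular"),
                              ff = force_field()) {
  orientation <- match.arg(orientation)
  stopifnot(N >= 2)
  l <- ff$mean_bond
  if (is.null(array) || orientation == "parallel") {
    c0 <- if (is.null(array)) 0 else array$S_p / 2
    pos <- cbind(x = (seq_len(N) - 1) * l, y = rep(c0, N), z = rep(c0, N))
  } else {
    pos <- cbind(x = rep(0, N), y = (seq_len(N) - 1) * l,
                 z = rep(array$S_p / 2, N))
  }
  st <- chain_state(pos, ff)
  if (!is.null(array) && orientation == "perpendicular")
    st <- soft_pushoff(st, array, ff)
  st
}

# Capped-displacement steepest descent: relieves large (finite) post overlaps
# of a straight perpendicular start without moving any bead more than
# max_step per iteration.
soft_pushoff <- function(state, array, ff, max_step = 0.05, n_iter = 500,
                         target = 2) {
  pos <- unclass(state)[, 1:3, drop = FALSE]
  n <- nrow(pos)
  for (it in seq_len(n_iter)) {
    e <- chain_energy(chain_state(pos, ff), array, ff)
    if (e$post / n < target) break
    f <- chain_forces(chain_state(pos, ff), array, ff)
    nf <- sqrt(rowSums(f^2))
    scal <- pmin(1, max_step / pmax(nf, 1e-12))
    pos <- pos + f * scal * max_step
  }
  chain_state(pos, ff)
}

# Maxwell-Boltzmann velocities: zero total momentum, kinetic temperature
# rescaled exactly to the target (dof = 3N - 3).
mb_velocities <- function(N, temperature) {
  v <- matrix(stats::rnorm(3 * N), N, 3)
  v <- sweep(v, 2, colMeans(v))
  ke <- 0.5 * sum(v^2)
  v * sqrt((3 * N - 3) * temperature / (2 * ke))
}

new_trajectory <- function(frames, time, kind, ff, array, seed, extra = list()) {
  structure(c(list(frames = frames, time = time, kind = kind, ff = ff,
                   array = array, seed = seed), extra),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- if (length(x$frames)) nrow(x$frames[[1]]) else 0
  cat(sprintf("Trajectory (%s): %d frames, N = %d beads, b = %g, %s\n",
              x$kind, length(x$frames), n, x$ff$stiffness,
              if (is.null(x$array)) "free chain"
              else sprintf("post array S_p = %g, D_p = %g",
                           x$array$S_p, x$array$D_p)))
  cat(sprintf("  seed = %s\n", as.character(x$seed)))
  invisible(x)
}

#' @export
summary.trajectory <- function(object, ...) {
  g <- gyration(object)
  sp <- axial_span(object)
  cat(sprintf("frames: %d   R_g = %.3f   span R_s = %.3f +/- %.3f\n",
              length(object$frames), g$R_g, sp$mean, sp$se))
  if (!is.null(object$array)) {
    occ <- occupation_number(object, object$array)
    cat(sprintf("occupation n_p = %.3f +/- %.3f\n", occ$mean, occ$se))
  }
  invisible(object)
}

#' Thermostatted dynamics of a (confined) chain
#'
#' Integrates the chain in the NVT ensemble from a starting conformation and
#' collects frames every \code{sample_stride} steps after discarding
#' \code{n_equil} equilibration steps. The default thermostat is a
#' single-variable Nose-Hoover coupling with relaxation time 0.1 tau on a
#' velocity-Verlet core (position updates identical to leap-frog); a
#' Langevin (BAOAB) thermostat with the same stationary distribution is
#' available for sampling-heavy runs, and \code{"none"} gives microcanonical
#' integration for energy-conservation checks. Runs are deterministic given
#' \code{config$seed}. If a bond reaches the FENE divergence or a bead
#' penetrates a post core the run aborts with a diagnostic error carrying the
#' failing step index.
#'
#' @param state Starting \code{\link{chain_state}} (see
#'   \code{\link{init_conformation}}).
#' @param array A \code{\link{post_array}} or NULL for a free chain.
#' @param ff A \code{\link{force_field}}.
#' @param config A \code{\link{sim_config}}.
#' @return A \code{"trajectory"} object; component \code{stats} holds the
#'   per-frame kinetic and potential energies and the kinetic temperature.
#' @export
run_dynamics <- function(state, array = NULL, ff = force_field(),
                         config = sim_config()) {
  pos <- unclass(state)[, 1:3, drop = FALSE]
  n <- nrow(pos)
  set.seed(config$seed)
  vel <- mb_velocities(n, config$temperature)
  th <- match(config$thermostat, c("none", "nose-hoover", "langevin")) - 1L
  dof_mode <- if (config$thermostat == "langevin") 1L else 0L
  use <- !is.null(array)
  Sp <- if (use) array$S_p else 1; Dp <- if (use) array$D_p else 0

  if (config$n_equil > 0) {
    eq <- .md_run_cpp(pos, vel, ff$epsilon, ff$sigma, ff$kappa, ff$r_max,
                      ff$stiffness, use, Sp, Dp, config$dt, config$n_equil,
                      0, th, config$temperature, config$thermostat_tau,
                      dof_mode)
    if (eq$fail_step >= 0)
      stop_blowup(eq, phase = "equilibration", config)
    pos <- eq$final; vel <- eq$vel_final
  }
  run <- .md_run_cpp(pos, vel, ff$epsilon, ff$sigma, ff$kappa, ff$r_max,
                     ff$stiffness, use, Sp, Dp, config$dt, config$n_prod,
                     config$sample_stride, th, config$temperature,
                     config$thermostat_tau, dof_mode)
  if (run$fail_step >= 0) stop_blowup(run, phase = "production", config)
  dof <- run$dof
  stats <- data.frame(time = run$time, ekin = run$ekin, epot = run$epot,
                      temperature = 2 * run$ekin / dof)
  new_trajectory(run$frames, run$time, "md", ff, array, config$seed,
                 list(config = config, stats = stats, final = run$final,
                      vel_final = run$vel_final))
}

stop_blowup <- function(run, phase, config) {
  msg <- sprintf(
    "integration aborted during %s at step %d (dt = %g): overstretched bond or post overlap; last sampled frame index %d",
    phase, as.integer(run$fail_step), config$dt, length(run$frames))
  cond <- structure(class = c("nanopost_blowup", "error", "condition"),
                    list(message = msg, call = sys.call(-1),
                         step = run$fail_step, frames = run$frames))
  stop(cond)
}

#' Equilibrium Monte Carlo sampling of a free chain
#'
#' Markov-chain sampler whose stationary distribution is the Boltzmann
#' distribution of the same Hamiltonian used by the dynamics (WCA + FENE +
#' bending): a mixture of single-bead displacements (relaxes bond lengths),
#' crankshaft rotations and pivot moves (decorrelates global shape), with
#' Metropolis acceptance. For stiff chains the pivot/crankshaft rotation
#' amplitude is reduced to about \code{2.5/sqrt(b)} so that the bending
#' penalty at the pivot joint does not suppress acceptance; amplitudes only
#' affect mixing speed, never the sampled ensemble. Intended as the
#' equilibrium cross-check and the cheap route to free-chain averages.
#'
#' @param N Bead count.
#' @param ff A \code{\link{force_field}}.
#' @param n_samples Frames to collect.
#' @param sample_stride Elementary moves between collected frames
#'   (default \code{5 N}).
#' @param n_equil Equilibration moves discarded before sampling
#'   (default \code{100 N}, from a straight-rod start).
#' @param temperature Temperature in epsilon/k_B.
#' @param seed RNG seed (uses R's RNG; runs are reproducible).
#' @param p_pivot,p_crank Move-type probabilities (remainder: displacement).
#' @param disp_delta Displacement half-width, units sigma.
#' @return A \code{"trajectory"} object; \code{stats} holds per-move-type
#'   acceptance rates.
#' @examples
#' \donttest{
#' tr <- pivot_sample(50, force_field(), n_samples = 200, seed = 7)
#' mean(sapply(tr$frames, function(f) mean(sqrt(rowSums(diff(f)^2)))))
#' }
#' @export
pivot_sample <- function(N, ff = force_field(), n_samples = 1000,
                         sample_stride = NULL, n_equil = NULL,
                         temperature = 1, seed = NULL,
                         p_pivot = 0.2, p_crank = 0.3, disp_delta = 0.12) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sample_stride)) sample_stride <- 5 * N
  if (is.null(n_equil)) n_equil <- 100 * N
  b <- ff$stiffness
  amp <- if (b > 0) min(pi, 2.5 / sqrt(b)) else pi
  pos <- unclass(init_conformation(N, NULL, "parallel", ff))[, 1:3]
  if (n_equil > 0) {
    eq <- .mc_run_cpp(pos, ff$epsilon, ff$sigma, ff$kappa, ff$r_max, b,
                      temperature, n_equil, p_pivot, p_crank, disp_delta,
                      amp, amp, 0)
    pos <- eq$final
  }
  run <- .mc_run_cpp(pos, ff$epsilon, ff$sigma, ff$kappa, ff$r_max, b,
                     temperature, n_samples * sample_stride, p_pivot, p_crank,
                     disp_delta, amp, amp, sample_stride)
  acc <- run$accepted / pmax(run$attempted, 1)
  new_trajectory(run$frames, seq_along(run$frames) * sample_stride, "mc", ff,
                 NULL, if (is.null(seed)) NA_integer_ else seed,
                 list(stats = list(acceptance = acc,
                                   attempted = run$attempted),
                      final = run$final))
}
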