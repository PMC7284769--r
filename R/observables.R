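#' Block-averaged standard error
#'
#' Standard error of the mean of a correlated series, from block averaging
#' with the block length chosen from the integrated autocorrelation time
#' (5 tau_int, at least 5 points per block).
#'
#' @param x Numeric series.
#' @param block_len Optional fixed block length.
#' @return Standard error estimate.
#' @export
block_se <- function(x, block_len = NULL) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(0)
  if (is.null(block_len)) {
    a <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    pos <- which(a <= 0)
    upto <- if (length(pos)) pos[1] - 1 else length(a)
    tau <- 0.5 + sum(a[seq_len(upto)])
    block_len <- max(5, ceiling(5 * tau))
  }
  nb <- floor(n / block_len)
  if (nb < 2) return(stats::sd(x) / sqrt(n))  # fall back: series too short
  bm <- colMeans(matrix(x[seq_len(nb * block_len)], block_len, nb))
  stats::sd(bm) / sqrt(nb)
}

traj_frames <- function(traj) {
  if (inherits(traj, "trajectory")) traj$frames
  else if (is.list(traj) && !is.null(traj$frames)) traj$frames
  else if (is.matrix(traj)) list(traj)
  else if (is.list(traj)) traj
  else stop("expected a trajectory, a list of frames, or a single frame")
}

#' Axial span of the chain
#'
#' Mean extension along the post axes, \code{R_s = <max(x) - min(x)>},
#' averaged over frames. For a chain stretched along x this approaches the
#' end-to-end distance.
#'
#' @param traj A trajectory, list of frames, or single N x 3 conformation.
#' @return List with \code{mean}, \code{se} (block-averaged) and the
#'   per-frame \code{values}.
#' @export
axial_span <- function(traj) {
  fr <- traj_frames(traj)
  if (!length(fr)) stop("empty trajectory")
  v <- vapply(fr, function(f) max(f[, 1]) - min(f[, 1]), 0)
  list(mean = mean(v), se = block_se(v), values = v)
}

#' Occupation number
#'
#' Number of distinct interstitial volumes containing at least one bead
#' centre, per frame, averaged over frames. Cells are the half-open lattice
#' tiles of \code{\link{cell_index}}; a bead inside a passage aperture is
#' assigned by the same tiling.
#'
#' @param traj A trajectory or list of frames.
#' @param array A \code{\link{post_array}}.
#' @return List with \code{mean}, \code{se} and per-frame \code{values}.
#' @export
occupation_number <- function(traj, array) {
  fr <- traj_frames(traj)
  if (!length(fr)) stop("empty trajectory")
  v <- vapply(fr, function(f) {
    i <- floor(f[, 2] / array$S_p); j <- floor(f[, 3] / array$S_p)
    nrow(unique(cbind(i, j)))
  }, 0)
  list(mean = mean(v), se = block_se(v), values = v)
}

#' Radius of gyration and its axial/lateral components
#'
#' Root-mean-square bead displacement from the per-frame centroid,
#' \code{R_g = sqrt(<R_g^2>)}, with the axial (x) component and the two
#' lateral (y, z) components; \code{R_g^2 = axial^2 + lateral_y^2 +
#' lateral_z^2} exactly.
#'
#' @param traj A trajectory or list of frames.
#' @return List with \code{R_g}, \code{axial}, \code{lateral_y},
#'   \code{lateral_z}, \code{se} (block SE of sqrt(per-frame R_g^2)) and the
#'   per-frame \code{values} of R_g^2.
#' @export
gyration <- function(traj) {
  fr <- traj_frames(traj)
  if (!length(fr)) stop("empty trajectory")
  comp <- t(vapply(fr, function(f) {
    c2 <- sweep(f[, 1:3, drop = FALSE], 2, colMeans(f[, 1:3, drop = FALSE]))
    colMeans(c2^2)
  }, numeric(3)))
  rg2 <- rowSums(comp)
  list(R_g = sqrt(mean(rg2)),
       axial = sqrt(mean(comp[, 1])),
       lateral_y = sqrt(mean(comp[, 2])),
       lateral_z = sqrt(mean(comp[, 3])),
       se = block_se(sqrt(rg2)),
       values = rg2)
}

#' Bond-orientation correlation and persistence length
#'
#' Average scalar product of bond unit vectors \code{<u_i . u_j>} as a
#' function of contour separation \code{s = |i - j|}, with the persistence
#' length \code{P} fitted from the initial exponential decay
#' \code{<cos theta> = exp(-l s / P)}. The fit window takes separations with
#' positive correlation at least \code{exp(-2)}, capped at \code{3 b} bonds,
#' and is refit once with the window capped at \code{2 P / l} after the first
#' estimate; the regression of \code{log <cos>} on \code{s} is through the
#' origin, as the model prescribes \code{<cos> = 1} at \code{s = 0}.
#'
#' @param traj A trajectory or list of frames (chains of at least 3 beads).
#' @param s_max Largest separation tabulated (default \code{N - 2}).
#' @return List with \code{correlation} (data.frame \code{s}, \code{mean_cos}),
#'   \code{P} (NA when no stable fit window exists, e.g. fully flexible
#'   chains), \code{fit_window} and \code{mean_bond}.
#' @export
bond_correlation <- function(traj, s_max = NULL) {
  fr <- traj_frames(traj)
  if (!length(fr)) stop("empty trajectory")
  n <- nrow(fr[[1]])
  if (n < 3) stop("need at least 3 beads for bond correlations")
  nb <- n - 1
  if (is.null(s_max)) s_max <- nb - 1
  s_max <- min(s_max, nb - 1)
  acc <- numeric(s_max); cnt <- numeric(s_max); lbar <- 0
  for (f in fr) {
    u <- diff(f[, 1:3, drop = FALSE])
    ln <- sqrt(rowSums(u^2))
    lbar <- lbar + mean(ln)
    u <- u / ln
    for (s in seq_len(s_max)) {
      acc[s] <- acc[s] + sum(u[1:(nb - s), , drop = FALSE] *
                               u[(1 + s):nb, , drop = FALSE])
      cnt[s] <- cnt[s] + (nb - s)
    }
  }
  lbar <- lbar / length(fr)
  cs <- acc / cnt
  corr <- data.frame(s = seq_len(s_max), mean_cos = cs)

  # fit window: contiguous positive decay down to exp(-2), optional 3b cap
  fit_P <- function(cap) {
    ok <- cs > 0
    last <- which(!ok)[1]
    upto <- if (is.na(last)) s_max else last - 1
    w <- which(cs[seq_len(upto)] >= exp(-2))
    if (!length(w)) return(list(P = NA_real_, smax = NA_integer_))
    smax <- min(max(w), cap)
    if (smax < 2) return(list(P = NA_real_, smax = NA_integer_))
    s <- seq_len(smax); y <- log(cs[s])
    slope <- sum(s * y) / sum(s^2)      # through the origin
    list(P = -lbar / slope, smax = smax)
  }
  b_ff <- if (inherits(traj, "trajectory")) traj$ff$stiffness else NA
  cap <- if (is.finite(b_ff) && b_ff > 0) ceiling(3 * b_ff) else s_max
  f1 <- fit_P(cap)
  if (is.finite(f1$P) && f1$P > 0) {
    f2 <- fit_P(min(cap, max(2, ceiling(2 * f1$P / lbar))))
    res <- if (is.finite(f2$P)) f2 else f1
  } else res <- f1
  list(correlation = corr, P = res$P, fit_window = res$smax, mean_bond = lbar)
}

#' Single-chain structure factor
#'
#' Orientationally averaged \code{S(q) = (1/N^2) < sum_ij sinc(q r_ij) >}
#' over frames: 1 at q -> 0, and its log-log slopes diagnose the statistics
#' of the chain on the length scale \code{2 pi / q} (-1 rod-like, -5/3
#' swollen blobs, -2 ideal or extended-blob statistics).
#'
#' @param traj A trajectory, list of frames, or single conformation.
#' @param q Wavevector grid (strictly positive, increasing). Default: 200
#'   logarithmically spaced points from \code{2 pi / (2 (N-1) <l>)} to
#'   \code{2 pi / sigma}.
#' @param frame_stride Use every frame_stride-th frame (the double sum is
#'   O(N^2) per frame per q).
#' @return Object of class \code{"sq_curve"}: data.frame with columns
#'   \code{q}, \code{S}; attributes \code{n_frames}, \code{N}.
#' @export
structure_factor <- function(traj, q = NULL, frame_stride = 1) {
  fr <- traj_frames(traj)
  if (!length(fr)) stop("empty trajectory")
  fr <- fr[seq(1, length(fr), by = frame_stride)]
  N <- nrow(fr[[1]])
  if (is.null(q)) {
    lbar <- if (inherits(traj, "trajectory")) traj$ff$mean_bond else 0.97
    q <- exp(seq(log(2 * pi / (2 * (N - 1) * lbar)), log(2 * pi),
                 length.out = 200))
  }
  if (any(q <= 0) || is.unsorted(q)) stop("q grid must be positive increasing")
  S <- .sq_cpp(fr, q)
  structure(data.frame(q = q, S = S), class = c("sq_curve", "data.frame"),
            n_frames = length(fr), N = N)
}

#' @export
plot.sq_curve <- function(x, ...) {
  graphics::plot(x$q, x$S, log = "xy", type = "l", xlab = "q (1/sigma)",
                 ylab = "S(q)", ...)
  invisible(x)
}

#' Log-log slope of a structure-factor interval
#'
#' Least-squares slope of \code{log S(q)} versus \code{log q} over
#' \code{[q_min, q_max]}; used to compare against the regime predictions
#' (-1, -5/3, -2).
#'
#' @param curve An \code{"sq_curve"}.
#' @param q_min,q_max Fit interval bounds.
#' @return The fitted slope.
#' @export
sq_slope <- function(curve, q_min, q_max) {
  sel <- curve$q >= q_min & curve$q <= q_max & curve$S > 0
  if (sum(sel) < 3) stop("fewer than 3 grid points in the fit interval")
  stats::coef(stats::lm(log(S) ~ log(q), data = curve[sel, ]))[[2]]
}

#' Detect the inter-strand correlation hump in S(q)
#'
#' A chain folded over several interstitial volumes shows a local hump in
#' S(q) near \code{q = 2 pi / S_p}, from correlations between parallel chain
#' fragments separated by one post. The detector compensates the rod-like
#' \code{q^-1} background by searching \code{S(q) q} for its largest interior
#' local maximum inside the window.
#'
#' @param curve An \code{"sq_curve"}.
#' @param window Wavevector window searched (default \code{c(0.4, 1.4)},
#'   bracketing post separations of roughly 4.5-16 sigma).
#' @return List with \code{q}, \code{wavelength} (= 2 pi / q) and the
#'   compensated height, or NULL when no interior local maximum exists.
#' @export
hump_detect <- function(curve, window = c(0.4, 1.4)) {
  if (window[1] < min(curve$q) || window[2] > max(curve$q))
    stop("window outside the q grid")
  sel <- which(curve$q >= window[1] & curve$q <= window[2])
  if (length(sel) < 3) return(NULL)
  y <- curve$S[sel] * curve$q[sel]
  k <- seq(2, length(y) - 1)          # interior points only
  ismax <- y[k] > y[k - 1] & y[k] >= y[k + 1]
  # a genuine hump must rise above the compensated background at the window
  # edges; this also rejects numerically flat curves
  prominent <- y[k] > (1 + 1e-3) * max(y[1], y[length(y)])
  if (!any(ismax & prominent)) return(NULL)
  cand <- k[ismax & prominent]
  best <- cand[which.max(y[cand])]
  q_star <- curve$q[sel][best]
  list(q = q_star, wavelength = 2 * pi / q_star, height = y[best])
}
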