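#' Plan a geometry sweep
#'
#' Describes one of the three series of nanopost-array geometries studied:
#' \code{constant_dp} (vary the post separation S_p at fixed effective post
#' diameter d_p), \code{constant_Sp} (vary d_p at fixed S_p) and
#' \code{constant_wp} (vary S_p with d_p = S_p - w_p), together with the
#' chain and simulation settings and per-replica seeds.
#'
#' @param mode \code{"constant_dp"}, \code{"constant_Sp"} or
#'   \code{"constant_wp"}.
#' @param fixed Value of the held-fixed parameter (d_p, S_p or w_p).
#' @param values Values taken by the varied parameter (S_p for
#'   \code{constant_dp}/\code{constant_wp}, d_p for \code{constant_Sp}).
#' @param N Bead count of the simulated chain.
#' @param stiffness Bending parameter b of the chain.
#' @param config A \code{\link{sim_config}} template; per-replica seeds are
#'   derived from it.
#' @param replicas Number of independent replicas per geometry.
#' @param w Bead width used for d_p = D_p + w.
#' @return An object of class \code{"sweep_plan"}.
#' @export
sweep_plan <- function(mode = c("constant_dp", "constant_Sp", "constant_wp"),
                       fixed, values, N = 100, stiffness = 0,
                       config = sim_config(thermostat = "langevin", thermostat_tau = 1),
                       replicas = 3, w = 0.9) {
  mode <- match.arg(mode)
  stopifnot(fixed > 0, length(values) >= 1, all(values > 0), N >= 2,
            replicas >= 1)
  structure(list(mode = mode, fixed = fixed, values = sort(values), N = N,
                 stiffness = stiffness, config = config,
                 replicas = replicas, w = w,
                 seeds = config$seed + seq_len(replicas) - 1L),
            class = "sweep_plan")
}

#' Build the post-array series of a sweep plan
#'
#' @param plan A \code{\link{sweep_plan}}.
#' @return List of \code{\link{post_array}} objects, one per varied value.
#' @export
build_series <- function(plan) {
  w <- plan$w
  lapply(plan$values, function(v) {
    switch(plan$mode,
      constant_dp = post_array(S_p = v, D_p = plan$fixed - w, w = w),
      constant_Sp = post_array(S_p = plan$fixed, D_p = v - w, w = w),
      constant_wp = post_array(S_p = v, D_p = v - plan$fixed - w, w = w))
  })
}

#' Run a scaled-down geometry sweep
#'
#' For every geometry and replica: initialise a straight chain, run
#' thermostatted dynamics, and aggregate the occupation number, axial span
#' and gyration components (pooled over replicas with equal weight; standard
#' errors from block averaging of the pooled frame series). Optionally also
#' computes the structure factor per geometry. When \code{out_dir} is given,
#' per-geometry result rows are written as CSV and geometries whose file is
#' already present are skipped, making long sweeps resumable; simulation
#' failures are recorded in the \code{status} column and the sweep continues.
#'
#' @param plan A \code{\link{sweep_plan}}.
#' @param sq Logical: also compute S(q) per geometry (pooled frames)?
#' @param out_dir Optional directory for per-geometry CSV rows.
#' @param progress Print one line per completed geometry.
#' @return List with \code{observables} (data.frame, one row per geometry)
#'   and, when requested, \code{sq} (named list of \code{"sq_curve"}s).
#' @export
run_sweep <- function(plan, sq = FALSE, out_dir = NULL, progress = FALSE) {
  arrays <- build_series(plan)
  ff <- force_field(stiffness = plan$stiffness)
  rows <- list(); curves <- list()
  for (k in seq_along(arrays)) {
    a <- arrays[[k]]
    tag <- sprintf("%s_b%g_Sp%g_Dp%g", plan$mode, plan$stiffness, a$S_p, a$D_p)
    f_out <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".csv"))
    if (!is.null(out_dir) && file.exists(f_out)) {
      rows[[k]] <- utils::read.csv(f_out)
      next
    }
    frames <- list(); status <- "ok"
    for (r in seq_len(plan$replicas)) {
      cfg <- plan$config
      cfg$seed <- plan$seeds[r]
      st <- init_conformation(plan$N, a, cfg$init_orientation, ff)
      tr <- tryCatch(run_dynamics(st, a, ff, cfg),
                     nanopost_blowup = function(e) e)
      if (inherits(tr, "condition")) { status <- "aborted"; next }
      frames <- c(frames, tr$frames)
    }
    if (!length(frames)) {
      rows[[k]] <- data.frame(mode = plan$mode, S_p = a$S_p, D_p = a$D_p,
                              d_p = a$d_p, w_p = a$w_p, d_c = a$d_c,
                              ratio = a$ratio, F = a$F, b = plan$stiffness,
                              N = plan$N, n_frames = 0, n_p = NA, n_p_se = NA,
                              R_s = NA, R_s_se = NA, R_g = NA, R_g_axial = NA,
                              R_g_lateral = NA, status = status)
    } else {
      occ <- occupation_number(frames, a)
      sp <- axial_span(frames)
      g <- gyration(frames)
      rows[[k]] <- data.frame(mode = plan$mode, S_p = a$S_p, D_p = a$D_p,
                              d_p = a$d_p, w_p = a$w_p, d_c = a$d_c,
                              ratio = a$ratio, F = a$F, b = plan$stiffness,
                              N = plan$N, n_frames = length(frames),
                              n_p = occ$mean, n_p_se = occ$se,
                              R_s = sp$mean, R_s_se = sp$se,
                              R_g = g$R_g, R_g_axial = g$axial,
                              R_g_lateral = sqrt(g$lateral_y^2 + g$lateral_z^2),
                              status = status)
      if (sq) curves[[tag]] <- structure_factor(frames)
    }
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(rows[[k]], f_out, row.names = FALSE)
    }
    if (progress)
      message(sprintf("[%d/%d] %s: n_p = %s", k, length(arrays), tag,
                      format(rows[[k]]$n_p, digits = 3)))
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  out <- list(observables = obs)
  if (sq) out$sq <- curves
  out
}

#' Render summary figures for sweep results
#'
#' Writes the standard diagnostic figures to \code{dir}: occupation number
#' and axial span against the confinement ratio d_c/w_p and the post volume
#' fraction F; the span against d_c in log-log scale with the Odijk and
#' de Gennes extension laws overlaid; and, when structure factors are
#' supplied, each S(q) in log-log scale with slope guide lines and a marker
#' at \code{q = 2 pi / S_p}. Missing inputs produce a warning and an empty
#' report.
#'
#' @param results A list as returned by \code{\link{run_sweep}}, or a list of
#'   such lists (e.g. the two stiffness values).
#' @param dir Output directory for PDF files.
#' @param P,L Persistence length and contour length used for the overlay
#'   curves (defaults: flexible bond scale and N <l> from the result rows).
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(results, dir = ".", P = NULL, L = NULL) {
  if (!is.null(results$observables)) results <- list(results)
  obs <- do.call(rbind, lapply(results, `[[`, "observables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (is.null(obs) || !nrow(obs) || all(is.na(obs$n_p))) {
    warning("no sweep observables to report")
    return(invisible(paths))
  }
  pal <- c("0" = "black", "20" = "red3")
  panel <- function(xcol, ycol, xlab, ylab, log = "") {
    graphics::plot(range(obs[[xcol]], na.rm = TRUE),
                   range(obs[[ycol]], na.rm = TRUE), type = "n",
                   xlab = xlab, ylab = ylab, log = log)
    for (b in unique(obs$b)) for (m in unique(obs$mode)) {
      d <- obs[obs$b == b & obs$mode == m & !is.na(obs[[ycol]]), ]
      d <- d[order(d[[xcol]]), ]
      if (nrow(d))
        graphics::lines(d[[xcol]], d[[ycol]], type = "b", pch = 16,
                        col = pal[as.character(b)],
                        lty = match(m, unique(obs$mode)))
    }
    graphics::legend("topright", bty = "n", cex = 0.8,
                     legend = c(paste0("b = ", unique(obs$b)),
                                unique(obs$mode)),
                     col = c(pal[as.character(unique(obs$b))],
                             rep("grey30", length(unique(obs$mode)))),
                     lty = c(rep(1, length(unique(obs$b))),
                             seq_along(unique(obs$mode))))
  }
  f1 <- file.path(dir, "occupation.pdf")
  grDevices::pdf(f1, width = 9, height = 4.5)
  graphics::par(mfrow = c(1, 2))
  panel("ratio", "n_p", "d_c / w_p", "occupation number n_p", log = "x")
  panel("F", "n_p", "post volume fraction F", "occupation number n_p")
  grDevices::dev.off(); paths <- c(paths, f1)

  f2 <- file.path(dir, "span.pdf")
  grDevices::pdf(f2, width = 9, height = 4.5)
  graphics::par(mfrow = c(1, 2))
  panel("ratio", "R_s", "d_c / w_p", "axial span R_s", log = "x")
  panel("F", "R_s", "post volume fraction F", "axial span R_s")
  grDevices::dev.off(); paths <- c(paths, f2)

  f3 <- file.path(dir, "span_extension_laws.pdf")
  grDevices::pdf(f3, width = 6, height = 5)
  sel <- !is.na(obs$R_s)
  graphics::plot(obs$d_c[sel], obs$R_s[sel], log = "xy", pch = 16,
                 col = pal[as.character(obs$b[sel])],
                 xlab = "d_c", ylab = "R_s")
  if (is.null(L)) L <- (obs$N[1] - 1) * 0.97
  dd <- exp(seq(log(min(obs$d_c)), log(max(obs$d_c)), length.out = 80))
  if (is.null(P)) P <- 19.4
  od <- dd < P
  if (any(od))
    graphics::lines(dd[od], odijk_extension(L, P, dd[od]), col = "red3", lty = 2)
  graphics::lines(dd, pmin(L, degennes_extension(L, P, 0.9, dd)),
                  col = "grey40", lty = 3)
  graphics::legend("bottomleft", bty = "n", cex = 0.8,
                   legend = c("Odijk (b = 20)", "de Gennes"),
                   col = c("red3", "grey40"), lty = c(2, 3))
  grDevices::dev.off(); paths <- c(paths, f3)

  sqs <- unlist(lapply(results, `[[`, "sq"), recursive = FALSE)
  if (length(sqs)) {
    f4 <- file.path(dir, "structure_factors.pdf")
    grDevices::pdf(f4, width = 6, height = 5)
    for (nm in names(sqs)) {
      cv <- sqs[[nm]]
      plot(cv, main = nm)
      sp <- suppressWarnings(as.numeric(sub(".*_Sp([0-9.]+)_.*", "\\1", nm)))
      if (is.finite(sp))
        graphics::abline(v = 2 * pi / sp, col = "blue", lty = 3)
      q0 <- stats::median(cv$q)
      s0 <- cv$S[which.min(abs(cv$q - q0))]
      for (sl in c(-1, -5 / 3, -2))
        graphics::lines(cv$q, s0 * (cv$q / q0)^sl, col = "grey70", lty = 2)
    }
    grDevices::dev.off(); paths <- c(paths, f4)
  }
  invisible(paths)
}
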