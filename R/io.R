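#' Write a trajectory as extended XYZ
#'
#' One block per frame: bead count, a comment line carrying the time stamp
#' and provenance key-value pairs (kind, seed, stiffness, array geometry),
#' then one \code{C x y z} line per bead. Plain text, readable by standard
#' molecular viewers.
#'
#' @param traj A trajectory (or list of frames).
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_xyz <- function(traj, file) {
  fr <- traj_frames(traj)
  time <- if (inherits(traj, "trajectory")) traj$time else seq_along(fr)
  meta <- if (inherits(traj, "trajectory"))
    sprintf(" kind=%s seed=%s b=%g%s", traj$kind, as.character(traj$seed),
            traj$ff$stiffness,
            if (is.null(traj$array)) "" else
              sprintf(" S_p=%g D_p=%g", traj$array$S_p, traj$array$D_p))
  else ""
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(fr)) {
    f <- fr[[k]]
    writeLines(as.character(nrow(f)), con)
    writeLines(sprintf("time=%g%s", time[k], meta), con)
    writeLines(sprintf("C %.8f %.8f %.8f", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(file)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of \code{\link{write_xyz}}: returns a bare trajectory (frames +
#' time stamps) regardless of which tool produced the file.
#'
#' @param file Path to an XYZ file.
#' @param ff Force field attached to the result (bond validation is skipped;
#'   provenance in the file is not re-interpreted).
#' @return A \code{"trajectory"} object of kind \code{"file"}.
#' @export
read_xyz <- function(file, ff = force_field()) {
  ln <- readLines(file)
  frames <- list(); time <- numeric(); k <- 1; i <- 1
  while (i <= length(ln)) {
    n <- as.integer(ln[i])
    tm <- suppressWarnings(
      as.numeric(sub(".*time=([-0-9.eE+]+).*", "\\1", ln[i + 1])))
    rows <- strsplit(trimws(ln[(i + 2):(i + 1 + n)]), "[[:space:]]+")
    m <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    colnames(m) <- c("x", "y", "z")
    frames[[k]] <- m
    time[k] <- if (is.finite(tm)) tm else k
    k <- k + 1; i <- i + 2 + n
  }
  new_trajectory(frames, time, "file", ff, NULL, NA_integer_)
}

#' Write pooled observables as CSV with a provenance header
#'
#' @param df A data.frame (e.g. \code{run_sweep(...)$observables}).
#' @param file Output path.
#' @param header Named character vector of provenance fields written as
#'   leading \code{# key: value} comment lines.
#' @return Invisibly, \code{file}.
#' @export
write_observables <- function(df, file, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s: %s", names(header), header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}
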