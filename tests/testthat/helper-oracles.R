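# Independent brute-force oracles, kept deliberately naive: plain R double
# loops over all pairs and an explicit post patch, no shared code with the
# package kernels.

oracle_energy <- function(pos, array = NULL, ff = force_field()) {
  n <- nrow(pos)
  rc <- 2^(1 / 6) * ff$sigma
  e_wca <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (r < rc) {
      s6 <- (ff$sigma / r)^6
      e_wca <- e_wca + 4 * ff$epsilon * (s6^2 - s6) + ff$epsilon
    }
  }
  e_fene <- 0
  for (i in seq_len(n - 1)) {
    l <- sqrt(sum((pos[i + 1, ] - pos[i, ])^2))
    e_fene <- e_fene - 0.5 * ff$kappa * ff$r_max^2 * log(1 - (l / ff$r_max)^2)
  }
  e_bend <- 0
  if (ff$stiffness > 0 && n >= 3) {
    for (i in 2:(n - 1)) {
      u1 <- pos[i, ] - pos[i - 1, ]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- pos[i + 1, ] - pos[i, ]; u2 <- u2 / sqrt(sum(u2^2))
      e_bend <- e_bend + ff$stiffness * (1 - sum(u1 * u2))
    }
  }
  e_post <- 0
  if (!is.null(array)) {
    # all posts within 2 lattice shells of each bead's cell
    for (i in seq_len(n)) {
      iy <- floor(pos[i, 2] / array$S_p); iz <- floor(pos[i, 3] / array$S_p)
      for (m in (iy - 2):(iy + 3)) for (k in (iz - 2):(iz + 3)) {
        d <- sqrt((pos[i, 2] - m * array$S_p)^2 +
                  (pos[i, 3] - k * array$S_p)^2) - array$D_p / 2
        if (d < rc) {
          s6 <- (ff$sigma / d)^6
          e_post <- e_post + 4 * ff$epsilon * (s6^2 - s6) + ff$epsilon
        }
      }
    }
  }
  list(wca = e_wca, fene = e_fene, bend = e_bend, post = e_post,
       total = e_wca + e_fene + e_bend + e_post)
}

oracle_sq <- function(frames, q) {
  S <- numeric(length(q))
  for (f in frames) {
    n <- nrow(f)
    for (k in seq_along(q)) {
      acc <- 0
      for (i in seq_len(n)) for (j in seq_len(n)) {
        r <- sqrt(sum((f[i, ] - f[j, ])^2))
        acc <- acc + if (r == 0) 1 else sin(q[k] * r) / (q[k] * r)
      }
      S[k] <- S[k] + acc / n^2
    }
  }
  S / length(frames)
}

# a mildly perturbed but valid random chain, reproducible
random_chain <- function(n, spread = 0.25, seed = 1, ff = force_field(),
                         origin = c(0, 0, 0)) {
  set.seed(seed)
  pos <- unclass(make_rod(n, 0.97, "x", origin, ff))[, 1:3]
  repeat {
    cand <- pos + matrix(stats::rnorm(3 * n, 0, spread), n, 3)
    if (all(sqrt(rowSums(diff(cand)^2)) < ff$r_max * 0.95)) return(cand)
  }
}
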