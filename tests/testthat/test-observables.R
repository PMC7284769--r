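test_that("axial span is exact on rods and matches per-frame extremes", {
  expect_equal(axial_span(make_rod(11, 0.97, "x"))$mean, 9.7)
  expect_equal(axial_span(make_rod(11, 0.97, "y"))$mean, 0)
  frames <- lapply(1:5, function(s) random_chain(20, seed = s))
  sp <- axial_span(frames)
  expect_equal(sp$values,
               sapply(frames, function(f) max(f[, 1]) - min(f[, 1])))
  expect_equal(sp$mean, mean(sp$values))
  expect_error(axial_span(list()), "empty")
})

test_that("span approaches the end-to-end distance under axial stretch", {
  f <- random_chain(60, seed = 3)
  for (lam in c(1, 3, 10, 30)) {
    g <- f; g[, 1] <- g[, 1] * lam
    e2e <- abs(g[nrow(g), 1] - g[1, 1])
    sp <- axial_span(list(g))$mean
    expect_gte(sp + 1e-9, e2e * (1 - 1 / lam))  # converges as stretch grows
  }
  g <- f; g[, 1] <- g[, 1] * 1000
  expect_equal(axial_span(list(g))$mean,
               sqrt(sum((g[nrow(g), ] - g[1, ])^2)), tolerance = 1e-3)
})

test_that("occupation number counts distinct cells and is lattice-invariant", {
  a <- post_array(12, 3)
  rod <- make_rod(20, 0.97, "x", origin = c(0, 6, 6))
  expect_equal(occupation_number(rod, a)$mean, 1)
  u <- make_u_turn(post_array(6, 3), N = 40)
  expect_equal(occupation_number(u, post_array(6, 3))$mean, 2)
  # brute-force set-of-cells count on random point clouds (occupation does
  # not require chain connectivity)
  frames <- lapply(1:4, function(s) {
    set.seed(s)
    matrix(runif(90, -30, 30), 30, 3)
  })
  occ <- occupation_number(frames, a)
  brute <- sapply(frames, function(f)
    nrow(unique(data.frame(floor(f[, 2] / 12), floor(f[, 3] / 12)))))
  expect_equal(occ$values, brute)
  # invariance under rigid lattice translations of all frames
  shifted <- lapply(frames, function(f) {
    f[, 2] <- f[, 2] + 3 * a$S_p; f[, 3] <- f[, 3] - 7 * a$S_p; f
  })
  expect_equal(occupation_number(shifted, a)$values, occ$values)
})

test_that("gyration: coincident beads, discrete rod closed form, additivity", {
  pts <- matrix(5, 4, 3)
  g0 <- gyration(list(pts))
  expect_equal(g0$R_g, 0)
  # discrete rod of N beads at spacing l: Rg^2 = l^2 (N^2 - 1)/12
  N <- 25; l <- 0.97
  g <- gyration(make_rod(N, l, "x"))
  expect_equal(g$R_g, sqrt(l^2 * (N^2 - 1) / 12), tolerance = 1e-12)
  expect_equal(g$axial, g$R_g, tolerance = 1e-12)
  expect_equal(g$lateral_y, 0)
  expect_equal(g$lateral_z, 0)
  # between the continuum rod values for lengths (N-1)l and (N+1)l
  expect_gt(g$R_g, (N - 1) * l / sqrt(12))
  expect_lt(g$R_g, (N + 1) * l / sqrt(12))
  # components add in quadrature
  frames <- lapply(1:3, function(s) random_chain(25, seed = s))
  gg <- gyration(frames)
  expect_equal(gg$R_g^2,
               gg$axial^2 + gg$lateral_y^2 + gg$lateral_z^2,
               tolerance = 1e-10)
})

test_that("bond correlations: straight chain is fully correlated, flexible decays fast", {
  bc <- bond_correlation(make_rod(30, 0.97, "x"))
  expect_equal(bc$correlation$mean_cos, rep(1, nrow(bc$correlation)))
  # flexible equilibrium chain: near-zero correlation beyond a few bonds
  tr <- pivot_sample(60, force_field(), n_samples = 150, seed = 5)
  bc0 <- bond_correlation(tr, s_max = 30)
  expect_lt(mean(abs(bc0$correlation$mean_cos[10:30])), 0.05)
  expect_gt(bc0$correlation$mean_cos[1], 0)   # excluded-volume residual
  expect_error(bond_correlation(list(matrix(0, 2, 3))), "3 beads")
})

test_that("structure factor: limits, dimer closed form, naive-oracle agreement", {
  # single bead: S(q) = 1 everywhere
  one <- matrix(c(0, 0, 0), 1, 3)
  expect_equal(as.numeric(structure_factor(list(one), q = c(0.1, 1, 5))$S),
               c(1, 1, 1))
  # q -> 0 limit
  f <- random_chain(20, seed = 2)
  expect_equal(structure_factor(list(f), q = 1e-6)$S, 1, tolerance = 1e-9)
  # dimer: S(q) = (1 + sinc(q r))/2; exactly 1/2 at q r = pi
  r <- 1.3
  dimer <- rbind(c(0, 0, 0), c(r, 0, 0))
  q <- c(2, pi / r, 5)
  Sd <- structure_factor(list(dimer), q = q)$S
  expect_equal(Sd, (1 + sin(q * r) / (q * r)) / 2, tolerance = 1e-12)
  expect_equal(Sd[2], 0.5, tolerance = 1e-12)
  # vectorised kernel equals the naive double loop
  frames <- lapply(1:3, function(s) random_chain(40, seed = s))
  q <- exp(seq(log(0.1), log(6), length.out = 12))
  expect_equal(as.numeric(structure_factor(frames, q = q)$S),
               oracle_sq(frames, q), tolerance = 1e-12)
  # S(q) in (0, 1], grid strictly increasing enforced
  expect_true(all(structure_factor(frames)$S <= 1 + 1e-12))
  expect_error(structure_factor(frames, q = c(2, 1)), "increasing")
})

test_that("rod structure factor shows the rod-like -1 slope", {
  rod <- make_rod(80, 0.97, "x")
  L <- 79 * 0.97
  cv <- structure_factor(rod)
  sl <- sq_slope(cv, 2 * pi / L * 1.5, 2 * pi / 0.97 / 1.5)
  expect_gt(sl, -1.1)
  expect_lt(sl, -0.9)
})

test_that("hump detection recovers synthetic bump positions", {
  for (k in seq_len(nrow(hump_rows))) {
    cv <- make_synthetic_sq(hump_rows$q[k])
    h <- hump_detect(cv)
    expect_equal(h$q, hump_rows$q[k], tolerance = 0.01)
    expect_equal(h$wavelength, hump_rows$two_pi_over_q[k], tolerance = 0.01)
  }
  # pure power law: nothing to find
  expect_null(hump_detect(make_synthetic_sq(1.0, amplitude = 0)))
  # maximum sitting on the window edge is not an interior maximum
  expect_null(hump_detect(make_synthetic_sq(0.4, bump_width = 0.03),
                          window = c(0.4, 1.4)))
  expect_error(hump_detect(make_synthetic_sq(1), window = c(0.001, 1)),
               "outside")
})

test_that("block averaging reflects serial correlation", {
  set.seed(1)
  iid <- rnorm(4000)
  se_iid <- block_se(iid)
  expect_equal(se_iid, 1 / sqrt(4000), tolerance = 0.35)
  # strongly correlated AR(1): block SE must exceed the naive iid estimate
  ar <- as.numeric(stats::arima.sim(list(ar = 0.95), 4000))
  expect_gt(block_se(ar), 3 * stats::sd(ar) / sqrt(4000))
})
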