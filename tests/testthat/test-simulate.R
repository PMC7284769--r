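test_that("initial conformations are straight, correctly placed and finite in energy", {
  ff <- force_field()
  a <- post_array(9, 3)
  st <- init_conformation(3, a, "parallel", ff)
  expect_equal(st[, 1], c(0, 0.97, 1.94))
  expect_equal(st[, 2], rep(4.5, 3))
  expect_equal(st[, 3], rep(4.5, 3))
  st2 <- init_conformation(2, a, "perpendicular", ff)
  expect_equal(diff(st2[, 2]), 0.97)
  expect_equal(st2[, 3], rep(4.5, 2))
  expect_true(is.finite(chain_energy(st, a, ff)$total))
  expect_true(is.finite(chain_energy(st2, a, ff)$total))
  # perpendicular start threading narrow passages still yields finite energy
  aa <- post_array(5, 3)
  st3 <- init_conformation(30, aa, "perpendicular", ff)
  expect_true(is.finite(chain_energy(st3, aa, ff)$total))
})

test_that("microcanonical integration conserves energy", {
  ff <- force_field()
  cfg <- sim_config(dt = 0.001, thermostat = "none", n_equil = 0,
                    n_prod = 10000, sample_stride = 200, seed = 3)
  tr <- run_dynamics(init_conformation(20, NULL, "parallel", ff), NULL, ff, cfg)
  etot <- tr$stats$ekin + tr$stats$epot
  expect_lt((max(etot) - min(etot)) / abs(mean(etot)), 1e-3)
})

test_that("identical seed and config give bit-identical trajectories", {
  ff <- force_field(stiffness = 20)
  cfg <- sim_config(n_equil = 500, n_prod = 2000, sample_stride = 500, seed = 11)
  a <- post_array(9, 3)
  st <- init_conformation(30, a, "parallel", ff)
  t1 <- run_dynamics(st, a, ff, cfg)
  t2 <- run_dynamics(st, a, ff, cfg)
  expect_identical(t1$frames, t2$frames)
  # and the Langevin route as well
  cfgL <- sim_config(thermostat = "langevin", n_equil = 500, n_prod = 2000,
                     sample_stride = 500, seed = 12)
  expect_identical(run_dynamics(st, a, ff, cfgL)$frames,
                   run_dynamics(st, a, ff, cfgL)$frames)
})

test_that("thermostats hold the kinetic temperature within 2%", {
  ff <- force_field()
  st <- init_conformation(50, NULL, "parallel", ff)
  for (th in c("nose-hoover", "langevin")) {
    cfg <- sim_config(thermostat = th, n_equil = 20000, n_prod = 150000,
                      sample_stride = 500, seed = 4)
    tr <- run_dynamics(st, NULL, ff, cfg)
    expect_equal(mean(tr$stats$temperature), 1, tolerance = 0.02,
                 label = paste("mean T with", th))
  }
})

test_that("dynamics recovers the equilibrium bond length ~0.97 for both b", {
  for (b in c(0, 20)) {
    ff <- force_field(stiffness = b)
    cfg <- sim_config(thermostat = "langevin", n_equil = 20000,
                      n_prod = 100000, sample_stride = 500, seed = 5)
    tr <- run_dynamics(init_conformation(40, NULL, "parallel", ff),
                       NULL, ff, cfg)
    bl <- sapply(tr$frames, function(f) mean(sqrt(rowSums(diff(f)^2))))
    expect_equal(mean(bl), 0.97, tolerance = 0.011,
                 label = sprintf("mean bond length at b = %d", b))
  }
})

test_that("dynamics and Monte Carlo agree on free-chain averages", {
  ff <- force_field()
  cfg <- sim_config(thermostat = "langevin", thermostat_tau = 1,
                    n_equil = 250000, n_prod = 700000,
                    sample_stride = 700, seed = 6)
  md <- run_dynamics(init_conformation(40, NULL, "parallel", ff),
                     NULL, ff, cfg)
  mc <- pivot_sample(40, ff, n_samples = 1000, seed = 7)
  g_md <- gyration(md); g_mc <- gyration(mc)
  se <- sqrt(g_md$se^2 + g_mc$se^2)
  expect_lt(abs(g_md$R_g - g_mc$R_g), 3 * se + 0.05 * g_mc$R_g)
  s_md <- axial_span(md); s_mc <- axial_span(mc)
  se_s <- sqrt(s_md$se^2 + s_mc$se^2)
  expect_lt(abs(s_md$mean - s_mc$mean), 3 * se_s + 0.05 * s_mc$mean)
})

test_that("parallel and perpendicular starts converge to the same spans", {
  ff <- force_field()
  a <- post_array(9, 3)
  res <- lapply(c("parallel", "perpendicular"), function(ori) {
    cfg <- sim_config(thermostat = "langevin", thermostat_tau = 1,
                      n_equil = 150000, n_prod = 400000,
                      sample_stride = 500, seed = 8,
                      init_orientation = ori)
    tr <- run_dynamics(init_conformation(40, a, ori, ff), a, ff, cfg)
    axial_span(tr)
  })
  se <- sqrt(res[[1]]$se^2 + res[[2]]$se^2)
  expect_lt(abs(res[[1]]$mean - res[[2]]$mean),
            3 * se + 0.1 * res[[2]]$mean)
})

test_that("integrator blow-up aborts with a diagnostic condition", {
  ff <- force_field()
  cfg <- sim_config(dt = 0.15, thermostat = "none", thermostat_tau = 0.5,
                    n_equil = 0, n_prod = 5000, sample_stride = 100,
                    seed = 9, temperature = 5)
  expect_error(
    run_dynamics(init_conformation(20, NULL, "parallel", ff), NULL, ff, cfg),
    class = "nanopost_blowup")
  err <- tryCatch(
    run_dynamics(init_conformation(20, NULL, "parallel", ff), NULL, ff, cfg),
    nanopost_blowup = function(e) e)
  expect_gte(err$step, 1)
})

test_that("Monte Carlo sampler: reproducible, correct bond statistics", {
  ff <- force_field()
  t1 <- pivot_sample(30, ff, n_samples = 50, seed = 13)
  t2 <- pivot_sample(30, ff, n_samples = 50, seed = 13)
  expect_identical(t1$frames, t2$frames)
  tr <- pivot_sample(50, ff, n_samples = 600, seed = 14)
  bl <- sapply(tr$frames, function(f) mean(sqrt(rowSums(diff(f)^2))))
  expect_equal(mean(bl), 0.97, tolerance = 0.011)
  # stiffness does not alter bond lengths (bonded terms are angle-free)
  trs <- pivot_sample(50, force_field(stiffness = 20), n_samples = 600,
                      seed = 15)
  bls <- sapply(trs$frames, function(f) mean(sqrt(rowSums(diff(f)^2))))
  expect_lt(abs(mean(bls) - mean(bl)),
            3 * sqrt(block_se(bls)^2 + block_se(bl)^2) + 0.004)
})

test_that("trajectory round-trips through extended XYZ", {
  ff <- force_field()
  tr <- pivot_sample(12, ff, n_samples = 4, seed = 21)
  f <- tempfile(fileext = ".xyz")
  write_xyz(tr, f)
  rd <- read_xyz(f, ff)
  expect_equal(length(rd$frames), 4)
  for (k in 1:4)
    expect_equal(unclass(rd$frames[[k]]),
                 unclass(tr$frames[[k]]), tolerance = 1e-7,
                 ignore_attr = TRUE)
  unlink(f)
})
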