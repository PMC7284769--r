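test_that("channel free energies: prefactors and scaling exponents", {
  expect_equal(degennes_channel_dA(1, 1, 1, 1), 4.0)
  expect_equal(degennes_channel_dA(1, 1, 1, 2) / degennes_channel_dA(1, 1, 1, 1),
               2^(-5 / 3))
  expect_equal(degennes_channel_dA(2, 1, 1, 1), 8.0)     # extensive in L
  expect_equal(odijk_channel_dA(1, 1, 1), 2.2072)
  expect_equal(odijk_channel_dA(1, 2, 1) / odijk_channel_dA(1, 1, 1), 2^(-1 / 3))
  expect_equal(odijk_channel_dA(2, 1, 1), 2 * 2.2072)
  expect_error(degennes_channel_dA(-1, 1, 1, 1))
  expect_error(odijk_channel_dA(1, 0, 1))
})

test_that("slit free energy is exactly half the channel value", {
  expect_equal(slit_dA(4.0), 2.0)
  expect_equal(slit_dA(2.2072), 1.1036)
  expect_equal(slit_dA(0), 0)
})

test_that("partition ratios re-derive from equating per-length free energies", {
  # independent numeric route: L_qc/L_qs = f_qs / f_qc where f is the
  # confinement free energy per unit contour length in each sub-geometry
  set.seed(1)
  for (k in 1:10) {
    d_c <- runif(1, 1, 30); w_p <- runif(1, 0.5, d_c)
    P <- runif(1, 5, 25); w <- 0.9
    f_dG_ch <- degennes_channel_dA(1, P, w, d_c)
    f_dG_sl <- slit_dA(degennes_channel_dA(1, P, w, w_p))
    f_od_ch <- odijk_channel_dA(1, P, d_c)
    f_od_sl <- slit_dA(odijk_channel_dA(1, P, w_p))
    expect_equal(partition_ratio("degennes", "degennes", d_c, w_p),
                 f_dG_sl / f_dG_ch, tolerance = 1e-12)
    expect_equal(partition_ratio("odijk", "odijk", d_c, w_p),
                 f_od_sl / f_od_ch, tolerance = 1e-12)
    expect_equal(partition_ratio("degennes", "odijk", d_c, w_p, P = P, w = w),
                 f_od_sl / f_dG_ch, tolerance = 1e-4)
  }
})

test_that("partition ratio closed forms and the mixed prefactor", {
  expect_equal(partition_ratio("odijk", "odijk", 5, 5), 0.5)
  expect_equal(partition_ratio("degennes", "degennes", 10, 5), 2^(5 / 3) / 2)
  # mixed de Gennes / Odijk prefactor = 1.1036/4.0 = 0.2759 to 4 decimals
  expect_equal(partition_ratio("degennes", "odijk", 1, 1, P = 1, w = 1),
               0.2759, tolerance = 1e-4)
  expect_error(partition_ratio("odijk", "degennes", 10, 5),
               "unsupported")
  expect_error(partition_ratio("degennes", "odijk", 10, 5), "needs P and w")
})

test_that("mixed-regime ratio depends on chain parameters, pure regimes do not", {
  r1 <- partition_ratio("degennes", "odijk", 10, 2, P = 10, w = 0.9)
  r2 <- partition_ratio("degennes", "odijk", 10, 2, P = 20, w = 0.9)
  expect_false(isTRUE(all.equal(r1, r2)))
  # d_c/w_p alone fixes the pure-regime ratios
  expect_equal(partition_ratio("degennes", "degennes", 10, 2),
               partition_ratio("degennes", "degennes", 5, 1))
  expect_equal(partition_ratio("odijk", "odijk", 10, 2),
               partition_ratio("odijk", "odijk", 5, 1))
})

test_that("extension laws: limits, constants, and R <= L", {
  L <- 970
  expect_equal(odijk_extension(L, 20, 1e-6), L, tolerance = 1e-4)
  expect_equal(suppressWarnings(odijk_extension(L, 20, 20)), 0.81726 * L)
  expect_equal(suppressWarnings(odijk_extension(L, 20, 20, "circular")),
               0.8299 * L)
  expect_warning(odijk_extension(L, 20, 25), "validity")
  D <- seq(1, 19, by = 1)
  expect_true(all(odijk_extension(L, 20, D) < L))
  expect_equal(degennes_extension(L, 1, 1, 1), L)
  expect_equal(degennes_extension(L, 20, 0.9, 40) /
               degennes_extension(L, 20, 0.9, 20), 2^(-2 / 3))
  expect_equal(degennes_extension(2 * L, 20, 0.9, 30),
               2 * degennes_extension(L, 20, 0.9, 30))
  D <- seq(25, 400, by = 25)
  expect_true(all(degennes_extension(L, 19.7, 0.9, D) < L))
})

test_that("regime classification and boundaries", {
  P <- 19.7; w <- 0.9
  expect_equal(P^2 / w, 431.2, tolerance = 1e-3)      # classic threshold ~430
  expect_equal(classify_regime(P, w, P / 2), "Odijk")
  expect_equal(classify_regime(P, w, 100), "extended de Gennes")
  expect_equal(classify_regime(P, w, 500), "classic de Gennes")
  # boundaries resolve to the stronger-confinement label
  expect_equal(classify_regime(P, w, P), "Odijk")
  expect_equal(classify_regime(P, w, P^2 / w), "extended de Gennes")
  # flexible limit: extended window empty
  expect_equal(classify_regime(1, 1, 1.5), "classic de Gennes")
})

test_that("extended-regime blob count scales as stated", {
  expect_equal(blob_count_extended(1, 1, 1, 1), 1)
  expect_equal(blob_count_extended(1, 1, 2, 1) / blob_count_extended(1, 1, 1, 1),
               2^(-4 / 3))
  expect_equal(blob_count_extended(2, 1, 1, 1), 2)
})

test_that("slope windows: Odijk is rod-like throughout, blob regimes ordered", {
  od <- slope_windows(P = 19.7, w = 0.9, D = 10, R_s = 500)
  expect_equal(od$slope[od$q_min > 0], -1)              # one -1 window
  expect_equal(nrow(od), 2)                             # plus saturation
  expect_equal(od$q_min[1], 2 * pi / 500)

  cg <- slope_windows(P = 19.7, w = 0.9, D = 600, R_s = 900)
  expect_equal(cg$slope, c(-1, -5 / 3, -1, 0))
  # intervals are disjoint and ordered by decreasing q
  expect_true(all(diff(cg$q_min) <= 0))
  expect_true(all(cg$q_min < cg$q_max))
  expect_true(all(cg$q_max[-1] <= cg$q_min[-nrow(cg)] + 1e-12))

  eg <- slope_windows(P = 19.7, w = 0.9, D = 100, R_s = 700)
  expect_true(-2 %in% eg$slope)
  expect_equal(eg$q_max[eg$slope == -2], 2 * pi / 19.7)
  expect_equal(eg$q_min[eg$slope == -2],
               2 * pi / (100^2 * 19.7^2 / 0.9)^(1 / 3))
})

test_that("regime report covers a geometry series with both stiff-chain entries", {
  arrays <- lapply(c(4.5, 9, 22), post_array, D_p = 3.0)
  rep <- regime_report(arrays, P = 19.7, w = 0.9)
  expect_equal(nrow(rep), 3)
  expect_true(all(c("ratio_dG_dG", "ratio_dG_odijk", "ratio_odijk_odijk")
                  %in% names(rep)))
  expect_true(all(rep$ratio_dG_dG > 0))
  # narrow apertures of this series are in the Odijk regime for a DNA-like P
  expect_true(all(rep$regime_slit[rep$w_p < 19.7] == "Odijk"))
})
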