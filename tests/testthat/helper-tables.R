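# Reference geometry tables for the three array series (printed to three
# decimals): columns S_p, w_p, d_c, d_c/w_p, F for the constant-d_p = 3.9
# series, and (d_c/w_p, w_p, d_c) for the constant-S_p = 12 and
# constant-w_p = 2 series.

constant_dp_rows <- data.frame(
  S_p  = c(4.0, 4.5, 5.0, 6.0, 7.0, 9.0, 11.0, 14.0, 16.0, 18.0, 22.0,
           32.0, 45.0, 60.0),
  w_p  = c(0.1, 0.6, 1.1, 2.1, 3.1, 5.1, 7.1, 10.1, 12.1, 14.1, 18.1,
           28.1, 41.1, 56.1),
  d_c  = c(1.757, 2.464, 3.171, 4.585, 5.999, 8.828, 11.656, 15.899,
           18.727, 21.556, 27.213, 41.355, 59.740, 80.953),
  ratio = c(17.569, 4.107, 2.883, 2.183, 1.935, 1.731, 1.642, 1.574,
            1.548, 1.529, 1.503, 1.472, 1.454, 1.443),
  F    = c(0.747, 0.590, 0.478, 0.332, 0.244, 0.147, 0.099, 0.061,
           0.047, 0.037, 0.025, 0.012, 0.006, 0.003))

constant_Sp_rows <- data.frame(   # S_p = 12, w_p = 12 - d_p
  w_p  = c(10.1, 9.1, 8.1, 7.1, 5.1, 3.1, 2.1, 1.6, 1.1, 0.6, 0.1),
  d_c  = c(15.071, 14.071, 13.071, 12.071, 10.071, 8.071, 7.071, 6.571,
           6.071, 5.571, 5.071),
  ratio = c(1.492, 1.546, 1.614, 1.700, 1.975, 2.603, 3.367, 4.107,
            5.519, 9.284, 50.706))

constant_wp_rows <- data.frame(   # w_p = 2, S_p = d_p + 2
  S_p  = c(3.9, 6.9, 8.9, 12.9, 16.9, 22.9, 32.9, 42.9, 52.9, 62.9),
  d_c  = c(3.615, 4.858, 5.687, 7.343, 9.000, 11.485, 15.628, 19.770,
           23.912, 28.054),
  ratio = c(1.808, 2.429, 2.843, 3.672, 4.500, 5.743, 7.814, 9.885,
            11.956, 14.027))

# wavevector of the inter-strand hump and its length scale per post
# separation, as reported in the reference study
hump_rows <- data.frame(S_p = c(6, 7, 9, 11),
                        q = c(1.02, 0.86, 0.68, 0.56),
                        two_pi_over_q = c(6.16, 7.31, 9.24, 11.22))
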