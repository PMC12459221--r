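test_that("intensity ratio follows the concentration-corrected form", {
  expect_equal(intensity_ratio(100, 100, 1.0), 1.0)
  expect_equal(intensity_ratio(100, 50, 1.0), 2.0)
  expect_equal(intensity_ratio(100, 50, 0.8), 2.5)
  # homogeneity: common intensity scaling cancels
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 1, 1e5); b <- runif(1, 1, 1e5)
    k <- 10^runif(1, -3, 3); cc <- runif(1, 0.5, 2)
    expect_equal(intensity_ratio(k * a, k * b, cc), intensity_ratio(a, b, cc))
  }
})

test_that("ratio uncertainty matches a seeded Monte-Carlo propagation", {
  expect_equal(ratio_uncertainty(100, 0, 50, 0), 0)
  # relative uncertainty is invariant under joint scaling
  r1 <- ratio_uncertainty(100, 5, 50, 5) / intensity_ratio(100, 50)
  r2 <- ratio_uncertainty(200, 10, 100, 10) / intensity_ratio(200, 100)
  expect_equal(r1, r2)
  for (frac in c(0.01, 0.05, 0.1)) {
    analytic <- ratio_uncertainty(100, 100 * frac, 50, 50 * frac)
    mc <- mc_ratio_sigma(100, 100 * frac, 50, 50 * frac)
    expect_lt(abs(analytic - mc) / mc, 0.05)
  }
})

test_that("two-time-point Gamma2 inverts noiseless exponential decay exactly", {
  # identical para/dia decay between the delays -> zero PRE rate
  g0 <- gamma2_two_point(80, 40, 80, 40, 0.002, 0.010)
  expect_equal(g0$gamma2_per_s, 0)
  expect_false(g0$is_lower_bound)

  forward <- function(gamma2, r2dia, ta, tb, i0 = 1000) {
    list(
      i_para_ta = i0 * exp(-(r2dia + gamma2) * ta),
      i_para_tb = i0 * exp(-(r2dia + gamma2) * tb),
      i_dia_ta = i0 * exp(-r2dia * ta),
      i_dia_tb = i0 * exp(-r2dia * tb)
    )
  }
  f <- forward(25, 20, 0.002, 0.010)
  g <- gamma2_two_point(f$i_para_ta, f$i_para_tb, f$i_dia_ta, f$i_dia_tb,
                        0.002, 0.010)
  expect_equal(g$gamma2_per_s, 25, tolerance = 1e-12)

  set.seed(5)
  planted <- runif(50, 0, 200)
  for (g2 in planted) {
    ta <- runif(1, 0, 0.005); tb <- ta + runif(1, 0.001, 0.02)
    f <- forward(g2, runif(1, 5, 40), ta, tb)
    est <- gamma2_two_point(f$i_para_ta, f$i_para_tb, f$i_dia_ta, f$i_dia_tb,
                            ta, tb)$gamma2_per_s
    expect_lt(abs(est - g2), 1e-10)
  }
})

test_that("intensities at the noise floor yield a lower bound on Gamma2", {
  # paramagnetic Tb signal below the floor: bound computed at the floor
  g <- gamma2_two_point(100, 0.5, 100, 80, 0.002, 0.010, noise_floor = 2)
  expect_true(g$is_lower_bound)
  at_floor <- gamma2_two_point(100, 2, 100, 80, 0.002, 0.010)
  expect_equal(g$gamma2_per_s, at_floor$gamma2_per_s)
  expect_error(gamma2_two_point(10, 5, 10, 5, 0.01, 0.002),
               class = "premap_validation_error")
})

test_that("a PRE profile from identical tables is flat at 1 with no bleaching", {
  dia <- peak_table(demo_records(5), meta_dia())
  para <- peak_table(demo_records(5), meta_para())
  prof <- build_pre_profile(dia, para)
  expect_equal(prof$i_ratio, rep(1, 5))
  expect_false(any(prof$bleached))
  expect_equal(unique(prof$c_correction), 1)
})

test_that("a planted close-approach site carries the maximum intensity ratio", {
  probes <- list(V197 = c(8, 0, 0), L12 = c(40, 5, 0), V20 = c(0, 42, 0),
                 I31 = c(-35, 0, 10), I237 = c(0, 0, 38))
  model <- loop_ensemble_model(
    members = rbind(c(0, 0, 0), c(45, 45, 45)),
    weights = c(0.08, 0.92),
    probe_sites = probes, noise_sigma = 200
  )
  tabs <- generate_pre_tables(model, seed = 101)
  prof <- build_pre_profile(tabs$dia, tabs$para)
  expect_equal(prof$residue_index[which.max(prof$i_ratio)], 197L)
})

test_that("weak or missing paramagnetic peaks are flagged bleached, none lost", {
  df <- demo_records(5)
  para_df <- df
  para_df$intensity <- c(50, 50, 1, 50, 50)  # I31: 0.5 * noise (sigma = 2)
  dia <- peak_table(df, meta_dia())
  para <- peak_table(para_df[-1, ], meta_para())  # L12 missing entirely
  prof <- build_pre_profile(dia, para, bleach_snr_threshold = 3)
  expect_true(prof$bleached[prof$residue_index == 31])
  expect_true(prof$bleached[prof$residue_index == 12])
  expect_true(all(prof$is_lower_bound == prof$bleached))
  # no record loss: every dia key appears exactly once
  expect_equal(sort(prof$residue_index), sort(df$residue_index))
  # bound is evaluated at the detection limit (3 * sigma), not at the raw peak
  expect_equal(prof$i_ratio[prof$residue_index == 31], 100 / (3 * 2))
  expect_true(is.na(prof$sigma_ratio[prof$residue_index == 31]))
})

test_that("delta-I profiles are antisymmetric with quadrature errors", {
  df <- demo_records(5)
  dia <- peak_table(df, meta_dia())
  mk_para <- function(ints) {
    d <- df; d$intensity <- ints
    peak_table(d, meta_para())
  }
  a <- build_pre_profile(dia, mk_para(c(100 / 5.2, 50, 40, 100 / 5.0, 60)))
  b <- build_pre_profile(dia, mk_para(c(100 / 2.1, 55, 45, 100 / 2.2, 65)))
  d_ab <- delta_intensity(a, b)
  d_ba <- delta_intensity(b, a)
  expect_equal(d_ab$delta_i[d_ab$residue_index == 12], 5.2 - 2.1,
               tolerance = 1e-12)
  expect_equal(d_ab$delta_i, -d_ba$delta_i)
  expect_equal(d_ab$sigma_delta,
               sqrt(a$sigma_ratio^2 + b$sigma_ratio^2)[order(a$residue_index)],
               ignore_attr = TRUE)

  # identical profiles: all differences vanish
  d0 <- delta_intensity(a, a)
  expect_equal(d0$delta_i, rep(0, 5))
})

test_that("bleached sides of a delta-I comparison become sign-only records", {
  df <- demo_records(3)
  dia <- peak_table(df, meta_dia())
  strong <- df; strong$intensity <- c(1, 50, 50)     # L12 bleached (< 3*sigma)
  mild <- df; mild$intensity <- c(60, 50, 50)
  a <- build_pre_profile(dia, peak_table(strong, meta_para()))
  b <- build_pre_profile(dia, peak_table(mild, meta_para()))
  d <- delta_intensity(a, b)
  rec <- d[d$residue_index == 12, ]
  expect_identical(rec$comparison, "a_bleached")
  expect_identical(rec$sign, ">0")
  expect_true(is.na(rec$delta_i))

  disjoint_a <- build_pre_profile(
    peak_table(demo_records(3), meta_dia()),
    peak_table(demo_records(3), meta_para())
  )
  other <- demo_records(8)[6:8, ]
  disjoint_b <- build_pre_profile(
    peak_table(other, meta_dia()), peak_table(other, meta_para())
  )
  expect_error(delta_intensity(disjoint_a, disjoint_b),
               class = "premap_empty_error")
})

test_that("group annotation uses the default proximal/distal membership", {
  df <- demo_records(8)
  prof <- build_pre_profile(peak_table(df, meta_dia()),
                            peak_table(df, meta_para()))
  ann <- annotate_groups(prof)
  expect_identical(ann$group[ann$residue_index == 197], "distal_group2")
  expect_identical(ann$group[ann$residue_index == 225], "proximal_group1")

  none <- annotate_groups(prof, groups = list())
  expect_true(all(none$group == "unassigned"))

  expect_error(
    annotate_groups(prof, groups = list(a = c(12L, 20L), b = c(20L, 31L))),
    class = "premap_config_error"
  )
})
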