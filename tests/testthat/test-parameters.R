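# Gait parameter extraction: ranges of motion, temporal parameters,
# symmetry-ratio algebra, and the full 21/25-column vectors.

test_that("angular range is max minus min", {
  expect_equal(angular_range(rep(3, 10)), 0)
  expect_equal(angular_range(c(-10, 5, 47)), 57)
  expect_error(angular_range(numeric(0)), "empty")
})

test_that("temporal parameters follow the cycle definitions", {
  tp <- temporal_parameters(1.0, 1.63, 2.12)
  expect_equal(tp$cycle_time, 1.12)
  expect_equal(tp$stance_time, 0.63)
  expect_equal(tp$swing_time, 0.49)
  expect_equal(tp$swing_phase, 0.4375)
  expect_equal(tp$stance_phase, 0.5625)
  expect_equal(tp$cadence, 60 / 1.12)
  # stance == swing -> both phases one half
  tp2 <- temporal_parameters(0, 0.5, 1.0)
  expect_equal(tp2$swing_phase, 0.5)
  expect_equal(tp2$stance_phase, 0.5)
  expect_equal(temporal_parameters(0, 0.6, 1.2)$cadence, 50)
  expect_error(temporal_parameters(1, 0.9, 2), "degenerate")
})

test_that("symmetry ratios are 1 on mirrored legs and invert under swap", {
  expect_equal(tsr(0.5, 0.7, 0.5, 0.7), 1)
  expect_equal(ssr1(50, 35, 50, 35), 1)
  expect_equal(ssr2(55, 55), 1)
  # frozen values evaluated from the definitions
  expect_equal(tsr(0.61, 0.64, 0.49, 0.76), 1.4783, tolerance = 1e-4)
  expect_equal(ssr1(47.66, 38.96, 63.98, 34.24), 0.6547, tolerance = 1e-4)
  expect_equal(round(ssr2(12.81, 53.74), 4), 0.2384)
  # swap property over random inputs
  set.seed(7)
  for (i in 1:20) {
    v <- runif(4, 0.3, 2)
    expect_equal(tsr(v[1], v[2], v[3], v[4]) * tsr(v[3], v[4], v[1], v[2]), 1)
    a <- runif(4, 10, 80)
    expect_equal(ssr1(a[1], a[2], a[3], a[4]) * ssr1(a[3], a[4], a[1], a[2]), 1)
    expect_equal(ssr2(a[1], a[3]) * ssr2(a[3], a[1]), 1)
  }
  expect_error(tsr(0, 1, 1, 1), "> 0")
  expect_error(ssr2(10, 0), "denominator")
})

test_that("IMU extraction emits exactly the 21 named parameters", {
  tr <- small_trial()
  seg <- segment_trial(tr$imu)
  pars <- extract_imu_parameters(tr$imu, seg$pairs)
  expect_identical(names(pars), imu_parameter_names())
  expect_length(imu_parameter_names(), 21L)
  expect_equal(nrow(pars), nrow(seg$pairs))
  # phase complement per leg, always
  expect_equal(pars$swing_phase_L + pars$stance_phase_L, rep(1, nrow(pars)))
  expect_equal(pars$swing_phase_R + pars$stance_phase_R, rep(1, nrow(pars)))
  expect_true(all(pars$swing_time_L > 0 & pars$stance_time_L > 0))
  expect_true(all(pars[, 1:6] >= 0))
  expect_error(extract_imu_parameters(tr$imu, seg$pairs[0, ]), "at least one")
})

test_that("perfectly mirrored legs give unit symmetry ratios", {
  tr <- mirrored_trial()
  cyc <- build_cycles(data.frame(leg = "L", type = rep(c("HS", "TO"), 4)[1:7],
                                 time = c(0.2, 0.8, 1.4, 2.0, 2.6, 3.2, 3.8)))
  cyc_r <- cyc; cyc_r$leg <- "R"
  pairs <- pair_cycles(cyc, cyc_r)
  pars <- extract_imu_parameters(tr, pairs)
  expect_equal(pars$tsr, rep(1, nrow(pars)), tolerance = 1e-9)
  expect_equal(pars$ssr1, rep(1, nrow(pars)), tolerance = 1e-9)
  expect_equal(pars$ssr2, rep(1, nrow(pars)), tolerance = 1e-9)
})

test_that("swapping leg labels inverts the ratios and swaps per-leg fields", {
  tr <- small_trial()
  seg <- segment_trial(tr$imu)
  pars <- extract_imu_parameters(tr$imu, seg$pairs)
  # swap the channels and the cycle assignments
  sw <- tr$imu$data
  swap <- function(a, b) { tmp <- sw[[a]]; sw[[a]] <<- sw[[b]]; sw[[b]] <<- tmp }
  swap("angle_thigh_L", "angle_thigh_R"); swap("angle_shank_L", "angle_shank_R")
  swap("angvel_shank_L", "angvel_shank_R")
  tr2 <- new_imu_trial(tr$imu$subject_id, tr$imu$condition,
                       tr$imu$trial_index, tr$imu$sample_rate, sw)
  pairs2 <- seg$pairs
  for (f in c("t_hs1", "t_to", "t_hs2", "stance_time", "swing_time", "cycle_time")) {
    tmp <- pairs2[[paste0(f, "_L")]]
    pairs2[[paste0(f, "_L")]] <- pairs2[[paste0(f, "_R")]]
    pairs2[[paste0(f, "_R")]] <- tmp
  }
  pars2 <- extract_imu_parameters(tr2, pairs2)
  expect_equal(pars2$tsr, 1 / pars$tsr, tolerance = 1e-9)
  expect_equal(pars2$ssr1, 1 / pars$ssr1, tolerance = 1e-9)
  expect_equal(pars2$ssr2, 1 / pars$ssr2, tolerance = 1e-9)
  expect_equal(pars2$swing_time_L, pars$swing_time_R)
  expect_equal(pars2$knee_sagittal_angle_L, pars$knee_sagittal_angle_R)
})

test_that("knee-impaired cohorts have lower SSR2 than ankle-impaired ones", {
  feats <- ref_features("imu")
  expect_lt(mean(feats$ssr2[feats$condition == "knee"]),
            mean(feats$ssr2[feats$condition == "ankle"]))
})

test_that("walkway extraction reproduces footfall geometry", {
  ff <- data.frame(side = c("L", "R", "L"),
                   heel_x = c(0, 64, 128), heel_y = c(0, 12, 0),
                   t_contact = c(0, 0.57, 1.13), t_off = c(0.7, 1.27, 1.83))
  rec <- new_walkway_record("S01", "normal", 1, ff)
  p <- extract_walkway_parameters(rec)
  expect_identical(names(p), walkway_parameter_names())
  expect_length(walkway_parameter_names(), 25L)
  expect_equal(nrow(p), 1L)
  expect_equal(p$step_length_R, 64)
  expect_equal(p$stride_length_L, 128)
  expect_equal(p$stride_time_L, 1.13)
  expect_equal(p$stride_velocity_L, 128 / 1.13)
  expect_equal(p$base_of_support_R, 12)  # lateral offset from the left line
  # right stride incomplete with three footfalls
  expect_true(is.na(p$stride_length_R))
  # zero lateral offset -> zero base of support
  ff0 <- ff; ff0$heel_y <- 0
  expect_equal(extract_walkway_parameters(
    new_walkway_record("S", "normal", 1, ff0))$base_of_support_R, 0)
  # non-alternating footfalls rejected
  ffbad <- ff; ffbad$side <- c("L", "L", "R")
  ffbad$t_contact <- c(0, 0.6, 1.1); ffbad$t_off <- c(0.5, 1.2, 1.7)
  expect_error(extract_walkway_parameters(
    new_walkway_record("S", "normal", 1, ffbad)), "alternate")
})

test_that("support times satisfy the stride identity and the interval oracle", {
  rec <- small_trial()$walkway
  p <- extract_walkway_parameters(rec)
  cc <- stats::complete.cases(p)
  # double support = stride - single support - swing, per leg
  expect_equal(p$double_support_time_L[cc],
               (p$stride_time_L - p$single_support_time_L - p$swing_time_L)[cc],
               tolerance = 1e-9)
  expect_equal(p$double_support_time_R[cc],
               (p$stride_time_R - p$single_support_time_R - p$swing_time_R)[cc],
               tolerance = 1e-9)
  # against brute-force interval arithmetic on the first left stride
  ff <- rec$footfalls[order(rec$footfalls$t_contact), ]
  i <- which(ff$side == "L")[1]
  ora <- oracle_support_times(ff, i)
  expect_equal(p$single_support_time_L[1], ora[["single"]], tolerance = 1e-3)
  expect_equal(p$double_support_time_L[1], ora[["double"]], tolerance = 1e-3)
})

test_that("cohort parameter tables carry keys plus the named columns", {
  feats <- ref_features("imu")
  expect_identical(names(feats),
                   c("subject_id", "condition", "trial_index", "cycle_index",
                     imu_parameter_names()))
  wk <- ref_features("walkway")
  expect_identical(names(wk),
                   c("subject_id", "condition", "trial_index", "cycle_index",
                     walkway_parameter_names()))
  expect_false(anyNA(wk))
  # stride velocity identity on every extracted stride
  expect_equal(wk$stride_velocity_L * wk$stride_time_L, wk$stride_length_L,
               tolerance = 1e-6)
})
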