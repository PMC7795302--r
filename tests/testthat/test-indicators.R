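# Crafted static/two-phase recordings pin the indicator formulas to their
# closed forms; the baseline mode "first_sample" matches the literal formulas.

test_that("symmetry is the min/max ratio of homologous distances", {
  pos <- neutral_face()
  pos[5, ] <- c(0, 0, 0);  pos[3, ] <- c(2, 0, 0)    # left pair (4,2): dist 2
  pos[11, ] <- c(0, 5, 0); pos[9, ] <- c(4, 5, 0)    # right pair (10,8): dist 4
  rec <- static_recording("Raising", pos)
  si <- symmetry_curve(rec, c(4L, 2L), c(10L, 8L))
  expect_equal(si$values, rep(0.5, 6))
  # swapping left and right pairs changes nothing
  expect_equal(symmetry_curve(rec, c(10L, 8L), c(4L, 2L))$values, si$values)
  # mirror-symmetric face: identically 1
  recn <- static_recording("Raising", neutral_face())
  expect_equal(symmetry_curve(recn, c(4L, 2L), c(10L, 8L))$values, rep(1, 6))
  # coincident points: degenerate geometry
  pos[5, ] <- pos[3, ]
  expect_hb_error(symmetry_curve(static_recording("Raising", pos),
                                 c(4L, 2L), c(10L, 8L)), "degenerate_geometry")
})

test_that("ratio intensity follows 1 - 1/max(ratio_L, ratio_R)", {
  pos0 <- neutral_face()
  pos0[5, ] <- c(0, 0, 0); pos0[3, ] <- c(4, 0, 0)     # left dist 4
  pos0[11, ] <- c(0, 5, 0); pos0[9, ] <- c(4, 5, 0)    # right dist 4
  pos1 <- pos0
  pos1[3, ] <- c(5, 0, 0)                              # left ratio 1.25
  rec <- two_phase_recording("Raising", pos0, pos1)
  iv <- intensity_ratio_curve(rec, c(4L, 2L), c(10L, 8L),
                              baseline = "first_sample")
  expect_equal(iv$values[1], 0)                        # I(0) = 0 always
  expect_equal(iv$values[2], 1 - 1 / 1.25)             # = 0.2
  # both distances shrinking gives a negative intensity
  pos2 <- pos0; pos2[3, ] <- c(3, 0, 0); pos2[9, ] <- c(3, 5, 0)
  rec2 <- two_phase_recording("Raising", pos0, pos2)
  expect_lt(intensity_ratio_curve(rec2, c(4L, 2L), c(10L, 8L),
                                  baseline = "first_sample")$values[2], 0)
})

test_that("baring intensity follows the ellipse-area formula", {
  pos0 <- neutral_face()
  pos0[15, ] <- c(-1, 0, 0); pos0[16, ] <- c(1, 0, 0)    # v(14,15) = 2
  pos0[14, ] <- c(0, -0.5, 0); pos0[17, ] <- c(0, 0.5, 0) # v(13,16) = 1
  same <- two_phase_recording("Baring", pos0, pos0)
  expect_equal(intensity_baring_curve(same, baseline = "first_sample")$values,
               c(0, 0))
  doubled <- pos0
  doubled[c(15, 16), ] <- 2 * pos0[c(15, 16), ]
  doubled[c(14, 17), ] <- 2 * pos0[c(14, 17), ]
  rec <- two_phase_recording("Baring", pos0, doubled)
  expect_equal(intensity_baring_curve(rec, baseline = "first_sample")$values[2],
               1 - 1 / 4)                                # both axes doubled
  halved <- pos0
  halved[c(15, 16, 14, 17), ] <- 0.5 * pos0[c(15, 16, 14, 17), ]
  rec2 <- two_phase_recording("Baring", pos0, halved)
  expect_equal(intensity_baring_curve(rec2, baseline = "first_sample")$values[2],
               -3)                                       # axes halved
})

test_that("pursing intensity follows the corner-distance formula", {
  pos0 <- neutral_face()
  pos0[15, ] <- c(-1, 0, 0); pos0[16, ] <- c(1, 0, 0)
  same <- two_phase_recording("Pursing", pos0, pos0)
  expect_equal(intensity_pursing_curve(same, baseline = "first_sample")$values,
               c(0, 0))
  shrunk <- pos0; shrunk[c(15, 16), 1] <- c(-0.8, 0.8)   # v(t) = 0.8 v(0)
  rec <- two_phase_recording("Pursing", pos0, shrunk)
  expect_equal(intensity_pursing_curve(rec, baseline = "first_sample")$values[2],
               1 - 1 / 0.8)                              # = -0.25
  wide <- pos0; wide[c(15, 16), 1] <- c(-2, 2)           # v(t) = 2 v(0)
  rec2 <- two_phase_recording("Pursing", pos0, wide)
  expect_equal(intensity_pursing_curve(rec2, baseline = "first_sample")$values[2],
               0.5)
})

test_that("speed curves live on the unit square, increasing, fast onset above", {
  # identity warp: the diagonal
  w <- fit_warping(c(0, 0.4, 1), c(0, 0.4, 1))
  sc <- speed_curve(w)
  expect_equal(sc$values, sc$times, tolerance = 1e-9)
  # any speed curve is strictly increasing
  p <- sim_params(grade = 1, speed_gamma = 0.75, n_repetitions = 3,
                  noise_sd = 0, time_jitter = 0, seed = 70)
  reg <- register_recording(simulate_session(p)$session$recordings$Raising)
  sc2 <- speed_curve(reg$warping)
  expect_true(all(diff(sc2$values) >= 0))
  expect_equal(range(sc2$values), c(0, 1))
  # fast-onset profile sits above the diagonal in the first half
  mid <- sc2$times > 0.05 & sc2$times < 0.45
  expect_true(all(sc2$values[mid] > sc2$times[mid]))
})

test_that("compute_indicators yields the 14 labels, flags absences", {
  p <- sim_params(grade = 2, seed = 80)
  s <- simulate_session(p)$session
  rs <- register_session(s)
  ind <- compute_indicators(rs)
  expect_setequal(names(ind$curves), indicator_labels())
  expect_length(ind$absent, 0)
  grids <- vapply(ind$curves, function(c) length(c$times), integer(1))
  expect_true(all(grids == 100))
  # a session missing Pursing: 12 curves plus 2 flagged absences
  s2 <- session(s$session_id, s$patient_id,
                unname(s$recordings[setdiff(names(s$recordings), "Pursing")]))
  ind2 <- compute_indicators(register_session(s2))
  expect_length(ind2$curves, 12)
  expect_setequal(ind2$absent, c("lips.intensity", "lips.speed"))
})

test_that("healthy sessions show higher smiling symmetry than paralysed ones", {
  s1 <- simulate_session(sim_params(grade = 1, seed = 81))$session
  s6 <- simulate_session(sim_params(grade = 6, seed = 82))$session
  i1 <- compute_indicators(register_session(s1))
  i6 <- compute_indicators(register_session(s6))
  expect_gt(mean(i1$curves$smiling.symmetry$values),
            mean(i6$curves$smiling.symmetry$values))
})

test_that("indicators agree with straight-from-the-formula recomputation", {
  rec <- random_recording("Smiling", n = 15, seed = 21)
  P <- rec$positions
  d <- function(a, b) sqrt(rowSums((P[, a + 1, ] - P[, b + 1, ])^2))
  vl <- d(14, 3); vr <- d(15, 9)
  expect_equal(symmetry_curve(rec, c(14L, 3L), c(15L, 9L))$values,
               pmin(vl, vr) / pmax(vl, vr), tolerance = 1e-12)
  expect_equal(intensity_ratio_curve(rec, c(14L, 3L), c(15L, 9L),
                                     baseline = "first_sample")$values,
               1 - 1 / pmax(vl / vl[1], vr / vr[1]), tolerance = 1e-12)
  expect_equal(intensity_pursing_curve(rec, baseline = "first_sample")$values,
               1 - d(14, 15)[1] / d(14, 15), tolerance = 1e-12)
  expect_equal(intensity_baring_curve(rec, baseline = "first_sample")$values,
               1 - (d(14, 15)[1] * d(13, 16)[1]) / (d(14, 15) * d(13, 16)),
               tolerance = 1e-12)
})

test_that("indicators are invariant to rigid translation and uniform scaling", {
  p <- sim_params(grade = 3, noise_sd = 0, time_jitter = 0, seed = 83)
  s <- simulate_session(p)$session
  transform_session <- function(s, scale, shift) {
    recs <- lapply(s$recordings, function(r) {
      pos <- r$positions * scale
      for (ax in 1:3) pos[, , ax] <- pos[, , ax] + shift[ax]
      exercise_recording(r$exercise, r$times, pos)
    })
    session(s$session_id, s$patient_id, unname(recs))
  }
  s2 <- transform_session(s, 3.7, c(0.5, -1, 2))
  i1 <- compute_indicators(register_session(s))
  i2 <- compute_indicators(register_session(s2))
  for (lab in names(i1$curves))
    expect_equal(i2$curves[[lab]]$values, i1$curves[[lab]]$values,
                 tolerance = 1e-9, label = lab)
})

test_that("symmetry stays in (0,1]; intensities are 0 at the baseline sample", {
  p <- sim_params(grade = 6, seed = 84)
  ind <- compute_indicators(register_session(simulate_session(p)$session),
                            baseline = "first_sample")
  for (lab in grep("\\.symmetry$", names(ind$curves), value = TRUE)) {
    v <- ind$curves[[lab]]$values
    expect_true(all(v > 0 & v <= 1), label = lab)
  }
  for (lab in grep("\\.intensity$", names(ind$curves), value = TRUE))
    expect_equal(ind$curves[[lab]]$values[1], 0, tolerance = 1e-9, label = lab)
})
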