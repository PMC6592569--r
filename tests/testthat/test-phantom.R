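test_that("build_network computes arc lengths and junctions", {
  # straight 100 px line at 1 um/px
  g <- build_network(list(straight_spec()), c(40, 140))
  expect_equal(g$vessels[[1]]$arc_length_um, 120)
  g2 <- build_network(list(vessel_spec(rbind(c(10, 10), c(10, 110)))),
                      c(120, 120))
  expect_equal(g2$vessels[[1]]$arc_length_um, 100)
  # 3-4-5 triangle: (1,1) -> (31,41) is 50 px long
  g3 <- build_network(list(vessel_spec(rbind(c(1, 1), c(31, 41)))),
                      c(60, 60))
  expect_equal(g3$vessels[[1]]$arc_length_um, 50)
  # Y-junction: three polylines sharing one endpoint
  j <- c(30, 30)
  specs <- list(vessel_spec(rbind(c(10, 10), j)),
                vessel_spec(rbind(c(50, 10), j)),
                vessel_spec(rbind(j, c(30, 55))))
  gy <- build_network(specs, c(60, 60))
  expect_length(gy$vessels, 3L)
  expect_true(nrow(gy$junctions) >= 1)
  expect_equal(gy$junctions[1, ], j, ignore_attr = TRUE)
  # errors: empty list, degenerate centerline, out-of-field points
  expect_error(build_network(list(), c(10, 10)), "empty")
  expect_error(build_network(list(vessel_spec(rbind(c(5, 5), c(5, 5)))),
                             c(10, 10)), "degenerate")
  expect_error(build_network(list(straight_spec()), c(10, 10)), "inside")
})

test_that("vessel_spec and waveform_spec validate their invariants", {
  expect_error(vessel_spec(rbind(c(1, 1))), "2 points")
  expect_error(vessel_spec(rbind(c(1, 1), c(2, 2)), width_um = 0), "positive")
  expect_error(vessel_spec(rbind(c(1, 1), c(2, 2)), gap_cv = -1), ">= 0")
  expect_error(waveform_spec(-1), ">= 0")
  expect_error(waveform_spec(1, pulsatility_depth = 1), "\\[0, 1\\)")
  expect_error(waveform_spec(1, period_s = 0), "positive")
})

test_that("simulate_cells advances cells by v(t)/fps with preserved order", {
  g <- build_network(list(straight_spec()), c(40, 140))
  # 4.5 mm/s at 300 fps -> 15 um between consecutive frames
  cl <- simulate_cells(g, waveform_spec(4.5), duration_s = 0.1, fps = 300,
                       seed = 1)
  adv <- diff(cl$vessels[[1]]$pos_um[, 1])
  expect_equal(adv, rep(15, length(adv)), tolerance = 1e-12)
  # zero mean velocity -> stationary cells
  cl0 <- simulate_cells(g, waveform_spec(0), duration_s = 0.1, fps = 300,
                        seed = 1)
  expect_equal(max(abs(diff(cl0$vessels[[1]]$pos_um[, 1]))), 0)
  # pulsatile advance oscillates between (1-d)v and (1+d)v times dt
  wf <- waveform_spec(2, pulsatility_depth = 0.5, period_s = 1)
  clp <- simulate_cells(g, wf, duration_s = 1, fps = 100, seed = 1)
  adv <- diff(clp$vessels[[1]]$pos_um[, 1])          # um per frame
  t_mid <- clp$t_mid_s[-1]
  expect_equal(adv, waveform_velocity(wf, t_mid) * 10, tolerance = 1e-12)
  expect_gt(max(adv), 28); expect_lt(min(adv), 12)   # ~[10, 30] um range
  # no overtaking: order along the vessel preserved in every frame
  pos <- clp$vessels[[1]]$pos_um
  expect_true(all(apply(pos, 1, function(p) all(diff(p) > 0))))
  # negative velocity (transient depth > 1) is an error
  wf_bad <- waveform_spec(1, transient = list(start_s = 0.01,
                                              duration_s = 0.05, depth = 2))
  expect_error(simulate_cells(g, wf_bad, 0.1, 300, seed = 1), "negative")
})

test_that("cell trains are heterogeneous and seeded draws reproducible", {
  g <- build_network(list(straight_spec()), c(40, 140))
  cl1 <- simulate_cells(g, waveform_spec(1), 0.2, 300, seed = 9)
  cl2 <- simulate_cells(g, waveform_spec(1), 0.2, 300, seed = 9)
  expect_identical(cl1, cl2)
  cells <- cl1$vessels[[1]]$cells
  expect_gt(sd(cells$diam_um), 0)
  expect_gt(sd(cells$contrast), 0)
  expect_gt(sd(diff(cells$s0_um)), 0)
  # cv = 0 gives an identical-cell train
  g0 <- build_network(list(straight_spec(cell_diam_cv = 0, gap_cv = 0,
                                         cell_contrast_cv = 0)), c(40, 140))
  cl0 <- simulate_cells(g0, waveform_spec(1), 0.2, 300, seed = 9)
  expect_equal(sd(cl0$vessels[[1]]$cells$diam_um), 0)
  expect_lt(sd(diff(cl0$vessels[[1]]$cells$s0_um)), 1e-12)
})

test_that("render_sequence honours its noise contract", {
  g <- build_network(list(straight_spec()), c(30, 140))
  # zero cells (zero-velocity far upstream train), zero noise:
  # identical frames, zero temporal sd
  sp_empty <- vessel_spec(rbind(c(15, 10), c(15, 130)), mean_gap_um = 5000)
  ge <- build_network(list(sp_empty), c(30, 140))
  cle <- simulate_cells(ge, waveform_spec(0), 0.05, 300, seed = 2)
  cle$vessels[[1]]$cells <- cle$vessels[[1]]$cells[0, ]
  cle$vessels[[1]]$pos_um <- cle$vessels[[1]]$pos_um[, 0, drop = FALSE]
  tr0 <- render_sequence(cle, ge, noise = list(), seed = 2)
  expect_equal(max(motion_contrast(tr0$sequence)), 0)
  expect_true(all(tr0$sequence$frames >= 0))
  # one moving cell, zero noise: motion contrast only on the swept path
  cl1 <- simulate_cells(g, waveform_spec(1.2), 0.05, 300, seed = 3)
  keep <- which.min(abs(cl1$vessels[[1]]$cells$s0_um - 60))
  cl1$vessels[[1]]$cells <- cl1$vessels[[1]]$cells[keep, , drop = FALSE]
  cl1$vessels[[1]]$pos_um <- cl1$vessels[[1]]$pos_um[, keep, drop = FALSE]
  tr1 <- render_sequence(cl1, g, noise = list(), seed = 3)
  mc <- motion_contrast(tr1$sequence)
  moving <- mc > 1e-9
  expect_true(any(moving))
  expect_true(all(g$mask[moving]))           # inside the tube only
  # swept path: cell travels from its start to start + 20 um (plus its
  # ~3 sigma footprint); vessel starts at column 10
  s_range <- range(cl1$vessels[[1]]$pos_um)
  cols <- which(moving, arr.ind = TRUE)[, "col"]
  pad <- ceiling(3 * cl1$vessels[[1]]$cells$diam_um / 2.355) + 1
  expect_true(all(cols >= 10 + s_range[1] - pad &
                  cols <= 10 + s_range[2] + pad))
  # bleaching: frame means decay monotonically when drift > 0
  trb <- render_sequence(cl1, g,
                         noise = list(bleach_drift_per_s = 0.5), seed = 3)
  mu <- apply(trb$sequence$frames, 3, mean)
  expect_true(all(diff(mu) < 0))
})

test_that("phantom generation is deterministic and truth is consistent", {
  t1 <- generate_phantom(list(straight_spec()), c(40, 140),
                         waveform_spec(1, pulsatility_depth = 0.25),
                         duration_s = 0.6, fps = 300, seed = 21)
  t2 <- generate_phantom(list(straight_spec()), c(40, 140),
                         waveform_spec(1, pulsatility_depth = 0.25),
                         duration_s = 0.6, fps = 300, seed = 21)
  expect_identical(t1$sequence$frames, t2$sequence$frames)
  expect_identical(t1$truth_traces, t2$truth_traces)
  # truth speeds never exceed the programmed maximum
  vmax_prog <- 1 * 1.25
  expect_true(all(t1$truth_traces <= vmax_prog + 1e-12))
  expect_true(all(unlist(t1$truth_speed_maps) <= vmax_prog + 1e-12,
                  na.rm = TRUE))
  # truth maps share the sequence's spatial shape; NaN off vessel
  expect_equal(dim(t1$truth_speed_maps[[1]]), dim(t1$sequence$frames)[1:2])
  expect_true(all(is.na(t1$truth_speed_maps[[1]][!t1$mask])))
  # integrating the truth trace reproduces cell displacement within 1%
  cl <- simulate_cells(t1$geometry,
                       waveform_spec(1, pulsatility_depth = 0.25),
                       0.6, 300, seed = 21)
  mids_s <- (t1$epoch_start_ms + 50) / 1000
  v <- t1$truth_traces[, 1]                           # mm/s = um/ms
  integral_um <- sum((v[-1] + v[-length(v)]) / 2 * diff(mids_s) * 1000)
  pos <- cl$vessels[[1]]$pos_um[, 1]
  f_lo <- round(mids_s[1] * 300); f_hi <- round(mids_s[length(mids_s)] * 300)
  true_disp <- pos[f_hi] - pos[f_lo]
  expect_equal(integral_um, true_disp, tolerance = 0.01)
})
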