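test_that("steady-state phase fractions match duration ratios", {
  # analytic oracle: uniform positions => P(phase) = t_phase / t_c,
  # binomial sampling error around it
  cases <- list(c(10, 6, 4), c(19.8, 6.5, 7.5), c(5, 5, 5))
  for (ph in cases) {
    n <- 20000
    pop <- make_population(n, phase_durations(ph[1], ph[2], ph[3]),
                           seed = 7)
    expected <- ph / sum(ph)
    observed <- c(mean(pop$phase == "G1"), mean(pop$phase == "S"),
                  mean(pop$phase == "G2M"))
    se <- sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(observed - expected) < 3 * se))
  }
})

test_that("exponential-age populations over-represent young (G1) cells", {
  pop_u <- make_population(30000, seed = 3)
  pop_e <- simulate_population(sim_config(
    default_phases(), 30000, growth_mode = "exponential_age", seed = 3))
  expect_gt(mean(pop_e$phase == "G1"), mean(pop_u$phase == "G1"))
  expect_lt(mean(pop_e$phase == "G2M"), mean(pop_u$phase == "G2M"))
})

test_that("simulation is deterministic in config + seed", {
  cfg <- sim_config(default_phases(), 500, quiescent_fraction = 0.3,
                    duration_cv = 0.1, seed = 99)
  expect_identical(simulate_population(cfg), simulate_population(cfg))
  cfg2 <- sim_config(default_phases(), 500, quiescent_fraction = 0.3,
                     duration_cv = 0.1, seed = 100)
  expect_false(identical(simulate_population(cfg),
                         simulate_population(cfg2)))
})

test_that("quiescent cells are Ki67-negative, SOX2-positive, unlabelled", {
  pop <- make_population(2000, quiescent = 1, seed = 5)
  expect_true(all(pop$phase == "quiescent"))
  expect_true(all(!pop$ki67))
  expect_true(all(pop$sox2))
  lab <- apply_dual_pulse(pop)
  expect_true(all(!lab$idu) && all(!lab$brdu))
  counts <- count_labeling(lab)
  expect_identical(counts$l_cells, 0L)
  expect_identical(counts$s_cells, 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(phase_durations(0, 6, 4), "positive")
  expect_error(phase_durations(10, -1, 4), "positive")
  expect_error(phase_durations(Inf, 6, 4), "finite")
  expect_error(sim_config(default_phases(), 0), "positive integer")
  expect_error(sim_config(list(t_g1 = 1), 10), "phase_durations")
})

test_that("dual-pulse labels follow the cell's path through S phase", {
  # hand-built population: three cells with known positions
  pop <- make_population(3, seed = 1)
  pop$cell_cycle_length <- rep(20, 3)
  pop$t_g1_cell <- rep(10, 3)
  pop$t_s_cell <- rep(6, 3)
  # cell 1: mid-S, stays in S through the whole window -> IdU+BrdU+
  # cell 2: at 8.2 in G1, enters S at +1.8 h, after the IdU-only window
  #   -> IdU-BrdU+ (in neither labelled class)
  # cell 3: in G2M throughout -> unlabelled
  pop$cycle_position <- c(12, 8.2, 17)
  pop$phase <- c("S", "G1", "G2M")
  lab <- apply_dual_pulse(pop, pulse_schedule(t_idu = 1.5, t_brdu = 0.5))
  expect_equal(lab$idu, c(TRUE, FALSE, FALSE))
  expect_equal(lab$brdu, c(TRUE, TRUE, FALSE))
  # cell positions advanced by the 2 h window
  expect_equal(lab$cycle_position, c(14, 10.2, 19))
  expect_equal(lab$phase, c("S", "S", "G2M"))
})

test_that("leaving/S-cell ratio converges to t_i / t_s", {
  # the constant-exit-rate premise: E[L] / E[S] = t_idu / t_s
  pop <- make_population(50000, phase_durations(10, 6, 4), seed = 11)
  counts <- count_labeling(apply_dual_pulse(pop, pulse_schedule(1.5, 0.5)))
  ratio <- counts$l_cells / counts$s_cells
  expected <- 1.5 / 6
  # delta-method SE of the count ratio
  se <- ratio * sqrt(1 / counts$l_cells + 1 / counts$s_cells)
  expect_lt(abs(ratio - expected), 3 * se)
})

test_that("labelling window longer than the shortest cycle errors", {
  pop <- make_population(100, phase_durations(0.6, 0.7, 0.7), seed = 2)
  expect_error(apply_dual_pulse(pop, pulse_schedule(1.5, 0.6)),
               "shortest cell cycle")
})

test_that("count_labeling counts IdU-only and IdU+BrdU+ classes only", {
  labels <- tibble::tibble(
    idu = c(rep(TRUE, 250), rep(FALSE, 30)),
    brdu = c(rep(FALSE, 50), rep(TRUE, 200), rep(TRUE, 30))
  )
  counts <- count_labeling(labels, pulse_schedule(1.5, 0.5))
  expect_identical(counts$l_cells, 50L)
  expect_identical(counts$s_cells, 200L)
  expect_identical(counts$t_i, 1.5)
})

test_that("noiseless events encode DNA content exactly", {
  pop <- make_population(5000, seed = 8)
  ev <- synthesize_flow_events(pop, noise_cv = 0, doublet_fraction = 0,
                               seed = 1)
  expect_equal(nrow(ev), 5000)
  expect_true(all(ev$hoechst_area[ev$phase == "G1"] == 2))
  expect_true(all(ev$hoechst_area[ev$phase == "G2M"] == 4))
  s <- ev$hoechst_area[ev$phase == "S"]
  expect_true(all(s > 2 & s < 4))
  expect_true(all(ev$hoechst_area >= 0))
})

test_that("doublet fraction and seeding behave as configured", {
  pop <- make_population(10000, seed = 9)
  ev <- synthesize_flow_events(pop, noise_cv = 0.05,
                               doublet_fraction = 0.1, seed = 4)
  p_hat <- mean(ev$is_doublet)
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
  ev2 <- synthesize_flow_events(pop, noise_cv = 0.05,
                                doublet_fraction = 0.1, seed = 4)
  expect_identical(ev, ev2)
  expect_error(synthesize_flow_events(pop[0, ]), "non-empty")
})

test_that("noiseless doublet-free gating reproduces truth counts exactly", {
  pop <- make_population(20000, seed = 7)
  ev <- synthesize_flow_events(pop, noise_cv = 0, doublet_fraction = 0,
                               seed = 3)
  fc <- gate_events(ev, gate_config(dna_ref_2n = 2, dna_halfwidth = 1e-9,
                                    s_phase_extension = FALSE))
  truth <- table(pop$phase)
  expect_identical(fc$n_g1, as.integer(truth[["G1"]]))
  expect_identical(fc$n_s_flow, as.integer(truth[["S"]]))
  expect_identical(fc$n_g2m, as.integer(truth[["G2M"]]))
  expect_identical(fc$n_pcells, nrow(pop))
})

test_that("gating with S-phase extension is accurate under noise", {
  pop <- make_population(20000, seed = 17)
  ev <- synthesize_flow_events(pop, noise_cv = 0.05,
                               doublet_fraction = 0.02, seed = 5)
  fc <- gate_events(ev, gate_config())
  fracs <- c(fc$n_g1, fc$n_s_flow, fc$n_g2m) / fc$n_pcells
  expect_true(all(abs(fracs - c(0.5, 0.3, 0.2)) < 0.02))
  expect_identical(fc$n_g1 + fc$n_s_flow + fc$n_g2m, fc$n_pcells)
})

test_that("constructed doublets are excluded by pulse geometry", {
  pop <- make_population(4000, seed = 12)
  ev <- synthesize_flow_events(pop, noise_cv = 0, doublet_fraction = 0,
                               seed = 2)
  # append events with doubled area at single-cell height: classic doublets
  dbl <- ev[1:400, ]
  dbl$hoechst_area <- dbl$hoechst_area * 2
  dbl$is_doublet <- TRUE
  fc <- gate_events(dplyr::bind_rows(ev, dbl),
                    gate_config(dna_ref_2n = 2, dna_halfwidth = 1e-9,
                                s_phase_extension = FALSE))
  expect_identical(fc$n_total_singlets, nrow(ev))
  # two events with wildly different pulse ratios bracket the median so
  # far apart that neither survives the tolerance band
  bad <- ev[1:2, ]
  bad$hoechst_area <- bad$hoechst_height * c(1, 10)
  expect_error(gate_events(bad, gate_config()), "removed every event")
})

test_that("a fully quiescent population gates to an empty, flagged pool", {
  pop <- make_population(3000, quiescent = 1, seed = 6)
  ev <- synthesize_flow_events(pop, noise_cv = 0.05, doublet_fraction = 0,
                               seed = 2)
  fc <- gate_events(ev, gate_config())
  expect_identical(fc$n_pcells, 0L)
  expect_true(attr(fc, "flagged"))
  expect_error(estimate_all(analytic_labeling(), fc), "flagged")
})

test_that("event tables and gate errors on empty/invalid input", {
  expect_error(gate_events(tibble::tibble()), "non-empty")
  expect_error(gate_events(tibble::tibble(x = 1)), "missing columns")
})
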