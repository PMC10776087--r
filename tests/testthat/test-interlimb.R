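# Limb-pair phases, variability bounds, irregular classification, coupling.

lead_cycles_fixture <- function(contacts) {
  build_step_cycles(make_events("LH", contacts, contacts + 0.3 * diff(range(contacts)) / length(contacts),
                                x = contacts * 20, y = 2))
}

test_that("pair phase is the trailing-contact fraction of the lead stride", {
  lead <- build_step_cycles(make_events("LH", c(1.0, 1.5), c(1.3, 1.8)))
  trail <- make_events("RH", 1.25, 1.5)
  ph <- compute_pair_phase(lead, trail, "hindlimb")
  expect_equal(ph$phi, 0.5)

  lead2 <- build_step_cycles(make_events("LH", c(0.8, 1.3), c(1.1, 1.6)))
  expect_equal(compute_pair_phase(lead2, make_events("RH", 0.8, 1.0),
                                  "hindlimb")$phi, 0)
  expect_equal(compute_pair_phase(lead2, make_events("RH", 1.175, 1.3),
                                  "hindlimb")$phi, 0.75)
})

test_that("lead cycles without a trailing contact yield no phase point", {
  lead <- build_step_cycles(make_events("LH", c(0, 0.5, 1.0), c(0.3, 0.8, 1.3)))
  trail <- make_events("RH", 0.25, 0.4)  # only inside the first cycle
  ph <- compute_pair_phase(lead, trail, "hindlimb")
  expect_equal(nrow(ph), 1)
  expect_equal(ph$cycle, 1L)
  # multiple trailing contacts in one cycle: first one wins, one point only
  trail2 <- make_events("RH", c(0.2, 0.35), c(0.3, 0.45))
  ph2 <- compute_pair_phase(lead, trail2, "hindlimb")
  expect_equal(nrow(ph2), 1)
  expect_equal(ph2$phi, 0.4)
  expect_error(compute_pair_phase(lead, trail, "sidelimb"), "unknown")
})

test_that("phase transformation wraps onto the unit interval bijectively", {
  expect_equal(transform_phase(0.5), 0.5)
  expect_equal(transform_phase(1.0), 0.0)
  expect_equal(transform_phase(-0.25), 0.75)
  expect_error(transform_phase(c(0.2, NA)), "finite")
  u <- seq(0, 0.999, by = 0.001)
  expect_equal(transform_phase(u), u)
})

test_that("control bounds match mean/SD arithmetic in both methods", {
  lin <- control_bounds(c(0.45, 0.50, 0.55), method = "linear")
  expect_equal(lin$center, 0.50)
  expect_equal(lin$sd, 0.05)
  expect_equal(lin$half_width, 2 * lin$sd)
  expect_equal(c(lin$lower, lin$upper), c(0.40, 0.60))

  degenerate <- control_bounds(rep(0.5, 5), method = "linear")
  expect_equal(degenerate$center, 0.5)
  expect_equal(degenerate$sd, 0)
  expect_equal(degenerate$lower, degenerate$upper)

  # frozen from cos/sin component sums at 144 and 216 degrees
  circ <- control_bounds(c(0.4, 0.6), method = "circular")
  expect_equal(circ$center, 0.5, tolerance = 1e-9)
  expect_equal(circ$sd, 0.10362, tolerance = 1e-4)

  expect_error(control_bounds(0.5), "at least 2")
  expect_error(control_bounds(c(0.1, 0.6), method = "circular"), "undefined")
})

test_that("irregular classification is wrap-aware around the 0/1 seam", {
  pts <- tibble::tibble(pair = "hindlimb",
                        transformed_phase = c(0.35, 0.55, 0.02))
  b_mid <- control_bounds(c(0.45, 0.5, 0.55), pair = "hindlimb")
  cls <- classify_irregular(pts[1:2, ], b_mid)
  expect_equal(cls$irregular, c(TRUE, FALSE))

  b_seam <- tibble::tibble(pair = "hindlimb", method = "linear",
                           center = 0.98, sd = 0.03, half_width = 0.06,
                           lower = 0.92, upper = 0.04, n = 10L)
  cls_seam <- classify_irregular(pts[3, ], b_seam)
  expect_false(cls_seam$irregular)  # wrap distance 0.04 < 0.06

  wrong_pair <- tibble::tibble(pair = "forelimb", transformed_phase = 0.5)
  expect_error(classify_irregular(wrong_pair, b_mid), "mismatch")
})

test_that("classification is monotone in the bound width", {
  set.seed(3)
  pts <- tibble::tibble(pair = "hindlimb", transformed_phase = runif(200))
  flags <- lapply(c(0.02, 0.05, 0.1, 0.2), function(s) {
    b <- tibble::tibble(pair = "hindlimb", method = "linear", center = 0.5,
                        sd = s, half_width = 2 * s, lower = 0.5 - 2 * s,
                        upper = 0.5 + 2 * s, n = 10L)
    classify_irregular(pts, b)$irregular
  })
  for (i in seq_len(length(flags) - 1)) {
    # enlarging sd never turns a regular point irregular
    expect_true(all(flags[[i]] | !flags[[i + 1]]))
  }
})

test_that("rotation equivariance: shifting all phases preserves the flags", {
  set.seed(12)
  control <- runif(60, 0.4, 0.6)
  test_ph <- runif(100)
  delta <- 0.37
  b0 <- control_bounds(control, method = "circular")
  b1 <- control_bounds((control + delta) %% 1, method = "circular")
  p0 <- classify_irregular(
    tibble::tibble(pair = "hindlimb", transformed_phase = test_ph),
    dplyr::mutate(b0, pair = "hindlimb"))
  p1 <- classify_irregular(
    tibble::tibble(pair = "hindlimb",
                   transformed_phase = (test_ph + delta) %% 1),
    dplyr::mutate(b1, pair = "hindlimb"))
  expect_equal(p0$irregular, p1$irregular)
})

test_that("swim-style hindlimb-only records flow through the same phase path", {
  # cycle times only, no placement coordinates: phases still computable
  ev <- make_alternating_pass(n_steps = 8, phi_rh = 0.5) %>%
    dplyr::mutate(x = 0, y = 0)
  cyc <- build_step_cycles(ev)
  ph <- compute_pair_phase(dplyr::filter(cyc, limb == "LH"),
                           dplyr::filter(ev, limb == "RH"), "hindlimb")
  expect_equal(nrow(ph), 8)
  expect_true(all(abs(ph$phi - 0.5) < 1e-12))
})

test_that("the coupling table joins one row per phased lead cycle", {
  cfg <- tiny_sim_config(seed = 23)
  sim <- simulate_pass(cfg, 1, 1, "control")
  ph <- cohort_phases(sim$events)$phases
  hl_pairs <- dplyr::filter(ph, pair != "forelimb")
  tab <- pair_coupling_table(hl_pairs)
  expect_equal(nrow(tab),
               dplyr::n_distinct(hl_pairs[c("pass_id", "cycle")]))
  expect_true(all(c("hindlimb", "homolateral", "heterolateral") %in%
                    names(tab)))
  # an epoch missing one pair keeps its row with an NA in that pair
  dropped <- hl_pairs %>%
    dplyr::filter(!(pair == "homolateral" & cycle == 2))
  tab2 <- pair_coupling_table(dropped)
  expect_true(is.na(tab2$homolateral[tab2$cycle == 2]))
  expect_false(is.na(tab2$hindlimb[tab2$cycle == 2]))
  # duplicated epoch rows are a data error
  expect_error(pair_coupling_table(dplyr::bind_rows(hl_pairs, hl_pairs[1, ])),
               "duplicate")
})
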