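# Coordination indices, BBB beyond-control counts, ladder summaries.

test_that("regularity index scores patterned plantar placements", {
  perfect <- rep(c("RF", "LH", "LF", "RH"), 3)
  expect_equal(regularity_index(perfect)$ri, 100)

  # exactly one pattern occurrence among 12 placements: 4/12
  one_hit <- c("RF", "RF", "RF", "RF", "LH", "LF", "RH", "RF",
               "RF", "RF", "RF", "RF")
  res <- regularity_index(one_hit)
  expect_equal(res$n_patterned, 4)
  expect_equal(res$ri, 100 * 4 / 12, tolerance = 1e-9)

  none <- rep(c("RF", "RF", "LH", "LH"), 3)
  expect_equal(regularity_index(none)$ri, 0)

  expect_error(regularity_index(character(0)), "empty")
  expect_error(regularity_index(c("RF", "XX")), "unknown limb")
  expect_error(regularity_index(perfect, patterns = list()), "non-empty")
})

test_that("greedy matching is non-overlapping with earliest-start priority", {
  # the first window RF LH LF RH consumes its 4 placements; the overlapping
  # candidate starting at position 3 cannot reuse them
  seq1 <- c("RF", "LH", "LF", "RH", "RF", "LH", "LF", "RH")
  expect_equal(regularity_index(seq1)$n_patterned, 8)
  seq2 <- c("RF", "LH", "LF", "RH", "LF", "RH")
  expect_equal(regularity_index(seq2)$n_patterned, 4)
})

test_that("CPI counts dorsal cycles where RI cannot", {
  cyc <- tibble::tibble(
    limb = rep(c("RF", "LH", "LF", "RH"), 3),
    start_contact = seq(0, by = 0.1, length.out = 12),
    placement = c(rep("plantar", 4), "plantar", "dorsal", "plantar",
                  "plantar", rep("plantar", 4))
  )
  rep_idx <- index_report(cyc)
  expect_equal(rep_idx$cpi, 100)  # all cycles patterned, dorsal included
  expect_lt(rep_idx$ri, 100)      # the dorsal step breaks a plantar pattern
  expect_equal(coordinated_pattern_index(cyc$limb)$cpi, 100)
  half <- c("RF", "LH", "LF", "RH", "RF", "RF", "LH", "LH")
  expect_equal(coordinated_pattern_index(half)$cpi, 50)

  # CPI - RI equals the patterned share lost to dorsal placements, by
  # exhaustive counting on this fixture
  ri_val <- regularity_index(cyc$limb[cyc$placement == "plantar"])$ri
  expect_equal(rep_idx$ri, ri_val)
})

test_that("PSI is the hindlimb-to-forelimb plantar ratio, uncapped", {
  expect_equal(plantar_stepping_index(50, 50), 100)
  expect_equal(plantar_stepping_index(40, 50), 80)
  expect_equal(plantar_stepping_index(91, 100), 91)
  expect_equal(plantar_stepping_index(120, 100), 120)
  expect_error(plantar_stepping_index(10, 0), "positive")
})

test_that("DSI and sidedness follow their count definitions", {
  expect_equal(dorsal_stepping_index(0, 20), 0)
  expect_equal(dorsal_stepping_index(2, 10), 20)
  expect_error(dorsal_stepping_index(11, 10), "exceed")

  side <- dorsal_sidedness(11, 9)
  expect_equal(side$sidedness_right, 55)
  expect_equal(side$sidedness_left, 45)
  expect_equal(side$sidedness_right + side$sidedness_left, 100)
  undef <- dorsal_sidedness(0, 0)
  expect_false(undef$defined)
})

test_that("indices re-derive from their stored counts", {
  cfg <- tiny_sim_config(seed = 31, p_dorsal = c(control = 0.3,
                                                 silenced = 0.1))
  sim <- simulate_cohort(cfg)
  cyc <- cohort_phases(sim$events)$cycles
  rep_idx <- cyc %>%
    dplyr::group_by(animal, timepoint) %>%
    dplyr::group_modify(~ index_report(.x)) %>%
    dplyr::ungroup()
  expect_equal(rep_idx$ri, 100 * rep_idx$ri_patterned / rep_idx$ri_total)
  expect_equal(rep_idx$cpi, 100 * rep_idx$cpi_patterned / rep_idx$cpi_total)
  expect_equal(rep_idx$dsi, 100 * rep_idx$n_dorsal / rep_idx$n_hindlimb)
  expect_equal(rep_idx$psi, 100 * rep_idx$hl_plantar / rep_idx$fl_plantar)
  has_dorsal <- rep_idx$n_dorsal > 0
  expect_true(all(abs(rep_idx$sidedness_right[has_dorsal] +
                        rep_idx$sidedness_left[has_dorsal] - 100) < 1e-9))
  expect_true(all(is.na(rep_idx$sidedness_right[!has_dorsal])))
  # DSI = 0 exactly when no dorsal steps
  expect_equal(rep_idx$dsi == 0, rep_idx$n_dorsal == 0)
})

test_that("BBB beyond-control counts respect the bound rule", {
  control <- c(rep(12, 40), rep(11, 8))
  test_all_below <- rep(c(11, 12), 10)
  expect_equal(bbb_beyond_control(test_all_below, control)$k, 0)

  test_scores <- c(rep(14, 28), rep(12, 52))
  res <- bbb_beyond_control(test_scores, control)
  expect_equal(res$k, 28)
  expect_equal(res$n, 80)
  expect_equal(res$percent, 35.0)

  # raising the bound never increases k
  k_max <- bbb_beyond_control(test_scores, control, rule = "max")$k
  k_higher <- sum(test_scores > max(control) + 1)
  expect_lte(k_higher, k_max)
  r2 <- bbb_beyond_control(test_scores, c(10, 14), rule = "mean_2sd")
  expect_equal(r2$bound, 12 + 2 * sd(c(10, 14)))
  expect_error(bbb_beyond_control(test_scores, numeric(0)), "empty")
})

test_that("ladder summaries keep limbs separate and handle single trials", {
  rec <- tibble::tibble(animal = 1L, condition = "control",
                        limb = c("LH", "LH", "RH"),
                        trial = c(1L, 2L, 1L), footfalls = c(8, 10, 7))
  s <- ladder_summary(rec)
  lh <- dplyr::filter(s, limb == "LH")
  expect_equal(lh$mean_footfalls, 9)
  expect_equal(lh$sd_footfalls, sqrt(2), tolerance = 1e-9)
  rh <- dplyr::filter(s, limb == "RH")
  expect_equal(rh$sd_footfalls, 0)
  expect_equal(rh$n_trials, 1L)
  expect_equal(nrow(s), 2)  # never combined across limbs

  # group mean over animals equals brute-force averaging of per-animal means
  cfg <- tiny_sim_config(seed = 3)
  rec2 <- gaitphase:::simulate_ladder(cfg)
  s2 <- ladder_summary(rec2)
  brute <- tapply(rec2$footfalls,
                  paste(rec2$animal, rec2$condition, rec2$limb), mean)
  grp <- dplyr::filter(s2, condition == "control", limb == "LH")
  expect_equal(mean(grp$mean_footfalls),
               mean(brute[paste(unique(rec2$animal), "control", "LH")]),
               tolerance = 1e-12)
  expect_error(ladder_summary(dplyr::mutate(rec, footfalls = -1)), "negative")
})
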