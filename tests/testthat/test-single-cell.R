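test_that("the baseline AP repolarizes below -75 mV within 1 s", {
  tr <- simulate_ap(make_params(), tail_ms = 3001)
  after <- tr[tr$t > 10, ]
  below <- after$t[after$V < -75]
  expect_true(length(below) > 0 && min(below) - 10 < 1000)
  expect_equal(classify_ap(tr)$label, "NORMAL")
})

test_that("a zero-amplitude stimulus leaves the trace flat at rest", {
  tr <- simulate_ap(make_params(), stim_amp = 0, tail_ms = 3001)
  expect_lt(max(tr$V) - min(tr$V), 0.2)
})

test_that("recorded currents satisfy the membrane equation between stimuli", {
  tr <- simulate_ap(make_params(), record_currents = TRUE, tail_ms = 3001)
  # away from the stimulus and upstroke, dV/dt = -I_ion to first order
  seg <- tr$t > 100 & tr$t < 250          # plateau, smooth
  dvdt <- diff(tr$V[seg]) / diff(tr$t[seg])
  iion <- tr$I_ion[seg][-1]
  expect_lt(max(abs(dvdt + iion)), 0.15)
})

test_that("classification matches the synthetic template family exactly", {
  cases <- list(list(kind = "normal_ap", k = 0, label = "NORMAL", n = 0L),
                list(kind = "ead_ap", k = 1, label = "EAD", n = 1L),
                list(kind = "ead_ap", k = 2, label = "EAD", n = 2L),
                list(kind = "ead_ap", k = 4, label = "EAD", n = 4L),
                list(kind = "osc_ap", k = 0, label = "OSCILLATORY", n = 0L))
  for (cs in cases) {
    cl <- classify_ap(make_ap_trace(cs$kind, k = cs$k))
    expect_equal(cl$label, cs$label, info = cs$kind)
    expect_equal(cl$ead_count, cs$n, info = cs$kind)
  }
  # determinism: identical trace, identical classification
  tr <- make_ap_trace("ead_ap", k = 3)
  expect_identical(tidy(classify_ap(tr)), tidy(classify_ap(tr)))
})

test_that("classification invariants hold (label vs fields)", {
  for (cs in list(c("normal_ap", 0), c("ead_ap", 3), c("osc_ap", 0))) {
    cl <- classify_ap(make_ap_trace(cs[1], k = as.integer(cs[2])))
    if (cl$label == "NORMAL") expect_true(cl$ead_count == 0 && cl$returned_to_rest)
    if (cl$label == "EAD") expect_true(cl$ead_count >= 1 && cl$returned_to_rest)
    if (cl$label == "OSCILLATORY") expect_false(cl$returned_to_rest)
  }
})

test_that("a too-short trace is rejected as insufficient data", {
  tr <- make_ap_trace("normal_ap", duration = 2000)
  expect_error(classify_ap(tr), "covers only")
})

test_that("I_CaL is the dominant inward current at EAD onsets", {
  tr <- simulate_ap(regime_params("sf_a"), record_currents = TRUE,
                    tail_ms = 5000)
  drv <- detect_ead_drivers(tr)
  expect_gt(nrow(drv), 0)
  expect_true(all(drv$ical_dominant_inward))
})

test_that("a normal-regime run yields an empty driver report", {
  tr <- simulate_ap(make_params(), record_currents = TRUE, tail_ms = 3001)
  expect_equal(nrow(detect_ead_drivers(tr)), 0)
})

test_that("an all-zero current trace reports an all-zero onset balance", {
  tr <- make_ap_trace("ead_ap", k = 1)
  cur_names <- c("I_Na", "I_K1", "I_to", "I_Kr", "I_Ks", "I_CaL", "I_NaCa",
                 "I_NaK", "I_pCa", "I_pK", "I_bCa", "I_bNa")
  for (nm in cur_names) tr[[nm]] <- 0
  drv <- detect_ead_drivers(tr)
  expect_equal(nrow(drv), 1)
  expect_true(all(as.numeric(drv[1, cur_names]) == 0))
  expect_false(drv$ical_dominant_inward[1])
})

test_that("a 1x1 sweep at baseline classifies NORMAL", {
  pd <- sweep_phase_diagram(1, "Ks", 1)
  expect_equal(pd$label, "NORMAL")
})

test_that("increasing G_CaL walks NORMAL -> EAD -> OSCILLATORY, no reversals", {
  pd <- sweep_phase_diagram(c(1, 3, 5, 8), "Ks", c(0.4, 1))
  expect_equal(nrow(check_regime_ordering(pd)), 0)
  col <- pd[pd$mult_y == 0.4, ]
  expect_equal(col$label[col$mult_CaL == 1], "NORMAL")
  expect_equal(col$label[col$mult_CaL == 8], "OSCILLATORY")
  expect_true("EAD" %in% col$label)
})

test_that("sweeps accept the Kr and NaCa axes too", {
  pd <- sweep_phase_diagram(1, "Kr", c(0.2, 1))
  expect_true(all(pd$label %in% c("NORMAL", "EAD", "OSCILLATORY")))
  expect_error(sweep_phase_diagram(c(2, 1), "Ks", 1), "ascending")
  expect_error(sweep_phase_diagram(numeric(0), "Ks", 1), "non-empty")
})
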