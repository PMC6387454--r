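ir_long <- seq_params("IR-sGRE", tr = 1.19, te = 0.0023, ti = 1.0,
                      flip = 5, echo_spacing = 0.0045, train_length = 80)
ir_short <- seq_params("IR-sGRE", tr = 0.632, te = 0.0023, ti = 0.45,
                       flip = 5, echo_spacing = 0.0045, train_length = 80)
sg12 <- seq_params("sGRE", tr = 0.0057, te = 0.0025, flip = 12)

test_that("sequence parameter validation enforces the timing invariants", {
  expect_error(seq_params("sGRE", tr = -1, te = 0.002, flip = 5), "positive")
  expect_error(seq_params("sGRE", tr = 0.005, te = 0.006, flip = 5),
               "shorter than 'tr'")
  expect_error(seq_params("IR-SE", tr = 1.55, te = 0.011, ti = 2, flip = 90),
               "shorter than 'tr'")
  expect_error(seq_params("IR-sGRE", tr = 1.19, te = 0.0023, ti = 1.0,
                          flip = 5, echo_spacing = 0.0045,
                          train_length = 80, readout_index = 90),
               "readout_index")
  # TI-to-first-pulse reading is geometrically impossible for this protocol
  expect_error(seq_params("IR-sGRE", tr = 1.19, te = 0.0023,
                          ti = 1.0 + 39 * 0.0045, flip = 5,
                          echo_spacing = 0.0045, train_length = 80),
               "train does not fit")
  expect_equal(ir_long$readout_index, 40L)  # midpoint default
})

test_that("sGRE steady-state signal matches limits and hand evaluation", {
  b0 <- seq_params("sGRE", tr = 0.0057, te = 0.0025, flip = 0)
  expect_equal(sgre_signal(100, 1, 1, b0), 0)
  # full-recovery limit r1*tr -> inf
  fast <- sgre_signal(100, 5000, 1, sg12)
  expect_equal(fast, 100 * sin(12 * pi / 180), tolerance = 1e-10)
  # frozen hand evaluation: s0=100, r1=1/s, TR=5.7ms, 12 deg, k=1
  expect_equal(sgre_signal(100, 1, 1, sg12), 4.310982, tolerance = 1e-6)
})

test_that("simplified IR-sGRE signal matches limits and hand evaluation", {
  expect_equal(irsgre_signal_simplified(100, 1e-9, 1, ir_long), 0,
               tolerance = 1e-6)
  # null point: ti = ln2/r1 with long tr
  irn <- seq_params("IR-sGRE", tr = 60, te = 0.0023, ti = log(2) / 1.0,
                    flip = 5, echo_spacing = 0.0045, train_length = 80)
  expect_equal(irsgre_signal_simplified(100, 1, 1, irn), 0, tolerance = 1e-4)
  # frozen hand evaluation of the closed form at s0=100, r1=1, ti=1, tr=1.19
  expect_equal(irsgre_signal_simplified(100, 1, 1, ir_long), 3.7988,
               tolerance = 1e-4)
})

test_that("closed-form Brix steady state equals the fixed-point oracle", {
  for (sq in list(ir_long, ir_short))
    for (r1 in c(0.1, 0.3, 1.0, 2.0, 4.5, 6.0))
      for (k in c(0.8, 1.0, 1.2)) {
        closed <- irsgre_signal_brix(100, r1, k, sq)
        iterated <- brix_fixed_point(100, r1, k, sq)
        expect_equal(closed, iterated, tolerance = 1e-10)
      }
})

test_that("single-pulse train reduces to the N=1 steady state", {
  ir1 <- seq_params("IR-sGRE", tr = 1.19, te = 0.0023, ti = 1.0, flip = 5,
                    echo_spacing = 0.0045, train_length = 1)
  expect_equal(irsgre_signal_brix(100, 1.3, 1.1, ir1),
               brix_fixed_point(100, 1.3, 1.1, ir1), tolerance = 1e-10)
})

test_that("Brix reduces to the simplified model as the pulses vanish", {
  tiny <- seq_params("IR-sGRE", tr = 1.19, te = 0.0023, ti = 1.0,
                     flip = 1e-4, echo_spacing = 0.0045, train_length = 80)
  for (r1 in c(0.5, 1.1, 4.7))
    expect_equal(irsgre_signal_brix(100, r1, 1, tiny),
                 irsgre_signal_simplified(100, r1, 1, tiny),
                 tolerance = 1e-8)
})

test_that("Deichmann model tracks Brix within 0.5% of s0 across R1", {
  r1 <- seq(0.1, 6, by = 0.05)
  for (sq in list(ir_long, ir_short)) {
    d <- irsgre_signal_deichmann(100, r1, 1, sq)
    b <- irsgre_signal_brix(100, r1, 1, sq)
    expect_lt(max(abs(d - b)), 0.5)
  }
  tiny <- seq_params("IR-sGRE", tr = 1.19, te = 0.0023, ti = 1.0,
                     flip = 1e-4, echo_spacing = 0.0045, train_length = 80)
  expect_equal(irsgre_signal_deichmann(100, 1, 1, tiny),
               irsgre_signal_simplified(100, 1, 1, tiny), tolerance = 1e-8)
})

test_that("simplified-model error is small at tissue R1, large at blood R1", {
  err <- function(r1) abs(irsgre_signal_simplified(100, r1, 1, ir_long) -
                            irsgre_signal_deichmann(100, r1, 1, ir_long))
  expect_lt(err(1.1) / 100, 0.005)       # WM-like: < 0.5% of s0
  expect_gt(err(4.7), 3 * err(1.1))      # post-USPIO blood-like
})

test_that("multi-echo decay hits its closed-form sample points", {
  me2 <- seq_params("ME-sGRE", tr = 0.5, te = c(0.005, 0.055), flip = 15)
  expect_equal(multiecho_signal(100, 20, me2), c(90.484, 33.287),
               tolerance = 1e-4)
  me0 <- seq_params("ME-sGRE", tr = 0.5, te = c(0, 0.01, 0.02), flip = 15)
  expect_equal(multiecho_signal(73, 25, me0)[1], 73)       # te = 0
  expect_equal(multiecho_signal(50, 0, me0), rep(50, 3))   # no decay
})

test_that("IR-SE signal has the null point and short-TI limits", {
  long_tr <- seq_params("IR-SE", tr = 100, te = 0.011, ti = log(2) / 0.6,
                        flip = 90)
  expect_equal(irse_signal(100, 0.6, long_tr), 0, tolerance = 1e-4)
  early <- seq_params("IR-SE", tr = 100, te = 0.011, ti = 1e-6, flip = 90)
  expect_equal(irse_signal(100, 0.6, early), -100, tolerance = 1e-3)
  expect_equal(irse_signal(100, 0.6, early, magnitude = TRUE), 100,
               tolerance = 1e-3)
})

test_that("all models scale linearly in s0", {
  me <- seq_params("ME-sGRE", tr = 0.05, te = c(0.0046, 0.0195), flip = 15)
  irse <- seq_params("IR-SE", tr = 1.55, te = 0.011, ti = 0.33, flip = 90)
  for (c_scale in c(0.5, 7)) {
    expect_equal(sgre_signal(c_scale * 10, 1.2, 1.05, sg12),
                 c_scale * sgre_signal(10, 1.2, 1.05, sg12))
    expect_equal(irsgre_signal_brix(c_scale * 10, 1.2, 1.05, ir_long),
                 c_scale * irsgre_signal_brix(10, 1.2, 1.05, ir_long))
    expect_equal(irsgre_signal_deichmann(c_scale * 10, 1.2, 1.05, ir_long),
                 c_scale * irsgre_signal_deichmann(10, 1.2, 1.05, ir_long))
    expect_equal(irsgre_signal_simplified(c_scale * 10, 1.2, 1.05, ir_long),
                 c_scale * irsgre_signal_simplified(10, 1.2, 1.05, ir_long))
    expect_equal(multiecho_signal(c_scale * 10, 30, me),
                 c_scale * multiecho_signal(10, 30, me))
    expect_equal(irse_signal(c_scale * 10, 0.8, irse),
                 c_scale * irse_signal(10, 0.8, irse))
  }
})

test_that("kind dispatch and kind mismatches are caught", {
  expect_error(sgre_signal(1, 1, 1, ir_long), "sGRE")
  expect_error(irsgre_signal_brix(1, 1, 1, sg12), "IR-sGRE")
  expect_equal(predict_signal(sg12, s0 = 100, r1 = 1),
               sgre_signal(100, 1, 1, sg12))
  expect_equal(predict_signal(ir_long, s0 = 100, r1 = 1, model = "simplified"),
               irsgre_signal_simplified(100, 1, 1, ir_long))
})
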