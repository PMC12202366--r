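test_that("parameter validation names the offending field and enforces ordering", {
  expect_error(model_params(gAHP = -1), "gAHP")
  expect_error(model_params(kCa = 0), "kCa")
  expect_error(model_params(vR = -40), "vR")
  expect_error(model_params(EK = -55), "EK < EL < vT")
  expect_silent(model_params())
})

test_that("EC period matches the closed form and direct integration", {
  p <- default_p
  # independent oracle: integrate dv/dt = (-gl (v-EL) + Istim)/Cm from vR
  # to vT with a tiny explicit step
  integrate_period <- function(p, h = 1e-4) {
    v <- p$vR
    t <- 0
    while (v < p$vT) {
      v <- v + h * (-p$gl * (v - p$EL) + p$Istim) / p$Cm
      t <- t + h
    }
    t
  }
  expect_equal(ec_period(p), integrate_period(p), tolerance = 1e-3)
  expect_equal(ec_period(p), 17.5389, tolerance = 1e-4)

  # 20 random suprathreshold draws agree with integration
  set.seed(42)
  for (i in 1:20) {
    gl <- runif(1, 0.05, 0.4)
    # keep the cell safely suprathreshold: v_inf at least 5 mV above vT
    q <- model_params(Cm = runif(1, 0.5, 2), gl = gl,
                      Istim = gl * runif(1, 15, 60))
    expect_equal(ec_period(q), integrate_period(q), tolerance = 1e-3)
  }
})

test_that("EC period scales linearly in Cm and diverges near rheobase", {
  p <- default_p
  p2 <- model_params(Cm = 2)
  expect_equal(ec_period(p2), 2 * ec_period(p), tolerance = 1e-12)
  # Istim just above rheobase: period grows without bound as the margin
  # shrinks
  rheo <- p$gl * (p$vT - p$EL)
  T6 <- ec_period(model_params(Istim = rheo + 1e-6))
  T9 <- ec_period(model_params(Istim = rheo + 1e-9))
  expect_gt(T6, 4 * ec_period(p))
  expect_gt(T9, T6)
  expect_error(ec_period(model_params(t3 = 1, Istim = rheo * 0.99)),
               "does not fire")
})

test_that("derived constants match hand transcription of their definitions", {
  # r and Abar in an exactly solvable configuration: with r = 1/2 each
  # cycle maps Ca to (Ca + 1)/2, whose fixed point is 1
  q <- model_params(kCa = 0.001, t3 = 1000 * log(2))
  dcq <- derive_constants(q)
  expect_equal(dcq$r, 0.5, tolerance = 1e-15)
  expect_equal(dcq$Abar, 1, tolerance = 1e-15)
  expect_equal(ca_loop(dcq$Abar, 40, q), dcq$Abar, tolerance = 1e-12)

  # default configuration: evaluate the four rational coefficients from the
  # raw constants, independently of derive_constants' internals
  p <- default_p
  dc <- default_dc
  si <- exp(-0.1 * p$t3)
  denA <- 0.18 * (-60 - -90) + 0.2
  denS <- 0.18 * (-60 - -90) + 25 * si * (-80 - -90) + 0.2
  expect_equal(dc$a, 0.18 / denA, tolerance = 1e-14)
  expect_equal(dc$b, 50 / denA, tolerance = 1e-14)
  expect_equal(dc$c, (0.18 + 25 * si) / denS, tolerance = 1e-14)
  expect_equal(dc$d, 50 / denS, tolerance = 1e-14)
  expect_equal(dc$m, (-dc$a - dc$b + dc$c + dc$d) / 10, tolerance = 1e-14)
  expect_equal(dc$siEnd, si, tolerance = 1e-14)

  # structural invariants
  expect_true(dc$r > 0 && dc$r < 1)
  expect_equal(dc$Abar * (1 - dc$r) / dc$r, p$dCa, tolerance = 1e-14)
})

test_that("potential-balance reduction is invariant under common scaling", {
  # multiplying every conductance and current by one factor cancels in the
  # numerator and denominator of each rational coefficient, so the reduced
  # balance a + b x = c + d y — and hence every burst count — is unchanged
  p1 <- default_p
  s <- 3.7
  p2 <- model_params(gl = p1$gl * s, gAHP = p1$gAHP * s, gi = p1$gi * s,
                     ge = p1$ge * s, Iapp = p1$Iapp * s, Istim = p1$Istim * s,
                     t3 = p1$t3)
  d1 <- derive_constants(p1)
  d2 <- derive_constants(p2)
  for (f in c("a", "b", "c", "d", "m")) {
    expect_equal(d2[[f]], d1[[f]], tolerance = 1e-12)
  }
  # hence identical burst counts
  expect_identical(nspb(0, 3, p1, d1), nspb(0, 3, p2, d2))
})

test_that("JSON configuration round-trips and rejects unknown keys", {
  p <- model_params(gAHP = 7.5, kCa = 0.004)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(p, path)
  q <- read_config(path)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)

  cfg <- jsonlite::read_json(path)
  cfg$not_a_field <- 1
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, bad, auto_unbox = TRUE)
  expect_error(read_config(bad), "unknown configuration key")

  def <- withr::local_tempfile(fileext = ".json")
  write_default_config(def)
  expect_equal(read_config(def)$gAHP, 50)
})
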