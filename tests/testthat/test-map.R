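test_that("closed-form iterated calcium equals the cycle-by-cycle recursion", {
  p <- default_p
  dc <- default_dc
  set.seed(7)
  for (i in 1:25) {
    a0 <- runif(1, 0, 2 * dc$Abar)
    n <- sample(0:200, 1)
    expect_equal(ca_active(a0, n, dc), ca_loop(a0, n, p), tolerance = 1e-12)
    expect_equal(ca_silent(a0, n, dc), a0 * exp(-p$kCa * p$t3)^n,
                 tolerance = 1e-12)
  }
  # boundary behaviors
  expect_identical(ca_active(1.5, 0, dc), 1.5)
  expect_identical(ca_silent(1.5, 0, dc), 1.5)
  expect_equal(ca_active(dc$Abar, 50, dc), dc$Abar, tolerance = 1e-12)
  expect_identical(ca_silent(0, 17, dc), 0)
})

test_that("subthreshold potential has the leak-only limit and is monotone", {
  p <- default_p
  # no calcium, no inhibition: balance of leak against applied current
  expect_equal(vsub(0, 0, p), p$EL + p$Iapp / p$gl, tolerance = 1e-12)
  # AHP dominance drives the potential to EK
  huge <- model_params(gAHP = 1e9, t3 = p$t3)
  expect_equal(vsub(5, 0, huge), huge$EK, tolerance = 1e-3)
  # strictly decreasing in calcium at fixed inhibition
  ca_grid <- seq(0, 60, by = 0.5)
  for (s in c(0, 0.2, 1)) {
    expect_true(all(diff(vsub(ca_grid, s, p)) < 0))
  }
})

test_that("the quadratic root satisfies the original potential balance", {
  # the returned crossing count, substituted back, equalizes the two
  # subthreshold potentials (the defining equation, not the solved form)
  for (g in c(2, 5, 50)) {
    p <- model_params(gAHP = g)
    dc <- derive_constants(p)
    set.seed(11)
    for (i in 1:20) {
      x0 <- runif(1, 0, 5)
      y0 <- runif(1, 0, 0.9 * dc$Abar)
      n <- nspb_real(x0, y0, p, dc)
      if (!is.finite(n)) next
      rn <- dc$r^n
      va <- vsub(rn * x0 + dc$Abar * (1 - rn), 0, p)
      vs <- vsub(y0 * rn, dc$siEnd, p)
      expect_equal(va, vs, tolerance = 1e-8)
    }
  }
})

test_that("burst length limits in the AHP conductance are as expected", {
  # overwhelming AHP: interchange within the first cycle
  p_hi <- model_params(gAHP = 1e6)
  dc_hi <- derive_constants(p_hi)
  expect_lt(nspb_real(0, 3, p_hi, dc_hi), 1)
  expect_lt(nspb_real(1, 30, p_hi, dc_hi), 1)
  # vanishing AHP: the active cell never loses its advantage
  p_lo <- model_params(gAHP = 1e-8)
  dc_lo <- derive_constants(p_lo)
  n_lo <- nspb_real(1, 3, p_lo, dc_lo)
  expect_true(!is.finite(n_lo) || n_lo > 1e3)
})

test_that("integer burst count uses the strictly-greater ceiling, floored at one", {
  p <- default_p
  dc <- default_dc
  set.seed(13)
  for (i in 1:50) {
    x0 <- runif(1, 0, 0.95 * dc$Abar)
    y0 <- runif(1, 0, 0.95 * dc$Abar)
    nr <- nspb_real(x0, y0, p, dc)
    ni <- nspb(x0, y0, p, dc)
    if (!is.finite(nr)) {
      expect_identical(ni, Inf)
    } else {
      expect_identical(ni, max(1, floor(nr) + 1))
      expect_gte(ni, 1)
      # strict ceiling: an integer crossing still takes one more spike
      expect_gt(ni, nr)
    }
  }
})

test_that("formula burst count equals the brute-force switch oracle", {
  # moderate grid here; the dense 50x50 sweep runs in the acceptance suite
  for (g in c(5, 50)) {
    p <- model_params(gAHP = g)
    dc <- derive_constants(p)
    grid <- seq(0, dc$Abar * 0.98, length.out = 15)
    for (x0 in grid) {
      for (y0 in grid) {
        nr <- nspb_real(x0, y0, p, dc)
        if (is.finite(nr) && abs(nr - round(nr)) < 1e-8) next
        expect_identical(nspb(x0, y0, p, dc),
                         nspb_oracle(x0, y0, p, dc))
      }
    }
  }
})

test_that("map step swaps roles and respects the update structure", {
  p <- default_p
  dc <- default_dc
  st <- map_step(c(1, 4), p, dc)
  rn <- dc$r^st$n
  expect_equal(st$state[1], rn * 4, tolerance = 1e-14)
  expect_equal(st$state[2], rn * 1 + dc$Abar * (1 - rn), tolerance = 1e-14)
  # a calcium-free silent cell stays calcium-free as the next active cell
  expect_identical(map_step(c(2, 0), p, dc)$state[1], 0)
  # two successive steps restore the original role assignment: the linear
  # part of the composition is r^(n1+n2) times the identity permutation
  st2 <- map_step(st$state, p, dc)
  r12 <- dc$r^(st$n + st2$n)
  expect_equal(st2$state,
               r12 * c(1, 4) + c(dc$Abar * dc$r^st2$n * (1 - dc$r^st$n),
                                 dc$Abar * (1 - dc$r^st2$n)),
               tolerance = 1e-12)
})

test_that("fixed points obey the closed form and the large-k limit", {
  p <- default_p
  dc <- default_dc
  for (k in c(1, 2, 5, 20)) {
    fp <- fixed_point(k, p, dc)
    rk <- dc$r^k
    expect_equal(fp$point, c(dc$Abar * rk / (1 + rk), dc$Abar / (1 + rk)),
                 tolerance = 1e-12)
  }
  far <- fixed_point(2000, p, dc)
  expect_equal(far$point, c(0, dc$Abar), tolerance = 1e-8)
})

test_that("tuned AHP conductance yields stable fixed points that attract", {
  p <- default_p
  for (k in c(1, 3)) {
    g <- find_gAHP_for_k(k, p)
    q <- model_params(gAHP = g)
    dc <- derive_constants(q)
    fp <- fixed_point(k, q, dc)
    expect_true(fp$stable)
    expect_gt(fp$nCa, k - 1)
    expect_lt(fp$nCa, k)
    # the fixed point is exactly invariant under the nonlinear map
    st <- map_step(fp$point, q, dc)
    expect_identical(st$n, k)
    expect_equal(st$state, fp$point, tolerance = 1e-12)
    # and attracts a perturbed start (inside the stability neighborhood,
    # i.e. still mapping to burst count k) at the theorem's contraction rate
    set.seed(17 + k)
    repeat {
      delta <- runif(2, -0.3, 0.3)
      state <- fp$point + delta
      if (all(state >= 0) && nspb(state[1], state[2], q, dc) == k) break
    }
    d_prev <- sqrt(sum(delta^2))
    for (i in 1:30) {
      st <- map_step(state, q, dc)
      expect_identical(st$n, k)
      d_now <- sqrt(sum((st$state - fp$point)^2))
      expect_lte(d_now, dc$r^k * d_prev * (1 + 1e-10))
      state <- st$state
      d_prev <- d_now
    }
  }
  expect_error(find_gAHP_for_k(1, p, bracket = c(1e4, 1e5)), "bracket")
})

test_that("n_Ca at the fixed point falls with gAHP and rises with gi", {
  p <- default_p
  gs <- seq(0.2, 2, by = 0.2)
  ncas <- sapply(gs, function(g) {
    q <- model_params(gAHP = g)
    fixed_point(2, q, derive_constants(q))$nCa
  })
  fin <- is.finite(ncas)
  expect_true(all(diff(ncas[fin]) < 0))
  gis <- seq(5, 50, by = 5)
  ncas_gi <- sapply(gis, function(g) {
    q <- model_params(gAHP = 0.51, gi = g)
    fixed_point(2, q, derive_constants(q))$nCa
  })
  fin <- is.finite(ncas_gi)
  expect_true(all(diff(ncas_gi[fin]) > 0))
})

test_that("the map contracts states sharing a burst count and orbits settle", {
  p <- default_p
  dc <- default_dc
  set.seed(23)
  # contraction inequality for same-count pairs
  for (i in 1:50) {
    u <- runif(2, 0, dc$Abar * 0.99)
    v <- u + runif(2, -0.3, 0.3)
    v <- pmax(v, 0)
    su <- map_step(u, p, dc)
    sv <- map_step(v, p, dc)
    if (su$n != sv$n) next
    expect_lte(sqrt(sum((su$state - sv$state)^2)),
               dc$r^su$n * sqrt(sum((u - v)^2)) * (1 + 1e-10))
  }
  # orbits from random starts converge to a constant integer burst count
  for (i in 1:100) {
    orb <- iterate_map(runif(2, 0, dc$Abar * 0.99), 200, p, dc)
    tail_n <- tail(orb$nspb, 10)
    expect_true(all(tail_n == tail_n[1]))
  }
})
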