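test_that("force reduces to the textbook lethal-recessive form at h = u = 0", {
  m <- lethal_model(u = 0, h = 0)
  x <- c(0.1, 0.25, 0.5)
  expect_equal(selection_force(x, m), -x^2 / (1 + x), tolerance = 1e-15)
  ## frozen value: F(0.1) = -0.01/1.1
  expect_equal(selection_force(0.1, m), -9.090909090909091e-3,
               tolerance = 1e-15)
  expect_equal(step_infinite(0.2, m), 0.2 / 1.2, tolerance = 1e-15)
})

test_that("force at zero frequency equals its closed form for random (h, u)", {
  set.seed(11)
  for (i in 1:100) {
    h <- runif(1, -2, 1); u <- runif(1, 0, 1)
    expect_equal(selection_force(0, lethal_model(u = u, h = h)),
                 (1 - h) * u / (1 + (1 - 2 * h) * u), tolerance = 1e-14)
  }
})

test_that("one generation maps [0, 1/2] into itself across extreme parameters", {
  set.seed(21)
  x <- seq(0, 0.5, length.out = 101)
  pars <- rbind(expand.grid(h = c(-100, -5, -0.5, 0, 0.5, 0.99, 1),
                            u = c(0, 1e-8, 1e-3, 0.5, 1)),
                data.frame(h = runif(200, -50, 1), u = runif(200)))
  ## the u = 1, h = 1 corner leaves no viable genotype and is rejected
  expect_error(lethal_model(u = 1, h = 1), "viable")
  pars <- pars[!(pars$h == 1 & pars$u == 1), ]
  for (i in seq_len(nrow(pars))) {
    m <- lethal_model(u = pars$u[i], h = pars$h[i])
    xp <- step_infinite(x, m)
    expect_true(all(xp >= 0 & xp <= 0.5))
    ## the raw update obeys the bound analytically, not only after clamping
    raw <- x + selection_force(x, m)
    expect_true(all(raw >= -1e-12 & raw <= 0.5 + 1e-12))
  }
})

test_that("recessive lethal without mutation follows x0 / (1 + t x0)", {
  tr <- trajectory_infinite(0.5, schedule = 0, u = 0, t_max = 50)
  expect_equal(tr$x, 0.5 / (1 + 0.5 * tr$t), tolerance = 1e-12)
  ## starting at equilibrium the trajectory is constant
  m <- lethal_model(u = 1e-8, h = 0)
  x_hat <- equilibrium_exact(m)$x_hat
  tr2 <- trajectory_infinite(x_hat, schedule = 0, u = 1e-8, t_max = 20)
  expect_equal(tr2$x, rep(x_hat, 21), tolerance = 1e-12)
  ## x = 0 absorbing without mutation, any h
  expect_equal(trajectory_infinite(0, schedule = -0.3, u = 0, t_max = 5)$x,
               rep(0, 6))
})

test_that("trajectory follows the dominance schedule epoch by epoch", {
  sch <- dominance_schedule(t_start = c(0, 10), h = c(0, -0.01))
  u <- 1e-5
  x_hat0 <- equilibrium_exact(lethal_model(u, 0))$x_hat
  tr <- trajectory_infinite("equilibrium", sch, u, 30)
  ## flat during the first epoch, strictly increasing after the jump
  expect_equal(tr$x[tr$t <= 10], rep(x_hat0, 11), tolerance = 1e-10)
  post <- tr$x[tr$t >= 10]
  expect_true(all(diff(post) > 0))
  expect_error(dominance_at(sch, -1), "t >= 0")
})

test_that("exact equilibrium is a machine-precision fixed point", {
  set.seed(31)
  for (i in 1:1000) {
    h <- runif(1, -5, 1)
    u <- 10^runif(1, -12, -1)
    m <- lethal_model(u = u, h = h)
    eq <- equilibrium_exact(m)
    expect_lt(abs(eq$residual), 1e-12)
    expect_true(eq$x_hat >= 0 && eq$x_hat <= 0.5)
    ## one deterministic step leaves the equilibrium unchanged
    expect_equal(step_infinite(eq$x_hat, m), eq$x_hat, tolerance = 1e-11)
  }
})

test_that("equilibrium limits: zero mutation and the recessive closed form", {
  ## u = 0 limits are exact, not approximate
  expect_identical(equilibrium_exact(lethal_model(0, 0))$x_hat, 0)
  expect_identical(equilibrium_exact(lethal_model(0, 0.3))$x_hat, 0)
  for (h in c(-0.05, -0.5, -3))
    expect_equal(equilibrium_exact(lethal_model(0, h))$x_hat,
                 abs(h) / (1 + 2 * abs(h)), tolerance = 1e-15)
  ## h = 0 equals sqrt(u)/(1 + sqrt(u)) to 10 significant digits
  for (u in c(1e-10, 1e-8, 1e-5, 1e-3))
    expect_equal(equilibrium_exact(lethal_model(u, 0))$x_hat,
                 sqrt(u) / (1 + sqrt(u)), tolerance = 1e-10)
  ## overdominant u -> 0 limit approached at rate O(u / h^2): the leading
  ## correction to sqrt(h^2 (1+u)^2 + 4 (1-2h) u) is 2(1-2h)u / |h|
  for (h in c(-0.01, -0.1)) for (u in c(1e-10, 1e-8)) {
    x <- equilibrium_exact(lethal_model(u, h))$x_hat
    lim <- abs(h) / (1 + 2 * abs(h))
    expect_lt(abs(x / lim - 1), 10 * u / h^2)
  }
})

test_that("overdominant equilibrium evaluation is cancellation-free", {
  ## the stable form agrees with a 50-digit evaluation frozen here:
  ## h = -0.01, u = 1e-8 -> 0.00980491166272658905...
  expect_equal(equilibrium_exact(lethal_model(1e-8, -0.01))$x_hat,
               0.0098049116627265890, tolerance = 1e-12)
  ## and stays accurate down to u = 1e-12
  x <- equilibrium_exact(lethal_model(1e-12, -0.01))$x_hat
  expect_equal(x, 0.0098039216676470578, tolerance = 1e-10)
})

test_that("convergence to equilibrium is monotone from either side", {
  for (h in c(-0.5, -0.01, 0, 0.2, 0.99)) for (u in c(1e-6, 1e-3)) {
    m <- lethal_model(u = u, h = h)
    x_hat <- equilibrium_exact(m)$x_hat
    lo <- trajectory_infinite(x_hat / 2, h, u, 200)$x
    expect_true(all(diff(lo) >= 0))
    expect_true(all(lo <= x_hat + 1e-12))
    hi <- trajectory_infinite(min(0.5, x_hat * 2 + 0.01), h, u, 200)$x
    expect_true(all(diff(hi) <= 0))
    expect_true(all(hi >= x_hat - 1e-12))
  }
})

test_that("asymptotic equilibrium approximations hit their regimes", {
  ## partially recessive: u << h^2
  m <- lethal_model(1e-8, 0.01)
  a <- equilibrium_approx(m, "small-positive-h")
  expect_lt(abs(a$x_hat / equilibrium_exact(m)$x_hat - 1), 0.05)
  ## recessive closed form is exact at h = 0
  m0 <- lethal_model(1e-8, 0)
  expect_equal(equilibrium_approx(m0, "recessive")$x_hat,
               equilibrium_exact(m0)$x_hat, tolerance = 1e-10)
  expect_equal(signif(equilibrium_approx(m0, "recessive")$x_hat, 2), 1.0e-4)
  ## overdominant plateau
  mo <- lethal_model(1e-8, -0.01)
  a2 <- equilibrium_approx(mo, "overdominant")
  expect_equal(a2$x_hat, 0.01 / 1.02, tolerance = 1e-12)
  expect_lt(abs(a2$x_hat / equilibrium_exact(mo)$x_hat - 1), 0.05)
  ## zero-mutation limit, cross-checked against tiny-u exact value
  mz <- lethal_model(0, -0.05)
  expect_equal(equilibrium_approx(mz, "zero-mutation-limit")$x_hat,
               0.05 / 1.10, tolerance = 1e-12)
  expect_equal(equilibrium_approx(mz, "zero-mutation-limit")$x_hat,
               equilibrium_exact(lethal_model(1e-12, -0.05))$x_hat,
               tolerance = 1e-4)
  ## out-of-regime use warns but does not fail
  expect_warning(equilibrium_approx(lethal_model(1e-3, 0.01),
                                    "small-positive-h"), "regime")
  expect_error(equilibrium_approx(m, "bogus"))
})

test_that("half-time machinery brackets the midpoint crossing", {
  pre <- lethal_model(1e-5, 0); post <- lethal_model(1e-5, -0.01)
  ht <- half_time_infinite(pre, post)
  expect_identical(ht$x_mid, (ht$x_start + ht$x_final) / 2)
  expect_true(ht$t_half %in% c(floor(ht$t_cross), ceiling(ht$t_cross)))
  ## trajectory brackets the interpolated crossing
  tr <- trajectory_infinite(ht$x_start, post$h, post$u,
                            ceiling(ht$t_cross) + 1)$x
  expect_lt(tr[floor(ht$t_cross) + 1], ht$x_mid)
  expect_gte(tr[ceiling(ht$t_cross) + 1], ht$x_mid)
  ## degenerate and mismatched inputs
  expect_error(half_time_infinite(pre, pre), "degenerate")
  expect_error(half_time_infinite(pre, lethal_model(1e-8, -0.01)),
               "mutation rate")
})

test_that("closed-form half-times track the exact iteration", {
  for (u in c(1e-8, 1e-5)) {
    exact_rise <- half_time_infinite(lethal_model(u, 0),
                                     lethal_model(u, -0.01))$t_cross
    expect_lt(abs(half_time_approx_rise(-0.01, u) / exact_rise - 1), 0.02)
    exact_fall <- half_time_infinite(lethal_model(u, -0.01),
                                     lethal_model(u, 0))$t_cross
    expect_lt(abs(half_time_approx_fall(-0.01, u) / exact_fall - 1), 0.05)
  }
  expect_error(half_time_approx_rise(0.01, 1e-8), "negative")
  expect_error(half_time_approx_fall(0.01, 1e-8), "negative")
  expect_error(half_time_approx_rise(-0.01, 0.5), "0 < u")
})
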