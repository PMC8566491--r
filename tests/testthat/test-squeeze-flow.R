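test_that("gap_at_time starts at h0 and orders its variants", {
  p <- default_oral_parameters()
  set.seed(11)
  for (i in 1:25) {
    fl <- power_law_fluid(runif(1, 0.01, 40), runif(1, 0.15, 1))
    expect_identical(gap_at_time(fl, p, 0, "main_text"), p$h0)
    expect_identical(gap_at_time(fl, p, 0, "derivation"), p$h0)
    t <- runif(1, 0.01, 5)
    g_main <- gap_at_time(fl, p, t, "main_text")
    g_der <- gap_at_time(fl, p, t, "derivation")
    expect_lte(g_main, g_der)  # bigger bracket constant squeezes faster
    expect_gte(tongue_stress(fl, p, t, "main_text"),
               tongue_stress(fl, p, t, "derivation"))
  }
  expect_error(gap_at_time(power_law_fluid(1, 0.5), p, -0.1), "non-negative")
})

test_that("Newtonian results are bitwise independent of tongue speed", {
  fl <- power_law_fluid(0.05, 1)
  t <- c(0, 0.3, 1.2)
  slow <- oral_parameters(V = 0.05)
  fast <- oral_parameters(V = 0.30)
  expect_identical(gap_at_time(fl, slow, t), gap_at_time(fl, fast, t))
  expect_identical(gap_at_time(fl, slow, t, "derivation"),
                   gap_at_time(fl, fast, t, "derivation"))
  expect_identical(integrate_gap_ode(fl, slow, t)$gap,
                   integrate_gap_ode(fl, fast, t)$gap)
})

test_that("closed form agrees with the ODE oracle; stress is cross-consistent", {
  p <- default_oral_parameters()
  fl <- power_law_fluid(0.026, 0.55)

  # shipped sample 1 at the assessment time: ~3.7e-5 m
  g <- gap_at_time(fl, p, 1.2, "derivation")
  expect_equal(g, 3.7e-5, tolerance = 0.02)
  tr <- integrate_gap_ode(fl, p, c(0, 1.2))
  expect_rel_equal(g, tr$gap[2], 1e-6)

  # stress at t = 0 equals the pure shear stress at rate V / h0 (~0.28 Pa)
  s0 <- tongue_stress(fl, p, 0)
  expect_equal(s0, stress_at_rate(fl, p$V / p$h0))
  expect_equal(s0, 0.28, tolerance = 0.02)

  # sigma(t) algebraically equals the published closed form (bracket^{n/(n+1)})
  for (v in c("main_text", "derivation")) {
    cc <- if (v == "main_text") 2 else 3
    n <- fl$n
    bracket <- 1 + (n + 1) * p$F_N * p$h0^(n + 1) * p$V^(1 - n) * 1.2 /
      (cc * pi * n * fl$kappa * p$R^4)
    expect_equal(tongue_stress(fl, p, 1.2, v),
                 fl$kappa * p$V^n * p$h0^(-n) * bracket^(n / (n + 1)))
  }
})

test_that("Newtonian trace matches the classical squeeze-film closed form", {
  mu <- 0.08
  p <- default_oral_parameters()
  t <- seq(0, 2, length.out = 9)
  tr <- integrate_gap_ode(power_law_fluid(mu, 1), p, t)
  exact <- p$h0 * (1 + 2 * p$F_N * p$h0^2 * t / (3 * pi * mu * p$R^4))^(-1 / 2)
  expect_rel_equal(tr$gap, exact, 1e-6)
})

test_that("zero load means no squeezing", {
  p <- oral_parameters(F_N = 0)
  fl <- power_law_fluid(0.1, 0.4)
  t <- c(0, 1, 5)
  expect_equal(gap_at_time(fl, p, t), rep(p$h0, 3))
  expect_equal(integrate_gap_ode(fl, p, t)$gap, rep(p$h0, 3))
})

test_that("gap traces satisfy their invariants; stress is monotone", {
  p <- default_oral_parameters()
  set.seed(23)
  for (i in 1:10) {
    fl <- power_law_fluid(runif(1, 0.01, 40), runif(1, 0.15, 1))
    tr <- integrate_gap_ode(fl, p, seq(0, 3, length.out = 31))
    expect_identical(tr$gap[1], p$h0)
    expect_true(all(tr$gap > 0))
    expect_true(all(diff(tr$gap) <= 0))
    expect_true(all(tr$stress >= 0))
    expect_true(all(diff(tr$stress) >= 0))
  }
  # sigma non-decreasing in t, F_N and kappa at fixed everything else
  fl <- power_law_fluid(0.2, 0.4)
  ts <- seq(0, 3, length.out = 20)
  expect_true(all(diff(tongue_stress(fl, p, ts)) >= 0))
  s_fn <- vapply(seq(0.1, 2, length.out = 15), function(f)
    tongue_stress(fl, oral_parameters(F_N = f), 1.2), 0)
  expect_true(all(diff(s_fn) >= 0))
  s_k <- vapply(seq(0.05, 5, length.out = 15), function(k)
    tongue_stress(power_law_fluid(k, 0.4), p, 1.2), 0)
  expect_true(all(diff(s_k) >= 0))
})

test_that("stress transforms correctly under a common length/speed rescale", {
  # scaling h0, R and V by lambda multiplies the bracket's time constant
  # by lambda^-2 and leaves V/h0 unchanged; check against the closed form
  fl <- power_law_fluid(0.3, 0.45)
  lambda <- 1.7
  base <- oral_parameters()
  scaled <- suppressWarnings(
    oral_parameters(V = base$V * lambda, R = base$R * lambda,
                    h0 = base$h0 * lambda))
  n <- fl$n
  for (v in c("main_text", "derivation")) {
    cc <- if (v == "main_text") 2 else 3
    a0 <- (n + 1) * base$F_N * base$h0^(n + 1) * base$V^(1 - n) /
      (cc * pi * n * fl$kappa * base$R^4)
    expected <- fl$kappa * (base$V / base$h0)^n *
      (1 + a0 * lambda^-2 * 1.2)^(n / (n + 1))
    expect_equal(tongue_stress(fl, scaled, 1.2, v), expected,
                 tolerance = 1e-12)
  }
})

test_that("gap floor triggers a warning instead of a crash", {
  # absurdly thin fluid under full load: the film collapses numerically
  p <- oral_parameters(F_N = 50)
  fl <- power_law_fluid(1e-8, 1)
  expect_warning(tr <- integrate_gap_ode(fl, p, c(0, 200, 400)), "floor")
  expect_true(all(tr$gap >= 1e-9))
})

test_that("velocity profile honours no-slip at both walls", {
  set.seed(31)
  for (i in 1:30) {
    fl <- power_law_fluid(runif(1, 0.01, 5), runif(1, 0.2, 1))
    h <- runif(1, 1e-5, 3e-3)
    V <- runif(1, 0.05, 0.4)
    # keep the gradient inside the V >> alpha regime the model assumes
    dPdx <- sample(c(-1, 1), 1) * runif(1, 0.1, 100)
    vp <- velocity_profile(fl, h, V, dPdx, n_z = 11)
    expect_lt(abs(vp$u_x[1] - V), 1e-9)
    expect_lt(abs(vp$u_x[11]), 1e-9)
  }
})

test_that("Newtonian profile reduces to signed Couette-Poiseuille", {
  h <- 1e-3; V <- 0.15; kappa <- 0.05
  fl <- power_law_fluid(kappa, 1)
  for (dPdx in c(-80, -5, 5, 80)) {
    vp <- velocity_profile(fl, h, V, dPdx, n_z = 51)
    z <- vp$z_grid
    classical <- V * (1 - z / h) - (dPdx / (2 * kappa)) * z * (h - z)
    expect_equal(vp$u_x, classical, tolerance = 1e-9)
  }
})

test_that("profile converges to pure Couette as the gradient vanishes", {
  fl <- power_law_fluid(0.1, 0.5)
  h <- 1e-3; V <- 0.15
  couette <- V * (1 - seq(0, h, length.out = 201) / h)
  dev <- vapply(c(10, 1, 0.1), function(g)
    max(abs(velocity_profile(fl, h, V, g)$u_x - couette)), 0)
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-4 * V)
  exact0 <- velocity_profile(fl, h, V, 0)
  expect_equal(exact0$u_x, couette)
  expect_equal(exact0$alpha, 0)
})

test_that("pressure field obeys its boundary condition and load integral", {
  p <- default_oral_parameters()
  fl <- power_law_fluid(0.026, 0.55)
  h <- 1e-3; hdot <- 1e-4
  pf <- pressure_field(fl, p, h, hdot)
  # rim and outside cells are at ambient pressure
  r2 <- outer(pf$x_grid^2, pf$y_grid^2, `+`)
  expect_true(all(pf$pressure[r2 >= p$R^2] == 0))
  expect_true(all(pf$pressure >= 0))
  # centre value is the analytic peak
  n <- fl$n
  amp <- 6 * fl$kappa * n * hdot / (h^(n + 2) * p$V^(1 - n))
  expect_equal(pf$peak_pressure, amp * p$R^2)
  # load by quadrature vs the analytic disk integral (pi R^4 / 2 moment)
  load_exact <- 3 * pi * fl$kappa * n * hdot * p$R^4 /
    (h^(n + 2) * p$V^(1 - n))
  expect_rel_equal(pf$load, load_exact, 1e-4)
})

test_that("approximation ratio vanishes without squeezing and grows with load", {
  p <- default_oral_parameters()
  fl <- power_law_fluid(0.026, 0.55)
  expect_equal(approximation_ratio(fl, oral_parameters(F_N = 0), 1.2), 0)
  # increasing in F_N at fixed time and fluid
  r_fn <- vapply(seq(0.1, 2, length.out = 12), function(f)
    approximation_ratio(fl, oral_parameters(F_N = f), 1.2), 0)
  expect_true(all(diff(r_fn) > 0))
  # the tongue-speed approximation holds at the assessment time for every
  # shipped sample (it does NOT hold at early times, where hdot diverges)
  tab <- table1_samples()
  r <- vapply(table1_fluids(tab), approximation_ratio, 0, params = p,
              t = 1.2)
  expect_true(all(r < 1))
  expect_gt(approximation_ratio(fl, p, 1e-6), 1)  # early-time breakdown
})

test_that("gap trace CSV export round-trips numerically", {
  p <- default_oral_parameters()
  tr <- integrate_gap_ode(power_law_fluid(0.2, 0.4), p,
                          seq(0, 1.2, length.out = 7))
  out <- file.path(tempdir(), "trace.csv")
  write_gap_trace(tr, out)
  back <- utils::read.csv(out, comment.char = "#")
  expect_equal(back$time_s, tr$times)
  expect_equal(back$gap_m, tr$gap, tolerance = 1e-12)
  expect_equal(back$stress_pa, tr$stress, tolerance = 1e-12)
})
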