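test_that("equilibrium states are fixed points of the stepper", {
  m <- default_model()
  s0 <- model_state(60, 0)
  s1 <- step_state(s0, rep(0, 7), m)
  expect_equal(s1$angle, 60)
  expect_equal(s1$velocity, 0)
  expect_error(step_state(model_state(60), rep(0, 7), m, dt = 0.5), "dt")
})

test_that("a constant torque on the passive limb settles at the stop", {
  m <- default_model()
  s <- settle(rep(0, 7), m, external_torque = 20,
              state = model_state(30), method = "dynamic")
  expect_true(attr(s, "settled"))
  expect_gt(s$angle, 119)   # pushed into the flexion stop region
  expect_lt(abs(s$velocity), 1)
})

test_that("the trajectory converges as the step size shrinks", {
  m <- default_model()
  run <- function(dt) {
    s <- model_state(80, 0)
    for (i in seq_len(round(5 / dt)))
      s <- step_state(s, c(0.3, 0.3, 0.3, 0, 0, 0, 0), m,
                      external_torque = 10, dt = dt)
    s$angle
  }
  expect_lt(abs(run(0.002) - run(0.001)), 0.1)
})

test_that("settling is idempotent and consistent across methods", {
  m <- default_model()
  a <- natural_activation(60)
  ## zero inputs: stays put
  s0 <- settle(rep(0, 7), m, state = model_state(60), method = "static")
  expect_equal(s0$angle, 60)
  ## full quadriceps drive reaches the extension stop
  squad <- settle(c(1, 1, 1, 0, 0, 0, 0), m, state = model_state(60),
                  method = "static")
  expect_lt(squad$angle, 2)
  expect_gt(squad$angle, -12)
  ## static and dynamic paths agree
  for (ext in c(40, 80, 120)) {
    st <- settle(a, m, external_torque = ext, state = model_state(60),
                 method = "static")
    dy <- settle(a, m, external_torque = ext, state = model_state(60),
                 method = "dynamic", t_max = 15)
    expect_lt(abs(st$angle - dy$angle), 0.5)
    ## settled states are fixed points
    st2 <- settle(a, m, external_torque = ext, state = st,
                  method = "static")
    expect_lt(abs(st2$angle - st$angle), 1e-6)
  }
})

test_that("mechanical energy dissipates under constant inputs", {
  ## model variant with angle-independent fiber lengths below optimum, so
  ## passive muscle forces vanish and every energy store is accounted for
  params <- yaml::read_yaml(system.file("extdata",
                                        "knee_params_default.yaml",
                                        package = "synergylab"))
  for (mus in names(params$muscles))
    params$muscles[[mus]]$fiberlen_affine <- list(0.9, 0.0)
  m <- knee_model(params)
  I <- m$limb$inertia_kgm2
  ext <- 15
  energy <- function(s) {
    th <- s$angle * pi / 180
    v <- s$velocity * pi / 180
    pot_stop <- if (s$angle > 120)
      0.5 * m$limb$stop_stiffness_nm_per_deg * (180 / pi) *
        (th - 120 * pi / 180)^2
    else if (s$angle < 0)
      0.5 * m$limb$stop_stiffness_nm_per_deg * (180 / pi) * th^2
    else 0
    0.5 * I * v^2 - ext * th + pot_stop
  }
  s <- model_state(30, 0)
  prev <- energy(s)
  drops <- logical(0)
  for (k in 1:50) {
    for (i in 1:100) s <- step_state(s, rep(0, 7), m, external_torque = ext)
    e <- energy(s)
    drops <- c(drops, e <= prev + 1e-9)
    prev <- e
  }
  expect_true(all(drops))
})

test_that("balancing torque matches the closed-form static oracle", {
  m <- default_model()
  expect_equal(balancing_torque(rep(0, 7), 60, m)$balancing_torque, 0)
  set.seed(4242)
  worst <- 0
  for (i in 1:50) {
    a <- runif(7)
    th <- sample(c(20, 60, 90), 1)
    got <- balancing_torque(a, th, m)
    oracle <- abs(oracle_extension_torque(m, a, th))
    err <- abs(got$balancing_torque - oracle)
    expect_lte(err, max(0.02 * oracle, 0.05))
    worst <- max(worst, err / max(oracle, 1e-12))
  }
  expect_lt(worst, 0.02)
})

test_that("balancing torque is monotone in uniform extensor scaling", {
  m <- default_model()
  base <- c(0.8, 0.7, 0.9, 0.1, 0.1, 0.1, 0.2)
  torques <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(sc) {
    a <- base
    a[1:3] <- base[1:3] * sc
    balancing_torque(a, 60, m)$balancing_torque
  }, numeric(1))
  expect_true(all(diff(torques) >= 0))
})

test_that("torque measurement is deterministic", {
  m <- default_model()
  a <- natural_activation(60)
  t1 <- balancing_torque(a, 60, m)
  t2 <- balancing_torque(a, 60, m)
  expect_identical(t1, t2)
})
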