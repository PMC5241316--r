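test_that("membrane update follows leaky Euler integration", {
  p <- model_params()
  # V = 1, no input, no noise, tau = 2.5 -> 0.6 after one step
  expect_equal(membrane_step(1, 0, tau = 2.5, k1 = p$k1), 0.6)
  # zero is a fixed point
  expect_equal(membrane_step(0, 0, tau = 2.5, k1 = p$k1), 0)
  # closed-form geometric decay over n steps
  V <- 1
  for (i in 1:7) V <- membrane_step(V, 0, tau = 2.5, k1 = p$k1)
  expect_equal(V, (1 - 1 / 2.5)^7, tolerance = 1e-12)
  # constant effective input: V converges to k1 * c
  V <- 0
  for (i in 1:250) V <- membrane_step(V, 30, tau = 2.5, k1 = p$k1)
  expect_equal(V, p$k1 * 30, tolerance = 1e-6)
})

test_that("spike output is strictly threshold-gated with adaptation", {
  p <- model_params()
  expect_equal(excitatory_output(0.19, 0, p), 1)   # 0.19 > 0.18
  expect_equal(excitatory_output(0.18, 0, p), 0)   # strict inequality
  expect_equal(excitatory_output(0.25, 0.01, p), 0) # 0.25 - 7*0.01 = 0.18
  expect_equal(excitatory_output(c(1, -1, 0.2), c(0, 0, 0), p), c(1, 0, 1))
})

test_that("inhibitory output is rectified-linear", {
  expect_equal(inhibitory_output(-0.3), 0)
  expect_equal(inhibitory_output(0), 0)
  expect_equal(inhibitory_output(0.42), 0.42)
})

test_that("low-pass estimators stay in [0,1] and decay geometrically", {
  p <- model_params()
  # constant 0 input: stays 0
  expect_equal(update_adaptation(0, 0, p), 0)
  # constant 1 input: monotone rise, asymptote 1, never exceeds 1
  om <- 0; prev <- -1
  ok <- TRUE
  for (i in 1:400) {
    om <- update_adaptation(om, 1, p)
    ok <- ok && om <= 1 && om >= prev && (om > prev || om > 1 - 1e-12)
    prev <- om
  }
  expect_true(ok)
  expect_equal(om, 1, tolerance = 1e-12)
  # single spike then silence: factor (1 - 1/tau) per step
  om <- update_adaptation(0, 1, p)
  expect_equal(om, 1 / p$tau_adapt)
  om2 <- update_adaptation(om, 0, p)
  expect_equal(om2, om * (1 - 1 / p$tau_adapt))
  # arbitrary {0,1} spike trains keep omega in [0,1]
  set.seed(1)
  om <- 0
  for (s in rbinom(500, 1, 0.5)) {
    om <- update_rate_estimate(om, s, p)
    expect_true(om >= 0 && om <= 1)
  }
})

test_that("global inhibition is a per-area low-pass of total spiking", {
  p <- model_params()
  area_of <- rep(1:2, each = 4)
  # no spikes ever -> stays 0
  expect_equal(update_global_inhibition(c(0, 0), numeric(8), area_of, p),
               c(0, 0))
  # sustained r spikes/step in area 1 converges to r; area 2 untouched
  og <- c(0, 0)
  phi <- c(1, 1, 1, 0, 0, 0, 0, 0)
  for (i in 1:600) og <- update_global_inhibition(og, phi, area_of, p)
  expect_equal(og, c(3, 0), tolerance = 1e-9)
  # burst then silence: exponential decay with tau_glob
  og2 <- update_global_inhibition(og, numeric(8), area_of, p)
  expect_equal(og2[1], og[1] * (1 - 1 / p$tau_glob))
  # area-locality within one step: perturbing spikes in area 1 never
  # changes area 2's accumulator
  og_a <- update_global_inhibition(c(1, 2), c(1, 1, 0, 0, 0, 1, 0, 0), area_of, p)
  og_b <- update_global_inhibition(c(1, 2), c(0, 0, 1, 1, 0, 1, 0, 0), area_of, p)
  expect_equal(og_a[2], og_b[2])
})

test_that("net input sums weighted presynaptic outputs", {
  cn <- toy_connectome(3)
  p <- model_params()
  st <- new_state(cn)
  # all outputs zero, no stimulus -> zero net input everywhere
  ni <- net_input(st, cn, NULL, p)
  expect_equal(ni$e, numeric(cn$n_exc))
  expect_equal(ni$i, numeric(cn$n_exc))
  # single presynaptic spike on a known link contributes its weight
  W <- cn$W_ee
  pre <- rep(seq_len(ncol(W)), diff(W@p))
  k <- which.max(W@x)                  # an arbitrary existing link
  st1 <- st
  st1$phi_e[pre[k]] <- 1
  ni1 <- net_input(st1, cn, NULL, p)
  expect_equal(ni1$e[W@i[k] + 1L], sum(W@x[pre == pre[k] & W@i == W@i[k]]))
  # random outputs: equals a naive dense double loop
  set.seed(8)
  st2 <- st
  st2$phi_e <- as.numeric(runif(cn$n_exc) < 0.3)
  st2$phi_i <- pmax(rnorm(cn$n_exc, 0, 0.1), 0)
  st2$omega_G <- runif(nrow(cn$areas))
  ext <- runif(cn$n_exc)
  ni2 <- net_input(st2, cn, ext, p)
  Wd <- as.matrix(cn$W_ee)
  expected <- numeric(cn$n_exc)
  for (x in seq_len(cn$n_exc)) {
    s <- 0
    for (y in seq_len(cn$n_exc)) s <- s + Wd[x, y] * st2$phi_e[y]
    expected[x] <- s - cn$g_ie * st2$phi_i[x] -
      p$kG * st2$omega_G[cn$area_of[x]] + ext[x]
  }
  expect_equal(ni2$e, expected, tolerance = 1e-12)
  # dimension mismatch is fatal
  bad <- new_state(cn); bad$V_e <- numeric(3)
  expect_error(net_input(bad, cn, NULL, p), "dimension mismatch")
})

test_that("compiled engine reproduces the scalar reference step-for-step", {
  cn <- toy_connectome(5)
  p <- set_mode(model_params(), "learning")
  st0 <- new_state(cn)
  st0$V_e <- runif(cn$n_exc, -0.1, 0.3)   # arbitrary start state
  set.seed(99)
  eng <- simulate_steps(st0, cn, p, 25, learn = TRUE)
  set.seed(99)
  st <- st0; cc <- cn
  for (i in 1:25) {
    out <- step_network(st, cc, p, learn = TRUE)
    st <- out$state; cc <- out$connectome
  }
  expect_equal(eng$state$V_e, st$V_e, tolerance = 1e-12)
  expect_equal(eng$state$V_i, st$V_i, tolerance = 1e-12)
  expect_equal(eng$state$omega, st$omega, tolerance = 1e-12)
  expect_equal(eng$state$omega_E, st$omega_E, tolerance = 1e-12)
  expect_equal(eng$state$omega_G, st$omega_G, tolerance = 1e-12)
  expect_equal(eng$connectome$W_ee@x, cc$W_ee@x, tolerance = 1e-12)
  # recorded S-ERP equals the direct per-area sum of potentials
  sums <- vapply(seq_len(nrow(cn$areas)),
                 function(a) sum(st$V_e[cn$area_of == a]), numeric(1))
  expect_equal(eng$serp[, 25], sums, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("two consecutive engine calls equal one longer call", {
  cn <- toy_connectome(6)
  p <- model_params()
  set.seed(7)
  one <- simulate_steps(new_state(cn), cn, p, 30)
  set.seed(7)
  a <- simulate_steps(new_state(cn), cn, p, 18)
  b <- simulate_steps(a$state, cn, p, 12)
  expect_identical(one$state$V_e, b$state$V_e)
  expect_identical(cbind(a$serp, b$serp), one$serp)
})

test_that("fixed seed gives a bit-identical trajectory", {
  cn <- toy_connectome(2)
  p <- model_params()
  set.seed(123)
  r1 <- simulate_steps(new_state(cn), cn, p, 40)
  set.seed(123)
  r2 <- simulate_steps(new_state(cn), cn, p, 40)
  expect_identical(r1$state, r2$state)
  expect_identical(r1$serp, r2$serp)
})

test_that("with zero weights, noise and stimulus the state decays to zero", {
  cn <- toy_connectome(4)
  cn$W_ee@x[] <- 0
  cn$W_ei@x[] <- 0
  cn$g_ie <- 0
  p <- model_params(k2 = 0)
  st <- new_state(cn)
  st$V_e[] <- 0.5; st$V_i[] <- 0.3; st$omega[] <- 0.4
  st$omega_E[] <- 0.2; st$omega_G[] <- 1
  prev <- st
  for (i in 1:12) {
    st <- simulate_steps(st, cn, p, 1, record = FALSE)$state
    expect_true(all(st$V_e <= prev$V_e + 1e-15), info = "V_e monotone")
    expect_true(all(st$omega <= prev$omega + 1e-15))
    expect_true(all(st$omega_G <= prev$omega_G + 1e-15))
    prev <- st
  }
  st <- simulate_steps(st, cn, p, 400, record = FALSE)$state
  expect_lt(max(abs(st$V_e)), 1e-10)
  expect_lt(max(abs(st$omega_G)), 1e-10)
  # exactly zero start state stays exactly zero
  z <- simulate_steps(new_state(cn), cn, p, 10, record = FALSE)$state
  expect_equal(z$V_e, numeric(cn$n_exc))
})

test_that("no spikes occur when max(V - alpha*omega) is below threshold", {
  cn <- toy_connectome(10)
  p <- model_params(k2 = 0)
  st <- new_state(cn)
  st$V_e <- runif(cn$n_exc, 0, p$thresh)   # all subthreshold
  r <- simulate_steps(st, cn, p, 5)
  expect_true(all(r$spikes == 0))
})

test_that("non-finite state aborts with the step index", {
  cn <- toy_connectome(11)
  st <- new_state(cn)
  st$V_e[1] <- Inf
  expect_error(simulate_steps(st, cn, model_params(), 3),
               "non-finite membrane potential at step 1")
})
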