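test_that("derivatives implement the coupled length, width and protein dynamics", {
  p <- model_params(k = 0.75)
  st <- cell_state(L = 3, w = 0.8)
  d <- cell_derivatives(st, p)
  expect_equal(d$dL, 0.75 * 3)
  expect_equal(d$dP, p$kP * 3)
  # width rate vanishes exactly at the fixed point w = 4k/beta, any L > w
  wss <- steady_state_width(p)
  for (L in c(2, 5, 40)) {
    expect_equal(cell_derivatives(cell_state(L = L, w = wss), p)$dw, 0)
  }
  # with w << L the shape factor tends to 1
  d2 <- cell_derivatives(cell_state(L = 1e4, w = 0.8), p)
  expect_equal(d2$dw, 0.8 * (p$k - p$beta * 0.8 / 4), tolerance = 1e-4)
})

test_that("two-component protein pool is conserved when production stops", {
  p <- model_params(k = 0.75, kP = 0, mode = "two_component")
  d <- cell_derivatives(cell_state(L = 3, w = 0.8, Pc = 2, Pr = 1), p)
  expect_equal(d$dPc + d$dPr, 0)
})

test_that("surface-synthesis rate follows the linear growth-rate relation", {
  expect_equal(beta_of_k(0), 0.996)
  expect_equal(beta_of_k(1), 4.697)
  expect_equal(beta_of_k(0.75), 3.77175)
  expect_error(beta_of_k(-1), ">= 0")
})

test_that("steady-state width is 4k/beta and depends only on the ratio", {
  p <- model_params(k = 0.75, beta = 3.7718)
  expect_equal(steady_state_width(p), 4 * 0.75 / 3.7718)
  p2 <- model_params(k = 1.5, beta = 2 * 3.7718)
  expect_equal(steady_state_width(p2), steady_state_width(p))
  expect_error(
    steady_state_width(model_params(k = 1, beta = 0)),
    "beta"
  )
})

test_that("the analytic cycle is an adder: added length ignores birth length", {
  p <- model_params(k = 0.75)
  a1 <- analytic_cycle(p, L_birth = 1, w = 0.8)
  a2 <- analytic_cycle(p, L_birth = 2, w = 0.8)
  expect_equal(a1$delta_L, a2$delta_L)
  expect_equal(a1$delta_L, p$rho * pi * 0.8 * p$k / p$kP)
  # doubling kP halves the added length (dL/dP = k/kP)
  p2 <- model_params(k = 0.75, kP = 2 * p$kP)
  expect_equal(analytic_cycle(p2, 1, 0.8)$delta_L, a1$delta_L / 2)
  # division time: longer-born cells divide sooner
  expect_gt(a1$T_div, a2$T_div)
})

test_that("stepping reproduces the analytic division time and added length", {
  p <- model_params(k = 0.75, delta_sigma = 0, width_dynamics = FALSE)
  w <- 0.8
  L0 <- 1.7
  ref <- analytic_cycle(p, L0, w)
  st <- cell_state(L = L0, w = w)
  dt <- default_dt(p)
  ev <- NULL
  for (i in 1:5000) {
    step <- advance_cell(st, p, dt)
    st <- step$state
    if (!is.null(step$event)) {
      ev <- step$event
      break
    }
  }
  expect_false(is.null(ev))
  expect_rel(ev$time_h, ref$T_div, 1e-6)
  expect_rel(ev$mother_length_um - L0, ref$delta_L, 1e-6)
  # noise-free division is exactly symmetric and conserves length
  expect_equal(ev$daughter_fraction, 0.5)
  expect_equal(ev$newborn_length_um, ev$mother_length_um / 2)
})

test_that("added length is constant across cycles with random birth lengths", {
  p <- model_params(k = 0.75, delta_sigma = 0, width_dynamics = FALSE)
  set.seed(5)
  n <- 100
  w <- 0.8
  births <- runif(n, 1.2, 4)
  st <- cell_state(L = births, w = rep(w, n), generation = rep(0L, n))
  deltas <- rep(NA_real_, n)
  for (i in 1:2500) {
    step <- advance_cell(st, p, 0.001)
    ev <- step$event
    if (!is.null(ev)) {
      first <- ev$generation == 1L
      deltas[ev$cell[first]] <- ev$mother_length_um[first] - births[ev$cell[first]]
    }
    st <- step$state
    if (!any(is.na(deltas))) break
  }
  expect_false(any(is.na(deltas)))
  target <- p$rho * pi * w * p$k / p$kP
  # the adder: every cycle adds the same length, whatever the birth length
  expect_lt((max(deltas) - min(deltas)) / mean(deltas), 1e-6)
  expect_rel(mean(deltas), target, 1e-6)
})

test_that("zero production means no division and unbounded elongation", {
  p <- model_params(k = 0.75, kP = 0, delta_sigma = 0, width_dynamics = FALSE)
  st <- cell_state(L = 2, w = 0.8)
  for (i in 1:200) {
    step <- advance_cell(st, p, 0.01)
    expect_null(step$event)
    st <- step$state
  }
  expect_equal(st$L, 2 * exp(0.75 * 2), tolerance = 1e-9)
})

test_that("a step spanning two divisions is rejected", {
  p <- model_params(k = 0.75, delta_sigma = 0, width_dynamics = FALSE)
  st <- cell_state(L = 2.26, w = 0.8)
  expect_error(advance_cell(st, p, 10), "two divisions")
})

test_that("two-component division time converges to the simple-mode time", {
  k <- 0.75
  w <- 0.8
  L0 <- 2
  simple <- model_params(k = k, delta_sigma = 0, width_dynamics = FALSE)
  ref <- analytic_cycle(simple, L0, w)
  t_div_at <- function(kb_mult) {
    two <- model_params(
      k = k, kP = simple$kP, kb = kb_mult * k, kd = kb_mult * k / 1000,
      delta_sigma = 0, mode = "two_component", width_dynamics = FALSE
    )
    st <- cell_state(L = L0, w = w)
    dt <- 2e-4
    for (i in 1:10000) {
      step <- advance_cell(st, two, dt)
      st <- step$state
      if (!is.null(step$event)) {
        return(step$event$time_h)
      }
    }
    NA_real_
  }
  gaps <- vapply(
    c(100, 300, 1000),
    function(m) abs(t_div_at(m) - ref$T_div) / ref$T_div, numeric(1)
  )
  # the lag scales as 1/(kb * T): fast binding recovers the simple mode
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[1], 0.02)
  expect_lt(gaps[2], 0.007)
  expect_lt(gaps[3], 0.003)
})

test_that("width ODE trajectory matches an independent stiff-solver integration", {
  skip_if_not_installed("deSolve")
  p <- model_params(k = 0.75, kP = 0) # no division: pure growth
  rhs <- function(t, y, parms) {
    L <- y[1]
    w <- y[2]
    shape <- (1 - w / (3 * L)) / (1 - w / L)
    list(c(p$k * L, w * (p$k - p$beta * w / 4) * shape))
  }
  sol <- deSolve::lsoda(
    y = c(L = 3, w = 1.3), times = seq(0, 3, by = 0.5),
    func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-12
  )
  st <- cell_state(L = 3, w = 1.3)
  dt <- 0.001
  ours <- matrix(NA_real_, nrow = 7, ncol = 2)
  ours[1, ] <- c(3, 1.3)
  row <- 2
  for (i in 1:3000) {
    st <- advance_cell(st, p, dt)$state
    if (abs(st$t %% 0.5) < dt / 2 || abs(st$t %% 0.5 - 0.5) < dt / 2) {
      ours[row, ] <- c(st$L, st$w)
      row <- row + 1
      if (row > 7) break
    }
  }
  expect_lt(max(abs(ours[, 2] - sol[, "w"])), 1e-6)
  expect_lt(max(abs(ours[, 1] - sol[, "L"]) / sol[, "L"]), 1e-6)
})

test_that("the width fixed point is stable from a wide basin", {
  p <- model_params(k = 0.75, delta_sigma = 0)
  wss <- steady_state_width(p)
  for (w0 in c(0.5, 1.1, 2)) {
    lin <- simulate_lineage(p, n_generations = 14, L0 = 3 * w0, w0 = w0)
    expect_rel(lin$mean_width_um[14], wss, 0.005)
    # convergence is monotone: the gap to the fixed point shrinks
    gaps <- abs(lin$mean_width_um - wss)
    expect_true(all(diff(gaps) < 1e-9))
  }
})

test_that("noise-free cycles relax geometrically to a strict limit cycle", {
  p <- model_params(k = 0.75, delta_sigma = 0, width_dynamics = FALSE)
  lin <- simulate_lineage(p, n_generations = 30, L0 = 1.4, w0 = 0.9)
  births <- lin$birth_length_um
  # adder dynamics: the distance to the fixed point halves every generation
  gap <- abs(births - births[30])
  expect_rel(gap[5] / gap[6], 2, 0.01)
  expect_rel(births[30], births[29], 1e-6)
  periods <- diff(lin$division_time_h)
  expect_rel(periods[29], log(2) / p$k, 1e-6)
})

test_that("division-asymmetry noise is truncated and conserves length", {
  p <- model_params(k = 0.75, delta_sigma = 0.2, width_dynamics = FALSE)
  lin <- simulate_lineage(p, n_generations = 60, seed = 6, w0 = 1)
  # every birth is a fraction of the mother within the truncation band
  frac <- lin$birth_length_um[-1] / lin$division_length_um[-60]
  expect_true(all(frac >= 0.1 & frac <= 0.9))
  # adder survives the noise: delta L has (almost) no variance
  expect_lt(
    stats::sd(lin$delta_L_um) / mean(lin$delta_L_um), 1e-9
  )
  expect_gt(stats::sd(lin$birth_length_um) / mean(lin$birth_length_um), 0.05)
})

test_that("parameter validation catches out-of-range inputs", {
  expect_error(model_params(k = 0), "k must be")
  expect_error(model_params(delta_sigma = 0.5), "delta_sigma")
  expect_error(model_params(k = 1, kb = -1), "kb")
  expect_error(cell_state(L = 0.5, w = 1), "L >= w")
  expect_error(advance_cell(cell_state(2, 1), model_params(), -0.1), "dt")
})
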