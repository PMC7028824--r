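test_that("uv_exposure implements the three exposure modes", {
  lat <- build_lattice(c(32, 32, 32))
  none <- uv_exposure(lat, rate_model(0.01, uv_mode = "none"))
  expect_true(all(none == 0))

  surf <- uv_exposure(lat, rate_model(0.01, alpha = 0.1,
                                      uv_mode = "surface"))
  expect_equal(sum(surf == 1), 1024)          # the 32 x 32 top layer
  expect_true(all(surf %in% c(0, 1)))
  expect_true(all(lat$coords[surf == 1, 3] == 1))

  att <- uv_exposure(lat, rate_model(0.01, alpha = 0.1, beta = 1,
                                     uv_mode = "attenuated"))
  expect_equal(att[lat$coords[, 3] == 1][1], 1)         # zhat = 0 -> e^0
  expect_equal(att[lat$coords[, 3] == 0][1], exp(-1))   # zhat = 1
  expect_equal(unname(range(att)), c(exp(-1), 1))
})

test_that("node_rate follows the distance-weighted neighbour law plus UV term", {
  # k cancerous face-neighbours at spacing h contribute k * lambda / h
  lat <- build_lattice(32L)       # 1-D, h = 1/31
  st <- initial_state(lat, seeds = c(1L, 3L))
  uv <- uv_exposure(lat, rate_model(0.01))
  expect_equal(node_rate(st, lat, rate_model(0.01), uv, 2L), 0.62)

  # no cancerous neighbours, uv none -> 0; cancerous node -> 0
  st0 <- initial_state(lat)
  expect_equal(node_rate(st0, lat, rate_model(0.01), uv, 2L), 0)
  expect_equal(node_rate(st, lat, rate_model(0.01), uv, 1L), 0)

  # mixed distances with a unit UV factor: 0.01*(1/0.5 + 1/0.25) + 0.1*1
  lat2 <- build_lattice(c(3, 3), extent = list(c(0, 1), c(0, 0.5)))
  expect_equal(lat2$spacing, c(0.5, 0.25))
  m <- rate_model(0.01, alpha = 0.1, beta = 2, uv_mode = "attenuated",
                  depth_axis = 2L)
  uv2 <- uv_exposure(lat2, m)
  st2 <- initial_state(lat2, seeds = c(5L, 7L))  # below (d=.25), left (d=.5)
  expect_equal(uv2[8L], 1)                        # node 8 on the top edge
  expect_equal(node_rate(st2, lat2, m, uv2, 8L), 0.16)

  # uniform validation mode ignores neighbours entirely
  mu <- rate_model(0.01, mode = "uniform")
  expect_equal(node_rate(st0, lat, mu, uv, 2L), 0.01)
})

test_that("transition_probability is the exponential-clock law", {
  expect_equal(transition_probability(0, 5), 0)
  expect_equal(transition_probability(0.01, 1), 1 - exp(-0.01))
  expect_equal(transition_probability(1e9, 1), 1)       # immediate a.s.
  # first-order expansion for small rate * tau
  expect_equal(transition_probability(1e-8, 1), 1e-8, tolerance = 1e-7)
  expect_error(transition_probability(-1, 1), "non-negative")
  expect_error(transition_probability(1, 0), "positive")
})

test_that("step_fixed_tau flips at the exponential frequency and freezes rates", {
  lat <- build_lattice(2L)
  m <- rate_model(0.8)
  uv <- uv_exposure(lat, m)
  tau <- 0.7
  set.seed(402)
  flips <- replicate(2000, {
    st <- initial_state(lat, seeds = 1L)
    length(step_fixed_tau(st, lat, m, uv, tau)$flipped)
  })
  p_hat <- mean(flips)
  p_exp <- transition_probability(m$lambda / 1, tau)
  se <- sqrt(p_exp * (1 - p_exp) / 2000)
  expect_lt(abs(p_hat - p_exp), 3 * se)

  # absorbing state: nothing changes, time advances
  st_all <- list(S = rep(1L, 2), t = 1)
  out <- step_fixed_tau(st_all, lat, m, uv, tau)
  expect_identical(out$state$S, st_all$S)
  expect_equal(out$state$t, 1 + tau)
})

test_that("trajectories are irreversible with non-decreasing counts", {
  set.seed(403)
  lat <- build_lattice(c(6, 6, 6))
  for (sampler in c("fixed_tau", "event_driven")) {
    tr <- simulate_growth(lat, rate_model(0.05), seeds = "center",
                          stop_fraction = 1, sampler = sampler)
    expect_false(any(duplicated(tr$nodes)))      # each node flips once
    expect_true(all(diff(tr$times) >= 0))
    expect_true(all(diff(tr$step_counts) >= 0))
    expect_equal(length(tr$times) + tr$n0, lat$n)
    cu <- fraction_curve(tr)
    expect_true(all(cu$fraction >= 0 & cu$fraction <= 1))
  }
})

test_that("zero hazard stagnates explicitly; empty seeds without UV warn", {
  lat <- build_lattice(c(3, 3))
  expect_warning(
    expect_error(simulate_growth(lat, rate_model(0.01), seeds = integer(0)),
                 class = "skinmarkov_stagnation"),
    "never change")
  expect_error(
    suppressWarnings(simulate_event_driven(lat, rate_model(0.01))),
    class = "skinmarkov_stagnation")
})

test_that("two-node mean transition time is 1/lambda (both samplers)", {
  lat <- build_lattice(2L)
  lambda <- 2
  set.seed(404)
  t_ev <- replicate(3000, simulate_event_driven(
    lat, rate_model(lambda), seeds = 1L, stop_fraction = 1)$times[1])
  expect_lt(abs(mean(t_ev) - 1 / lambda),
            3 * sd(t_ev) / sqrt(length(t_ev)))
  # the waiting time is Exponential(lambda): check the spread too
  expect_lt(abs(sd(t_ev) - 1 / lambda), 4 * sd(t_ev) / sqrt(length(t_ev)))

  t_fx <- replicate(1500, time_to_fraction(simulate_growth(
    lat, rate_model(lambda), seeds = 1L, stop_fraction = 1,
    tau_control = tau_rule(c = 0.01)), 1))
  expect_lt(abs(mean(t_fx) - 1 / lambda),
            3 * sd(t_fx) / sqrt(length(t_fx)) + 0.01 / lambda)
})

test_that("UV-only transition times at depth are exponential with rate alpha*exp(-beta*zhat)", {
  # lambda-term effectively disabled by seeding nothing on a 1-D column
  lat <- build_lattice(c(2, 5), extent = list(c(0, 1), c(0, 1)))
  m <- rate_model(lambda = 1e-9, alpha = 0.8, beta = 1.2,
                  uv_mode = "attenuated", depth_axis = 2L)
  set.seed(405)
  # first flip of the top row vs a bottom row node: compare means
  n_rep <- 2500
  uv <- uv_exposure(lat, m)
  top <- which(uv == 1)[1]
  bottom <- which.min(uv)
  tt <- replicate(n_rep, {
    tr <- simulate_event_driven(lat, m, stop_fraction = 1)
    c(tr$times[match(top, tr$nodes)], tr$times[match(bottom, tr$nodes)])
  })
  # per-node clocks are independent exponentials: mean time e^{beta*zhat}/alpha
  for (k in 1:2) {
    zhat <- c(0, 1)[k]
    expected <- exp(m$beta * zhat) / m$alpha
    expect_lt(abs(mean(tt[k, ]) - expected),
              3 * sd(tt[k, ]) / sqrt(n_rep))
  }
})

test_that("time_to_fraction reads the first crossing", {
  tr <- fake_trajectory(times = c(1, 2, 3), n = 4L, n0 = 1L)
  expect_equal(time_to_fraction(tr, 0.5), 1)   # 2 of 4 nodes at t = 1
  expect_equal(time_to_fraction(tr, 0.25), 0)  # start already satisfies
  expect_equal(time_to_fraction(tr, 1), 3)
  tr2 <- fake_trajectory(times = c(1, 2), n = 8L, n0 = 1L)
  expect_true(is.na(time_to_fraction(tr2, 1)))  # stopped before full cancer
  expect_error(time_to_fraction(tr, 0), "\\(0, 1]")
})

test_that("cancer_fraction averages the binary flags", {
  expect_equal(cancer_fraction(rep(0L, 5)), 0)
  expect_equal(cancer_fraction(rep(1L, 5)), 1)
  expect_equal(cancer_fraction(c(1, 1, 1, 0, 0, 0, 0, 0)), 0.375)
  expect_error(cancer_fraction(integer(0)), "empty")
})
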