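# Shared builders for the test suite. All fixtures are generated in code.

unit_lattice <- function(m, d = 1L, adjacency = "face") {
  build_lattice(rep(m, d), adjacency = adjacency)
}

# Trajectory object with a prescribed event list (for pure-accessor tests).
fake_trajectory <- function(times, n, n0 = 1L, nodes = seq_along(times),
                            sampler = "fixed_tau") {
  structure(list(times = as.numeric(times), nodes = as.integer(nodes),
                 step_times = as.numeric(times),
                 step_counts = n0 + seq_along(times),
                 n = n, n0 = n0, t_end = max(c(0, times)),
                 sampler = sampler, tau = NULL, stop_count = n),
            class = "trajectory")
}

# Mean first-passage time to a target fraction over replicate runs.
mean_Tf <- function(lattice, model, reps, f = 0.5, seeds = integer(0),
                    stop_count = NULL, tau_control = tau_rule()) {
  target <- if (is.null(stop_count)) f else stop_count / lattice$n
  mean(vapply(seq_len(reps), function(i) {
    tr <- simulate_growth(lattice, model, seeds = seeds,
                          stop_fraction = f, stop_count = stop_count,
                          tau_control = tau_control)
    time_to_fraction(tr, target)
  }, numeric(1)))
}

# Counts sign changes of the (smoothed) curvature of a fraction curve;
# an S-shaped curve has exactly one, from convex to concave.
curvature_changes <- function(traj, grid = 50, win = 11, thr = 0.08) {
  cu <- fraction_curve(traj)
  tg <- seq(0, time_to_fraction(traj, 0.99), length.out = grid)
  fg <- approx(cu$time, cu$fraction, xout = tg, method = "constant",
               rule = 2, ties = max, f = 0)$y
  fs <- stats::filter(fg, rep(1 / win, win), sides = 2)
  fs <- fs[!is.na(fs)]
  d2 <- diff(fs, differences = 2)
  sgn <- sign(d2[abs(d2) > thr * max(abs(d2))])
  list(changes = sum(diff(sgn) != 0), first = sgn[1L],
       last = sgn[length(sgn)])
}

config_lattice_for_test <- function(cfg) {
  build_lattice(unlist(cfg$lattice$nodes_per_axis),
                adjacency = cfg$lattice$adjacency)
}
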