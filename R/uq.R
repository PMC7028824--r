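#' Input-parameter distributions for Monte Carlo studies
#'
#' Each of the base rate `lambda`, the UV sensitivity `alpha` and the UV
#' attenuation `beta` is drawn from an independent normal distribution.
#' Draws violating positivity (`lambda <= 0`, `alpha < 0`, `beta < 0`) are
#' handled by the truncation policy: `"resample"` (default; the marginal is
#' a truncated normal) or `"clip"` (values clamped at the boundary).
#'
#' The default means and spreads are the study values
#' `lambda ~ N(0.005, 0.001^2)`, `alpha ~ N(0.1, 0.02^2)`,
#' `beta ~ N(3, 0.6^2)`, each spread being 20% of the mean and read as a
#' standard deviation (`spread = "sd"`); set `spread = "variance"` to read
#' the second entries as variances instead.
#'
#' @param lambda,alpha,beta length-2 numerics `c(mean, spread)`.
#' @param spread `"sd"` or `"variance"`.
#' @param truncation `"resample"` or `"clip"`.
#' @export
parameter_dists <- function(lambda = c(0.005, 0.001),
                            alpha = c(0.1, 0.02),
                            beta = c(3, 0.6),
                            spread = c("sd", "variance"),
                            truncation = c("resample", "clip")) {
  spread <- match.arg(spread)
  truncation <- match.arg(truncation)
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2L || x[2L] < 0)
      stop(sprintf("`%s` must be c(mean, spread) with spread >= 0", nm),
           call. = FALSE)
    sdv <- if (spread == "variance") sqrt(x[2L]) else x[2L]
    c(mean = x[1L], sd = sdv)
  }
  if (lambda[1L] <= 0)
    stop("mean of `lambda` must be positive", call. = FALSE)
  structure(list(lambda = chk(lambda, "lambda"), alpha = chk(alpha, "alpha"),
                 beta = chk(beta, "beta"), truncation = truncation),
            class = "parameter_dists")
}

#' Draw admissible parameter triples
#'
#' @param dists a [parameter_dists()].
#' @param n number of draws.
#' @return data.frame with columns `lambda`, `alpha`, `beta`; every row is
#'   admissible for [rate_model()]. A warning is raised when rejection
#'   resampling discards more than half of the raw draws (the distribution
#'   is then inconsistent with the positivity constraint).
#' @export
sample_parameters <- function(dists, n = 1L) {
  stopifnot(inherits(dists, "parameter_dists"), n >= 1L)
  draw <- function(spec, lower_open) {
    x <- rnorm(n, spec["mean"], spec["sd"])
    bad <- if (lower_open) x <= 0 else x < 0
    if (dists$truncation == "clip") {
      x[bad] <- if (lower_open) .Machine$double.eps else 0
      return(x)
    }
    attempts <- n
    while (any(bad)) {
      x[bad] <- rnorm(sum(bad), spec["mean"], spec["sd"])
      attempts <- attempts + sum(bad)
      bad <- if (lower_open) x <= 0 else x < 0
      if (attempts > 1000 * n + 1000)
        stop("rejection sampling failed to produce admissible draws",
             call. = FALSE)
    }
    if (attempts > 2 * n)
      warning(paste("more than half of the raw draws violated positivity;",
                    "the distribution is inconsistent with the constraint"),
              call. = FALSE)
    x
  }
  data.frame(lambda = draw(dists$lambda, lower_open = TRUE),
             alpha = draw(dists$alpha, lower_open = FALSE),
             beta = draw(dists$beta, lower_open = FALSE))
}

#' Monte Carlo mean of first-passage times
#' @param samples numeric vector of `T_f` values (at least one).
#' @export
mc_mean <- function(samples) {
  if (length(samples) < 1L) stop("need at least one sample", call. = FALSE)
  mean(samples)
}

#' Monte Carlo Error
#'
#' The standard error of the Monte Carlo mean from a single batch:
#' `MCE_N = s_N / sqrt(N) = sqrt(sum (T_j - mean)^2 / (N (N - 1)))` with
#' the `N - 1` sample variance. A biased but consistent estimator of the
#' standard deviation of the mean.
#'
#' @param samples numeric vector of `T_f` values (at least two).
#' @export
mc_error <- function(samples) {
  if (length(samples) < 2L) stop("need at least two samples", call. = FALSE)
  sd(samples) / sqrt(length(samples))
}

#' Empirical cumulative distribution of first-passage times
#'
#' `F_N(T) = (1/N) * sum_j 1[T_j <= T]`: the fraction of trials in which
#' the target fraction was reached by time `T`. Vectorised over `T`.
#'
#' @param samples numeric vector of `T_f` values (at least one).
#' @param T evaluation time(s).
#' @export
empirical_cdf <- function(samples, T) {
  if (length(samples) < 1L) stop("need at least one sample", call. = FALSE)
  vapply(T, function(tt) mean(samples <= tt), numeric(1L))
}

#' Run a Monte Carlo uncertainty-quantification study
#'
#' Repeats the lattice simulation `N` times. Trial `j` seeds the RNG
#' deterministically from `(seed, j)`, draws one `(lambda, alpha, beta)`
#' triple from `dists`, builds the rate model under the requested UV mode,
#' simulates from the all-susceptible initial state until the cancer
#' fraction reaches `f`, and records `T_f`. Trials that stagnate are
#' recorded as failed and excluded from the summaries (with a warning).
#'
#' @inheritParams simulate_growth
#' @param dists a [parameter_dists()].
#' @param N number of trials.
#' @param f target fraction (default 1/2).
#' @param seed integer RNG seed for the whole study.
#' @param uv_mode UV mode for every trial (default `"attenuated"`).
#' @param depth_axis depth axis passed to [rate_model()].
#' @return object of class `mc_study`: per-trial data.frame `trials`
#'   (`trial`, `lambda`, `alpha`, `beta`, `T_f`, `status`) and a `summary`
#'   list (`N_done`, `mean`, `s`, `mce`, and Pearson `r`/`p` per
#'   parameter).
#' @export
run_study <- function(lattice, dists, N, f = 0.5, seed = 1L,
                      uv_mode = "attenuated", depth_axis = NULL,
                      tau_control = tau_rule(), max_steps = 1e6L) {
  stopifnot(inherits(lattice, "skin_lattice"),
            inherits(dists, "parameter_dists"), N >= 1L)
  N <- as.integer(N)
  rows <- vector("list", N)
  for (j in seq_len(N)) {
    set.seed((seed + j) %% .Machine$integer.max)
    par <- sample_parameters(dists, 1L)
    model <- rate_model(lambda = par$lambda, alpha = par$alpha,
                        beta = par$beta, uv_mode = uv_mode,
                        depth_axis = depth_axis)
    traj <- tryCatch(
      simulate_growth(lattice, model, seeds = integer(0),
                      stop_fraction = f, tau_control = tau_control,
                      max_steps = max_steps),
      skinmarkov_stagnation = function(e) e)
    if (inherits(traj, "trajectory")) {
      rows[[j]] <- data.frame(trial = j, lambda = par$lambda,
                              alpha = par$alpha, beta = par$beta,
                              T_f = time_to_fraction(traj, f),
                              status = "ok")
    } else {
      rows[[j]] <- data.frame(trial = j, lambda = par$lambda,
                              alpha = par$alpha, beta = par$beta,
                              T_f = NA_real_, status = conditionMessage(traj))
    }
  }
  trials <- do.call(rbind, rows)
  study <- structure(list(trials = trials, N = N, f = f, seed = seed,
                          uv_mode = uv_mode, summary = NULL),
                     class = "mc_study")
  study$summary <- summarise_study(study)
  study
}

summarise_study <- function(study) {
  done <- study$trials[study$trials$status == "ok", ]
  n_fail <- study$N - nrow(done)
  if (n_fail > 0L)
    warning(sprintf("%d of %d trials failed and were excluded", n_fail,
                    study$N), call. = FALSE)
  if (nrow(done) == 0L) return(list(N_done = 0L))
  out <- list(N_done = nrow(done), mean = mc_mean(done$T_f),
              s = if (nrow(done) >= 2L) sd(done$T_f) else NA_real_,
              mce = if (nrow(done) >= 2L) mc_error(done$T_f) else NA_real_)
  if (nrow(done) >= 3L) {
    for (which in c("lambda", "alpha", "beta")) {
      ct <- correlate_vectors(done[[which]], done$T_f)
      out[[paste0("r_", which)]] <- ct$r
      out[[paste0("p_", which)]] <- ct$p
    }
  }
  out
}

#' Input-output correlation of a study
#'
#' Pearson product-moment correlation between one sampled input parameter
#' and the realised `T_f` across the completed trials, with the two-sided
#' p-value from the standard t transform (N - 2 degrees of freedom).
#'
#' @param study an `mc_study`.
#' @param which `"lambda"`, `"alpha"` or `"beta"`.
#' @return list with elements `r` and `p`.
#' @export
correlate <- function(study, which = c("lambda", "alpha", "beta")) {
  stopifnot(inherits(study, "mc_study"))
  which <- match.arg(which)
  done <- study$trials[study$trials$status == "ok", ]
  correlate_vectors(done[[which]], done$T_f)
}

correlate_vectors <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 completed trials",
                           call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in one of the series", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' @export
print.mc_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("mc_study: N=%d (done %d), f=%g\n", x$N, s$N_done, x$f))
  if (s$N_done >= 2L)
    cat(sprintf("  T_f mean=%.4f, s=%.4f, MCE=%.4f\n", s$mean, s$s, s$mce))
  if (!is.null(s$r_lambda))
    cat(sprintf("  r(lambda)=%.4f  r(alpha)=%.4f  r(beta)=%.4f\n",
                s$r_lambda, s$r_alpha, s$r_beta))
  invisible(x)
}
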