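# Stochastic clone-growth model. A clone starts from one cell; on each day
# t it gains an exponential number of population doublings r_t, so
# log2(N_t) = r_1 + ... + r_t ~ Gamma(shape t, rate lambda). The realized
# in vivo doubling time t / log2(N_t) therefore concentrates around the
# subpopulation's mean doubling time as t grows, with Gamma (asymptotically
# normal) fluctuations - the mechanism behind the multimodal doubling-time
# distributions seen across clones.

#' Growth-simulation limits
#'
#' Trajectories stop at the first limit reached: a cell capacity that
#' mimics the maximum permissible tumor size in mice, or a time stop.
#'
#' @param max_cells cell capacity (default 1e7).
#' @param max_days time stop in days (default 1e3).
#' @return A list of class `SimulationLimits`.
#' @export
sim_limits <- function(max_cells = 1e7, max_days = 1e3) {
  stopifnot(max_cells > 0, max_days > 0)
  structure(list(max_cells = max_cells, max_days = max_days),
            class = "SimulationLimits")
}

# Exponential rate for the daily doubling increments. The self-consistent
# convention draws increments with mean 1/mu doublings per day so the
# realized doubling time equals the configured mu; the literal convention
# uses rate 1/mu (mean mu doublings per day) instead.
increment_rate <- function(mu, rate_convention) {
  switch(rate_convention, per_day = mu, literal = 1 / mu,
         stop("unknown rate convention"))
}

#' Simulate one clone growth trajectory
#'
#' Daily exponential doubling increments are accumulated until the cell
#' capacity or the time stop is hit; the increment that crosses the
#' capacity is included. The realized doubling time is
#' `days / log2(final size)`.
#'
#' @param mu target mean doubling time in days (> 0).
#' @param limits a [sim_limits()] object.
#' @param seed integer seed.
#' @param rate_convention `"per_day"` (default; increments have mean `1/mu`
#'   doublings per day, so realized doubling times center on `mu`) or
#'   `"literal"` (increments have mean `mu`).
#' @return A list with `log2_sizes` (cumulative log2 cell numbers per day),
#'   `final_cells`, `days`, and `doubling_time` (NA when no doubling
#'   occurred, i.e. `days = 0`).
#' @export
simulate_clone_trajectory <- function(mu, limits = sim_limits(), seed = NULL,
                                      rate_convention = c("per_day",
                                                          "literal")) {
  rate_convention <- match.arg(rate_convention)
  stopifnot(mu > 0, inherits(limits, "SimulationLimits"))
  lambda <- increment_rate(mu, rate_convention)
  log2_cap <- log2(limits$max_cells)
  with_seed(seed, {
    log2_sizes <- numeric(0)
    cum <- 0
    t <- 0L
    while (t < limits$max_days && cum < log2_cap) {
      cum <- cum + stats::rexp(1L, lambda)
      t <- t + 1L
      log2_sizes <- c(log2_sizes, cum)
    }
    list(log2_sizes = log2_sizes, final_cells = 2^cum, days = t,
         doubling_time = if (t > 0L && cum > 0) t / cum else NA_real_)
  })
}

#' Simulate a population of clones with growth-rate subpopulations
#'
#' Each clone is assigned to a subpopulation by weight and grown
#' independently with that subpopulation's mean doubling time. All clones
#' advance synchronously day by day; with `cap = "population"` (the
#' default, matching a shared tumor capacity) the simulation stops when the
#' summed cell number reaches `max_cells`, with `cap = "clone"` each clone
#' stops at its own capacity. The resulting doubling-time sample feeds
#' [fit_doubling_mixture()]; truth labels are retained per clone.
#'
#' @param specs data.frame of subpopulations with columns `label`, `mu`
#'   (mean doubling time, days) and `weight` (fractions summing to 1).
#' @param n_clones number of clones (> 0).
#' @param limits a [sim_limits()] object.
#' @param seed integer seed.
#' @param cap capacity semantics, `"population"` or `"clone"`.
#' @param overshoot `"include"` keeps the increment that crosses the
#'   capacity (default); `"truncate"` stops just before it so the capacity
#'   is never exceeded.
#' @inheritParams simulate_clone_trajectory
#' @return data.frame with one row per clone: `clone`, `subpopulation`,
#'   `mu`, `log2_cells`, `cells`, `days`, `doubling_time`.
#' @export
simulate_population <- function(specs, n_clones, limits = sim_limits(),
                                seed = NULL, cap = c("population", "clone"),
                                overshoot = c("include", "truncate"),
                                rate_convention = c("per_day", "literal")) {
  cap <- match.arg(cap)
  overshoot <- match.arg(overshoot)
  rate_convention <- match.arg(rate_convention)
  if (is.null(specs) || nrow(specs) == 0L) {
    stop("at least one subpopulation spec is required")
  }
  stopifnot(all(c("label", "mu", "weight") %in% names(specs)),
            all(specs$mu > 0), n_clones > 0)
  if (abs(sum(specs$weight) - 1) > 1e-8) {
    stop("subpopulation weights must sum to 1")
  }
  log2_cap <- log2(limits$max_cells)
  with_seed(seed, {
    comp <- sample.int(nrow(specs), n_clones, replace = TRUE,
                       prob = specs$weight)
    lambda <- increment_rate(specs$mu[comp], rate_convention)
    cum <- numeric(n_clones)
    days <- integer(n_clones)
    active <- rep(TRUE, n_clones)
    t <- 0L
    while (t < limits$max_days && any(active)) {
      idx <- which(active)
      inc <- stats::rexp(length(idx), lambda[idx])
      newcum <- cum
      newcum[idx] <- newcum[idx] + inc
      t <- t + 1L
      if (cap == "population") {
        if (is.finite(log2_cap) && sum(2^newcum) >= limits$max_cells) {
          if (overshoot == "include") {
            cum <- newcum
            days[] <- t
          } else {
            days[] <- t - 1L
          }
          active[] <- FALSE
          break
        }
        cum <- newcum
        days[] <- t
      } else {
        hit <- idx[newcum[idx] >= log2_cap]
        if (overshoot == "include") {
          cum[idx] <- newcum[idx]
          days[idx] <- t
        } else {
          keep <- idx[newcum[idx] < log2_cap]
          cum[keep] <- newcum[keep]
          days[keep] <- t
        }
        active[hit] <- FALSE
      }
    }
    data.frame(clone = seq_len(n_clones),
               subpopulation = as.character(specs$label[comp]),
               mu = specs$mu[comp], log2_cells = cum, cells = 2^cum,
               days = days,
               doubling_time = ifelse(days > 0 & cum > 0, days / cum,
                                      NA_real_),
               stringsAsFactors = FALSE)
  })
}

#' Closed-form moments of the per-day doubling rate
#'
#' `log2(N_t)` is a sum of `t` i.i.d. exponential increments with rate
#' `rate`, i.e. Gamma(shape `t`, rate `rate`), so `log2(N_t)/t` has mean
#' `1/rate` and variance `1/(t * rate^2)` and is asymptotically normal.
#'
#' @param t number of time steps (days, >= 1).
#' @param rate exponential rate of the daily increments (> 0).
#' @return A list with `mean` and `variance` of `log2(N_t)/t`.
#' @examples
#' gamma_limit_stats(100, 1)  # mean 1, variance 0.01
#' @export
gamma_limit_stats <- function(t, rate) {
  stopifnot(t >= 1, rate > 0)
  list(mean = 1 / rate, variance = 1 / (t * rate^2))
}
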