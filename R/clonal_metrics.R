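# Clone-level statistics: clone-initiating-cell frequency, in vivo
# doubling time, Gaussian-mixture growth-speed classification, fate
# calling, Shannon entropy, dose-response slopes and tumor volume.

#' Clone-initiating cell (CIC) frequency
#'
#' The number of clones detected in a primary barcoded xenograft as a
#' fraction of the single, uniquely barcoded cells implanted
#' (`cells implanted * transduction efficiency`). Reported both as a
#' fraction and in "1 in N" form.
#'
#' @param n_clones clones detected in the primary xenograft.
#' @param cells_implanted total cells implanted.
#' @param transduction_efficiency fraction of implanted cells carrying a
#'   barcode, in (0, 1].
#' @return A list with `fraction`, `one_in`, `n_clones`, `barcoded_cells`.
#' @examples
#' cic_frequency(50, 1e5, 0.2)$one_in  # 1 in 400
#' @export
cic_frequency <- function(n_clones, cells_implanted, transduction_efficiency) {
  stopifnot(cells_implanted > 0,
            transduction_efficiency > 0, transduction_efficiency <= 1,
            n_clones >= 0)
  barcoded <- cells_implanted * transduction_efficiency
  if (n_clones > barcoded) {
    stop("inconsistent: more clones than barcoded cells implanted")
  }
  list(fraction = n_clones / barcoded,
       one_in = if (n_clones > 0) barcoded / n_clones else Inf,
       n_clones = n_clones, barcoded_cells = barcoded)
}

#' In vivo clone doubling time
#'
#' Days in vivo divided by the number of population doublings needed to
#' reach the clone's absolute size from a single cell:
#' `doubling time = days / log2(est_cells)`. Undefined for clones of one
#' cell or fewer (zero doublings); those return NA and are reported in the
#' `excluded` attribute.
#'
#' @param est_cells absolute clone size(s) in cells.
#' @param days_in_vivo days the xenograft grew (positive scalar or vector).
#' @return Numeric vector of doubling times in days per doubling, NA where
#'   undefined.
#' @examples
#' doubling_time(1024, 100)  # 10 days per doubling
#' @export
doubling_time <- function(est_cells, days_in_vivo) {
  if (any(days_in_vivo <= 0)) {
    stop("days_in_vivo must be positive")
  }
  n <- max(length(est_cells), length(days_in_vivo))
  est_cells <- rep_len(est_cells, n)
  days_in_vivo <- rep_len(days_in_vivo, n)
  out <- rep(NA_real_, n)
  ok <- est_cells > 1
  out[ok] <- days_in_vivo[ok] / log2(est_cells[ok])
  attr(out, "excluded") <- which(!ok)
  out
}

## ---- Gaussian mixture fitting (EM) ----------------------------------------

# k-means++ style draw of K initial component means from the data.
kmeanspp_means <- function(x, K) {
  centers <- numeric(K)
  centers[1] <- x[sample.int(length(x), 1L)]
  if (K > 1L) {
    for (k in 2:K) {
      d2 <- apply(outer(x, centers[1:(k - 1)], "-")^2, 1, min)
      if (all(d2 == 0)) {
        centers[k] <- x[sample.int(length(x), 1L)]
      } else {
        centers[k] <- x[sample.int(length(x), 1L, prob = d2)]
      }
    }
  }
  sort(centers)
}

# One EM run for a univariate K-component Gaussian mixture.
# `init` is either a vector of component means or a full parameter list
# (weights/means/sds). Returns parameters, the log-likelihood and its
# per-iteration trace.
em_gaussian_mixture <- function(x, K, init, sd_floor, tol = 1e-6,
                                max_iter = 1000L) {
  n <- length(x)
  if (is.list(init)) {
    w <- init$weights
    mu <- init$means
    sigma <- init$sds
  } else {
    w <- rep(1 / K, K)
    mu <- init
    sigma <- rep(max(stats::sd(x), sd_floor), K)
  }
  ll_old <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K),
                   function(k) w[k] * stats::dnorm(x, mu[k], sigma[k]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    sigma <- pmax(sigma, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(K = K, weights = w, means = mu, sds = sigma, loglik = ll,
       loglik_trace = trace)
}

#' Fit a Gaussian mixture to in vivo doubling times
#'
#' Expectation-maximization fit of univariate Gaussian mixtures with 1 to
#' `max_K` components; the number of components is chosen by the Akaike
#' Information Criterion (BIC available by flag). Each K is fitted from
#' `n_restarts` seeded k-means++ initializations plus one deterministic
#' quantile initialization, keeping the best log-likelihood, so the fit is
#' reproducible under `seed`.
#'
#' @param times doubling times in days (needs at least `5 * max_K`
#'   observations).
#' @param max_K largest number of components considered.
#' @param criterion model-selection criterion, `"AIC"` (default) or
#'   `"BIC"`.
#' @param seed integer seed controlling the restarts.
#' @param n_restarts random initializations per K.
#' @return A `MixtureFit` with components ordered by increasing mean:
#'   `K`, `means`, `sds`, `weights`, `cutoffs` (K-1 posterior-equality
#'   boundaries between adjacent components), `criterion_value`,
#'   `criterion_table` (one row per candidate K), `loglik`,
#'   `loglik_trace`, `n` and a `degenerate` flag (all observations equal:
#'   K = 1 with a floored standard deviation).
#' @export
fit_doubling_mixture <- function(times, max_K = 3, criterion = c("AIC", "BIC"),
                                 seed = NULL, n_restarts = 10) {
  criterion <- match.arg(criterion)
  times <- times[!is.na(times)]
  n <- length(times)
  if (any(times <= 0)) {
    stop("doubling times must be positive")
  }
  if (n < 5 * max_K) {
    stop(sprintf("need at least %d observations for max_K = %d", 5 * max_K,
                 max_K))
  }
  sd_all <- stats::sd(times)
  degenerate <- !is.finite(sd_all) || sd_all == 0
  sd_floor <- if (degenerate) 1e-6 * max(mean(times), 1) else 1e-4 * sd_all
  if (degenerate) {
    fit <- list(K = 1L, weights = 1, means = mean(times), sds = sd_floor,
                loglik = sum(stats::dnorm(times, mean(times), sd_floor,
                                          log = TRUE)),
                loglik_trace = numeric(0))
    crit_tab <- data.frame(K = 1L, loglik = fit$loglik,
                           criterion = NA_real_)
    return(new_mixture_fit(fit, criterion, NA_real_, crit_tab, n,
                           degenerate = TRUE))
  }

  fits <- with_seed(seed, {
    lapply(seq_len(max_K), function(K) {
      n_params <- 3L * K - 1L
      if (K == 1L) {
        mu <- mean(times)
        sg <- stats::sd(times) * sqrt((n - 1) / n)
        ll <- sum(stats::dnorm(times, mu, sg, log = TRUE))
        best <- list(K = 1L, weights = 1, means = mu, sds = sg, loglik = ll,
                     loglik_trace = ll)
      } else {
        # short EM runs from each initialization, then run the best one to
        # convergence (the usual multi-start budget scheme)
        inits <- c(list(stats::quantile(times, probs = (seq_len(K) - 0.5) / K,
                                        names = FALSE)),
                   lapply(seq_len(n_restarts),
                          function(r) kmeanspp_means(times, K)))
        short <- lapply(inits, function(init) {
          em_gaussian_mixture(times, K, init, sd_floor, max_iter = 40L)
        })
        top <- short[[which.max(vapply(short, `[[`, numeric(1), "loglik"))]]
        best <- em_gaussian_mixture(times, K, top[c("weights", "means",
                                                    "sds")], sd_floor)
        best$loglik_trace <- c(top$loglik_trace, best$loglik_trace)
      }
      penalty <- if (criterion == "AIC") 2 * n_params else log(n) * n_params
      best$criterion <- penalty - 2 * best$loglik
      best
    })
  })
  crit_tab <- data.frame(K = vapply(fits, `[[`, integer(1), "K"),
                         loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                         criterion = vapply(fits, `[[`, numeric(1),
                                            "criterion"))
  best <- fits[[which.min(crit_tab$criterion)]]
  new_mixture_fit(best, criterion, min(crit_tab$criterion), crit_tab, n,
                  degenerate = FALSE)
}

new_mixture_fit <- function(fit, criterion, criterion_value, crit_tab, n,
                            degenerate) {
  ord <- order(fit$means)
  means <- fit$means[ord]
  sds <- fit$sds[ord]
  weights <- fit$weights[ord]
  structure(list(K = fit$K, means = means, sds = sds, weights = weights,
                 cutoffs = mixture_cutoffs(means, sds, weights),
                 criterion = criterion, criterion_value = criterion_value,
                 criterion_table = crit_tab, loglik = fit$loglik,
                 loglik_trace = fit$loglik_trace, n = n,
                 degenerate = degenerate),
            class = "MixtureFit")
}

# Posterior-equality boundaries between adjacent (mean-ordered) components:
# the point between the two means where the weighted densities cross.
mixture_cutoffs <- function(means, sds, weights) {
  K <- length(means)
  if (K < 2L) {
    return(numeric(0))
  }
  vapply(seq_len(K - 1L), function(k) {
    f <- function(x) {
      log(weights[k]) + stats::dnorm(x, means[k], sds[k], log = TRUE) -
        log(weights[k + 1]) - stats::dnorm(x, means[k + 1], sds[k + 1],
                                           log = TRUE)
    }
    lo <- means[k]
    hi <- means[k + 1]
    if (!is.finite(f(lo)) || !is.finite(f(hi)) || f(lo) * f(hi) > 0) {
      return((lo + hi) / 2)
    }
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf("MixtureFit: %d component(s) selected by %s (n = %d)\n", x$K,
              x$criterion, x$n))
  for (k in seq_len(x$K)) {
    cat(sprintf("  comp %d: mean %.3f, sd %.3f, weight %.3f\n", k,
                x$means[k], x$sds[k], x$weights[k]))
  }
  if (length(x$cutoffs)) {
    cat("  cutoffs:", paste(sprintf("%.3f", x$cutoffs), collapse = ", "),
        "\n")
  }
  if (x$degenerate) cat("  (degenerate input: all observations equal)\n")
  invisible(x)
}

#' Export a mixture fit as a JSON report
#'
#' @param fit a `MixtureFit`.
#' @param path output file; when NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
write_mixture_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "MixtureFit"))
  rpt <- list(K = fit$K, means = fit$means, sds = fit$sds,
              weights = fit$weights, cutoffs = fit$cutoffs,
              criterion = fit$criterion,
              criterion_table = fit$criterion_table, n = fit$n)
  js <- jsonlite::toJSON(rpt, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Classify clone growth speed from a mixture fit
#'
#' Assigns each doubling time to a speed class using the mixture
#' components ordered by increasing mean (fast clones double in the fewest
#' days). With three components the classes are fast/medium/slow; with two,
#' fast/slow; a single component labels everything medium. The default
#' assignment is by maximum posterior probability; `method = "cutoff"` uses
#' the hard density-crossing boundaries instead (the two coincide except
#' where a wide component's tail overtakes a narrow one far from the
#' boundary).
#'
#' @param times doubling times in days (positive).
#' @param fit a `MixtureFit` with at most three components.
#' @param method `"posterior"` (argmax, default) or `"cutoff"`.
#' @return Factor of speed classes, levels ordered fast to slow.
#' @export
classify_speed <- function(times, fit, method = c("posterior", "cutoff")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "MixtureFit"))
  if (fit$K > 3L) {
    stop("speed classification is defined for at most 3 components")
  }
  if (any(times <= 0)) {
    stop("doubling times must be positive")
  }
  labels <- switch(fit$K, "medium", c("fast", "slow"),
                   c("fast", "medium", "slow"))
  if (method == "posterior" && fit$K > 1L) {
    dens <- vapply(seq_len(fit$K), function(k) {
      log(fit$weights[k]) + stats::dnorm(times, fit$means[k], fit$sds[k],
                                         log = TRUE)
    }, numeric(length(times)))
    dens <- matrix(dens, ncol = fit$K)
    idx <- max.col(dens, ties.method = "first")
  } else {
    idx <- findInterval(times, fit$cutoffs) + 1L
  }
  factor(labels[idx], levels = labels)
}

#' Classify clone fate across passages
#'
#' Clones detected (above the limit of detection) in both the primary and
#' at least one secondary xenograft are propagating; in the primary only,
#' transient; in a secondary only, emerging.
#'
#' @param present_primary logical; detected in the primary xenograft.
#' @param present_any_secondary logical; detected in any secondary.
#' @return Factor with levels propagating/transient/emerging.
#' @export
classify_fate <- function(present_primary, present_any_secondary) {
  n <- max(length(present_primary), length(present_any_secondary))
  p <- rep_len(as.logical(present_primary), n)
  s <- rep_len(as.logical(present_any_secondary), n)
  if (any(!p & !s)) {
    stop("clone never observed: both presence flags are FALSE")
  }
  out <- ifelse(p & s, "propagating", ifelse(p, "transient", "emerging"))
  factor(out, levels = c("propagating", "transient", "emerging"))
}

#' Shannon entropy of a probability vector
#'
#' `H = -sum(p * log(p))` with `0 * log(0) = 0`. Fractions must be
#' nonnegative and sum to one within `1e-9` (or set `normalize = TRUE` to
#' renormalize arbitrary nonnegative weights, e.g. raw cell counts).
#'
#' @param fractions nonnegative vector.
#' @param base logarithm base; 2 (bits, the default) or `exp(1)` (nats).
#' @param normalize renormalize `fractions` to sum to one.
#' @return Entropy (scalar).
#' @examples
#' shannon_entropy(rep(0.25, 4))  # 2 bits
#' @export
shannon_entropy <- function(fractions, base = 2, normalize = FALSE) {
  if (any(fractions < 0)) {
    stop("fractions must be nonnegative")
  }
  s <- sum(fractions)
  if (normalize) {
    if (s <= 0) stop("fractions sum to zero")
    fractions <- fractions / s
  } else if (abs(s - 1) > 1e-9) {
    stop("fractions must sum to 1 (use normalize = TRUE for raw weights)")
  } else {
    fractions <- fractions / s
  }
  p <- fractions[fractions > 0]
  -sum(p * log(p, base = base))
}

#' Tumor volume from caliper measurements
#'
#' `volume = width^2 * height / 2`, in cubic millimeters.
#'
#' @param w tumor width (mm).
#' @param h tumor height (mm).
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 20)  # 1000
#' @export
tumor_volume <- function(w, h) {
  if (any(w < 0) || any(h < 0)) {
    stop("dimensions must be nonnegative")
  }
  w^2 * h / 2
}

#' Per-model dose-response slope of CIC frequency
#'
#' Ordinary least-squares fit of `log10(CIC frequency)` on `log10(cells
#' implanted)`, separately per xenograft model. Models with fewer than two
#' distinct doses are skipped with a warning.
#'
#' @param doses cells implanted per xenograft.
#' @param cic CIC frequencies (fractions).
#' @param group model label per xenograft; a single model when omitted.
#' @return data.frame with one row per fitted model: `group`, `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `n`, `r_squared`.
#' @export
dose_response_slope <- function(doses, cic, group = NULL) {
  if (is.null(group)) {
    group <- rep("all", length(doses))
  }
  stopifnot(length(doses) == length(cic), length(group) == length(doses),
            all(doses > 0), all(cic > 0))
  res <- lapply(split(seq_along(doses), group), function(idx) {
    if (length(unique(doses[idx])) < 2L) {
      warning(sprintf("group '%s' has a single dose; skipped",
                      group[idx[1]]))
      return(NULL)
    }
    fit <- stats::lm(log10(cic[idx]) ~ log10(doses[idx]))
    sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
    cf <- sm$coefficients
    data.frame(group = group[idx[1]], slope = cf[2, 1], slope_se = cf[2, 2],
               intercept = cf[1, 1], intercept_se = cf[1, 2],
               n = length(idx), r_squared = sm$r.squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
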