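#' Fit the surface-to-volume power law S = gamma * V^beta
#'
#' Ordinary least squares in log-log space on the rows of a shape table:
#' \eqn{\log S = \log\gamma + \beta \log V}. Two modes:
#'
#' * `exponent = "free"` — both \eqn{\log\gamma} and \eqn{\beta} are fitted
#'   by [stats::lm()];
#' * `exponent = "fixed"` — \eqn{\beta} is pinned to the geometric value
#'   \eqn{2/3} and \eqn{\log\gamma} is the mean of
#'   \eqn{\log S - (2/3)\log V}; the exponent standard error is reported
#'   as exactly 0.
#'
#' Rows are weighted equally; the data this law describes have
#' multiplicative scatter over about two decades of volume, which is what
#' unweighted log-space least squares assumes. Weighted alternatives move
#' \eqn{\gamma} only in the third digit for realistic scatter.
#'
#' @param table A shape table; [complete_shape_table()] is applied first, so
#'   rows may carry either dimensions or surface/volume.
#' @param exponent `"free"` or `"fixed"` (the 2/3 law).
#' @return An object of class `"sv_fit"`: a list with elements `gamma`,
#'   `exponent`, `gamma_se`, `exponent_se`, `n`, `mode`, `logS`, `logV`,
#'   `fitted_logS`, `sigma_log` (residual SD of log S). Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `residuals()`, `plot()` and
#'   `simulate()`.
#' @examples
#' tab <- make_population_table(n = 200, seed = 1)
#' fit <- fit_power_law(tab)
#' coef(fit)
#' @export
fit_power_law <- function(table, exponent = c("free", "fixed")) {
  exponent <- match.arg(exponent)
  table <- complete_shape_table(table)
  S <- table$surface_um2
  V <- table$volume_um3
  ok <- !is.na(S) & !is.na(V)
  S <- S[ok]
  V <- V[ok]
  if (length(S) < 3L) {
    stop("power-law fit needs at least 3 rows with surface and volume",
      call. = FALSE
    )
  }
  if (any(S <= 0) || any(V <= 0)) {
    stop("surface and volume must be positive", call. = FALSE)
  }
  logS <- log(S)
  logV <- log(V)
  if (exponent == "free") {
    if (length(unique(logV)) < 2L) {
      stop("degenerate design: all volumes identical", call. = FALSE)
    }
    fit <- stats::lm(logS ~ logV)
    cf <- stats::coef(fit)
    se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
    beta <- unname(cf[2])
    log_gamma <- unname(cf[1])
    beta_se <- unname(se[2])
    log_gamma_se <- unname(se[1])
    fitted_logS <- unname(stats::fitted(fit))
  } else {
    resid0 <- logS - (2 / 3) * logV
    beta <- 2 / 3
    beta_se <- 0
    log_gamma <- mean(resid0)
    log_gamma_se <- if (length(resid0) > 1L) {
      stats::sd(resid0) / sqrt(length(resid0))
    } else {
      0
    }
    fitted_logS <- log_gamma + (2 / 3) * logV
  }
  res <- logS - fitted_logS
  sigma_log <- if (length(res) > 2L) {
    sqrt(sum(res^2) / (length(res) - 2L))
  } else {
    0
  }
  structure(
    list(
      gamma = exp(log_gamma),
      exponent = beta,
      # delta method on gamma = exp(log gamma)
      gamma_se = exp(log_gamma) * log_gamma_se,
      exponent_se = beta_se,
      n = length(S),
      mode = if (exponent == "free") "free-exponent" else "fixed-2/3",
      logS = logS, logV = logV, fitted_logS = fitted_logS,
      sigma_log = sigma_log
    ),
    class = "sv_fit"
  )
}

#' @export
print.sv_fit <- function(x, ...) {
  cat("Surface-to-volume power law S = gamma * V^beta (", x$mode, ")\n",
    sep = ""
  )
  cat(sprintf(
    "  gamma    = %.4f (se %.4f)\n  exponent = %.4f (se %.4f)\n  n = %d rows\n",
    x$gamma, x$gamma_se, x$exponent, x$exponent_se, x$n
  ))
  invisible(x)
}

#' @export
summary.sv_fit <- function(object, ...) {
  out <- object
  out$implied_eta <- tryCatch(eta_from_gamma_rod(object$gamma),
    error = function(e) NA_real_
  )
  class(out) <- "summary.sv_fit"
  out
}

#' @export
print.summary.sv_fit <- function(x, ...) {
  print.sv_fit(x)
  cat(sprintf("  residual SD of log S = %.4g\n", x$sigma_log))
  if (is.finite(x$implied_eta)) {
    cat(sprintf(
      "  implied spherocylinder aspect ratio eta = %.3f\n",
      x$implied_eta
    ))
  } else {
    cat("  gamma below the sphere bound: no spherocylinder aspect ratio\n")
  }
  invisible(x)
}

#' @export
coef.sv_fit <- function(object, ...) {
  c(gamma = object$gamma, exponent = object$exponent)
}

#' Predict surface area from volume under a fitted power law
#'
#' @param object An `sv_fit`.
#' @param newdata Optional data.frame with a `volume_um3` column (or a bare
#'   numeric vector of volumes); defaults to the fitting volumes.
#' @param ... Unused.
#' @return Predicted surface areas, um^2.
#' @export
predict.sv_fit <- function(object, newdata = NULL, ...) {
  V <- if (is.null(newdata)) {
    exp(object$logV)
  } else if (is.data.frame(newdata)) {
    newdata$volume_um3
  } else {
    as.numeric(newdata)
  }
  object$gamma * V^object$exponent
}

#' @export
residuals.sv_fit <- function(object, ...) {
  object$logS - object$fitted_logS
}

#' @export
plot.sv_fit <- function(x, ...) {
  graphics::plot(exp(x$logV), exp(x$logS),
    log = "xy",
    xlab = expression(V ~ (mu * m^3)), ylab = expression(S ~ (mu * m^2)),
    pch = 16, col = "#00000055", ...
  )
  vv <- exp(seq(min(x$logV), max(x$logV), length.out = 100))
  graphics::lines(vv, x$gamma * vv^x$exponent, col = "red3", lwd = 2)
  graphics::legend("topleft",
    bty = "n",
    legend = sprintf("S = %.3f V^%.3f", x$gamma, x$exponent)
  )
  invisible(x)
}

#' Simulate surface areas from a fitted power law
#'
#' Draws new log-normal surface areas at the fitting volumes using the
#' fitted \eqn{\gamma}, exponent and residual log-SD.
#'
#' @param object An `sv_fit`.
#' @param nsim Number of replicate tables.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` data.frames with columns `volume_um3`,
#'   `surface_um2`.
#' @export
simulate.sv_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  V <- exp(object$logV)
  lapply(seq_len(nsim), function(i) {
    data.frame(
      volume_um3 = V,
      surface_um2 = object$gamma * V^object$exponent *
        exp(stats::rnorm(length(V), 0, object$sigma_log))
    )
  })
}

#' Fit the phenomenological nutrient growth law V = V0 * exp(alpha * kappa)
#'
#' Log-linear least squares of volume on growth rate: the mean cell volume
#' of many bacteria grows exponentially with the population growth rate
#' \eqn{\kappa}, with `V0` the extrapolated volume at \eqn{\kappa = 0} and
#' `alpha` (hours) the relative rate of volume increase.
#'
#' @param kappa Growth rates, 1/h.
#' @param volume Mean cell volumes, um^3.
#' @return An object of class `"growth_law"` with elements `V0`, `alpha`,
#'   their standard errors, and `n`; supports `print()`, `coef()` and
#'   `predict()` (on new `kappa`).
#' @examples
#' fit_growth_law(c(0.5, 1, 1.5, 2), 0.5 * exp(c(0.5, 1, 1.5, 2)))
#' @export
fit_growth_law <- function(kappa, volume) {
  if (length(kappa) != length(volume)) {
    stop("kappa and volume must have equal length", call. = FALSE)
  }
  if (length(unique(kappa)) < 2L) {
    stop("growth-law fit needs at least 2 distinct growth rates",
      call. = FALSE
    )
  }
  if (any(volume <= 0)) stop("volumes must be positive", call. = FALSE)
  fit <- stats::lm(log(volume) ~ kappa)
  cf <- stats::coef(fit)
  se <- if (length(kappa) > 2L) {
    sqrt(diag(suppressWarnings(stats::vcov(fit))))
  } else {
    c(0, 0)
  }
  structure(
    list(
      V0 = exp(unname(cf[1])), alpha = unname(cf[2]),
      V0_se = exp(unname(cf[1])) * unname(se[1]), alpha_se = unname(se[2]),
      n = length(kappa)
    ),
    class = "growth_law"
  )
}

#' @export
print.growth_law <- function(x, ...) {
  cat("Nutrient growth law V = V0 * exp(alpha * kappa)\n")
  cat(sprintf(
    "  V0 = %.4f um^3 (se %.4f)\n  alpha = %.4f h (se %.4f)\n  n = %d\n",
    x$V0, x$V0_se, x$alpha, x$alpha_se, x$n
  ))
  invisible(x)
}

#' @export
coef.growth_law <- function(object, ...) {
  c(V0 = object$V0, alpha = object$alpha)
}

#' @export
predict.growth_law <- function(object, newdata = NULL, ...) {
  kappa <- if (is.null(newdata)) {
    stop("supply kappa values to predict at", call. = FALSE)
  } else if (is.data.frame(newdata)) {
    newdata$kappa
  } else {
    as.numeric(newdata)
  }
  object$V0 * exp(object$alpha * kappa)
}

#' Predicted surface-to-volume ratio as a function of growth rate
#'
#' Combines the 2/3 scaling law with the nutrient growth law: with
#' \eqn{S \approx 2\pi V^{2/3}} and \eqn{V = V_0 e^{\alpha\kappa}},
#' \deqn{S/V \approx 2\pi V_0^{-1/3} e^{-\alpha\kappa/3},}
#' a negative correlation between surface-to-volume ratio and growth rate:
#' slow-growing cells raise S/V, which favours nutrient influx.
#'
#' @param kappa Growth rate(s), 1/h.
#' @param params A `growth_law` object or a list with `V0` and `alpha`.
#' @return Predicted S/V, 1/um.
#' @examples
#' sv_ratio_prediction(1, list(V0 = 0.5, alpha = 1))
#' @export
sv_ratio_prediction <- function(kappa, params) {
  V0 <- params$V0
  alpha <- params$alpha
  if (is.null(V0) || is.null(alpha) || V0 <= 0 || alpha < 0) {
    stop("params must provide V0 > 0 and alpha >= 0", call. = FALSE)
  }
  2 * pi * V0^(-1 / 3) * exp(-alpha * kappa / 3)
}

#' Summarise an aspect-ratio sample
#'
#' Arithmetic mean, coefficient of variation (SD/mean, natural scale) and
#' maximum-likelihood log-normal parameters (mean and SD of the logs) of a
#' sample of cell aspect ratios. Newborn aspect-ratio distributions are well
#' described by a log-normal whose parameters do not depend on growth rate.
#'
#' @param etas Sample of aspect ratios, all > 0 (values >= 1 up to
#'   measurement tolerance).
#' @return An object of class `"aspect_ratio_summary"`: list with `mean`,
#'   `cv`, `meanlog`, `sdlog`, `n`.
#' @examples
#' aspect_ratio_summary(exp(rnorm(1000, log(4.14), 0.14)))
#' @export
aspect_ratio_summary <- function(etas) {
  if (length(etas) < 2L) stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(etas)) || any(etas <= 0)) {
    stop("aspect ratios must be positive and finite", call. = FALSE)
  }
  m <- mean(etas)
  structure(
    list(
      mean = m,
      cv = stats::sd(etas) / m,
      meanlog = mean(log(etas)),
      sdlog = stats::sd(log(etas)),
      n = length(etas)
    ),
    class = "aspect_ratio_summary"
  )
}

#' @export
print.aspect_ratio_summary <- function(x, ...) {
  cat(sprintf(
    "Aspect-ratio sample (n = %d): mean %.3f, CV %.3f, log-normal(meanlog %.4f, sdlog %.4f)\n",
    x$n, x$mean, x$cv, x$meanlog, x$sdlog
  ))
  invisible(x)
}

#' Intergeneration autocorrelation across lineages
#'
#' Pooled-pairs Pearson correlation at a given generation lag: for every
#' lineage the pairs (value at generation g, value at generation g + lag)
#' are collected, pooled across lineages, and the Pearson correlation of the
#' pooled pairs is returned. Lag 0 returns exactly 1.
#'
#' @param series A numeric vector (one lineage) or a list of numeric
#'   vectors (one per lineage), each ordered by generation.
#' @param lag Non-negative integer lag, generations.
#' @return Pearson correlation coefficient at the requested lag.
#' @examples
#' lineage_autocorrelation(list(rnorm(50), rnorm(50)), lag = 1)
#' @export
lineage_autocorrelation <- function(series, lag = 1) {
  if (is.numeric(series)) series <- list(series)
  lag <- as.integer(lag)
  if (lag < 0L) stop("lag must be >= 0", call. = FALSE)
  if (lag == 0L) {
    return(1.0)
  }
  x <- numeric(0)
  y <- numeric(0)
  for (s in series) {
    n <- length(s)
    if (n >= lag + 1L) {
      x <- c(x, s[seq_len(n - lag)])
      y <- c(y, s[seq_len(n - lag) + lag])
    }
  }
  if (length(x) < 2L) {
    stop("no valid generation pairs at lag ", lag, call. = FALSE)
  }
  stats::cor(x, y)
}
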