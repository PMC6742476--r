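#' Ensemble simulation protocol
#'
#' Describes a population run: a fixed-size ensemble of independent
#' lineages (mother-machine semantics: one daughter kept, chosen with equal
#' probability, per division) growing at `k_pre` until the shift time and
#' at `k_post` after it, with the surface-synthesis rate slaved to
#' [beta_of_k()] and the division-protein production rate rescaled so that
#' the target newborn aspect ratio (k/kP ratio) is unchanged by the shift —
#' a nutrient shift changes cell width (k/beta) but not the homeostatic
#' aspect ratio.
#'
#' Each lineage is initialised at a uniformly random phase of the analytic
#' division cycle and run through `burn_in` generations before the
#' recording window opens at `t_start`, guaranteeing a stationary
#' asynchronous population.
#'
#' @param n_cells Ensemble size (default 1e5, the full-scale run; reduce
#'   for interactive work and tests).
#' @param k_pre,k_post Elongation rates before and after the shift, 1/h.
#' @param t_start Start of the recording window, h (the shift is at t = 0).
#' @param t_end End of the run, h.
#' @param burn_in Generations simulated before `t_start` and discarded.
#' @param bin_min Temporal bin width for newborn aspect ratios, minutes.
#' @param dt Integration step, h.
#' @param record_dt Spacing of the population-mean trace, h.
#' @return An object of class `"protocol"`.
#' @examples
#' protocol(n_cells = 300, k_pre = 0.75, k_post = 0.25, t_end = 10)
#' @export
protocol <- function(n_cells = 1e5, k_pre = 0.75, k_post = k_pre,
                     t_start = -2, t_end = 10, burn_in = 10,
                     bin_min = 10, dt = 0.002, record_dt = 0.05) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (burn_in < 1) stop("burn_in must be >= 1", call. = FALSE)
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  if (dt <= 0 || record_dt <= 0 || bin_min <= 0) {
    stop("dt, record_dt and bin_min must be positive", call. = FALSE)
  }
  structure(
    list(
      n_cells = as.integer(n_cells), k_pre = k_pre, k_post = k_post,
      t_start = t_start, t_end = t_end, burn_in = burn_in,
      bin_min = bin_min, dt = dt, record_dt = record_dt
    ),
    class = "protocol"
  )
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf(
    "Ensemble protocol: %d lineages, k %.3g -> %.3g /h at t = 0, window [%g, %g] h, burn-in %g generations\n",
    x$n_cells, x$k_pre, x$k_post, x$t_start, x$t_end, x$burn_in
  ))
  invisible(x)
}

# asynchronous steady-state initial ensemble at elongation rate of `params`
.init_ensemble <- function(n, params, w0 = NULL) {
  if (is.null(w0)) {
    w0 <- if (params$width_dynamics && params$beta > 0) {
      steady_state_width(params)
    } else {
      1
    }
  }
  Lb <- params$rho * pi * w0 * params$k / params$kP
  age <- stats::runif(n) * log(2) / params$k
  L <- Lb * exp(params$k * age)
  P <- params$kP * Lb * (exp(params$k * age) - 1) / params$k
  simple <- params$mode == "simple"
  list(
    L = L, w = rep(w0, n),
    Pc = if (simple) P else rep(params$Pstar, n),
    Pr = if (simple) rep(0, n) else P,
    t = 0, generation = rep(0L, n)
  )
}

# run the ensemble from ens$t to t_end, recording means and newborn events
.run_ensemble <- function(ens, params, t_end, dt, record_dt,
                          record_from = -Inf, length_cap = Inf) {
  n_steps <- max(0L, ceiling((t_end - ens$t) / dt - 1e-9))
  rec_times <- list()
  rec_L <- list()
  rec_w <- list()
  events <- list()
  ri <- 0L
  ei <- 0L
  next_rec <- ens$t
  capped <- FALSE
  for (s in seq_len(n_steps)) {
    if (ens$t >= record_from && ens$t >= next_rec - 1e-12) {
      ri <- ri + 1L
      rec_times[[ri]] <- ens$t
      rec_L[[ri]] <- mean(ens$L)
      rec_w[[ri]] <- mean(ens$w)
      next_rec <- next_rec + record_dt
    }
    st <- .ensemble_step(ens, params, dt)
    ens <- st$ens
    if (is.finite(length_cap) && any(ens$L > length_cap)) {
      ens$L <- pmin(ens$L, length_cap)
      capped <- TRUE
    }
    if (!is.null(st$events) && ens$t >= record_from) {
      ei <- ei + 1L
      events[[ei]] <- st$events
    }
  }
  list(
    ens = ens,
    trace = data.frame(
      time_h = unlist(rec_times),
      mean_length_um = unlist(rec_L),
      mean_width_um = unlist(rec_w)
    ),
    events = if (ei) do.call(rbind, events) else NULL,
    capped = capped
  )
}

#' Bin newborn aspect ratios in time
#'
#' @param events Division-event data.frame (as emitted by the simulators)
#'   with columns `time_h` and `newborn_eta`.
#' @param bin_min Bin width, minutes.
#' @return A data.frame with `bin_time_h` (bin centre), `mean_eta`,
#'   `n_events`; only non-empty bins are reported.
#' @export
bin_newborn_eta <- function(events, bin_min = 10) {
  if (is.null(events) || nrow(events) == 0L) {
    return(data.frame(
      bin_time_h = numeric(0), mean_eta = numeric(0),
      n_events = integer(0)
    ))
  }
  bw <- bin_min / 60
  bin <- floor(events$time_h / bw)
  agg <- stats::aggregate(events$newborn_eta, by = list(bin = bin),
    FUN = function(v) c(mean(v), length(v)))
  data.frame(
    bin_time_h = (agg$bin + 0.5) * bw,
    mean_eta = agg$x[, 1],
    n_events = as.integer(agg$x[, 2])
  )
}

#' Run a nutrient-shift ensemble protocol
#'
#' Simulates `protocol$n_cells` independent lineages. Before t = 0 cells
#' grow at `k_pre`; at t = 0 the elongation rate steps to `k_post`, the
#' surface-synthesis rate follows `beta_of_k(k_post)` instantaneously, and
#' `kP` is rescaled to keep the k/kP ratio (the homeostatic newborn aspect
#' ratio) unchanged. Population-mean length and width are recorded on a
#' regular grid and newborn aspect ratios are binned in time.
#'
#' @param protocol A [protocol()].
#' @param params Optional [model_params()] evaluated at `k_pre`; defaults
#'   to `model_params(k = protocol$k_pre)`.
#' @param seed Integer seed for the single RNG stream of the run.
#' @param keep_events Keep the full division-event log in the result.
#' @return An object of class `"population_trace"`: list with `trace`
#'   (time, mean length, mean width), `newborn` (binned newborn aspect
#'   ratio), `events` (if kept), `protocol`, `params_pre`, `params_post`,
#'   `seed`.
#' @examples
#' \donttest{
#' pr <- protocol(n_cells = 200, k_pre = 0.75, k_post = 0.25, t_end = 6)
#' run <- run_protocol(pr, seed = 1)
#' }
#' @export
run_protocol <- function(protocol, params = NULL, seed = NULL,
                         keep_events = TRUE) {
  if (!inherits(protocol, "protocol")) {
    stop("protocol must be created with protocol()", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- model_params(k = protocol$k_pre)
  if (abs(params$k - protocol$k_pre) > 1e-12) {
    stop("params$k must equal protocol$k_pre", call. = FALSE)
  }
  eta_target <- params$rho * pi * params$k / params$kP
  params_post <- model_params(
    k = protocol$k_post,
    kP = params$rho * pi * protocol$k_post / eta_target,
    rho = params$rho, beta = beta_of_k(protocol$k_post),
    delta_sigma = params$delta_sigma, mode = params$mode,
    Pstar = params$Pstar, width_dynamics = params$width_dynamics
  )
  ens <- .init_ensemble(protocol$n_cells, params)
  ens$t <- protocol$t_start - protocol$burn_in * log(2) / params$k
  # burn-in + pre-shift window at k_pre
  pre <- .run_ensemble(ens, params,
    t_end = min(0, protocol$t_end),
    dt = protocol$dt, record_dt = protocol$record_dt,
    record_from = protocol$t_start
  )
  ens <- pre$ens
  post <- NULL
  if (protocol$t_end > 0) {
    post <- .run_ensemble(ens, params_post,
      t_end = protocol$t_end,
      dt = protocol$dt, record_dt = protocol$record_dt,
      record_from = protocol$t_start
    )
  }
  trace <- rbind(pre$trace, if (!is.null(post)) post$trace)
  events <- rbind(pre$events, if (!is.null(post)) post$events)
  structure(
    list(
      trace = trace,
      newborn = bin_newborn_eta(events, protocol$bin_min),
      events = if (keep_events) events else NULL,
      protocol = protocol, params_pre = params, params_post = params_post,
      seed = seed
    ),
    class = "population_trace"
  )
}

#' @export
print.population_trace <- function(x, ...) {
  cat(sprintf(
    "Population trace: %d lineages, k %.3g -> %.3g /h, t in [%.3g, %.3g] h, %d newborn bins\n",
    x$protocol$n_cells, x$protocol$k_pre, x$protocol$k_post,
    min(x$trace$time_h), max(x$trace$time_h), nrow(x$newborn)
  ))
  invisible(x)
}

#' @export
plot.population_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$trace$time_h,
    cbind(x$trace$mean_length_um, x$trace$mean_width_um),
    type = "l", lty = 1, col = c("steelblue4", "tomato3"),
    xlab = "time (h)", ylab = "population mean (um)", ...
  )
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright",
    bty = "n", lty = 1,
    col = c("steelblue4", "tomato3"), legend = c("length", "width")
  )
  graphics::plot(x$newborn$bin_time_h, x$newborn$mean_eta,
    pch = 16, cex = 0.6, xlab = "time (h)",
    ylab = "newborn aspect ratio"
  )
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' FtsZ knockdown simulation
#'
#' Reproduces the division-protein depletion protocol: cell width is fixed
#' (default 1 um; width dynamics off) and at t = 0 the production rate `kP`
#' is reduced to `knockdown_fraction` of its baseline. Because the added
#' length per cycle is \eqn{\Delta L = \rho\pi w k/k_P}, the steady-state
#' newborn length grows by the factor `1/knockdown_fraction`. Along the
#' transition the population traces out an S-V curve that approaches
#' \eqn{S \propto V} at large lengths (constant width).
#'
#' @param params Baseline [model_params()]; its `width_dynamics` is forced
#'   off and width fixed at `w`.
#' @param knockdown_fraction Fraction of baseline `kP` retained, in (0, 1].
#'   A fraction of 0 means no division ever (unbounded filamentation):
#'   lengths are capped at `length_cap` and the run is flagged.
#' @param w Fixed cell width, um.
#' @param n_cells Ensemble size.
#' @param t_end Post-knockdown duration, h.
#' @param burn_in Pre-knockdown generations.
#' @param length_cap Maximum simulated length, um.
#' @param dt Integration step, h.
#' @param seed Integer seed.
#' @return An object of class `"knockdown_run"`: list with `trace` (time,
#'   mean length, surface, volume), `events`, `newborn_pre`/`newborn_post`
#'   (mean newborn lengths in the baseline and final windows), `capped`
#'   flag, inputs.
#' @examples
#' \donttest{
#' kd <- run_ftsz_knockdown(model_params(k = 0.75), 0.4,
#'   n_cells = 100, t_end = 8, seed = 1)
#' }
#' @export
run_ftsz_knockdown <- function(params = model_params(), knockdown_fraction = 0.4,
                               w = 1, n_cells = 500, t_end = 12, burn_in = 8,
                               length_cap = 200, dt = 0.002, seed = NULL) {
  if (knockdown_fraction < 0 || knockdown_fraction > 1) {
    stop("knockdown_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  base <- model_params(
    k = params$k, kP = params$kP, rho = params$rho, beta = params$beta,
    delta_sigma = params$delta_sigma, mode = params$mode,
    Pstar = params$Pstar, width_dynamics = FALSE
  )
  ens <- .init_ensemble(n_cells, base, w0 = w)
  ens$t <- -burn_in * log(2) / base$k
  pre <- .run_ensemble(ens, base,
    t_end = 0, dt = dt, record_dt = 0.05,
    record_from = -burn_in * log(2) / base$k / 2
  )
  kd <- model_params(
    k = base$k, kP = base$kP * knockdown_fraction, rho = base$rho,
    beta = base$beta, delta_sigma = base$delta_sigma, mode = base$mode,
    Pstar = base$Pstar, width_dynamics = FALSE
  )
  post <- .run_ensemble(pre$ens, kd,
    t_end = t_end, dt = dt, record_dt = 0.05,
    record_from = 0, length_cap = length_cap
  )
  trace <- rbind(pre$trace, post$trace)
  trace$surface_um2 <- rod_surface(trace$mean_length_um, w)
  trace$volume_um3 <- rod_volume(trace$mean_length_um, w)
  newborn_pre <- if (!is.null(pre$events)) {
    mean(pre$events$newborn_length_um)
  } else {
    NA_real_
  }
  post_ev <- post$events
  newborn_post <- if (!is.null(post_ev)) {
    late <- post_ev$time_h > 0.8 * t_end
    if (any(late)) mean(post_ev$newborn_length_um[late]) else NA_real_
  } else {
    NA_real_
  }
  structure(
    list(
      trace = trace, events = rbind(pre$events, post$events),
      newborn_pre = newborn_pre, newborn_post = newborn_post,
      capped = post$capped, knockdown_fraction = knockdown_fraction,
      w = w, params = base, seed = seed
    ),
    class = "knockdown_run"
  )
}

#' @export
print.knockdown_run <- function(x, ...) {
  cat(sprintf(
    "FtsZ knockdown run: kP -> %.0f%% at fixed w = %.3g um\n",
    100 * x$knockdown_fraction, x$w
  ))
  cat(sprintf(
    "  mean newborn length: %.3f um (baseline) -> %.3f um (final window), ratio %.3f\n",
    x$newborn_pre, x$newborn_post, x$newborn_post / x$newborn_pre
  ))
  if (x$capped) cat("  NOTE: length cap reached (filamentation limit)\n")
  invisible(x)
}

#' Constant-aspect-ratio perturbation sweeps
#'
#' Machinery behind the MreB-depletion and filamentation curves: for a
#' sweep of steady-state widths, the surface-synthesis rate is set to
#' \eqn{\beta = 4k/w} (so the width ODE's fixed point lands on the target
#' width) and the division-protein production rate is set to
#' \eqn{k_P = \rho\pi k/\eta} so the steady-state newborn aspect ratio is
#' held at the target. Each sweep point is simulated to steady state and
#' the mean newborn (length, width) is converted to a surface-volume point,
#' so the emitted locus lies on the constant-aspect-ratio curve
#' \eqn{S = \gamma(\eta) V^{2/3}}.
#'
#' The experiment-matching wrappers are `run_mreb_depletion()` (default target
#' aspect ratio 2.7, widths 0.9–1.8 um) and `run_filamentation()` (default
#' target 11.0, widths 0.9–1.4 um). The co-adjustment rule (hold the target
#' aspect ratio while beta varies) is a reconstruction: the source
#' experiments report only that `kP` and `beta` were varied together.
#'
#' @param target_eta Target steady-state newborn aspect ratio, >= 1.
#' @param width_range Range of steady-state widths to sweep, um.
#' @param n_widths Number of sweep points.
#' @param k Elongation rate, 1/h.
#' @param n_cells Lineages per sweep point.
#' @param burn_in Discarded generations per point.
#' @param measure_gens Generations over which newborn means are taken.
#' @param delta_sigma Division-asymmetry noise SD.
#' @param dt Integration step, h.
#' @param seed Integer seed.
#' @return An object of class `"sv_locus"`: a data.frame with one row per
#'   sweep point (`width_target_um`, `width_um`, `length_um`, `eta`,
#'   `surface_um2`, `volume_um3`, `beta`, `kP`) and attributes
#'   `target_eta`, `k`, `seed`. Fit it with [fit_power_law()].
#' @examples
#' \donttest{
#' loc <- run_constant_eta_sweep(2.7, c(0.9, 1.8),
#'   n_widths = 4, n_cells = 50, seed = 1)
#' fit_power_law(loc)
#' }
#' @export
run_constant_eta_sweep <- function(target_eta, width_range, n_widths = 8,
                                   k = 0.75, n_cells = 100, burn_in = 5,
                                   measure_gens = 10, delta_sigma = 0.05,
                                   dt = 0.002, seed = NULL) {
  if (target_eta < 1) stop("target_eta must be >= 1", call. = FALSE)
  if (any(width_range <= 0) || any(width_range > 3)) {
    stop("width range must lie within (0, 3] um", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  widths <- seq(width_range[1], width_range[2], length.out = n_widths)
  rows <- vector("list", n_widths)
  t_run <- (burn_in + measure_gens) * log(2) / k
  for (i in seq_along(widths)) {
    wt <- widths[i]
    p <- model_params(
      k = k, kP = pi * k / target_eta, rho = 1, beta = 4 * k / wt,
      delta_sigma = delta_sigma
    )
    ens <- .init_ensemble(n_cells, p)
    ens$t <- -burn_in * log(2) / k
    run <- .run_ensemble(ens, p,
      t_end = t_run - burn_in * log(2) / k,
      dt = dt, record_dt = Inf, record_from = 0
    )
    if (is.null(run$events)) {
      stop(sprintf(
        "no division events at sweep width %.3g um; increase the run length",
        wt
      ), call. = FALSE)
    }
    Lb <- mean(run$events$newborn_length_um)
    wb <- mean(run$events$width_um)
    rows[[i]] <- data.frame(
      width_target_um = wt, width_um = wb, length_um = Lb,
      eta = Lb / wb,
      surface_um2 = rod_surface(Lb, wb),
      volume_um3 = rod_volume(Lb, wb),
      beta = p$beta, kP = p$kP
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "target_eta") <- target_eta
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  class(out) <- c("sv_locus", "data.frame")
  out
}

#' @rdname run_constant_eta_sweep
#' @export
run_mreb_depletion <- function(target_eta = 2.7, width_range = c(0.9, 1.8),
                               ...) {
  run_constant_eta_sweep(target_eta, width_range, ...)
}

#' @rdname run_constant_eta_sweep
#' @export
run_filamentation <- function(target_eta = 11.0, width_range = c(0.9, 1.4),
                              ...) {
  run_constant_eta_sweep(target_eta, width_range, ...)
}

#' @export
print.sv_locus <- function(x, ...) {
  cat(sprintf(
    "Constant-aspect-ratio S-V locus: target eta %.3g, k = %.3g /h, %d sweep points\n",
    attr(x, "target_eta"), attr(x, "k"), nrow(x)
  ))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
plot.sv_locus <- function(x, ...) {
  graphics::plot(x$volume_um3, x$surface_um2,
    log = "xy", pch = 16,
    xlab = expression(V ~ (mu * m^3)), ylab = expression(S ~ (mu * m^2)), ...
  )
  g <- gamma_from_eta_rod(attr(x, "target_eta"))
  vv <- exp(seq(log(min(x$volume_um3)), log(max(x$volume_um3)),
    length.out = 50
  ))
  graphics::lines(vv, g * vv^(2 / 3), col = "red3")
  invisible(x)
}
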