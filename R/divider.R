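#' Surface-synthesis rate as a function of elongation rate
#'
#' Empirical linear relation between the surface-synthesis rate
#' \eqn{\beta} (rate of surface area production relative to volume,
#' \eqn{dS/dt = \beta V}) and the elongation rate k, obtained from fits of
#' \eqn{4k/w} against k for *E. coli* grown across nutrient conditions:
#' \deqn{\beta(k) = 3.701\,k + 0.996,}
#' with k in 1/h and \eqn{\beta} in 1/(h um).
#'
#' @param k Elongation rate, 1/h, >= 0. Vectorised.
#' @return \eqn{\beta}, 1/(h um).
#' @examples
#' beta_of_k(0.75) # 3.77175
#' @export
beta_of_k <- function(k) {
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("elongation rate must be finite and >= 0", call. = FALSE)
  }
  3.701 * k + 0.996
}

#' Model parameters for the growth-division simulator
#'
#' Bundles all rates and noise parameters of the single-cell model:
#' exponential elongation \eqn{dL/dt = kL}; division-protein (FtsZ)
#' production at rate \eqn{k_P} per unit length; division when the
#' accumulated (simple mode) or ring-bound (two-component mode) protein
#' reaches the width-proportional threshold \eqn{P_0 = \rho\pi w}; and the
#' width-control ODE
#' \eqn{dw/dt = w(k - \beta w/4)\,(1 - w/3L)/(1 - w/L)} with stable fixed
#' point \eqn{w = 4k/\beta}.
#'
#' Only the ratio \eqn{\rho\pi k/k_P} — the steady-state newborn aspect
#' ratio — is observable, so `rho` defaults to 1 molecule/um and, when `kP`
#' is not given, it is calibrated as \eqn{k_P = \rho\pi k/\eta_{birth}} with
#' a default newborn aspect-ratio target `eta_birth_target = 2.83`, chosen
#' so that the time-average aspect ratio over an exponential division cycle
#' is about 4.1 (a calibration of this package, matching the homeostatic
#' aspect ratio of steady-state rod bacteria).
#'
#' @param k Elongation rate, 1/h, > 0.
#' @param kP Division-protein production rate per unit length,
#'   molecules/(um h); default \eqn{\rho\pi k / \eta_{birth}}.
#' @param kb Cytoplasm-to-ring binding rate, 1/h (two-component mode);
#'   default `100 * k`, fast binding.
#' @param kd Ring disassembly rate, 1/h; default `0.01 * kb`, honouring
#'   \eqn{k_b \gg k_d}.
#' @param rho Ring density, molecules/um; threshold is
#'   \eqn{P_0 = \rho \pi w}.
#' @param beta Surface-synthesis rate relative to volume, 1/(h um); default
#'   [beta_of_k]`(k)`.
#' @param delta_sigma SD of the division-asymmetry noise: daughters get
#'   fractions \eqn{0.5 \pm \delta} of the mother length with
#'   \eqn{\delta \sim N(0, \sigma)}, \eqn{\sigma} in `[0, 0.2]`, default
#'   0.05; fractions are truncated to `[0.1, 0.9]` (an 8-sigma event at the
#'   default).
#' @param mode `"simple"` (track accumulated P, divide at \eqn{P = P_0}) or
#'   `"two_component"` (track cytoplasmic Pc and ring-bound Pr, divide at
#'   \eqn{P_r = P_0}).
#' @param eta_birth_target Newborn aspect-ratio target used only to default
#'   `kP`.
#' @param Pstar Cytoplasmic amount at birth, molecules (two-component mode).
#' @param width_dynamics If `FALSE` the width ODE is frozen (used e.g. for
#'   FtsZ-knockdown runs at fixed width).
#' @return An object of class `"model_params"`.
#' @examples
#' model_params(k = 0.75)
#' @export
model_params <- function(k = 0.75, kP = NULL, kb = NULL, kd = NULL,
                         rho = 1, beta = NULL, delta_sigma = 0.05,
                         mode = c("simple", "two_component"),
                         eta_birth_target = 2.83, Pstar = 0,
                         width_dynamics = TRUE) {
  mode <- match.arg(mode)
  if (!is.finite(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  if (!is.finite(rho) || rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (is.null(kP)) kP <- rho * pi * k / eta_birth_target
  if (!is.finite(kP) || kP < 0) stop("kP must be >= 0", call. = FALSE)
  if (is.null(beta)) beta <- beta_of_k(k)
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (is.null(kb)) kb <- 100 * k
  if (is.null(kd)) kd <- 0.01 * kb
  if (kb < 0 || kd < 0) stop("kb and kd must be >= 0", call. = FALSE)
  if (mode == "two_component" && kb <= 0) {
    stop("two-component mode requires kb > 0", call. = FALSE)
  }
  if (!is.finite(delta_sigma) || delta_sigma < 0 || delta_sigma > 0.2) {
    stop("delta_sigma must lie in [0, 0.2]", call. = FALSE)
  }
  structure(
    list(
      k = k, kP = kP, kb = kb, kd = kd, rho = rho, beta = beta,
      delta_sigma = delta_sigma, mode = mode,
      eta_birth_target = eta_birth_target, Pstar = Pstar,
      width_dynamics = isTRUE(width_dynamics)
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Growth-division model parameters (", x$mode, " mode)\n", sep = "")
  cat(sprintf(
    "  k = %.4g /h   kP = %.4g /(um h)   rho = %.4g /um   beta = %.4g /(h um)\n",
    x$k, x$kP, x$rho, x$beta
  ))
  cat(sprintf(
    "  kb = %.4g /h   kd = %.4g /h   delta_sigma = %.3g   Pstar = %.4g\n",
    x$kb, x$kd, x$delta_sigma, x$Pstar
  ))
  cat(sprintf(
    "  division threshold P0 = rho*pi*w; steady newborn aspect ratio rho*pi*k/kP = %.3f\n",
    x$rho * pi * x$k / x$kP
  ))
  if (!x$width_dynamics) cat("  width dynamics frozen\n")
  invisible(x)
}

#' One simulated cell's dynamical state
#'
#' @param L Length, um.
#' @param w Width, um, `L >= w > 0`.
#' @param P Accumulated division protein since birth (simple mode),
#'   molecules.
#' @param Pc,Pr Cytoplasmic and ring-bound amounts (two-component mode),
#'   molecules.
#' @param t Absolute time, h.
#' @param generation Generation counter.
#' @return An object of class `"cell_state"`.
#' @export
cell_state <- function(L, w, P = 0, Pc = 0, Pr = 0, t = 0, generation = 0L) {
  if (any(w <= 0) || any(L < w)) {
    stop("cell state requires L >= w > 0", call. = FALSE)
  }
  if (any(P < 0) || any(Pc < 0) || any(Pr < 0)) {
    stop("protein amounts must be >= 0", call. = FALSE)
  }
  structure(
    list(
      L = L, w = w, P = P, Pc = Pc, Pr = Pr, t = t,
      generation = as.integer(generation)
    ),
    class = "cell_state"
  )
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf(
    "cell_state: L = %.4g um, w = %.4g um, P = %.4g, Pc = %.4g, Pr = %.4g, t = %.4g h, gen %d\n",
    x$L[1], x$w[1], x$P[1], x$Pc[1], x$Pr[1], x$t[1], x$generation[1]
  ))
  invisible(x)
}

# width ODE right-hand side; clamps L at 1.001 w (removable singularity of
# the shape factor at L = w; newborns in all supported regimes have L > w)
.width_rate <- function(L, w, params) {
  if (!params$width_dynamics || params$beta == 0) {
    return(rep(0, length(w)))
  }
  Lc <- pmax(L, 1.001 * w)
  shape <- (1 - w / (3 * Lc)) / (1 - w / Lc)
  w * (params$k - params$beta * w / 4) * shape
}

#' Time derivatives of the cell state
#'
#' Right-hand sides of the coupled model:
#' \eqn{dL/dt = kL};
#' simple mode \eqn{dP/dt = k_P L}; two-component mode
#' \eqn{dP_c/dt = -k_b P_c + k_d P_r + k_P L},
#' \eqn{dP_r/dt = k_b P_c - k_d P_r};
#' width ODE \eqn{dw/dt = w(k - \beta w/4)(1 - w/3L)/(1 - w/L)}.
#' The width ODE's shape factor is singular at \eqn{L = w}; the
#' implementation clamps L at `1.001 * w` there.
#'
#' @param state A [cell_state()] (fields may be vectors).
#' @param params A [model_params()].
#' @return A list with elements `dL`, `dw` and, depending on mode, `dP` or
#'   `dPc`, `dPr` (per hour).
#' @examples
#' p <- model_params(k = 0.75)
#' cell_derivatives(cell_state(L = 2.5, w = 0.8), p)
#' @export
cell_derivatives <- function(state, params) {
  dL <- params$k * state$L
  dw <- .width_rate(state$L, state$w, params)
  if (params$mode == "simple") {
    list(dL = dL, dw = dw, dP = params$kP * state$L)
  } else {
    list(
      dL = dL, dw = dw,
      dPc = -params$kb * state$Pc + params$kd * state$Pr + params$kP * state$L,
      dPr = params$kb * state$Pc - params$kd * state$Pr
    )
  }
}

# --- vectorised fixed-step RK4 over the ensemble -------------------------
# y is a list of equal-length vectors L, w, P, Pc, Pr; dt may be a vector.
.deriv <- function(L, w, Pc, Pr, params) {
  dw <- .width_rate(L, w, params)
  if (params$mode == "simple") {
    list(dL = params$k * L, dw = dw, dPc = params$kP * L, dPr = 0)
  } else {
    list(
      dL = params$k * L, dw = dw,
      dPc = -params$kb * Pc + params$kd * Pr + params$kP * L,
      dPr = params$kb * Pc - params$kd * Pr
    )
  }
}

.rk4 <- function(L, w, Pc, Pr, params, dt) {
  k1 <- .deriv(L, w, Pc, Pr, params)
  h2 <- dt / 2
  k2 <- .deriv(L + h2 * k1$dL, w + h2 * k1$dw, Pc + h2 * k1$dPc,
    Pr + h2 * k1$dPr, params)
  k3 <- .deriv(L + h2 * k2$dL, w + h2 * k2$dw, Pc + h2 * k2$dPc,
    Pr + h2 * k2$dPr, params)
  k4 <- .deriv(L + dt * k3$dL, w + dt * k3$dw, Pc + dt * k3$dPc,
    Pr + dt * k3$dPr, params)
  s <- dt / 6
  list(
    L = L + s * (k1$dL + 2 * k2$dL + 2 * k3$dL + k4$dL),
    w = w + s * (k1$dw + 2 * k2$dw + 2 * k3$dw + k4$dw),
    Pc = Pc + s * (k1$dPc + 2 * k2$dPc + 2 * k3$dPc + k4$dPc),
    Pr = Pr + s * (k1$dPr + 2 * k2$dPr + 2 * k3$dPr + k4$dPr)
  )
}

# cubic Hermite interpolation at fraction theta of a step of size dt
.hermite <- function(theta, y0, d0, y1, d1, dt) {
  t2 <- theta * theta
  t3 <- t2 * theta
  (2 * t3 - 3 * t2 + 1) * y0 + (t3 - 2 * t2 + theta) * dt * d0 +
    (-2 * t3 + 3 * t2) * y1 + (t3 - t2) * dt * d1
}

# daughter fraction 0.5 + delta, delta ~ N(0, sigma) truncated to [0.1, 0.9]
.draw_fraction <- function(n, sigma) {
  if (sigma == 0) {
    return(rep(0.5, n))
  }
  f <- 0.5 + stats::rnorm(n, 0, sigma)
  bad <- f < 0.1 | f > 0.9
  while (any(bad)) {
    f[bad] <- 0.5 + stats::rnorm(sum(bad), 0, sigma)
    bad <- f < 0.1 | f > 0.9
  }
  f
}

# Advance the whole ensemble by dt (vector allowed), handling at most one
# division per cell per step. ens: list(L, w, Pc, Pr, t, generation).
# In simple mode Pc carries the accumulated amount P (Pr unused, 0).
# Returns list(ens, events) where events is NULL or a data.frame.
.ensemble_step <- function(ens, params, dt, allow_divide = TRUE,
                           second_pass = FALSE) {
  n <- length(ens$L)
  dt <- rep_len(dt, n)
  d0 <- .deriv(ens$L, ens$w, ens$Pc, ens$Pr, params)
  y1 <- .rk4(ens$L, ens$w, ens$Pc, ens$Pr, params, dt)
  simple <- params$mode == "simple"
  marker0 <- if (simple) ens$Pc else ens$Pr
  marker1 <- if (simple) y1$Pc else y1$Pr
  thr0 <- params$rho * pi * ens$w
  thr1 <- params$rho * pi * y1$w
  cross <- allow_divide & (marker1 - thr1 >= 0) & (marker0 - thr0 < 0)
  # cells already at/over threshold at step start divide immediately
  cross_at0 <- allow_divide & (marker0 - thr0 >= 0)
  events <- NULL
  out <- list(
    L = y1$L, w = y1$w, Pc = y1$Pc, Pr = y1$Pr,
    t = ens$t + max(dt), generation = ens$generation
  )
  idx <- which(cross | cross_at0)
  if (length(idx)) {
    if (second_pass) {
      stop("integration step too large: two divisions within one step",
        call. = FALSE
      )
    }
    d1 <- .deriv(y1$L, y1$w, y1$Pc, y1$Pr, params)
    theta <- rep(0, length(idx))
    bis <- which(!cross_at0[idx])
    if (length(bis)) {
      ii <- idx[bis]
      lo <- rep(0, length(ii))
      hi <- rep(1, length(ii))
      gfun <- function(th) {
        wth <- .hermite(th, ens$w[ii], d0$dw[ii], y1$w[ii], d1$dw[ii], dt[ii])
        mth <- if (simple) {
          # accumulated protein is exact given exponential length growth
          ens$Pc[ii] + params$kP * ens$L[ii] *
            (exp(params$k * th * dt[ii]) - 1) / params$k
        } else {
          .hermite(th, ens$Pr[ii], d0$dPr[ii], y1$Pr[ii], d1$dPr[ii], dt[ii])
        }
        mth - params$rho * pi * wth
      }
      for (iter in 1:52) {
        mid <- (lo + hi) / 2
        pos <- gfun(mid) >= 0
        hi[pos] <- mid[pos]
        lo[!pos] <- mid[!pos]
      }
      theta[bis] <- (lo + hi) / 2
    }
    tau <- theta * dt[idx]
    L_div <- ens$L[idx] * exp(params$k * tau) # length is exactly exponential
    d1w <- d1$dw[idx]
    w_div <- .hermite(theta, ens$w[idx], d0$dw[idx], y1$w[idx], d1w, dt[idx])
    f <- .draw_fraction(length(idx), params$delta_sigma)
    keep_first <- stats::runif(length(idx)) < 0.5
    frac <- ifelse(keep_first, f, 1 - f)
    L_new <- frac * L_div
    events <- data.frame(
      cell = idx,
      time_h = ens$t + tau,
      mother_length_um = L_div,
      width_um = w_div,
      daughter_fraction = frac,
      generation = ens$generation[idx] + 1L,
      newborn_length_um = L_new,
      newborn_eta = L_new / w_div
    )
    # daughter state at the crossing, then advance over the step remainder
    sub <- list(
      L = L_new, w = w_div,
      Pc = if (simple) rep(0, length(idx)) else rep(params$Pstar, length(idx)),
      Pr = rep(0, length(idx)),
      t = ens$t, generation = ens$generation[idx] + 1L
    )
    rem <- dt[idx] - tau
    sub2 <- .ensemble_step(sub, params, rem, allow_divide = TRUE,
      second_pass = TRUE)
    out$L[idx] <- sub2$ens$L
    out$w[idx] <- sub2$ens$w
    out$Pc[idx] <- sub2$ens$Pc
    out$Pr[idx] <- sub2$ens$Pr
    out$generation[idx] <- ens$generation[idx] + 1L
  }
  list(ens = out, events = events)
}

#' Advance a single cell by one integration step
#'
#' Integrates the coupled length/width/protein dynamics over `dt` with a
#' fixed-step 4th-order Runge-Kutta step. If the division threshold
#' (\eqn{P \ge \rho\pi w} in simple mode, \eqn{P_r \ge \rho\pi w} in
#' two-component mode, evaluated at the crossing) is crossed within the
#' step, the crossing time is located by bisection on the interpolated step
#' (to about 1e-9 h at default steps), a division event is emitted, and the
#' state becomes one daughter chosen at random: length \eqn{f L} with
#' \eqn{f = 0.5 + \delta}, width unchanged, protein reset (`P = 0`; in
#' two-component mode `Pr = 0`, `Pc = Pstar`). Randomness is drawn from R's
#' global RNG: seed the simulation once with [set.seed()].
#'
#' @param state A [cell_state()].
#' @param params A [model_params()].
#' @param dt Step size, h, > 0. A step so large that a daughter would
#'   divide again within it is an error.
#' @return A list with elements `state` (the new [cell_state()]) and
#'   `event` (`NULL`, or a one-row data.frame with `time_h`,
#'   `mother_length_um`, `width_um`, `daughter_fraction`, `generation`,
#'   `newborn_length_um`, `newborn_eta`).
#' @examples
#' set.seed(1)
#' p <- model_params(k = 0.75)
#' advance_cell(cell_state(L = 2.3, w = 0.8), p, dt = 0.001)
#' @export
advance_cell <- function(state, params, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  simple <- params$mode == "simple"
  ens <- list(
    L = state$L, w = state$w,
    Pc = if (simple) state$P else state$Pc,
    Pr = if (simple) 0 else state$Pr,
    t = state$t, generation = state$generation
  )
  step <- .ensemble_step(ens, params, dt)
  e <- step$ens
  new_state <- cell_state(
    L = e$L, w = e$w,
    P = if (simple) e$Pc else max(e$Pc + e$Pr - params$Pstar, 0),
    Pc = if (simple) 0 else e$Pc,
    Pr = if (simple) 0 else e$Pr,
    t = e$t, generation = e$generation
  )
  list(state = new_state, event = step$events)
}

#' Default integration step
#'
#' `min(0.001 h, 0.01/k)`: small enough that the smooth, non-stiff model
#' ODEs are integrated far below other error sources while the division
#' event time is located by bisection within the step.
#'
#' @param params A [model_params()].
#' @return Step size, h.
#' @export
default_dt <- function(params) min(0.001, 0.01 / params$k)

#' Closed-form division cycle at constant width (simple mode)
#'
#' With \eqn{dP/dt = k_P L}, \eqn{L = L_{birth} e^{kt}} and threshold
#' \eqn{P_0 = \rho\pi w}, division occurs at
#' \deqn{T = \frac{1}{k}\ln\!\left(1 + \frac{\rho\pi w\,k}{k_P
#'   L_{birth}}\right)}
#' and the added length is
#' \deqn{\Delta L = \frac{\rho\pi w\, k}{k_P},}
#' independent of birth length — the adder. \eqn{\Delta L/w = \rho\pi k/k_P}
#' is the homeostatic newborn aspect ratio.
#'
#' @param params A [model_params()] in simple mode.
#' @param L_birth Birth length, um.
#' @param w Cell width, um (held constant over the cycle).
#' @return A list with `T_div` (h) and `delta_L` (um).
#' @examples
#' p <- model_params(k = 0.75)
#' analytic_cycle(p, L_birth = 2.26, w = 0.8)
#' @export
analytic_cycle <- function(params, L_birth, w) {
  if (params$mode != "simple") {
    stop("analytic cycle is defined for simple-accumulation mode",
      call. = FALSE
    )
  }
  if (params$kP <= 0) {
    stop("kP must be > 0 for a finite division time", call. = FALSE)
  }
  P0 <- params$rho * pi * w
  delta_L <- P0 * params$k / params$kP
  list(
    T_div = log(1 + delta_L / L_birth) / params$k,
    delta_L = delta_L
  )
}

#' Steady-state cell width
#'
#' Fixed point \eqn{w = 4k/\beta} of the width-control ODE; stable, and
#' independent of cell length.
#'
#' @param params A [model_params()] with `beta > 0`.
#' @return Width, um.
#' @examples
#' steady_state_width(model_params(k = 0.75)) # 4 * 0.75 / beta_of_k(0.75)
#' @export
steady_state_width <- function(params) {
  if (params$beta <= 0) {
    stop("beta must be > 0 for a finite steady-state width", call. = FALSE)
  }
  4 * params$k / params$beta
}

#' Simulate one lineage for a number of generations
#'
#' Runs a single mother-machine-style lineage (one daughter kept per
#' division) and records per-generation birth and division lengths, the
#' time-averaged width over each cycle, the added length and the
#' added-length-to-width ratio.
#'
#' @param params A [model_params()].
#' @param n_generations Number of completed generations to record.
#' @param L0,w0 Initial length and width, um; default: the analytic steady
#'   state (newborn length \eqn{\rho\pi w k/k_P} at width \eqn{4k/\beta}).
#' @param dt Integration step, h; default [default_dt()].
#' @param seed Optional integer seed.
#' @return A data.frame with one row per generation: `generation`,
#'   `birth_time_h`, `division_time_h`, `birth_length_um`,
#'   `division_length_um`, `mean_width_um`, `delta_L_um`, `delta_L_over_w`.
#' @examples
#' simulate_lineage(model_params(k = 0.75), n_generations = 3, seed = 1)
#' @export
simulate_lineage <- function(params, n_generations, L0 = NULL, w0 = NULL,
                             dt = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dt)) dt <- default_dt(params)
  if (is.null(w0)) {
    w0 <- if (params$beta > 0 && params$width_dynamics) {
      steady_state_width(params)
    } else {
      1
    }
  }
  if (is.null(L0)) L0 <- params$rho * pi * w0 * params$k / max(params$kP, 1e-12)
  simple <- params$mode == "simple"
  ens <- list(
    L = L0, w = w0,
    Pc = if (simple) 0 else params$Pstar, Pr = 0,
    t = 0, generation = 0L
  )
  rec <- vector("list", n_generations)
  gen <- 0L
  birth_t <- 0
  birth_L <- L0
  w_sum <- 0
  w_n <- 0L
  max_steps <- ceiling(50 * n_generations * log(2) / params$k / dt) + 1e5
  for (step_i in seq_len(max_steps)) {
    w_sum <- w_sum + ens$w
    w_n <- w_n + 1L
    st <- .ensemble_step(ens, params, dt)
    ens <- st$ens
    if (!is.null(st$events)) {
      gen <- gen + 1L
      ev <- st$events
      rec[[gen]] <- data.frame(
        generation = gen,
        birth_time_h = birth_t,
        division_time_h = ev$time_h,
        birth_length_um = birth_L,
        division_length_um = ev$mother_length_um,
        mean_width_um = w_sum / w_n,
        delta_L_um = ev$mother_length_um - birth_L,
        delta_L_over_w = (ev$mother_length_um - birth_L) / (w_sum / w_n)
      )
      birth_t <- ev$time_h
      birth_L <- ev$newborn_length_um
      w_sum <- 0
      w_n <- 0L
      if (gen >= n_generations) break
    }
  }
  if (gen < n_generations) {
    stop("lineage did not reach the requested generations (kP too small?)",
      call. = FALSE
    )
  }
  do.call(rbind, rec)
}
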