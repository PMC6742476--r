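#' Synthetic population-level shape table
#'
#' Generates a shape table with the statistical backbone of pooled
#' multi-condition surface-volume data: volumes drawn log-uniformly over
#' (by default) two decades, surfaces on the power law
#' \eqn{S = \gamma V^{\beta}} with log-normal multiplicative scatter, and
#' per-row dimensions back-solved from the exact spherocylinder geometry
#' (rows whose scatter would put them below the sphere bound
#' \eqn{S/V^{2/3} < \gamma_{sphere}} are redrawn; the redraw count is
#' returned as an attribute). Conditions are volume strata, with a growth
#' rate attached per condition by inverting the nutrient growth law at the
#' stratum's geometric-mean volume.
#'
#' Volumes are drawn log-uniformly so the log-log fit has balanced leverage
#' across the range; the default aspect-ratio generator is calibrated to
#' the printed population statistics of rod bacteria (mean 4.14, CV 14%),
#' not to any raw dataset.
#'
#' @param n Number of rows.
#' @param gamma True prefactor.
#' @param exponent True power-law exponent.
#' @param sigma_log SD of the log-normal scatter of S about the law.
#' @param v_range Volume range, um^3 (log-uniform; default two decades).
#' @param n_conditions Number of volume-stratum conditions.
#' @param growth_law List with `V0` (um^3) and `alpha` (h) used to attach
#'   growth rates; defaults are representative of *E. coli* nutrient
#'   limitation.
#' @param seed Optional integer seed.
#' @return A completed shape table (see [complete_shape_table()]) with
#'   attribute `redraws`.
#' @examples
#' tab <- make_population_table(n = 100, seed = 1)
#' fit_power_law(tab)
#' @export
make_population_table <- function(n = 1000, gamma = 6.24, exponent = 2 / 3,
                                  sigma_log = 0.05, v_range = c(0.2, 20),
                                  n_conditions = 5,
                                  growth_law = list(V0 = 0.5, alpha = 1),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(v_range <= 0) || v_range[2] <= v_range[1]) {
    stop("v_range must be positive and increasing", call. = FALSE)
  }
  if (sigma_log < 0) stop("sigma_log must be >= 0", call. = FALSE)
  V <- exp(stats::runif(n, log(v_range[1]), log(v_range[2])))
  S <- gamma * V^exponent * exp(stats::rnorm(n, 0, sigma_log))
  g_row <- S / V^(2 / 3)
  redraws <- 0L
  bad <- g_row < gamma_sphere
  while (any(bad)) {
    redraws <- redraws + sum(bad)
    nb <- sum(bad)
    V[bad] <- exp(stats::runif(nb, log(v_range[1]), log(v_range[2])))
    S[bad] <- gamma * V[bad]^exponent * exp(stats::rnorm(nb, 0, sigma_log))
    g_row <- S / V^(2 / 3)
    bad <- g_row < gamma_sphere
  }
  eta <- eta_from_gamma_rod(g_row)
  dims <- rod_dimensions_from_volume(V, eta)
  strat <- cut(log(V), breaks = n_conditions, labels = FALSE)
  vbar <- tapply(log(V), strat, mean)
  kappa_cond <- (vbar - log(growth_law$V0)) / growth_law$alpha
  tab <- data.frame(
    condition = sprintf("cond%02d", strat),
    length_um = dims$length,
    width_um = dims$width,
    growth_rate_per_h = pmax(as.numeric(kappa_cond[strat]), 0.01),
    surface_um2 = S,
    volume_um3 = V,
    geometry = "rod"
  )
  tab <- complete_shape_table(tab)
  attr(tab, "redraws") <- redraws
  tab
}

#' Synthetic newborn-cell shape table
#'
#' Emulates mother-machine newborn data across growth conditions: for each
#' condition (growth rate kappa) widths are drawn around the steady-state
#' value \eqn{4\kappa/\beta(\kappa)} with narrow unit-mean log-normal noise,
#' and aspect ratios are drawn from a log-normal whose parameters are the
#' **same in every condition** — the newborn aspect-ratio distribution is
#' independent of growth rate by construction, as it is in steady-state
#' rod bacteria.
#'
#' The default log-normal is calibrated so the arithmetic mean is
#' `eta_mean` and the CV is about `eta_sigma_log`:
#' `meanlog = log(eta_mean) - eta_sigma_log^2/2`.
#'
#' @param n_per_condition Cells per condition.
#' @param kappas Growth rates of the conditions, 1/h.
#' @param eta_mean Target arithmetic-mean aspect ratio.
#' @param eta_sigma_log Log-scale SD of the aspect-ratio distribution.
#' @param width_sigma_log Log-scale SD of the width noise.
#' @param seed Optional integer seed.
#' @return A completed shape table with one row per cell.
#' @examples
#' tab <- make_newborn_table(n_per_condition = 50, seed = 1)
#' aspect_ratio_summary(tab$eta)
#' @export
make_newborn_table <- function(n_per_condition = 2000,
                               kappas = c(0.35, 0.55, 0.75, 1.05, 1.35),
                               eta_mean = 4.14, eta_sigma_log = 0.14,
                               width_sigma_log = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meanlog <- log(eta_mean) - eta_sigma_log^2 / 2
  rows <- lapply(seq_along(kappas), function(i) {
    kap <- kappas[i]
    w0 <- 4 * kap / beta_of_k(kap)
    w <- w0 * exp(stats::rnorm(n_per_condition, -width_sigma_log^2 / 2,
      width_sigma_log))
    eta <- exp(stats::rnorm(n_per_condition, meanlog, eta_sigma_log))
    eta <- pmax(eta, 1)
    data.frame(
      condition = sprintf("kappa%.2f", kap),
      length_um = eta * w,
      width_um = w,
      growth_rate_per_h = kap,
      surface_um2 = NA_real_,
      volume_um3 = NA_real_,
      geometry = "rod"
    )
  })
  complete_shape_table(do.call(rbind, rows))
}

#' Synthetic single-lineage table
#'
#' Wraps [simulate_lineage()] to produce a per-generation table of birth
#' and division lengths, mean width, added length and the added-length to
#' width ratio — the quantity the threshold-accumulation model predicts to
#' be constant across generations and growth conditions.
#'
#' @param params A [model_params()].
#' @param n_generations Generations to simulate.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `generation`, `birth_length_um`,
#'   `division_length_um`, `mean_width_um`, `delta_L_um`,
#'   `delta_L_over_w`.
#' @examples
#' make_lineage_table(model_params(k = 0.75), n_generations = 3, seed = 1)
#' @export
make_lineage_table <- function(params = model_params(), n_generations = 50,
                               seed = NULL) {
  lin <- simulate_lineage(params, n_generations, seed = seed)
  lin[c(
    "generation", "birth_length_um", "division_length_um",
    "mean_width_um", "delta_L_um", "delta_L_over_w"
  )]
}
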