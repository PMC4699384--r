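# Kinetic model of H3K27me3 abundance under enzyme-dependent deposition and
# cell-division dilution.
#
# The mark is modeled as a site-occupancy fraction m in [0, 1] obeying the
# linear mass-action ODE
#
#     dm/dt = alpha * E * (1 - m) - delta * m - g * ln(2) * m
#
# where alpha is the deposition rate per unit enzyme, delta the enzymatic
# turnover rate, E the enzyme abundance (possibly coupled to growth as
# E = c0 + c1 * g), and g the growth rate in divisions per cell per hour;
# exponential growth at rate g dilutes the mark at rate g*ln2. A discrete
# variant instead halves m instantaneously at each division (new histones
# unmarked) with the same deposition/turnover dynamics in between.

#' Kinetic parameters for the mark-homeostasis model
#'
#' @param alpha Deposition rate per unit enzyme per hour (>= 0).
#' @param delta Mark turnover rate per hour (>= 0).
#' @param g Growth rate, divisions per cell per hour (>= 0).
#' @param E Enzyme abundance (arbitrary units); alternatively supply the
#'   coupling `c0`, `c1` so that `E = c0 + c1 * g`.
#' @param c0,c1 Optional affine enzyme-growth coupling (used when `E` is NULL).
#' @return List of class `mark_kinetics_params`.
#' @export
mark_kinetics_params <- function(alpha, delta, g, E = NULL, c0 = NULL,
                                 c1 = NULL) {
  check_number(alpha, "alpha", lower = 0)
  check_number(delta, "delta", lower = 0)
  check_number(g, "g", lower = 0)
  if (is.null(E)) {
    if (is.null(c0) || is.null(c1))
      stop_bad("supply either 'E' or the coupling (c0, c1)")
    check_number(c0, "c0"); check_number(c1, "c1")
    E <- c0 + c1 * g
  }
  check_number(E, "E", lower = 0)
  structure(list(alpha = alpha, delta = delta, g = g, E = E,
                 c0 = c0, c1 = c1),
            class = "mark_kinetics_params")
}

#' Steady-state mark occupancy
#'
#' Closed form of the continuous model:
#' \eqn{m^* = \alpha E / (\alpha E + \delta + g \ln 2)}.
#' Under proportional enzyme-growth coupling (`E = c1 * g`, `delta = 0`) this
#' is independent of the growth rate — the homeostatic regime; with fixed or
#' insufficiently coupled enzyme, m* declines with growth.
#'
#' @param params A `mark_kinetics_params` object.
#' @return Steady-state occupancy in \[0, 1\].
#' @export
steady_state_mark <- function(params) {
  stopifnot(inherits(params, "mark_kinetics_params"))
  ae <- params$alpha * params$E
  denom <- ae + params$delta + params$g * log(2)
  if (denom == 0) stop_bad("all rates zero: steady state undefined")
  ae / denom
}

#' Simulate mark dynamics
#'
#' Continuous variant: fixed-step RK4 integration of the ODE. Discrete
#' variant: exact linear-ODE propagation between divisions with `m -> m/2` at
#' division times `k / g` (requires `g > 0` and `dt` smaller than the
#' division interval).
#'
#' @param params A `mark_kinetics_params` object.
#' @param t_end Simulation horizon in hours (> 0).
#' @param dt Time step in hours (> 0; default 0.01).
#' @param m0 Initial occupancy in \[0, 1\] (default 0.5).
#' @param variant `"continuous"` or `"discrete_division"`.
#' @return Data frame of class `mark_trajectory`: `time`, `m`; for the
#'   discrete variant, attribute `division_times`.
#' @export
simulate_mark_dynamics <- function(params, t_end, dt = 0.01, m0 = 0.5,
                                   variant = c("continuous",
                                               "discrete_division")) {
  stopifnot(inherits(params, "mark_kinetics_params"))
  variant <- match.arg(variant)
  check_number(t_end, "t_end", lower = 0, strict_lower = TRUE)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(m0, "m0", lower = 0, upper = 1)
  ae <- params$alpha * params$E
  if (variant == "continuous") {
    f <- function(m) ae * (1 - m) - params$delta * m - params$g * log(2) * m
    n <- ceiling(t_end / dt)
    tt <- numeric(n + 1); mm <- numeric(n + 1)
    tt[1] <- 0; mm[1] <- m0
    m <- m0
    for (i in seq_len(n)) {
      h <- min(dt, t_end - tt[i])
      k1 <- f(m); k2 <- f(m + h / 2 * k1); k3 <- f(m + h / 2 * k2)
      k4 <- f(m + h * k3)
      m <- m + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      m <- min(max(m, 0), 1)
      tt[i + 1] <- tt[i] + h; mm[i + 1] <- m
    }
    out <- data.frame(time = tt, m = mm)
    attr(out, "division_times") <- numeric(0)
  } else {
    if (params$g <= 0) stop_bad("discrete variant requires g > 0")
    T_div <- 1 / params$g
    if (dt >= T_div)
      stop_bad("dt (%g h) must be smaller than the division interval (%g h)",
               dt, T_div)
    r <- ae + params$delta
    m_eq <- if (r > 0) ae / r else 0
    # exact propagation of dm/dt = ae - r m over a step h
    prop <- function(m, h) {
      if (r == 0) m else m_eq + (m - m_eq) * exp(-r * h)
    }
    times <- seq(0, t_end, by = dt)
    if (times[length(times)] < t_end) times <- c(times, t_end)
    div_times <- seq(T_div, t_end, by = T_div)
    grid <- sort(unique(c(times, div_times)))
    mm <- numeric(length(grid))
    m <- m0; t_prev <- 0
    for (i in seq_along(grid)) {
      m <- prop(m, grid[i] - t_prev)
      t_prev <- grid[i]
      mm[i] <- m
      if (any(abs(div_times - grid[i]) < 1e-12)) m <- m / 2  # division
    }
    out <- data.frame(time = grid, m = mm)
    attr(out, "division_times") <- div_times
  }
  class(out) <- c("mark_trajectory", "data.frame")
  out
}

#' Pre-division fixed point of the discrete-division model
#'
#' Closed form of the periodic steady state reached by the discrete variant:
#' the mark level immediately before each division converges to
#' \eqn{\hat m = m_{eq}(1 - e^{-rT}) / (1 - e^{-rT}/2)} with
#' \eqn{r = \alpha E + \delta}, \eqn{m_{eq} = \alpha E / r}, \eqn{T = 1/g}.
#'
#' @param params A `mark_kinetics_params` object with `g > 0`.
#' @return Pre-division fixed-point occupancy.
#' @export
discrete_fixed_point <- function(params) {
  stopifnot(inherits(params, "mark_kinetics_params"))
  if (params$g <= 0) stop_bad("requires g > 0")
  r <- params$alpha * params$E + params$delta
  if (r == 0) return(0)
  m_eq <- params$alpha * params$E / r
  ert <- exp(-r / params$g)
  m_eq * (1 - ert) / (1 - ert / 2)
}

#' Steady-state sweep over growth rates
#'
#' Evaluates the steady-state mark across growth rates under an affine
#' enzyme-growth coupling `E = c0 + c1 * g` (e.g. control vs knockdown with
#' reduced slope), and reports monotonicity flags.
#'
#' @param alpha,delta Kinetic rates (>= 0).
#' @param c0,c1 Coupling intercept and slope.
#' @param rates Growth rates (> 0), divisions per cell per hour.
#' @return Data frame `g`, `E`, `m_star`, with attributes
#'   `monotone_increasing` / `monotone_decreasing` / `constant` over the
#'   supplied rates.
#' @export
sweep_growth_rates <- function(alpha, delta, c0, c1, rates) {
  if (any(rates <= 0)) stop_bad("growth rates must be > 0")
  rates <- sort(rates)
  rows <- lapply(rates, function(g) {
    p <- mark_kinetics_params(alpha, delta, g, c0 = c0, c1 = c1)
    data.frame(g = g, E = p$E, m_star = steady_state_mark(p))
  })
  out <- do.call(rbind, rows)
  d <- diff(out$m_star)
  eps <- 1e-12
  attr(out, "monotone_increasing") <- all(d > eps)
  attr(out, "monotone_decreasing") <- all(d < -eps)
  attr(out, "constant") <- all(abs(d) <= eps * pmax(1, abs(out$m_star[-1])))
  out
}

#' Fit deposition and turnover rates from steady-state observations
#'
#' Nonlinear least squares for `m = alpha*E / (alpha*E + delta + g*ln2)` on
#' observed (g, E, m) triplets. Parameters are optimized on the log scale to
#' enforce positivity, with a Nelder-Mead refinement of a coarse grid start.
#'
#' @param observations Data frame with columns `g`, `E`, `m` (>= 3 rows, not
#'   all identical in both g and E).
#' @return List: `alpha`, `delta`, `residual_norm`, `converged`.
#' @export
fit_steady_state_params <- function(observations) {
  obs <- as.data.frame(observations)
  if (!all(c("g", "E", "m") %in% names(obs)))
    stop_bad("observations need columns g, E, m")
  if (nrow(obs) < 3L) stop_bad("need >= 3 observations")
  if (length(unique(obs$g)) == 1L && length(unique(obs$E)) == 1L)
    stop_bad("degenerate design: g and E both constant")
  model <- function(alpha, delta) {
    ae <- alpha * obs$E
    ae / (ae + delta + obs$g * log(2))
  }
  rss <- function(par) {
    pred <- model(exp(par[1]), exp(par[2]))
    sum((obs$m - pred)^2)
  }
  # coarse log-grid start, then Nelder-Mead
  grid <- expand.grid(la = seq(-6, 4, length.out = 12),
                      ld = seq(-9, 3, length.out = 12))
  vals <- apply(grid, 1, rss)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, rss, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt <- stats::optim(opt$par, rss, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(alpha = exp(opt$par[1]), delta = exp(opt$par[2]),
       residual_norm = sqrt(opt$value), converged = opt$convergence == 0)
}

#' Simple linear regression with significance of the slope
#'
#' OLS slope/intercept, coefficient of determination, and the two-sided
#' t-test p-value on the slope — the statistic reported on
#' signal-vs-proliferation correlation plots.
#'
#' @param x,y Numeric vectors, >= 3 points, `var(x) > 0`.
#' @return List of class `linear_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `df`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) stop_bad("length mismatch")
  if (length(x) < 3L) stop_bad("need >= 3 points")
  if (stats::var(x) == 0) stop_bad("var(x) is zero")
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b1 <- sxy / sxx
  b0 <- mean(y) - b1 * mean(x)
  resid <- y - b0 - b1 * x
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(resid^2) / sst
  df <- n - 2L
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 / sxx)
  if (se == 0) {
    p <- if (b1 == 0) 1 else 0
  } else {
    p <- 2 * stats::pt(-abs(b1 / se), df = df)
  }
  structure(list(slope = b1, intercept = b0, r_squared = r2,
                 p_value = p, df = df),
            class = "linear_fit")
}
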