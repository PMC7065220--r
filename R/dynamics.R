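# Nonsteady-state analysis: induction metrics, stomatal kinetics fitting,
# dynamic A/ci decomposition, and Ball-Berry fitting from light curves.

# first time (s, relative) at which the linearly interpolated series
# crosses `level` from below; NA when never reached
.first_crossing <- function(t, x, level) {
  above <- x >= level
  if (above[1]) return(t[1])
  i <- which(above)[1]
  if (is.na(i)) return(NA_real_)
  t0 <- t[i - 1]; t1 <- t[i]
  x0 <- x[i - 1]; x1 <- x[i]
  t0 + (level - x0) / (x1 - x0) * (t1 - t0)
}

#' Photosynthetic induction metrics from a shade-sun transition
#'
#' The reference "maximum" is the value 30 min after the transition (not
#' baseline-subtracted by default). `T50A`/`T90A` are the first crossing
#' times of 50%/90% of that reference, by linear interpolation between
#' samples; `T50gs` analogously for stomatal conductance. `gsT0` is the
#' last conductance sample at or before the transition. `CCF` is the sum of
#' the assimilation samples over the first 5 min (the 10-s sampling
#' convention of the published tables); the true time integral in
#' umol m-2 is also returned as `CCF_integral`.
#'
#' @param trace a [gasex_trace()] or `sim_trace` sampled (about) every 10 s.
#' @param high_light_start time (s, on the trace clock) of the transition.
#' @param baseline_subtract reference T50/T90 to the rise above the
#'   pre-transition baseline instead of the absolute value.
#' @return list of class `induction_metrics`: `T50A`, `T90A`, `T50gs`
#'   (min), `CCF`, `CCF_integral`, `gsT0`, `A_final`, `gs_final`,
#'   `provisional` (TRUE when the trace ends before 30 min post-transition).
#' @export
induction_metrics <- function(trace, high_light_start,
                              baseline_subtract = FALSE) {
  t <- trace$time_s - high_light_start
  A <- trace$a_umol_m2_s
  gs <- trace$gsw_mol_m2_s
  pre <- t <= 0
  if (!any(pre)) stop("trace contains no samples at or before the transition")
  gsT0 <- gs[max(which(pre))]
  post <- t >= 0
  tp <- t[post]; Ap <- A[post]; gp <- gs[post]
  provisional <- max(tp) < 1800
  t_ref <- min(1800, max(tp))
  A_final <- stats::approx(tp, Ap, xout = t_ref)$y
  gs_final <- stats::approx(tp, gp, xout = t_ref)$y
  base_A <- if (baseline_subtract) A[max(which(pre))] else 0
  base_g <- if (baseline_subtract) gsT0 else 0
  lev <- function(frac, final, base) base + frac * (final - base)
  T50A <- .first_crossing(tp, Ap, lev(0.5, A_final, base_A)) / 60
  T90A <- .first_crossing(tp, Ap, lev(0.9, A_final, base_A)) / 60
  T50gs <- .first_crossing(tp, gp, lev(0.5, gs_final, base_g)) / 60
  five <- tp > 0 & tp <= 300
  CCF <- sum(Ap[five])
  dt_med <- stats::median(diff(tp))
  structure(list(T50A = T50A, T90A = T90A, T50gs = T50gs, CCF = CCF,
                 CCF_integral = CCF * dt_med, gsT0 = gsT0,
                 A_final = A_final, gs_final = gs_final,
                 provisional = provisional),
            class = "induction_metrics")
}

#' Fit exponential stomatal kinetics to a conductance transient
#'
#' Fits `gs(t) = (g_start - g_end) exp(-t/k) + g_end` by nonlinear least
#' squares to a segment beginning at a light transition. The exponent uses
#' a time-*constant* convention: k carries units of minutes and a larger k
#' means slower stomata. (The widely printed form `e^{-kt}` with k in
#' minutes is dimensionally a time constant too; this implementation makes
#' that explicit.)
#'
#' @param segment a data frame with `time_s` and `gsw_mol_m2_s`, `time_s`
#'   starting at the transition; at least 20 samples.
#' @param rmse_warn RMSE (mol m-2 s-1) above which a non-monotone or poor
#'   fit is flagged.
#' @return list of class `kinetics_fit`: `g0`/`gmax` (the smaller/larger of
#'   the fitted start and asymptote), `g_start`/`g_end` (in time order),
#'   `k` (min), `direction` (`"opening"`/`"closing"`), `rmse`, `flagged`.
#' @export
fit_stomatal_kinetics <- function(segment, rmse_warn = 0.02) {
  stopifnot(all(c("time_s", "gsw_mol_m2_s") %in% names(segment)))
  if (nrow(segment) < 20) stop("need at least 20 samples in the segment")
  t_min <- (segment$time_s - segment$time_s[1]) / 60
  gs <- segment$gsw_mol_m2_s
  g_start0 <- gs[1]
  g_end0 <- mean(utils::tail(gs, max(3, length(gs) %/% 10)))
  if (abs(g_end0 - g_start0) < 1e-8 || stats::sd(gs) < 1e-10) {
    return(structure(list(g0 = min(g_start0, g_end0),
                          gmax = max(g_start0, g_end0),
                          g_start = g_start0, g_end = g_end0, k = NA_real_,
                          direction = "none", rmse = 0, flagged = TRUE),
                     class = "kinetics_fit"))
  }
  fit <- tryCatch(
    suppressWarnings( # warnOnly convergence chatter on near-perfect data
      stats::nls(gs ~ (a - b) * exp(-t_min / k) + b,
                 start = list(a = g_start0, b = g_end0,
                              k = max(max(t_min) / 4, 0.5)),
                 control = stats::nls.control(maxiter = 500,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(g0 = min(g_start0, g_end0),
                          gmax = max(g_start0, g_end0),
                          g_start = g_start0, g_end = g_end0, k = NA_real_,
                          direction = "none", rmse = NA_real_,
                          flagged = TRUE),
                     class = "kinetics_fit"))
  }
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  direction <- if (cf[["b"]] > cf[["a"]]) "opening" else "closing"
  monotone <- all(diff(gs) >= -3 * rmse_warn) || all(diff(gs) <= 3 * rmse_warn)
  structure(list(g0 = min(cf[["a"]], cf[["b"]]),
                 gmax = max(cf[["a"]], cf[["b"]]),
                 g_start = unname(cf[["a"]]), g_end = unname(cf[["b"]]),
                 k = unname(cf[["k"]]), direction = direction, rmse = rmse,
                 flagged = rmse > rmse_warn && !monotone),
            class = "kinetics_fit")
}

#' Dynamic A/ci analysis of induction at several CO2 levels
#'
#' Takes one induction trace per CO2 level, all time-aligned to the
#' shade-sun transition. At each common time point the instantaneous
#' `(Ci, A)` pairs across CO2 levels form a snapshot A/ci curve whose
#' initial (Rubisco-limited) slope yields `Vcmax_t`. Stomatal limitation at
#' time t is
#' `SL_t = (A_t(Ci_ref) - A_t(Ci_t,400)) / A_t(Ci_ref)` where `A_t()` is
#' the fitted Rubisco-limited curve, `Ci_ref` the steady-state operating
#' Ci of the ambient trace and `Ci_t,400` its instantaneous Ci.
#'
#' @param inductions named list of traces (names = CO2 level, e.g. `"400"`),
#'   each with columns `time_s`, `a_umol_m2_s`, `ci_umol_mol`, time 0 at
#'   the transition.
#' @param GammaStar,Rd,Kc,Ko,O kinetic constants at leaf temperature.
#' @param Ci_ref reference Ci; default: final Ci of the ambient (400) trace.
#' @param min_levels minimum CO2 levels required per time point.
#' @return data frame with `time_s`, `Vcmax_t`, `SL_t` (clamped to [0, 1]).
#' @export
dynamic_aci <- function(inductions, GammaStar = 50, Rd = 1.7, Kc = 566,
                        Ko = 325, O = 210, Ci_ref = NULL, min_levels = 4) {
  stopifnot(is.list(inductions), length(inductions) >= min_levels,
            "400" %in% names(inductions))
  Km <- Kc * (1 + O / Ko)
  amb <- inductions[["400"]]
  if (is.null(Ci_ref)) Ci_ref <- utils::tail(amb$ci_umol_mol, 1)
  t_common <- Reduce(intersect, lapply(inductions, function(x) x$time_s))
  t_common <- sort(t_common[t_common >= 0])
  rows <- lapply(t_common, function(tt) {
    ci <- a <- numeric(0)
    for (tr in inductions) {
      i <- match(tt, tr$time_s)
      if (!is.na(i) && tr$ci_umol_mol[i] > GammaStar) {
        ci <- c(ci, tr$ci_umol_mol[i])
        a <- c(a, tr$a_umol_m2_s[i])
      }
    }
    if (length(ci) < min_levels) return(NULL)
    x <- (ci - GammaStar) / (ci + Km)
    vc <- sum(x * (a + Rd)) / sum(x^2)
    ahat <- function(c0) vc * (c0 - GammaStar) / (c0 + Km) - Rd
    i400 <- match(tt, amb$time_s)
    sl <- (ahat(Ci_ref) - ahat(amb$ci_umol_mol[i400])) / ahat(Ci_ref)
    data.frame(time_s = tt, Vcmax_t = vc,
               SL_t = min(max(sl, 0), 1))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) stop("no time point had enough usable CO2 levels")
  do.call(rbind, rows)
}

#' Fit Ball-Berry slope and intercept from a light-response curve
#'
#' Ordinary least squares of `gs` on the Ball-Berry index `A hs / cs`
#' across steady-state light levels at ambient CO2. The humidity at the
#' leaf surface is computed from cuvette VPD and leaf temperature; the
#' boundary layer is assumed well mixed so `cs ~ Ca`.
#'
#' @param light_curve data frame with `a_umol_m2_s`, `gsw_mol_m2_s`,
#'   `vpd_kpa`, `tleaf_c`, `ca_umol_mol` -- one row per light level.
#' @return a [ball_berry_params()] with extra fields `r2`, `n` and
#'   `flagged` (TRUE for a non-physiological negative slope).
#' @export
ball_berry_fit <- function(light_curve) {
  need <- c("a_umol_m2_s", "gsw_mol_m2_s", "vpd_kpa", "tleaf_c",
            "ca_umol_mol")
  stopifnot(all(need %in% names(light_curve)))
  df <- light_curve[light_curve$a_umol_m2_s > 0, , drop = FALSE]
  if (nrow(df) < 5) stop("need at least 5 steady-state levels with A > 0")
  hs <- vapply(seq_len(nrow(df)),
               function(i) surface_humidity(df$vpd_kpa[i], df$tleaf_c[i]),
               numeric(1))
  x <- df$a_umol_m2_s * hs / df$ca_umol_mol
  if (stats::sd(x) < 1e-12) {
    bb <- ball_berry_params(0, mean(df$gsw_mol_m2_s))
    bb$r2 <- NA_real_; bb$n <- nrow(df); bb$flagged <- FALSE
    return(bb)
  }
  fit <- stats::lm(df$gsw_mol_m2_s ~ x)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  bb <- ball_berry_params(m, b)
  bb$r2 <- suppressWarnings(summary(fit)$r.squared)
  bb$n <- nrow(df)
  bb$flagged <- m < 0
  bb
}

#' Recover stomatal time constants from a trace by ODE regression
#'
#' The empirical exponential of [fit_stomatal_kinetics()] estimates an
#' *apparent* time constant: during opening the Ball-Berry target rises
#' together with assimilation, so the apparent constant exceeds the
#' mechanistic one. This estimator removes that feedback by reconstructing
#' the target path `gs_target(t)` from the observed assimilation and
#' humidity channels and fitting the relaxation
#' `d gs/dt = (gs_target - gs)/tau` directly, with separate constants for
#' opening (`tau = k_i`) and closing (`k_d`). The candidate trajectory is
#' integrated exactly piecewise (exponential update per sampling interval)
#' and least-squares compared with the observed conductance.
#'
#' @param trace a trace with `time_s`, `gsw_mol_m2_s`, `a_umol_m2_s`,
#'   `ca_umol_mol`, `vpd_kpa`, `tleaf_c` (e.g. from
#'   [generate_induction()]).
#' @param bb [ball_berry_params()] governing the target (e.g. recovered via
#'   [ball_berry_fit()]).
#' @param gs_min conductance floor of the target (mol m-2 s-1).
#' @return list with `k_i`, `k_d` (min) and the fit `rmse`.
#' @export
fit_kinetics_ode <- function(trace, bb, gs_min = 0) {
  need <- c("time_s", "gsw_mol_m2_s", "a_umol_m2_s", "ca_umol_mol",
            "vpd_kpa", "tleaf_c")
  stopifnot(all(need %in% names(trace)))
  t <- trace$time_s
  gs <- trace$gsw_mol_m2_s
  hs <- vapply(seq_len(nrow(trace)),
               function(i) surface_humidity(trace$vpd_kpa[i],
                                            trace$tleaf_c[i]),
               numeric(1))
  tgt <- pmax(gs_min, bb$m * trace$a_umol_m2_s * hs / trace$ca_umol_mol +
                bb$b)
  n <- length(t)
  pred <- function(par) {
    tau_i <- exp(par[1]) * 60
    tau_d <- exp(par[2]) * 60
    g <- numeric(n)
    g[1] <- gs[1]
    for (k in seq_len(n - 1)) {
      tau <- if (tgt[k] > g[k]) tau_i else tau_d
      g[k + 1] <- tgt[k] + (g[k] - tgt[k]) * exp(-(t[k + 1] - t[k]) / tau)
    }
    g
  }
  obj <- function(par) sum((gs - pred(par))^2)
  op <- stats::optim(log(c(8, 8)), obj, method = "Nelder-Mead",
                     control = list(maxit = 1000, reltol = 1e-12))
  list(k_i = exp(op$par[1]), k_d = exp(op$par[2]),
       rmse = sqrt(op$value / n))
}
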