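# Steady-state analysis: A/ci curve fitting, GammaStar/Rd estimation,
# fluorescence-based J, variable-J mesophyll conductance, Cc-basis Vcmax,
# and Grassi-Magnani limitation partitioning.

#' Construct an A/ci response curve
#'
#' Wraps a set of steady-state observations taken across a CO2 staircase.
#' Invariants enforced: at least 8 observations, all `Ci > 0`, at least 3
#' points with `Ci < 250` (Rubisco-limited region) and at least 2 above 700.
#'
#' @param df data frame with columns `ca_set` (commanded cuvette CO2),
#'   `ca_umol_mol`, `ci_umol_mol`, `a_umol_m2_s`, `gsw_mol_m2_s`, `ppfd`,
#'   `tleaf_c`, `vpd_kpa` and optionally `phipsii`.
#' @param cultivar,replicate metadata strings.
#' @return classed `aci_curve` data frame.
#' @export
aci_curve <- function(df, cultivar = NA_character_,
                      replicate = NA_character_) {
  need <- c("ca_set", "ca_umol_mol", "ci_umol_mol", "a_umol_m2_s",
            "gsw_mol_m2_s", "ppfd", "tleaf_c", "vpd_kpa")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("A/ci curve is missing column(s): ", paste(missing, collapse = ", "))
  }
  ci <- df$ci_umol_mol
  if (nrow(df) < 8) stop("an A/ci curve needs at least 8 observations")
  if (any(ci <= 0)) stop("all Ci must be positive")
  if (sum(ci < 250) < 3) stop("need at least 3 points with Ci < 250")
  if (sum(ci > 700) < 2) stop("need at least 2 points with Ci > 700")
  structure(as.data.frame(df), cultivar = cultivar, replicate = replicate,
            class = c("aci_curve", "data.frame"))
}

#' The standard cuvette CO2 staircase
#'
#' The 13-step sequence of commanded cuvette CO2 concentrations used for
#' the steady-state response curves, in measurement order.
#'
#' @return numeric vector (umol mol-1).
#' @export
aci_co2_sequence <- function() {
  c(400, 270, 150, 100, 75, 50, 400, 400, 600, 800, 1100, 1300, 1500)
}

#' Fit the FvCB model to an A/ci curve
#'
#' Estimates Vcmax, Jmax and (when identifiable) TPU on the intercellular
#' CO2 basis, together with Rd unless supplied. The Rubisco/RuBP-regeneration
#' breakpoint is not fixed at a Ci cutoff: every admissible partition of the
#' Ci-sorted points is fitted and the partition with minimum total SSE wins.
#' Within a partition the Rubisco limb is linear in (Vcmax, Rd) and solved
#' exactly; Jmax is profiled by 1-D optimization through the light response.
#' TPU is reported only when the high-Ci region is flat (mean observed A
#' within `tpu_flat_tol` of the RuBP prediction) or fluorescence J declines
#' with Ci; otherwise it is `NA`, never extrapolated.
#'
#' Fitted values are normalized to 25 degC through the temperature
#' responses in `constants` using the mean leaf temperature of the curve.
#'
#' @param curve an [aci_curve()].
#' @param GammaStar,Rd optional fixed values at leaf temperature; when
#'   `NULL`, GammaStar comes from the shipped constants and Rd is fitted.
#' @param constants temperature-response set, see [bernacchi_constants()].
#' @param alpha,theta light-response parameters held fixed during the fit.
#' @param O oxygen mole fraction (mmol mol-1).
#' @param tpu_flat_tol relative flattening threshold for TPU detection.
#' @return object of class `aci_fit`: list with `params` (a
#'   [photo_params()] at 25 degC), `values_leaf_t`, `states`, `rmse`, `se`,
#'   `transition_ci`, `T_leaf`.
#' @export
fit_aci <- function(curve, GammaStar = NULL, Rd = NULL,
                    constants = bernacchi_constants(), alpha = 0.35,
                    theta = 0.9, O = 210, tpu_flat_tol = 0.02) {
  stopifnot(inherits(curve, "aci_curve"))
  df <- curve[order(curve$ci_umol_mol), , drop = FALSE]
  Ci <- df$ci_umol_mol
  A <- df$a_umol_m2_s
  Q <- df$ppfd
  Tl <- mean(df$tleaf_c)
  Kc <- arrhenius_scale(constants$Kc, Tl)
  Ko <- arrhenius_scale(constants$Ko, Tl)
  Gs <- if (is.null(GammaStar)) arrhenius_scale(constants$GammaStar, Tl) else GammaStar
  Km <- Kc * (1 + O / Ko)
  n <- length(Ci)
  xc <- (Ci - Gs) / (Ci + Km) # Rubisco-limb regressor
  yj <- (Ci - Gs) / (4 * Ci + 8 * Gs) # RuBP-limb regressor (A+Rd = J*yj)

  fit_partition <- function(i) {
    lo <- seq_len(i)
    up <- setdiff(seq_len(n), lo)
    # Rubisco limb: A = Vcmax*xc - Rd, linear
    if (is.null(Rd)) {
      fit <- stats::lm(A[lo] ~ xc[lo])
      rd_hat <- -unname(stats::coef(fit)[1])
      vc_hat <- unname(stats::coef(fit)[2])
      se_vc <- summary(fit)$coefficients[2, 2]
      se_rd <- summary(fit)$coefficients[1, 2]
    } else {
      rd_hat <- Rd
      vc_hat <- sum(xc[lo] * (A[lo] + rd_hat)) / sum(xc[lo]^2)
      se_vc <- NA_real_
      se_rd <- NA_real_
    }
    if (!is.finite(vc_hat) || vc_hat <= 0) return(NULL)
    sse <- sum((A[lo] - (vc_hat * xc[lo] - rd_hat))^2)

    # TPU candidates: high-Ci points; Jmax fitted on the rest of the limb
    tpu_cand <- up[Ci[up] > 700]
    j_pts <- setdiff(up, tpu_cand)
    fit_jmax <- function(idx) {
      if (length(idx) == 0) return(NULL)
      obj <- function(jm) {
        J <- electron_transport(Q[idx], jm, alpha, theta)
        sum((A[idx] - (J * yj[idx] - rd_hat))^2)
      }
      if (length(unique(Q[idx])) == 1) {
        # constant light: the operating J is linear-in-parameters, solve
        # exactly and invert the light response for Jmax
        Jhat <- sum(yj[idx] * (A[idx] + rd_hat)) / sum(yj[idx]^2)
        jm <- invert_electron_transport(Jhat, Q[idx][1], alpha, theta)
        if (is.finite(jm) && jm > 0) return(list(Jmax = jm, sse = obj(jm)))
      }
      op <- stats::optimize(obj, c(1, 2000), tol = 1e-6)
      list(Jmax = op$minimum, sse = op$objective)
    }
    jm_fit <- fit_jmax(if (length(j_pts) > 0) j_pts else up)
    if (is.null(jm_fit)) return(NULL)
    jm_hat <- jm_fit$Jmax

    tpu_hat <- NA_real_
    tpu_idx <- integer(0)
    if (length(tpu_cand) >= 1) {
      Jp <- electron_transport(Q[tpu_cand], jm_hat, alpha, theta)
      a_rubp <- Jp * yj[tpu_cand] - rd_hat
      # clear shortfall below the extrapolated RuBP limb, or a merely flat
      # region backed by declining fluorescence-J, marks the TPU ceiling
      shortfall <- mean(A[tpu_cand]) < mean(a_rubp) * (1 - tpu_flat_tol)
      flat <- mean(A[tpu_cand]) < mean(a_rubp) * (1 + tpu_flat_tol)
      j_declines <- FALSE
      if (!is.null(df$phipsii) && all(is.finite(df$phipsii[tpu_cand]))) {
        hi <- df$phipsii[c(utils::tail(j_pts, 1), tpu_cand)]
        cr <- if (length(hi) >= 2 && stats::sd(hi) > 0) {
          suppressWarnings(stats::cor(seq_along(hi), hi))
        } else {
          NA_real_
        }
        j_declines <- is.finite(cr) && cr < -0.5
      }
      if (shortfall || (flat && j_declines)) {
        tpu_hat <- mean(A[tpu_cand] + rd_hat) / 3
        tpu_idx <- tpu_cand
        # refit Jmax without points the fitted ceiling marks as TPU-limited
        # (the Ci cutoff alone can miss marginal ones)
        if (length(j_pts) > 0) {
          keep <- j_pts[A[j_pts] + rd_hat < 3 * tpu_hat * (1 - 1e-3)]
          jm_fit <- fit_jmax(if (length(keep) > 0) keep else j_pts)
          jm_hat <- jm_fit$Jmax
        }
      } else {
        jm_fit <- fit_jmax(up)
        jm_hat <- jm_fit$Jmax
      }
    }
    pred_up <- {
      J <- electron_transport(Q[up], jm_hat, alpha, theta)
      w <- J * yj[up]
      if (!is.na(tpu_hat)) w <- pmin(w, 3 * tpu_hat)
      w - rd_hat
    }
    sse <- sse + sum((A[up] - pred_up)^2)
    list(Vcmax = vc_hat, Jmax = jm_hat, TPU = tpu_hat, Rd = rd_hat,
         sse = sse, break_i = i, tpu_idx = tpu_idx,
         se = c(Vcmax = se_vc, Rd = se_rd))
  }

  lo_min <- max(3, if (is.null(Rd)) 3 else 2)
  cands <- lapply(lo_min:(n - 2), fit_partition)
  cands <- Filter(Negate(is.null), cands)
  if (length(cands) == 0) {
    stop("A/ci fit failed on every candidate partition (singular fit)")
  }
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "sse"))]]

  # limiting state per point at the fitted parameters
  Jfit <- electron_transport(Q, best$Jmax, alpha, theta)
  Wc <- best$Vcmax * xc
  Wj <- Jfit * yj
  states <- ifelse(Wc <= Wj, "rubisco", "rubp_regen")
  if (!is.na(best$TPU)) {
    states[pmin(Wc, Wj) > 3 * best$TPU & Ci > Gs] <- "tpu"
  }
  # Rubisco -> RuBP transition Ci: Wc(Ci) == Wj(Ci) at saturating Q
  Jsat <- electron_transport(max(Q), best$Jmax, alpha, theta)
  trans_ci <- if (4 * best$Vcmax > Jsat) {
    (Jsat * Km - 8 * best$Vcmax * Gs) / (4 * best$Vcmax - Jsat)
  } else {
    NA_real_
  }
  trans_flag <- is.na(trans_ci) || trans_ci < min(Ci) || trans_ci > max(Ci)

  rmse <- sqrt(best$sse / n)
  norm <- function(nm, v) {
    if (is.na(v)) return(NA_real_)
    v / .arrhenius_factor(constants[[nm]], Tl)
  }
  params <- photo_params(
    Vcmax25 = norm("Vcmax", best$Vcmax),
    Jmax25 = norm("Jmax", best$Jmax),
    TPU25 = norm("TPU", best$TPU),
    Rd25 = norm("Rd", best$Rd),
    GammaStar25 = norm("GammaStar", Gs),
    Kc25 = norm("Kc", Kc), Ko25 = norm("Ko", Ko),
    O = O, alpha = alpha, theta = theta, temp = constants)
  structure(list(params = params,
                 values_leaf_t = c(Vcmax = best$Vcmax, Jmax = best$Jmax,
                                   TPU = best$TPU, Rd = best$Rd,
                                   GammaStar = Gs, Kc = Kc, Ko = Ko),
                 states = states, ci_sorted = Ci, rmse = rmse, se = best$se,
                 transition_ci = trans_ci, transition_flagged = trans_flag,
                 T_leaf = Tl),
            class = "aci_fit")
}

#' @export
print.aci_fit <- function(x, ...) {
  cat("FvCB A/ci fit (25 degC basis)\n")
  p <- x$params
  cat(sprintf("  Vcmax25 = %.2f  Jmax25 = %.2f  TPU25 = %s  Rd25 = %.2f\n",
              p$Vcmax25, p$Jmax25,
              if (is.na(p$TPU25)) "n.e." else sprintf("%.2f", p$TPU25),
              p$Rd25))
  cat(sprintf("  RMSE = %.3f umol m-2 s-1; rubisco->rubp transition Ci = %s\n",
              x$rmse,
              if (is.na(x$transition_ci)) "n.a."
              else sprintf("%.0f", x$transition_ci)))
  cat("  states:", paste(x$states, collapse = " "), "\n")
  invisible(x)
}

#' Estimate GammaStar and Rd from combined gas exchange and fluorescence
#'
#' Joint nonlinear estimate from gas exchange paired with
#' fluorescence-derived electron transport. The fitted model is the
#' RuBP-regeneration identity evaluated at the realized electron flux,
#' `A = s * phiPSII * Q / 4 * (Cc - G*) / (Cc + 2 G*) - Rd` with
#' `Cc = Ci - A/gm`, which holds in every limitation state because
#' phiPSII tracks the electron transport actually sustaining carboxylation
#' plus photorespiration. The compensation point `G*` and (unless supplied)
#' the mesophyll conductance `gm` are profiled by direct optimization; for
#' fixed `(G*, gm)` the model is linear in the fluorescence-to-J
#' calibration factor `s` and `Rd`, which are solved exactly. One or more
#' replicate curves may be pooled.
#'
#' @param curve an [aci_curve()] with a `phipsii` column, or a list of
#'   replicate curves to pool.
#' @param gm optional known mesophyll conductance (mol m-2 s-1, `Inf`
#'   allowed); fitted when `NULL`.
#' @param s fluorescence-to-J calibration (absorptance times the PSII
#'   partitioning fraction). The default fixes it at the instrument-standard
#'   0.85 x 0.5: jointly fitting it is possible (`s = NULL`) but the
#'   (s, G*, Rd, gm) objective has a near-flat ridge, so realistic channel
#'   noise then translates into large correlated biases.
#' @param ci_max points with `Ci` above this are excluded (default keeps
#'   all; the identity does not require restricting to the Laisk region).
#' @return list with `GammaStar`, `Rd`, `s`, `gm`, `flagged` (TRUE when
#'   the estimates fall outside the physiological windows Rd > 0,
#'   G* in \[20, 80\]).
#' @export
estimate_gamma_rd <- function(curve, gm = NULL, s = 0.85 * 0.5,
                              ci_max = Inf) {
  curves <- if (inherits(curve, "aci_curve")) list(curve) else curve
  for (cu in curves) {
    stopifnot(inherits(cu, "aci_curve"))
    if (is.null(cu$phipsii)) stop("curve has no 'phipsii' column")
    low <- cu$ci_umol_mol < 250 & is.finite(cu$phipsii)
    if (sum(low) < 4) {
      stop("need at least 4 low-Ci points (Ci < 250) with paired ",
           "fluorescence; got ", sum(low))
    }
  }
  # replicate curves on the same staircase are averaged pointwise before
  # fitting: channel noise enters the regressor (phiPSII), and averaging
  # is what keeps the errors-in-variables attenuation negligible
  nr <- vapply(curves, nrow, integer(1))
  if (length(curves) > 1 && length(unique(nr)) == 1 &&
      all(vapply(curves, function(x) all(x$ca_set == curves[[1]]$ca_set),
                 logical(1)))) {
    Ci <- rowMeans(sapply(curves, function(x) x$ci_umol_mol))
    A <- rowMeans(sapply(curves, function(x) x$a_umol_m2_s))
    jraw <- rowMeans(sapply(curves, function(x) x$phipsii * x$ppfd / 4))
  } else {
    Ci <- unlist(lapply(curves, function(x) x$ci_umol_mol))
    A <- unlist(lapply(curves, function(x) x$a_umol_m2_s))
    jraw <- unlist(lapply(curves, function(x) x$phipsii * x$ppfd / 4))
  }
  sel <- Ci < ci_max
  Ci <- Ci[sel]; A <- A[sel]; jraw <- jraw[sel]

  inner <- function(gs, gmv) {
    Cc <- Ci - A / gmv
    if (any(Cc <= gs)) return(NULL)
    z <- jraw * (Cc - gs) / (Cc + 2 * gs)
    if (is.null(s)) {
      fit <- stats::lm(A ~ z)
      list(sse = sum(stats::resid(fit)^2),
           s = unname(stats::coef(fit)[2]),
           Rd = -unname(stats::coef(fit)[1]))
    } else {
      rd <- mean(s * z - A)
      list(sse = sum((A - (s * z - rd))^2), s = s, Rd = rd)
    }
  }
  obj <- function(par) {
    gs <- par[1]
    gmv <- if (is.null(gm)) exp(par[2]) else gm
    if (gs < 10 || gs > 100) return(1e10)
    f <- inner(gs, gmv)
    if (is.null(f)) 1e10 else f$sse
  }
  if (is.null(gm)) {
    op <- stats::optim(c(45, log(0.3)), obj, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-12))
    gs_hat <- op$par[1]
    gm_hat <- exp(op$par[2])
  } else {
    op <- stats::optimize(function(g) obj(g), c(10, 100), tol = 1e-8)
    gs_hat <- op$minimum
    gm_hat <- gm
  }
  f <- inner(gs_hat, gm_hat)
  if (is.null(f)) stop("GammaStar/Rd estimation failed: no admissible fit")
  flagged <- !(f$Rd > 0 && gs_hat >= 20 && gs_hat <= 80)
  list(GammaStar = gs_hat, Rd = f$Rd, s = f$s, gm = gm_hat,
       flagged = flagged)
}

#' Electron transport from PSII operating efficiency
#'
#' `J = phiPSII * Q * absorptance * beta`, the standard fluorescence-based
#' estimate with leaf absorptance and the fraction of absorbed light
#' reaching PSII.
#'
#' @param phipsii PSII operating efficiency in `[0, 1]`.
#' @param Q incident PPFD (umol m-2 s-1).
#' @param absorptance leaf absorptance (default 0.85).
#' @param beta fraction of absorbed quanta partitioned to PSII (default 0.5).
#' @return J (umol m-2 s-1), vectorized.
#' @export
fluorescence_j <- function(phipsii, Q, absorptance = 0.85, beta = 0.5) {
  stopifnot(all(phipsii >= 0), all(phipsii <= 1), all(Q >= 0))
  phipsii * Q * absorptance * beta
}

#' Mesophyll conductance by the variable-J method
#'
#' `gm = A / (Ci - G* (J + 8 (A + Rd)) / (J - 4 (A + Rd)))`. The bracketed
#' term is the chloroplast CO2 implied by the fluorescence-based electron
#' transport; when it meets or exceeds Ci (zero or negative drawdown) the
#' estimate is returned as `NA` (flagged non-estimable) rather than a
#' negative conductance. `J <= 4 (A + Rd)` is an inconsistency between
#' electron transport and the gas-exchange fluxes (as arises under TPU
#' limitation) and raises an error.
#'
#' @param A net assimilation (umol m-2 s-1).
#' @param Ci intercellular CO2 (umol mol-1).
#' @param J fluorescence-based electron transport (umol m-2 s-1).
#' @param GammaStar,Rd compensation point and day respiration at leaf
#'   temperature.
#' @return gm (mol m-2 s-1), vectorized; `NA` where non-estimable, `Inf`
#'   flagged as `NA` too (zero drawdown).
#' @export
variable_j_gm <- function(A, Ci, J, GammaStar, Rd) {
  k <- 4 * (A + Rd)
  if (any(J <= k)) {
    stop("electron transport inconsistent with fluxes (J <= 4(A+Rd)); ",
         "gm cannot be estimated (e.g. under TPU limitation)")
  }
  Cc <- GammaStar * (J + 8 * (A + Rd)) / (J - k)
  gm <- A / (Ci - Cc)
  gm[Ci - Cc <= 0 | gm <= 0] <- NA_real_
  gm
}

#' Refit Vcmax on the chloroplast-CO2 basis
#'
#' Converts `Cc = Ci - A/gm` pointwise and refits the Rubisco-limited FvCB
#' expression on `(Cc, A)` by least squares over the Rubisco-limited points
#' of a Ci-basis fit. `Jmax_Cc` is attempted on the RuBP-regeneration
#' points, but is `NA` when those points are TPU-limited (electron
#' transport then declines and the variable-J construction is inconsistent).
#'
#' @param curve an [aci_curve()].
#' @param gm finite mesophyll conductance (mol m-2 s-1).
#' @param GammaStar,Rd values at leaf temperature; defaults from the fit.
#' @param ci_fit optionally a precomputed [fit_aci()] result for the same
#'   curve (avoids refitting).
#' @param ... passed to [fit_aci()].
#' @return list with `Vcmax_Cc`, `Jmax_Cc` (possibly `NA`), `Cc`, and the
#'   Ci-basis `Vcmax` for reference (all at leaf temperature).
#' @export
fit_vcmax_cc <- function(curve, gm, GammaStar = NULL, Rd = NULL,
                         ci_fit = NULL, ...) {
  stopifnot(inherits(curve, "aci_curve"), is.finite(gm), gm > 0)
  if (is.null(ci_fit)) ci_fit <- fit_aci(curve, GammaStar = GammaStar,
                                         Rd = Rd, ...)
  vt <- ci_fit$values_leaf_t
  Gs <- if (is.null(GammaStar)) vt[["GammaStar"]] else GammaStar
  rd <- if (is.null(Rd)) vt[["Rd"]] else Rd
  Km <- vt[["Kc"]] * (1 + ci_fit$params$O / vt[["Ko"]])
  df <- curve[order(curve$ci_umol_mol), , drop = FALSE]
  Cc <- df$ci_umol_mol - df$a_umol_m2_s / gm
  rub <- ci_fit$states == "rubisco" & Cc > Gs
  if (!any(rub)) stop("no Rubisco-limited points with Cc above GammaStar")
  if (all(ci_fit$states == "tpu")) stop("all points TPU-limited; refusing")
  x <- (Cc[rub] - Gs) / (Cc[rub] + Km)
  vcmax_cc <- sum(x * (df$a_umol_m2_s[rub] + rd)) / sum(x^2)
  jmax_cc <- NA_real_
  rubp <- ci_fit$states == "rubp_regen" & Cc > Gs
  if (sum(rubp) >= 2 && !any(ci_fit$states == "tpu")) {
    y <- (Cc[rubp] - Gs) / (4 * Cc[rubp] + 8 * Gs)
    Jhat <- sum(y * (df$a_umol_m2_s[rubp] + rd)) / sum(y^2)
    jmax_cc <- invert_electron_transport(Jhat, max(df$ppfd),
                                         ci_fit$params$alpha,
                                         ci_fit$params$theta)
  }
  list(Vcmax_Cc = vcmax_cc, Jmax_Cc = jmax_cc, Cc = Cc,
       Vcmax_Ci = unname(vt[["Vcmax"]]))
}

#' Grassi-Magnani partitioning of steady-state limitation
#'
#' Splits the relative limitation of light-saturated assimilation into
#' stomatal (`l_s`), mesophyll (`l_m`) and biochemical (`l_b`) shares using
#' the total diffusive conductance `g_tot = (1/gsc + 1/gm)^-1` and the
#' carboxylation sensitivity
#' `dA/dCc = Vcmax (G* + Kc(1 + O/Ko)) / (Cc + Kc(1 + O/Ko))^2`:
#' \deqn{l_s = (g_t/gsc \cdot dA/dCc)/(g_t + dA/dCc),\quad
#'       l_m = (g_t/gm \cdot dA/dCc)/(g_t + dA/dCc),\quad
#'       l_b = g_t/(g_t + dA/dCc).}
#' The three shares sum to one by construction.
#'
#' @param Vcmax Rubisco capacity at leaf temperature (Cc basis).
#' @param gsc stomatal conductance to CO2 (mol m-2 s-1).
#' @param gm mesophyll conductance to CO2 (mol m-2 s-1); `Inf` allowed.
#' @param Cc operating chloroplast CO2 (umol mol-1).
#' @param Kc,Ko,GammaStar kinetic constants at leaf temperature.
#' @param O oxygen mole fraction (mmol mol-1).
#' @return list with `l_s`, `l_m`, `l_b` (dimensionless, sum to 1).
#' @export
limitation_partition <- function(Vcmax, gsc, gm, Cc, Kc = 404.9, Ko = 278.4,
                                 O = 210, GammaStar = 42.75) {
  if (!(gsc > 0) || !(gm > 0)) stop("conductances must be positive")
  Km <- Kc * (1 + O / Ko)
  dAdCc <- Vcmax * (GammaStar + Km) / (Cc + Km)^2
  g_tot <- if (is.infinite(gm)) gsc else 1 / (1 / gsc + 1 / gm)
  den <- g_tot + dAdCc
  l_s <- (g_tot / gsc) * dAdCc / den
  l_m <- if (is.infinite(gm)) 0 else (g_tot / gm) * dAdCc / den
  l_b <- g_tot / den
  list(l_s = l_s, l_m = l_m, l_b = l_b)
}

#' Operating point and intrinsic water-use efficiency at ambient CO2
#'
#' Averages the observations taken at a commanded cuvette CO2 of 400
#' umol mol-1 (the ambient steps of the staircase).
#'
#' @param curve an [aci_curve()].
#' @return list with `A`, `gsw`, `Ci` and `iWUE` (= mean of per-point
#'   `A/gsw` ratios; see [iwue()] for the conventions).
#' @export
operating_point <- function(curve) {
  stopifnot(inherits(curve, "aci_curve"))
  sel <- curve$ca_set == 400
  if (!any(sel)) stop("curve contains no Ca = 400 points")
  list(A = mean(curve$a_umol_m2_s[sel]),
       gsw = mean(curve$gsw_mol_m2_s[sel]),
       Ci = mean(curve$ci_umol_mol[sel]),
       iWUE = mean(curve$a_umol_m2_s[sel] / curve$gsw_mol_m2_s[sel]))
}

#' Intrinsic water-use efficiency
#'
#' `iWUE = A / gsw` (umol CO2 mol-1 H2O). For replicate sets the published
#' convention is mean-of-ratios (average the per-replicate `A/gsw`), which
#' `method = "mean_of_ratios"` implements; `"ratio_of_means"` divides the
#' averaged fluxes instead.
#'
#' @param A net assimilation (scalar or per-replicate vector).
#' @param gsw stomatal conductance to water vapour, same length.
#' @param method aggregation convention for vectors.
#' @return iWUE (umol mol-1).
#' @export
iwue <- function(A, gsw, method = c("mean_of_ratios", "ratio_of_means")) {
  method <- match.arg(method)
  stopifnot(length(A) == length(gsw), all(gsw > 0))
  if (method == "mean_of_ratios") mean(A / gsw) else mean(A) / mean(gsw)
}
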