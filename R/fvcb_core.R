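# Steady-state biochemical model of C3 photosynthesis (FvCB) with
# temperature responses and CO2 supply-demand coupling.
#
# Unit conventions (fixed throughout the package):
#   A, Vcmax, Jmax, TPU, Rd, J   umol m-2 s-1
#   Cc, Ci, Ca, Kc, GammaStar    umol mol-1 (mole fraction)
#   Ko, O                        mmol mol-1
#   gsw                          mol m-2 s-1 (water vapour); gsc = gsw / 1.6
#   gm                           mol m-2 s-1 (already a CO2 conductance)
#   temperatures                 degrees C; energies kJ mol-1

.RGAS <- 8.314 # J mol-1 K-1
.TREF <- 298.15 # K

#' Temperature response descriptor
#'
#' Bundles a parameter value at the 25 degC reference temperature with its
#' Arrhenius activation energy and, optionally, the peaked-function
#' deactivation terms used for Vcmax and Jmax.
#'
#' @param value25 parameter value at 25 degC (units of the parameter).
#' @param Ha activation energy (kJ mol-1).
#' @param Hd optional deactivation energy (kJ mol-1); requires `dS`.
#' @param dS optional entropy term (kJ mol-1 K-1).
#' @return an object of class `temp_response`.
#' @export
temp_response <- function(value25, Ha, Hd = NULL, dS = NULL) {
  stopifnot(is.finite(value25), value25 > 0, is.finite(Ha))
  if (!is.null(Hd) && is.null(dS)) {
    stop("if 'Hd' is given, 'dS' must be given too")
  }
  structure(list(value25 = value25, Ha = Ha, Hd = Hd, dS = dS),
            class = "temp_response")
}

#' Default temperature-response constants (Bernacchi set)
#'
#' Shipped kinetic constants and activation energies for the Rubisco
#' Michaelis constants, the photorespiratory compensation point and day
#' respiration, plus peaked-Arrhenius terms for Vcmax/Jmax/TPU
#' normalization. All entries can be overridden by the caller.
#'
#' @param Vcmax25,Jmax25,TPU25,Rd25 reference values at 25 degC used to seed
#'   the respective `temp_response` entries (the rate values themselves are
#'   usually replaced by fitted estimates; only the energies matter then).
#' @param Hd deactivation energy for the peaked rates (kJ mol-1).
#' @param dS entropy term for the peaked rates (kJ mol-1 K-1).
#' @return named list of `temp_response` objects: `Kc`, `Ko`, `GammaStar`,
#'   `Rd`, `Vcmax`, `Jmax`, `TPU`.
#' @export
bernacchi_constants <- function(Vcmax25 = 100, Jmax25 = 160, TPU25 = 10,
                                Rd25 = 1.5, Hd = 200, dS = 0.65) {
  list(
    Kc        = temp_response(404.9, 79.43),
    Ko        = temp_response(278.4, 36.38),
    GammaStar = temp_response(42.75, 37.83),
    Rd        = temp_response(Rd25, 46.39),
    Vcmax     = temp_response(Vcmax25, 65.33, Hd, dS),
    Jmax      = temp_response(Jmax25, 43.54, Hd, dS),
    TPU       = temp_response(TPU25, 53.10, Hd, dS)
  )
}

#' FvCB parameter set for one leaf
#'
#' @param Vcmax25 maximum Rubisco carboxylation rate at 25 degC.
#' @param Jmax25 maximum electron transport rate at 25 degC.
#' @param TPU25 maximum triose-phosphate utilization rate at 25 degC, or
#'   `NA` when not identifiable.
#' @param Rd25 day respiration at 25 degC.
#' @param GammaStar25 photorespiratory CO2 compensation point at 25 degC.
#' @param Kc25,Ko25 Rubisco Michaelis constants for CO2 (umol mol-1) and O2
#'   (mmol mol-1) at 25 degC.
#' @param O oxygen mole fraction (mmol mol-1).
#' @param alpha apparent quantum yield of electron transport
#'   (mol e- mol-1 photon, incident basis).
#' @param theta curvature of the non-rectangular hyperbola light response.
#' @param temp named list of `temp_response` objects (see
#'   [bernacchi_constants()]).
#' @return object of class `photo_params`.
#' @export
photo_params <- function(Vcmax25, Jmax25, TPU25 = NA, Rd25 = 1.5,
                         GammaStar25 = 42.75, Kc25 = 404.9, Ko25 = 278.4,
                         O = 210, alpha = 0.35, theta = 0.9,
                         temp = bernacchi_constants()) {
  rates <- c(Vcmax25, Jmax25, Rd25, GammaStar25, Kc25, Ko25)
  stopifnot(all(is.finite(rates)), all(rates >= 0),
            is.na(TPU25) || TPU25 >= 0,
            theta > 0, theta <= 1, alpha > 0, alpha < 1)
  structure(list(Vcmax25 = Vcmax25, Jmax25 = Jmax25, TPU25 = TPU25,
                 Rd25 = Rd25, GammaStar25 = GammaStar25, Kc25 = Kc25,
                 Ko25 = Ko25, O = O, alpha = alpha, theta = theta,
                 temp = temp),
            class = "photo_params")
}

#' Arrhenius temperature scaling
#'
#' Scales a 25 degC parameter value to leaf temperature. When the
#' `temp_response` carries deactivation terms the peaked-function correction
#' is applied. The transform is exactly invertible (see
#' [arrhenius_normalize()]), which is how fitted leaf-temperature values are
#' reported back on the 25 degC basis.
#'
#' @param tr a [temp_response()] object.
#' @param T_leaf leaf temperature (degC), in `[0, 50]`.
#' @return the parameter value at `T_leaf`.
#' @export
arrhenius_scale <- function(tr, T_leaf) {
  stopifnot(inherits(tr, "temp_response"))
  if (!is.finite(T_leaf) || T_leaf < 0 || T_leaf > 50) {
    stop("'T_leaf' must be a finite temperature in [0, 50] degC")
  }
  tr$value25 * .arrhenius_factor(tr, T_leaf)
}

#' @rdname arrhenius_scale
#' @param value_at_T a value measured/fitted at leaf temperature.
#' @return `arrhenius_normalize`: the equivalent 25 degC value.
#' @export
arrhenius_normalize <- function(value_at_T, tr, T_leaf) {
  stopifnot(inherits(tr, "temp_response"))
  value_at_T / .arrhenius_factor(tr, T_leaf)
}

.arrhenius_factor <- function(tr, T_leaf) {
  Tk <- T_leaf + 273.15
  f <- exp(tr$Ha * 1000 * (Tk - .TREF) / (.TREF * .RGAS * Tk))
  if (!is.null(tr$Hd)) {
    Hd <- tr$Hd * 1000
    dS <- tr$dS * 1000
    f <- f * (1 + exp((.TREF * dS - Hd) / (.TREF * .RGAS))) /
      (1 + exp((Tk * dS - Hd) / (Tk * .RGAS)))
  }
  f
}

# All FvCB parameters of `p` scaled to leaf temperature. Returns a plain
# list used by the demand/supply functions.
params_at_leaf_temp <- function(p, T_leaf) {
  stopifnot(inherits(p, "photo_params"))
  sc <- function(nm, v25) {
    if (is.na(v25)) return(NA_real_)
    tr <- p$temp[[nm]]
    v25 * .arrhenius_factor(tr, T_leaf)
  }
  list(Vcmax = sc("Vcmax", p$Vcmax25),
       Jmax = sc("Jmax", p$Jmax25),
       TPU = sc("TPU", p$TPU25),
       Rd = sc("Rd", p$Rd25),
       GammaStar = sc("GammaStar", p$GammaStar25),
       Kc = sc("Kc", p$Kc25),
       Ko = sc("Ko", p$Ko25),
       O = p$O, alpha = p$alpha, theta = p$theta)
}

#' Electron transport rate from the non-rectangular hyperbola
#'
#' Smaller root of `theta J^2 - (alpha Q + Jmax) J + alpha Q Jmax = 0`;
#' `theta = 0` degenerates to the rectangular hyperbola
#' `alpha Q Jmax / (alpha Q + Jmax)`.
#'
#' @param Q incident photosynthetic photon flux density (umol m-2 s-1).
#' @param Jmax maximum electron transport rate at leaf temperature.
#' @param alpha apparent quantum yield (incident basis).
#' @param theta curvature (0 <= theta <= 1).
#' @return J (umol m-2 s-1), vectorized over `Q`.
#' @export
electron_transport <- function(Q, Jmax, alpha = 0.35, theta = 0.9) {
  stopifnot(all(Q >= 0), Jmax >= 0, theta >= 0, theta <= 1)
  aQ <- alpha * Q
  if (theta == 0) {
    J <- ifelse(aQ + Jmax > 0, aQ * Jmax / (aQ + Jmax), 0)
  } else {
    b <- aQ + Jmax
    disc <- pmax(b^2 - 4 * theta * aQ * Jmax, 0)
    J <- (b - sqrt(disc)) / (2 * theta)
  }
  pmin(J, pmin(aQ, Jmax)) # guard rounding at the limits
}

# Invert electron_transport: Jmax such that J(Q, Jmax) == J. Requires
# J < alpha*Q (otherwise Jmax is unbounded).
invert_electron_transport <- function(J, Q, alpha = 0.35, theta = 0.9) {
  aQ <- alpha * Q
  if (J >= aQ) return(NA_real_)
  (aQ * J - theta * J^2) / (aQ - J)
}

#' CO2 demand: net assimilation at a given chloroplast CO2
#'
#' Evaluates the three potential limitations and returns the minimum:
#' `Wc = f_act * Vcmax * (Cc - G*) / (Cc + Kc (1 + O/Ko))` (Rubisco),
#' `Wj = J (Cc - G*) / (4 Cc + 8 G*)` (RuBP regeneration) and `Wp = 3 TPU`
#' (triose-phosphate utilization, applying only above the compensation
#' point). Net assimilation is `A = min(Wc, Wj, Wp) - Rd`.
#'
#' @param Cc chloroplast CO2 mole fraction (umol mol-1), > 0.
#' @param p a [photo_params()] object.
#' @param J electron transport rate actually available (umol m-2 s-1); if
#'   `NULL`, computed from `Q` via [electron_transport()].
#' @param f_act Rubisco activation fraction in `[0, 1]`.
#' @param T_leaf leaf temperature (degC) used to scale the constants.
#' @param Q incident PPFD, only used when `J` is `NULL`.
#' @return list with `A`, `state` (one of `"rubisco"`, `"rubp_regen"`,
#'   `"tpu"`) and the three gross rates `Wc`, `Wj`, `Wp`.
#' @export
co2_demand <- function(Cc, p, J = NULL, f_act = 1, T_leaf = 25, Q = 1500) {
  stopifnot(Cc > 0, f_act >= 0, f_act <= 1)
  v <- params_at_leaf_temp(p, T_leaf)
  if (is.null(J)) J <- electron_transport(Q, v$Jmax, v$alpha, v$theta)
  Km <- v$Kc * (1 + v$O / v$Ko)
  Wc <- f_act * v$Vcmax * (Cc - v$GammaStar) / (Cc + Km)
  Wj <- J * (Cc - v$GammaStar) / (4 * Cc + 8 * v$GammaStar)
  Wp <- if (is.na(v$TPU)) Inf else 3 * v$TPU
  rates <- c(rubisco = Wc, rubp_regen = Wj, tpu = Wp)
  # TPU is a ceiling on export, only meaningful above the compensation point
  if (Cc <= v$GammaStar) rates <- rates[c("rubisco", "rubp_regen")]
  state <- names(rates)[which.min(rates)]
  list(A = unname(min(rates)) - v$Rd, state = state,
       Wc = Wc, Wj = Wj, Wp = unname(Wp))
}

#' Couple CO2 diffusion supply with FvCB demand
#'
#' Finds the operating point where the diffusive flux
#' `A = gsc (Ca - Ci) = gm (Ci - Cc)` equals the biochemical demand at `Cc`.
#' The root is located by bisection on `Cc` (tolerance 1e-4 umol mol-1,
#' maximum 200 iterations); the bracket extends above `Ca` so the dark case
#' (respiratory efflux, `Ci > Ca`) is handled. Pathological parameter sets
#' that give no sign change raise an error rather than clamping silently.
#'
#' @param Ca ambient CO2 mole fraction (umol mol-1).
#' @param gsc stomatal conductance to CO2 (mol m-2 s-1), i.e. `gsw / 1.6`.
#' @param gm mesophyll conductance to CO2 (mol m-2 s-1); may be `Inf`.
#' @param p a [photo_params()] object.
#' @param Q incident PPFD (umol m-2 s-1).
#' @param T_leaf leaf temperature (degC).
#' @param f_act Rubisco activation fraction.
#' @return list with `A`, `Ci`, `Cc` and the limiting `state`.
#' @export
solve_supply_demand <- function(Ca, gsc, gm = Inf, p, Q = 1500,
                                T_leaf = 25, f_act = 1) {
  stopifnot(Ca > 0, gsc > 0, gm > 0)
  v <- params_at_leaf_temp(p, T_leaf)
  J <- electron_transport(Q, v$Jmax, v$alpha, v$theta)
  g_tot <- if (is.infinite(gm)) gsc else 1 / (1 / gsc + 1 / gm)
  demand <- function(Cc) {
    Km <- v$Kc * (1 + v$O / v$Ko)
    Wc <- f_act * v$Vcmax * (Cc - v$GammaStar) / (Cc + Km)
    Wj <- J * (Cc - v$GammaStar) / (4 * Cc + 8 * v$GammaStar)
    W <- pmin(Wc, Wj)
    if (!is.na(v$TPU) && Cc > v$GammaStar) W <- pmin(W, 3 * v$TPU)
    W - v$Rd
  }
  resid <- function(Cc) demand(Cc) - g_tot * (Ca - Cc)
  lo <- 1e-6
  hi <- Ca + (v$Rd + 5) / g_tot # room for respiratory efflux in the dark
  if (resid(lo) > 0 || resid(hi) < 0) {
    stop("supply-demand residual has no sign change on the bracket; ",
         "check conductances and parameters")
  }
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) < 1e-4) break
  }
  Cc <- (lo + hi) / 2
  A <- demand(Cc) # demand side: insensitive to the Cc tolerance
  Ci <- Ca - A / gsc
  d <- co2_demand(Cc, p, J = J, f_act = f_act, T_leaf = T_leaf)
  list(A = A, Ci = Ci, Cc = if (is.infinite(gm)) Ci else Cc, state = d$state)
}

# Fast analytic operating point used by the dynamic simulator: each FvCB
# branch combined with the linear supply A = g_tot (Ca - Cc) is a quadratic
# in Cc; the operating branch is the one with the smallest intersection A.
# `v` is a params_at_leaf_temp() list; J precomputed. Returns c(A, Cc).
.solve_operating_point <- function(Ca, g, v, J, f_act) {
  Km <- v$Kc * (1 + v$O / v$Ko)
  Gs <- v$GammaStar
  Rd <- v$Rd
  # Rubisco branch
  fV <- f_act * v$Vcmax
  b <- g * Km - g * Ca + fV - Rd
  cc <- -(g * Ca * Km + fV * Gs + Rd * Km)
  Cc1 <- (-b + sqrt(b^2 - 4 * g * cc)) / (2 * g)
  A1 <- g * (Ca - Cc1)
  # RuBP-regeneration branch
  b <- 8 * g * Gs - 4 * g * Ca + J - 4 * Rd
  cc <- -(8 * g * Ca * Gs + J * Gs + 8 * Rd * Gs)
  Cc2 <- (-b + sqrt(b^2 - 16 * g * cc)) / (8 * g)
  A2 <- g * (Ca - Cc2)
  A <- min(A1, A2)
  Cc <- max(Cc1, Cc2)
  # TPU ceiling (only above the compensation point)
  if (!is.na(v$TPU)) {
    A3 <- 3 * v$TPU - Rd
    Cc3 <- Ca - A3 / g
    if (Cc3 > Gs && A3 < A) {
      A <- A3
      Cc <- Cc3
    }
  }
  c(A, Cc)
}
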