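# Synthetic gas-exchange data: every input the analysis pipeline consumes,
# generated from known parameters with Gaussian instrument noise so that
# all stages are testable without an infrared gas analyzer.

#' Instrument noise model
#'
#' Gaussian, homoscedastic noise on the measured channels; the simplest
#' defensible IRGA error model (no autocorrelation). Identical seeds give
#' identical output (R's default Mersenne-Twister RNG).
#'
#' @param sigma_A s.d. of assimilation noise (umol m-2 s-1).
#' @param sigma_gs s.d. of conductance noise (mol m-2 s-1).
#' @param sigma_phi s.d. of phiPSII noise (dimensionless).
#' @param seed optional RNG seed applied before generation.
#' @return classed list `noise_model`.
#' @export
noise_model <- function(sigma_A = 0.3, sigma_gs = 0.01, sigma_phi = 0.01,
                        seed = NULL) {
  stopifnot(sigma_A >= 0, sigma_gs >= 0, sigma_phi >= 0)
  structure(list(sigma_A = sigma_A, sigma_gs = sigma_gs,
                 sigma_phi = sigma_phi, seed = seed),
            class = "noise_model")
}

.apply_seed <- function(noise) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  invisible(NULL)
}

#' Shipped and randomized cassava-like cultivar presets
#'
#' Three named presets span the observed behaviour of the cultivar panel:
#' `"mean"` is the panel average (Vcmax 105, Jmax 165, TPU 10.8, stomatal
#' opening time constant 9.8 min); `"fast"` is a fast-induction type whose
#' shade conductance ends near 0.047 mol m-2 s-1 at the shade-sun
#' transition; `"slow"` is a slow type with large opening time constant and
#' a shade conductance near the 0.005 mol m-2 s-1 floor. With `seed` given
#' instead of a name, parameters are drawn uniformly within the observed
#' panel envelopes (Vcmax 95-118, Jmax 149-184, TPU 9.9-11.7, gs
#' 0.25-0.34, k_i 4.5-15 min).
#'
#' @param name one of `"mean"`, `"fast"`, `"slow"`; ignored when `seed`
#'   is given.
#' @param seed integer seed for a random preset.
#' @return a [cultivar_preset()].
#' @export
make_preset <- function(name = c("mean", "fast", "slow"), seed = NULL) {
  if (!is.null(seed)) {
    set.seed(seed)
    p <- photo_params(Vcmax25 = stats::runif(1, 95, 118),
                      Jmax25 = stats::runif(1, 149, 184),
                      TPU25 = stats::runif(1, 9.9, 11.7),
                      Rd25 = 1.5)
    return(cultivar_preset(
      p, k_i = stats::runif(1, 4.5, 15), k_d = stats::runif(1, 4, 10),
      bb = ball_berry_params(8, stats::runif(1, 0.02, 0.055)),
      gm = 0.4, gs_min = stats::runif(1, 0.005, 0.03),
      gsw_ref = stats::runif(1, 0.25, 0.34),
      name = sprintf("random_seed_%d", seed)))
  }
  name <- match.arg(name)
  switch(name,
    mean = cultivar_preset(
      photo_params(105, 165, 10.8, Rd25 = 1.5),
      k_i = 9.8, k_d = 6, bb = ball_berry_params(8, 0.03),
      gm = 0.4, gs_min = 0.01, gsw_ref = 0.30, name = "mean"),
    fast = cultivar_preset(
      photo_params(97, 161, 10.45, Rd25 = 1.5),
      k_i = 4.5, k_d = 5, bb = ball_berry_params(8, 0.046),
      gm = 0.4, gs_min = 0.02, gsw_ref = 0.30, name = "fast"),
    slow = cultivar_preset(
      photo_params(110, 171, 11.43, Rd25 = 1.5),
      k_i = 15, k_d = 8, bb = ball_berry_params(8, 0.005),
      gm = 0.4, gs_min = 0.004, gsw_ref = 0.33, name = "slow"))
}

#' Generate a synthetic A/ci curve
#'
#' Evaluates the FvCB supply-demand balance at the standard 13-step
#' commanded CO2 staircase (see [aci_co2_sequence()]) with the preset's
#' fixed stomatal and mesophyll conductances, then adds instrument noise.
#' The paired phiPSII channel is derived from the *realized* electron
#' transport -- the flux actually needed to support carboxylation plus
#' photorespiration -- so it declines with Ci once the TPU ceiling binds,
#' as observed fluorescence does.
#'
#' @param preset a [cultivar_preset()].
#' @param noise a [noise_model()]; use `noise_model(0, 0, 0)` for exact
#'   model output.
#' @param Q PPFD (umol m-2 s-1).
#' @param T_leaf leaf temperature (degC).
#' @param absorptance,beta fluorescence conversion constants (see
#'   [fluorescence_j()]).
#' @param cultivar,replicate metadata.
#' @return an [aci_curve()] with a `phipsii` column.
#' @export
generate_aci <- function(preset, noise = noise_model(), Q = 1500,
                         T_leaf = 28, absorptance = 0.85, beta = 0.5,
                         cultivar = preset$name, replicate = "1") {
  stopifnot(inherits(preset, "cultivar_preset"))
  .apply_seed(noise)
  ca_seq <- aci_co2_sequence()
  v <- params_at_leaf_temp(preset$params, T_leaf)
  gsw <- preset$gsw_ref
  gsc <- gsw / 1.6
  n <- length(ca_seq)
  A <- Ci <- Cc <- J_real <- numeric(n)
  for (i in seq_len(n)) {
    sol <- solve_supply_demand(ca_seq[i], gsc, preset$gm, preset$params,
                               Q = Q, T_leaf = T_leaf, f_act = 1)
    A[i] <- sol$A; Ci[i] <- sol$Ci; Cc[i] <- sol$Cc
    # realized electron transport consistent with the net flux
    J_real[i] <- (A[i] + v$Rd) * (4 * Cc[i] + 8 * v$GammaStar) /
      (Cc[i] - v$GammaStar)
  }
  phipsii <- J_real / (Q * absorptance * beta)
  A_n <- A + stats::rnorm(n, 0, noise$sigma_A)
  gs_n <- pmax(gsw + stats::rnorm(n, 0, noise$sigma_gs), 1e-4)
  phi_n <- pmin(pmax(phipsii + stats::rnorm(n, 0, noise$sigma_phi), 0), 1)
  # noise is applied to the measured channels (A, gs, phiPSII); the latent
  # Ci is emitted as such -- the instrument's error propagation into its
  # derived Ci is outside this simple noise model
  df <- data.frame(ca_set = ca_seq, ca_umol_mol = ca_seq,
                   ci_umol_mol = Ci, a_umol_m2_s = A_n,
                   gsw_mol_m2_s = gs_n, ppfd = Q, tleaf_c = T_leaf,
                   vpd_kpa = 1.5, phipsii = phi_n)
  aci_curve(df, cultivar = cultivar, replicate = replicate)
}

#' Generate a synthetic induction (or relaxation) trace
#'
#' Runs the dynamic leaf simulator through `regime`, samples every
#' `sample_dt` seconds and adds instrument noise. With
#' `low_co2_shade = TRUE` the stomatal target during all pre-high-light
#' phases is pinned at the high-light steady-state conductance, emulating
#' the stomatal pre-opening produced by a low-CO2 (100 ppm) shade
#' treatment; the CO2 of those phases is also set to 100 for the record.
#'
#' @param preset a [cultivar_preset()].
#' @param regime a [light_regime()]; default [induction_regime()].
#' @param noise a [noise_model()].
#' @param sample_dt sampling interval (s), default 10 as recorded by the
#'   instrument.
#' @param low_co2_shade emulate the low-CO2 shade stomatal pre-opening.
#' @param dt integration step (s).
#' @return a [gasex_trace()] with a `phipsii` column; time 0 at the start
#'   of the regime. The transition time to high light is stored in the
#'   `"high_light_start"` attribute.
#' @export
generate_induction <- function(preset, regime = NULL,
                               noise = noise_model(), sample_dt = 10,
                               low_co2_shade = FALSE, dt = 0.5) {
  stopifnot(inherits(preset, "cultivar_preset"))
  if (is.null(regime)) regime <- induction_regime()
  .apply_seed(noise)
  ovr <- NULL
  if (low_co2_shade) {
    ph <- regime$phases
    hi <- which.max(ph$ppfd)
    ss_hi <- steady_state_leaf(preset, ph$ppfd[hi], Ca = ph$ca[hi],
                               VPD = regime$env$VPD,
                               T_leaf = regime$env$T_leaf,
                               P_atm = regime$env$P_atm)
    ovr <- rep(NA_real_, nrow(ph))
    pre <- seq_len(hi - 1)
    ovr[pre] <- ss_hi$gs
    regime$phases$ca[pre] <- 100
  }
  tr <- simulate_leaf(preset, regime, dt = dt, gs_target_override = ovr)
  keep <- tr$time_s %% sample_dt < dt / 2
  tr <- tr[keep, , drop = FALSE]
  n <- nrow(tr)
  v <- params_at_leaf_temp(preset$params, regime$env$T_leaf)
  J_real <- ifelse(tr$cc_umol_mol > v$GammaStar,
                   (tr$a_umol_m2_s + v$Rd) *
                     (4 * tr$cc_umol_mol + 8 * v$GammaStar) /
                     (tr$cc_umol_mol - v$GammaStar), 0)
  phipsii <- ifelse(tr$ppfd > 0,
                    pmin(J_real / (tr$ppfd * 0.85 * 0.5), 1), 0)
  a_n <- tr$a_umol_m2_s + stats::rnorm(n, 0, noise$sigma_A)
  gs_n <- pmax(tr$gsw_mol_m2_s + stats::rnorm(n, 0, noise$sigma_gs), 1e-4)
  phi_n <- pmin(pmax(phipsii + stats::rnorm(n, 0, noise$sigma_phi), 0), 1)
  df <- data.frame(time_s = tr$time_s, ppfd = tr$ppfd,
                   ca_umol_mol = tr$ca_umol_mol, a_umol_m2_s = a_n,
                   gsw_mol_m2_s = gs_n, ci_umol_mol = tr$ci_umol_mol,
                   tleaf_c = tr$tleaf_c, vpd_kpa = tr$vpd_kpa,
                   phipsii = phi_n)
  out <- gasex_trace(df, cultivar = preset$name,
                     protocol = if (low_co2_shade) "induction_low_co2"
                                else "induction")
  ph <- regime$phases
  attr(out, "high_light_start") <-
    sum(ph$duration_s[seq_len(which.max(ph$ppfd) - 1)])
  out
}

#' Generate a synthetic steady-state light-response curve
#'
#' Coupled steady states (Ball-Berry x FvCB fixed points) at a ladder of
#' light levels at ambient CO2, with noise -- the input for
#' [ball_berry_fit()].
#'
#' @param preset a [cultivar_preset()].
#' @param Q_levels PPFD ladder (umol m-2 s-1).
#' @param noise a [noise_model()].
#' @param Ca,VPD,T_leaf environment.
#' @return data frame with one row per light level (columns as a
#'   [gasex_trace()] minus time).
#' @export
generate_light_curve <- function(preset,
                                 Q_levels = c(50, 100, 200, 400, 700,
                                              1000, 1500, 2000),
                                 noise = noise_model(), Ca = 400,
                                 VPD = 1.5, T_leaf = 28) {
  stopifnot(inherits(preset, "cultivar_preset"))
  .apply_seed(noise)
  rows <- lapply(Q_levels, function(Q) {
    ss <- steady_state_leaf(preset, Q, Ca = Ca, VPD = VPD, T_leaf = T_leaf)
    data.frame(ppfd = Q, ca_umol_mol = Ca,
               a_umol_m2_s = ss$A + stats::rnorm(1, 0, noise$sigma_A),
               gsw_mol_m2_s = max(ss$gs + stats::rnorm(1, 0, noise$sigma_gs),
                                  1e-4),
               ci_umol_mol = ss$Ci, tleaf_c = T_leaf, vpd_kpa = VPD)
  })
  do.call(rbind, rows)
}
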