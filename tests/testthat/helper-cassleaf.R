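# Shared fixtures. Everything is generated in code; the heavier objects are
# built once per test run and reused across files.

quiet_noise <- function() noise_model(0, 0, 0)

# noiseless A/ci curve for the mean preset at cuvette temperature
mean_preset <- make_preset("mean")

mean_curve_28 <- generate_aci(mean_preset, quiet_noise(), T_leaf = 28)

# a preset with effectively infinite mesophyll conductance: the Ci basis
# then coincides with the Cc basis and fits are exactly self-consistent
inf_gm_preset <- local({
  p <- make_preset("mean")
  p$gm <- 1e9
  p
})

inf_gm_curve_25 <- generate_aci(inf_gm_preset, quiet_noise(), T_leaf = 25)

# pure exponential induction trace: A and gs rise with known time
# constants; 60 min after the transition so the 30-min reference is
# effectively the asymptote
exp_induction_trace <- function(tau_A_min = 5, tau_gs_min = 8,
                                A_f = 20, gs_f = 0.3, gs_0 = 0.02,
                                t_pre_s = 60, t_post_s = 3600, dt = 10) {
  tt <- seq(0, t_pre_s + t_post_s, dt)
  rel <- pmax(tt - t_pre_s, 0)
  A <- A_f * (1 - exp(-rel / (tau_A_min * 60)))
  gs <- gs_f + (gs_0 - gs_f) * exp(-rel / (tau_gs_min * 60))
  gs[tt <= t_pre_s] <- gs_0
  gasex_trace(data.frame(time_s = tt, ppfd = ifelse(tt > t_pre_s, 1500, 50),
                         ca_umol_mol = 400, a_umol_m2_s = A,
                         gsw_mol_m2_s = gs, ci_umol_mol = 250,
                         tleaf_c = 28, vpd_kpa = 1.5))
}
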