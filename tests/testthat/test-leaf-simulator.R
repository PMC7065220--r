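# Coupled stomatal + Rubisco-activation + FvCB dynamic leaf model.

test_that("gs_target: floor, zero slope, direct arithmetic", {
  bb <- ball_berry_params(10, 0.03)
  expect_equal(gs_target(-2, 0.7, 400, bb, gs_min = 0.01), 0.01)
  expect_equal(gs_target(22, 0.7, 400, ball_berry_params(0, 0.04)), 0.04)
  expect_equal(gs_target(22, 0.7, 400, bb), 10 * 22 * 0.7 / 400 + 0.03)
})

test_that("long-run simulation converges to the analytic fixed point", {
  p <- make_preset("mean")
  for (Q in c(300, 1500)) {
    ss <- steady_state_leaf(p, Q) # independent root-finder oracle
    tr <- simulate_leaf(p, light_regime(2 * 3600, Q), dt = 1)
    last <- tr[nrow(tr), ]
    expect_equal(last$a_umol_m2_s, ss$A, tolerance = 1e-3)
    expect_equal(last$gsw_mol_m2_s, ss$gs, tolerance = 1e-3)
    expect_equal(last$f_act, ss$f_act, tolerance = 1e-3)
  }
})

test_that("dark limit: A -> -Rd and gs at its floor/intercept", {
  p <- make_preset("mean")
  tr <- simulate_leaf(p, light_regime(3600, 0), dt = 1)
  last <- tr[nrow(tr), ]
  Rd28 <- cassleaf:::params_at_leaf_temp(p$params, 28)$Rd
  expect_equal(last$a_umol_m2_s, -Rd28, tolerance = 1e-2)
  # Ball-Berry target with A < 0 collapses to the floor/intercept
  expect_equal(last$gsw_mol_m2_s,
               max(p$gs_min, p$bb$b + p$bb$m * last$a_umol_m2_s *
                     cassleaf:::surface_humidity(1.5, 28) / 400),
               tolerance = 1e-4)
  # respiratory efflux: Ci above ambient
  expect_gt(last$ci_umol_mol, 400)
})

test_that("mass consistency: A equals the diffusive flux at every step", {
  p <- make_preset("fast")
  tr <- simulate_leaf(p, induction_regime(dark_min = 2, high_min = 5),
                      dt = 0.5)
  flux <- (tr$gsw_mol_m2_s / 1.6) * (tr$ca_umol_mol - tr$ci_umol_mol)
  expect_lt(max(abs(tr$a_umol_m2_s - flux)), 1e-6)
  flux_m <- p$gm * (tr$ci_umol_mol - tr$cc_umol_mol)
  expect_lt(max(abs(tr$a_umol_m2_s - flux_m)), 1e-6)
  expect_true(all(tr$gsw_mol_m2_s >= p$gs_min - 1e-12))
})

test_that("instantaneous mode equals the tau -> 0 limit of the dynamics", {
  p <- make_preset("mean")
  p$k_i <- p$k_d <- 0.02 # 1.2 s kinetics
  p$tau_R <- 0.02
  reg <- light_regime(c(240, 240), c(150, 1200))
  fast <- simulate_leaf(p, reg, dt = 0.1)
  inst <- simulate_leaf(p, reg, dt = 0.1, instantaneous = TRUE)
  sel <- fast$time_s %in% c(120, 230, 300, 470)
  expect_equal(fast$a_umol_m2_s[sel], inst$a_umol_m2_s[sel],
               tolerance = 5e-3)
})

test_that("halving dt changes A by less than 0.01 umol m-2 s-1", {
  p <- make_preset("fast")
  reg <- induction_regime(dark_min = 2, shade_min = 2, high_min = 6)
  a <- simulate_leaf(p, reg, dt = 1)
  b <- simulate_leaf(p, reg, dt = 0.5)
  common <- intersect(a$time_s, b$time_s)
  da <- a$a_umol_m2_s[match(common, a$time_s)] -
    b$a_umol_m2_s[match(common, b$time_s)]
  expect_lt(max(abs(da)), 0.01)
})

test_that("sun-shade transition: A drops instantly, gs decays slowly", {
  p <- make_preset("slow")
  tr <- simulate_leaf(p, fig6_regime(), dt = 1)
  # characteristic slow induction at the 35-min transition
  at <- function(mins) tr[match(mins * 60, tr$time_s), ]
  expect_lt(at(36)$a_umol_m2_s, 0.5 * at(74)$a_umol_m2_s)
  # at 75 min light drops 1500 -> 150: A falls at once...
  drop_a <- (at(74)$a_umol_m2_s - at(76)$a_umol_m2_s) / at(74)$a_umol_m2_s
  expect_gt(drop_a, 0.4)
  # ...while gs has barely moved and needs > 20 min to approach the low
  # steady state
  drop_g <- (at(74)$gsw_mol_m2_s - at(76)$gsw_mol_m2_s) /
    at(74)$gsw_mol_m2_s
  expect_lt(drop_g, 0.1)
  ss_low <- steady_state_leaf(p, 150)
  expect_gt(at(85)$gsw_mol_m2_s, ss_low$gs * 1.1)
  expect_gt(at(95)$gsw_mol_m2_s, ss_low$gs * 1.02)
})

test_that("WUE lag direction on sun -> shade matches stomatal physiology", {
  p <- make_preset("mean")
  reg <- sun_shade_sun_regime(high_min = 30, low_min = 30)
  dyn <- simulate_leaf(p, reg, dt = 1)
  inst <- simulate_leaf(p, reg, dt = 1, instantaneous = TRUE)
  shade0 <- 30 * 60
  w <- function(tr, t) tr$wue[match(t, tr$time_s)]
  # right after the transition the dynamic leaf still has sun-level gs:
  # same A, more transpiration, lower WUE than the instantaneous model
  expect_lt(w(dyn, shade0 + 60), w(inst, shade0 + 60))
  # only after gs has decayed does the dynamic WUE recover to parity
  expect_gt(w(dyn, shade0 + 29 * 60), 0.95 * w(inst, shade0 + 29 * 60))
})

test_that("larger k_i lowers cumulative A over the induction phase", {
  base <- make_preset("mean")
  slow <- base
  slow$k_i <- base$k_i * 2
  reg <- induction_regime(dark_min = 5)
  a1 <- simulate_leaf(base, reg, dt = 1)
  a2 <- simulate_leaf(slow, reg, dt = 1)
  hl <- a1$ppfd == 1500
  expect_gt(sum(a1$a_umol_m2_s[hl]), sum(a2$a_umol_m2_s[hl]))
})

test_that("compare_scenarios: identity at unit multipliers, induction signs", {
  p <- make_preset("fast")
  reg <- induction_regime(dark_min = 5, high_min = 15)
  sc0 <- compare_scenarios(p, reg, ki_mult = 1, kd_mult = 1, dt = 1)
  expect_true(all(abs(sc0$dA_pct) < 1e-9))
  expect_true(all(abs(sc0$dWUE_pct) < 1e-9))
  # accelerated opening: more carbon, less efficient water use during
  # induction
  hl_start <- 10 * 60
  sc3 <- compare_scenarios(p, reg, ki_mult = 3, kd_mult = 1, dt = 1,
                           windows = list(ind10 = c(hl_start,
                                                    hl_start + 600)))
  expect_gt(sc3$dA_pct, 0)
  expect_lt(sc3$dWUE_pct, 0)
})

test_that("diurnal loss: zero for instant kinetics, increasing in k_i", {
  reg <- square_wave_regime(low_min = 5, high_min = 5, n_cycles = 2)
  p0 <- make_preset("mean")
  p0$k_i <- p0$k_d <- 0.02
  p0$tau_R <- 0.02
  expect_lt(abs(diurnal_loss(p0, reg, dt = 0.1)$dA_pct), 0.5)
  losses <- vapply(c(3, 6, 12), function(ki) {
    p <- make_preset("mean")
    p$k_i <- ki
    diurnal_loss(p, reg, dt = 1)$dA_pct
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
  expect_true(all(losses > 0))
})

test_that("stiff kinetics stay finite thanks to the state clamps", {
  p <- make_preset("mean")
  p$k_i <- p$k_d <- 1e-4 # far below dt: RK4 would diverge unclamped
  tr <- simulate_leaf(p, light_regime(60, 1500), dt = 1)
  expect_true(all(is.finite(tr$a_umol_m2_s)))
  expect_true(all(tr$gsw_mol_m2_s >= p$gs_min))
})
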