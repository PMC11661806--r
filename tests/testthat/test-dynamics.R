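test_that("trajectories conserve total receptor to solver precision", {
  p <- gr_profile_step(data.frame(start_min = c(0, 200), nM = c(10, 0)),
                       t_end = 400)
  traj <- gr_simulate("dexamethasone", profile = p)
  mass <- rowSums(as.data.frame(traj)[, GR_STATES])
  expect_lt(max(abs(mass - 1)), 1e-8)
  expect_true(all(as.matrix(as.data.frame(traj)[, GR_STATES]) >= -1e-12))
})

test_that("the ODE settles onto the analytic steady state", {
  for (lig in c("dexamethasone", "cortisol")) {
    for (g in c(0.1, 5, 200)) {
      traj <- gr_simulate(lig, profile = gr_profile_constant(g, t_end = 30000),
                          dt = 100)
      ss <- gr_steady_state(lig, G = g)
      final <- unlist(as.data.frame(traj)[nrow(traj), GR_STATES])
      expect_equal(as.numeric(final), as.numeric(ss), tolerance = 1e-6)
    }
  }
})

test_that("initial conditions: drug-naive, steady and explicit states", {
  prof <- gr_profile_constant(5, t_end = 10)
  t1 <- gr_simulate("dexamethasone", profile = prof, init = "cytoplasmic")
  # loose binding is an instantaneous equilibrium: drug-naive receptor is
  # entirely cytoplasmic (Rc + RcG = 1) but redistributes within the pool
  expect_equal(t1$Rc[1] + t1$RcG[1], 1)
  expect_equal(t1$nuclear_fraction[1], 0)
  t2 <- gr_simulate("dexamethasone", profile = prof, init = "steady")
  ss <- gr_steady_state("dexamethasone", G = 5)
  # starting at the fixed point, the state does not move
  expect_equal(unlist(as.data.frame(t2)[nrow(t2), GR_STATES]),
               unlist(as.data.frame(t2)[1, GR_STATES]), tolerance = 1e-6)
  expect_equal(t2$fRnGN[1], f_rngn(ss))
  t3 <- gr_simulate("dexamethasone", profile = prof, init = ss)
  expect_equal(t3$fRnGN[1], f_rngn(ss))
  expect_error(gr_simulate("dexamethasone", profile = prof, init = "banana"),
               "init must be")
})

test_that("washout after a step decays the active state", {
  p <- gr_profile_step(data.frame(start_min = c(0, 200), nM = c(100, 0)),
                       t_end = 500)
  traj <- gr_simulate("dexamethasone", profile = p)
  on <- traj$fRnGN[traj$time == 200]
  off <- traj$fRnGN[traj$time == 500]
  expect_gt(on, 0.4)
  expect_lt(off, on / 4)
  # after washout the decay of RnGN is governed by k4 = 0.04/min
  tail <- traj[traj$time >= 300, ]
  expect_true(all(diff(tail$fRnGN) < 0))
})

test_that("chase with zero unlabeled ligand reduces to the one-species model", {
  ch0 <- gr_chase("dexamethasone",
                  protocol = gr_chase_protocol(labeled_conc = 100,
                                               chase_conc = 0,
                                               total_duration = 300))
  tr <- gr_simulate("dexamethasone",
                    profile = gr_profile_constant(100, t_end = 300))
  expect_lt(max(abs(ch0$labeled_nuclear - (tr$RnGt + tr$RnGN))), 1e-9)
  expect_lt(max(abs(ch0$RcGt_u)), 1e-12)
})

test_that("chase trajectories conserve total receptor", {
  ch <- gr_chase("dexamethasone", protocol = gr_chase_protocol())
  mass <- ch$Pc + ch$Pn + ch$RcGt_l + ch$RnGt_l + ch$RnGN_l +
    ch$RcGt_u + ch$RnGt_u + ch$RnGN_u
  expect_lt(max(abs(mass - 1)), 1e-8)
})

test_that("chase protocol validates its arguments", {
  expect_error(gr_chase_protocol(labeled_conc = -1), "labeled_conc >= 0")
  expect_error(gr_chase_protocol(total_duration = 50), "total_duration > label_duration")
})

test_that("labeled nuclear signal plateaus before the chase and then decays", {
  ch <- gr_chase("dexamethasone", protocol = gr_chase_protocol())
  at90 <- ch$labeled_nuclear[ch$time == 90]
  at100 <- ch$labeled_nuclear[ch$time == 100]
  expect_lt(abs(at100 - at90) / at100, 0.005) # plateau by 100 min
  post <- ch[ch$time >= 101, ]
  expect_true(all(diff(post$labeled_nuclear) < 0))
  # the displaced label ends far below the plateau
  expect_lt(post$labeled_nuclear[nrow(post)], 0.05 * at100)
})

test_that("trajectory CSV export round-trips", {
  traj <- gr_simulate("dexamethasone",
                      profile = gr_profile_constant(5, t_end = 50))
  f <- tempfile(fileext = ".csv")
  gr_write_trajectory(traj, f)
  back <- read.csv(f)
  expect_equal(back$RnGN, traj$RnGN, tolerance = 1e-12)
  unlink(f)
})
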