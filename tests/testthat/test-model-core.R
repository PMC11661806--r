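test_that("reaction scheme is the canonical 8-edge list", {
  sch <- gr_scheme("dexamethasone")
  expect_equal(nrow(sch), 8L)
  expect_setequal(unique(c(sch$from, sch$to)), GR_STATES)
  expect_equal(sum(sch$kind == "equilibrium"), 2L)
  expect_equal(sch$constant[sch$kind == "equilibrium"], c("Kc", "Kn"))
  # generator columns sum to zero (mass conservation built in)
  M <- grpkpd:::.gr_generator(sch, as_gr_ligand("dexamethasone"), 1)
  expect_equal(max(abs(colSums(M))), 0)
})

test_that("closed-form steady state matches the linear-solve route", {
  grid <- 10^seq(-4, 3, length.out = 50)
  for (lig in c("dexamethasone", "cortisol", "prednisolone")) {
    for (g in grid) {
      a <- gr_steady_state(lig, G = g, method = "closed")
      b <- gr_steady_state(lig, G = g, method = "solve")
      expect_equal(unclass(a), unclass(b), tolerance = 1e-9)
    }
  }
})

test_that("steady state conserves mass and handles G = 0 and Rtot scaling", {
  s <- gr_steady_state("dexamethasone", G = 3)
  expect_equal(sum(s), 1)
  expect_true(all(s >= 0))
  s0 <- gr_steady_state("cortisol", G = 0)
  expect_equal(unname(s0[["Rc"]]), 1)
  expect_equal(sum(s0) - s0[["Rc"]], 0)
  lig <- gr_ligand("custom", Kc = 5, Kn = 155, Rtot = 7)
  s7 <- gr_steady_state(lig, G = 3)
  expect_equal(sum(s7), 7)
  expect_equal(f_rngn(s7), f_rngn(s))
})

test_that("invalid concentrations are rejected", {
  expect_error(gr_steady_state("dexamethasone", G = -1), "non-negative")
  expect_error(gr_steady_state("dexamethasone", G = c(1, 2)), "single")
  expect_error(gr_steady_state("dexamethasone", G = NA_real_), "single")
})

test_that("fRnGN and nuclear fraction are monotone in G", {
  grid <- 10^seq(-4, 3, length.out = 60)
  for (lig in c("dexamethasone", "cortisol")) {
    dr <- gr_dose_response(lig, G = grid)
    expect_true(all(diff(dr$fRnGN) > 0))
    expect_true(all(diff(dr$nuclear_fraction) > 0))
    expect_true(all(dr$relative_activity >= 0 & dr$relative_activity <= 1))
  }
})

test_that("rngn_max is the infinite-dose limit of the steady state", {
  rmax <- rngn_max()
  expect_equal(rmax, (1 / 0.04) / (1 + 1 / 0.2 + 1 / 0.04))
  s <- gr_steady_state("dexamethasone", G = 1e9)
  expect_equal(f_rngn(s), rmax, tolerance = 1e-6)
  # ligand-independent
  expect_equal(f_rngn(gr_steady_state("cortisol", G = 1e10)), rmax,
               tolerance = 1e-6)
})

test_that("high-concentration reduction agrees with the full model for G >= KmT", {
  dex <- get_gr_ligand("dexamethasone")$params
  hi <- mm_high(dex)
  expect_equal(hi$Km, dex$Kn / hi$denom_const)
  for (g in dex$KmT * c(1, 3, 10, 100)) {
    full <- f_rngn(gr_steady_state(dex, G = g))
    expect_lt(abs(mm_activity(hi, g) / full - 1), 0.05)
  }
})

test_that("low-concentration reduction agrees with the full model for G <= 0.002 KmT", {
  dex <- get_gr_ligand("dexamethasone")$params
  lo <- mm_low(dex)
  for (g in dex$KmT * c(2e-3, 5e-4, 1e-4, 1e-5)) {
    full <- f_rngn(gr_steady_state(dex, G = g))
    expect_lt(abs(mm_activity(lo, g) / full - 1), 0.05)
  }
})

test_that("mm_low scales as documented: Km ~ Kc / k1", {
  dex <- get_gr_ligand("dexamethasone")$params
  base <- mm_low(dex)
  slow <- mm_low(dex, gr_rates(k1 = 1))
  expect_equal(slow$Km / base$Km, 9.988, tolerance = 1e-3) # k1 also enters D weakly
  dbl <- mm_low(gr_ligand("x", Kc = 10, Kn = 155), gr_rates())
  expect_equal(dbl$Km, 2 * base$Km)
})

test_that("mm_activity half-saturates at Km and kn_from_kmt inverts mm_high", {
  mm <- mm_experimental(KmT = 50)
  expect_equal(mm_activity(mm, 50), 0.5)
  expect_equal(mm_activity(mm, 0), 0)
  expect_equal(mm_activity(mm, 1.45, relative = TRUE), 1.45 / 51.45)
  lig <- gr_ligand("y", Kc = 5, Kn = kn_from_kmt(5))
  expect_equal(mm_high(lig)$Km, 5)
})

test_that("custom rate constants are validated", {
  r <- gr_rates(k1 = 2)
  expect_equal(r$k1, 2)
  expect_equal(r$k4, 0.04) # other defaults untouched
  expect_error(gr_rates(k3 = -1), "positive")
  expect_error(gr_rates(k6 = 0), "positive")
})
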