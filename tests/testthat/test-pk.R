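test_that("regimen builder implements q.d. and b.i.d. schedules", {
  qd <- gr_regimen("dexamethasone", 10, "q.d.", "oral", days = 2)
  expect_equal(nrow(qd$events), 2L)
  expect_equal(qd$events$amount_mg, c(10, 10))
  expect_equal(qd$events$time_min, c(480, 480 + 1440))
  bid <- gr_regimen("dexamethasone", 10, "b.i.d.", "oral", days = 2)
  expect_equal(nrow(bid$events), 4L)
  expect_equal(unique(bid$events$amount_mg), 5)
  expect_equal(diff(bid$events$time_min)[1], 720) # 12 h apart
  clock <- gr_regimen("dexamethasone", 10, "qd", "oral", dose_time = "06:30")
  expect_equal(clock$events$time_min[1], 390)
})

test_that("regimen builder rejects unsupported input", {
  expect_error(gr_regimen("prednisone", 10, "qd", "IV"), "only administered orally")
  expect_error(gr_regimen("dexamethasone", 10, "tid", "oral"), "q.d. or b.i.d.")
  expect_error(gr_regimen("dexamethasone", -1, "qd", "oral"), "total_daily_mg > 0")
  expect_error(gr_regimen("aspirin", 10, "qd", "oral"))
})

test_that("compact regimen text parses", {
  reg <- gr_parse_regimen("prednisone 100mg oral b.i.d.")
  expect_equal(reg$drug, "prednisone")
  expect_equal(reg$total_daily_mg, 100)
  expect_equal(reg$schedule, "bid")
  expect_error(gr_parse_regimen("prednisone oral"), "expected")
})

test_that("linear PK is exactly superposable and dose-proportional", {
  reg1 <- gr_regimen("dexamethasone", 1, "qd", "IV")
  reg2 <- gr_regimen("dexamethasone", 2, "qd", "IV")
  p1 <- gr_free_concentration(reg1)
  p2 <- gr_free_concentration(reg2)
  tt <- seq(0, 2880, by = 30)
  expect_equal(gr_profile_value(p2, tt), 2 * gr_profile_value(p1, tt),
               tolerance = 1e-12)
  # b.i.d. profile is the superposition of two half-dose q.d. profiles 12 h apart
  bid <- gr_free_concentration(gr_regimen("methylprednisolone", 80, "bid", "IV"))
  qd_a <- gr_free_concentration(gr_regimen("methylprednisolone", 40, "qd", "IV"))
  qd_b <- gr_free_concentration(gr_regimen("methylprednisolone", 40, "qd", "IV",
                                           dose_time = 480 + 720))
  expect_equal(gr_profile_value(bid, tt),
               gr_profile_value(qd_a, tt) + gr_profile_value(qd_b, tt),
               tolerance = 1e-12)
})

test_that("IV dexamethasone-phosphate converts to active-drug equivalents", {
  iv <- gr_regimen("dexamethasone", 1, "qd", "IV")
  expect_equal(iv$events$salt[1], "phosphate")
  p <- gr_pk_params("dexamethasone")
  nmol_iv <- grpkpd:::.gr_active_nmol(iv$events[1, ], p)
  expect_equal(nmol_iv, 1e6 * (392.5 / 472.4) / 392.5) # ~83 % of 1 mg DEX
  # systemic dose: IV delivers (MW ratio)/F ~ 1.41x the oral systemic dose
  oral <- gr_regimen("dexamethasone", 1, "qd", "oral")
  nmol_oral <- grpkpd:::.gr_active_nmol(oral$events[1, ], p) * p$F
  expect_equal(nmol_iv / nmol_oral, (392.5 / 472.4) / 0.59, tolerance = 1e-12)
  expect_gt(nmol_iv / nmol_oral, 1.4)
})

test_that("reference PK constants match the documented values", {
  p <- gr_pk_params("dexamethasone")
  expect_equal(p$fu, 0.23)
  expect_equal(p$F, 0.59)
  expect_equal(c(p$MW, p$MW_salt), c(392.5, 472.4))
  mp <- gr_pk_params("methylprednisolone")
  expect_equal(mp$fu, 0.23)
})

test_that("prednisolone free fraction rises with concentration, free <= total", {
  p <- gr_pk_params("prednisone")
  conc <- c(0, 1, 10, 50, 200, 1000, 5000)
  ff <- prednisolone_free_fraction(conc, p)
  expect_true(all(diff(ff) > 0))
  expect_true(all(ff > 0 & ff <= 1))
  expect_true(all(grpkpd:::.gr_prednisolone_free(conc, p) <= conc))
  # low concentration (5 mg scale) vs high (100 mg scale)
  expect_lt(ff[2], prednisolone_free_fraction(300, p))
  # Bmax = 0 reduces to constant linear binding
  p0 <- p
  p0$transcortin_Bmax_nM <- 0
  expect_equal(prednisolone_free_fraction(c(1, 100, 1e4), p0),
               rep(1 / (1 + p$NS_bound_per_free), 3))
  expect_error(prednisolone_free_fraction(-1, p), "total_nM >= 0")
})

test_that("prednisone PK is nonlinear: superposition fails, free dose-response is supra-linear", {
  tt <- seq(480, 2880, by = 60)
  f5 <- gr_profile_value(gr_free_concentration(gr_regimen("prednisone", 5, "qd", "oral")), tt)
  f50 <- gr_profile_value(gr_free_concentration(gr_regimen("prednisone", 50, "qd", "oral")), tt)
  ratio <- f50[f5 > 0.01] / f5[f5 > 0.01]
  # linear PK would give exactly 10; saturable binding makes free exposure supra-linear
  expect_gt(max(ratio), 10.5)
  expect_false(isTRUE(all.equal(ratio, rep(10, length(ratio)), tolerance = 1e-3)))
})

test_that("prednisolone/prednisone total ratio stays within [2.7, 10] at all sampled times", {
  for (spec in list(c(5, "qd"), c(20, "qd"), c(100, "qd"), c(100, "bid"),
                    c(400, "qd"))) {
    reg <- gr_regimen("prednisone", as.numeric(spec[1]), spec[2], "oral")
    sp <- attr(gr_free_concentration(reg), "species")
    on <- sp$prednisone_total_nM + sp$prednisolone_total_nM > 1e-9
    ratio <- sp$prednisolone_total_nM[on] / sp$prednisone_total_nM[on]
    expect_gt(min(ratio), 2.7)
    expect_lt(max(ratio), 10)
  }
})

test_that("mismatched regimen and parameters are rejected", {
  reg <- gr_regimen("dexamethasone", 1, "qd", "IV")
  expect_error(gr_free_concentration(reg, gr_pk_params("methylprednisolone")),
               "PK parameters are for")
  expect_error(gr_free_concentration(gr_regimen("prednisone", 5, "qd", "oral"),
                                     gr_pk_params("dexamethasone")),
               "PK parameters are for")
})
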