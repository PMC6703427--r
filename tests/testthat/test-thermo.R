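# independent hand sums over the shipped table entries, frozen here
gf <- stats::setNames(tab$dGf0_kJ_mol, tab$id)
dg_methanation_gas <- gf[["ch4_g"]] + 2 * gf[["h2o"]] - gf[["co2_g"]] # -130.75
RT <- 8.31446e-3 * 298.15

test_that("standard Gibbs energy is the formation-energy sum", {
  rxn <- reaction(c(co2_g = -1, h2_g = -4, ch4_g = 1, h2o = 2))
  expect_equal(delta_g_standard(rxn, tab), dg_methanation_gas)
  expect_equal(delta_g_standard(rxn, tab), -130.75, tolerance = 1e-10)
  # identity and antisymmetry
  expect_identical(delta_g_standard(reaction(c(h2o = -1, h2o = 1)), tab), 0)
  rev <- reaction(c(co2_g = 1, h2_g = 4, ch4_g = -1, h2o = -2))
  expect_equal(delta_g_standard(rev, tab), -delta_g_standard(rxn, tab))
})

test_that("missing formation energies raise an error naming the species", {
  expect_error(delta_g_standard(reaction(c(rh = -1, rch3 = 1)), tab),
               "missing dGf0.*rh")
})

test_that("the pH transformation applies R*T*ln(10^-pH) per net proton", {
  rxn <- balance_alkane(16, "acetogenic") # produces 8 H+
  corr <- delta_g_prime(rxn, tab, ph = 7) - delta_g_standard(rxn, tab)
  expect_equal(corr, 8 * RT * log(1e-7), tolerance = 1e-12)
  expect_equal(corr, 8 * -39.95, tolerance = 1e-3)
  # no net protons: transformed equals standard at any pH
  meth <- balance_alkane(16, "methanogenic")
  expect_identical(delta_g_prime(meth, tab, ph = 7),
                   delta_g_standard(meth, tab))
  # pH 0 is the standard state
  expect_identical(delta_g_prime(rxn, tab, ph = 0),
                   delta_g_standard(rxn, tab))
})

test_that("in-situ dG reduces to dG0' in the Q = 1 limit", {
  rxn <- balance_alkane(16, "acetogenic")
  cond <- conditions(298.15, ph = 7,
                     activities = c(acetate = 1, h2_g = 1))
  expect_equal(delta_g_insitu(rxn, tab, cond), delta_g_prime(rxn, tab, 7),
               tolerance = 1e-12)
})

test_that("the methanogenic fate stays exergonic under cold seep conditions", {
  t16 <- with_alkane(tab, 16)
  rxn <- balance_alkane(16, "methanogenic")
  cond <- conditions(277, ph = 7.5, activities = c(ch4_g = 0.5, co2_aq = 0.1))
  expect_lt(delta_g_insitu(rxn, t16, cond), 0)
})

test_that("in-situ dG is extensive and monotone in activities", {
  t16 <- with_alkane(tab, 16)
  rxn <- balance_alkane(16, "methanogenic")
  cond <- conditions(285, ph = 7, activities = c(ch4_g = 0.2, co2_aq = 0.3))
  doubled <- reaction(stats::setNames(2 * rxn$coef, rxn$species))
  expect_equal(delta_g_insitu(doubled, t16, cond),
               2 * delta_g_insitu(rxn, t16, cond), tolerance = 1e-10)
  # increasing a product activity increases dG; a reactant activity decreases it
  base <- delta_g_insitu(rxn, t16, cond)
  up_prod <- conditions(285, 7, c(ch4_g = 0.4, co2_aq = 0.3))
  expect_gt(delta_g_insitu(rxn, t16, up_prod), base)
  expect_error(conditions(285, 7, c(ch4_g = -1)), "> 0")
})

test_that("energy_report reproduces the hexadecane reference energies", {
  # reference per-mol-alkane dG0' at pH 7: +1365.1 / +471.8 / -339.2;
  # tolerance policy absorbs inter-compilation differences
  ref <- c(complete_oxidation = 1365.1, acetogenic = 471.8,
           methanogenic = -339.2)
  for (fate in names(ref)) {
    g <- glance(energy_report(16, fate))
    tol <- max(0.05 * abs(ref[[fate]]), 15)
    expect_lt(abs(g$per_mol_alkane_kJ - ref[[fate]]), tol)
    expect_identical(sign(g$per_mol_alkane_kJ), sign(ref[[fate]]))
  }
  # per-mol-alkane normalization divides the 4-alkane reaction by 4
  g <- glance(energy_report(16, "methanogenic"))
  expect_identical(g$alkane_coef, 4)
  expect_equal(g$per_mol_alkane_kJ, g$dG0_prime_kJ / 4, tolerance = 1e-12)
  expect_identical(g$electrons, 200L)
  expect_equal(g$per_electron_kJ, g$dG0_prime_kJ / 200, tolerance = 1e-12)
  expect_false(g$pressure_corrected)
})

test_that("half-step fates are not energy-evaluable", {
  expect_error(energy_report(16, "oxidation_half"), "not applicable")
})

test_that("per-species contributions sum to the standard value", {
  er <- energy_report(16, "methanogenic")
  expect_equal(sum(tidy(er)$contribution_kJ), er$dG0_kJ, tolerance = 1e-10)
})

test_that("Hess's law ties the fates together exactly on any table", {
  # methanogenic (per 4 alkanes) = 4 x complete oxidation (per alkane)
  #   + (3n+1) x methanation of dissolved CO2
  methanation <- reaction(c(co2_aq = -1, h2_g = -4, ch4_g = 1, h2o = 2))
  dg_meth <- delta_g_prime(methanation, tab, ph = 7)
  tabx <- tab
  for (n in 2:40) tabx <- with_alkane(tabx, n)
  for (n in 2:40) {
    lhs <- delta_g_prime(balance_alkane(n, "methanogenic"), tabx, ph = 7)
    rhs <- 4 * delta_g_prime(balance_alkane(n, "complete_oxidation"),
                             tabx, ph = 7) + (3 * n + 1) * dg_meth
    expect_lt(abs(lhs - rhs), 1e-9)
  }
})

test_that("Gibbs-Helmholtz extrapolation shifts dG0 when dHf0 is available", {
  rxn <- reaction(c(co2_g = -1, h2_g = -4, ch4_g = 1, h2o = 2))
  dh <- sum(c(-1, -4, 1, 2) *
              c(-393.51, 0, -74.81, -285.83))
  expected_277 <- dh - 277 / 298.15 * (dh - dg_methanation_gas)
  got <- alkanogen:::dg0_at_temperature(rxn, tab, 277, "gibbs_helmholtz")
  expect_equal(got, expected_277, tolerance = 1e-9)
  # isothermal default leaves dG0 at its 298.15 K value
  expect_identical(alkanogen:::dg0_at_temperature(rxn, tab, 277),
                   dg_methanation_gas)
  expect_error(
    alkanogen:::dg0_at_temperature(
      reaction(c(rh = -1, rch3 = 1)), tab, 277, "gibbs_helmholtz"),
    "dGf0|dHf0")
})

test_that("alkane formation energies pass through or extrapolate linearly", {
  expect_identical(alkane_gf_estimate(16, tab), 49.8) # tabulated passthrough
  fit <- alkanogen:::alkane_gf_fit(tab)
  expect_gt(fit[2], 0) # formation energy grows with chain length
  # midpoint consistency within the fit residual band
  for (n in 6:19) {
    mid <- (alkane_gf_estimate(n - 1, tab) + alkane_gf_estimate(n + 1, tab)) / 2
    expect_lt(abs(alkane_gf_estimate(n, tab) - mid), 0.5)
  }
  # beyond the table the linear fit takes over and stays monotone
  expect_gt(alkane_gf_estimate(25, tab), alkane_gf_estimate(20, tab))
  expect_error(alkane_gf_estimate(1, tab[tab$id != "ch4_g", ]),
               "n >= 5")
})

test_that("chain scan is strictly more exergonic with chain length", {
  scan <- chain_scan(6, 20, "methanogenic")
  expect_identical(nrow(scan), 15L)
  expect_true(all(diff(scan$per_mol_alkane_kJ) < 0))
  expect_true(all(is.finite(scan$per_electron_kJ)))
  # a single-n scan equals the energy report
  one <- chain_scan(16, 16, "methanogenic")
  expect_equal(one$per_mol_alkane_kJ,
               glance(energy_report(16, "methanogenic"))$per_mol_alkane_kJ)
})

test_that("per-electron column matches the ledger for the methanogenic fate", {
  scan <- chain_scan(2, 10, "methanogenic")
  for (i in seq_len(nrow(scan))) {
    led <- electron_ledger(scan$n[i])
    expect_equal(scan$per_electron_kJ[i],
                 scan$dG0_prime_kJ[i] / led$e_released, tolerance = 1e-12)
  }
})

test_that("conditions files round-trip through the YAML reader", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("temperature_k: 277.0", "ph: 7.5", "activities:",
               "  ch4_g: 0.5", "  co2_aq: 0.1"), f)
  cond <- read_conditions(f)
  expect_equal(cond$temperature_k, 277)
  expect_equal(cond$ph, 7.5)
  expect_equal(cond$activities[["ch4_g"]], 0.5)
})
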