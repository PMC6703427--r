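test_that("scenario generation is bit-reproducible given spec and seed", {
  spec <- scenario_spec(n_scenarios = 100, seed = 42)
  a <- generate_scenarios(spec)
  b <- generate_scenarios(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_scenarios(scenario_spec(n_scenarios = 100, seed = 43))
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("scenarios respect the declared ranges", {
  r <- default_scenario_ranges()
  for (design in c("lhs", "random", "grid")) {
    sc <- generate_scenarios(scenario_spec(design = design,
                                           n_scenarios = 60, seed = 5))
    expect_true(all(sc$temperature_k >= r$temperature_k$min &
                      sc$temperature_k <= r$temperature_k$max))
    expect_true(all(sc$ph >= r$ph$min & sc$ph <= r$ph$max))
    expect_true(all(sc$ch4_g >= r$activities$ch4_g$min - 1e-12 &
                      sc$ch4_g <= r$activities$ch4_g$max + 1e-12))
  }
})

test_that("degenerate ranges yield the single specified condition set", {
  r <- list(temperature_k = list(min = 280, max = 280),
            ph = list(min = 7, max = 7),
            activities = list(ch4_g = list(min = 0.5, max = 0.5,
                                           log10 = TRUE)))
  sc <- generate_scenarios(scenario_spec(ranges = r, n_scenarios = 1,
                                         seed = 1))
  expect_identical(nrow(sc), 1L)
  expect_equal(sc$temperature_k, 280)
  expect_equal(sc$ph, 7)
  expect_equal(sc$ch4_g, 0.5)
})

test_that("the grid design enumerates levels over free axes only", {
  sc <- generate_scenarios(scenario_spec(design = "grid", n_levels = 3,
                                         seed = 1))
  expect_identical(nrow(sc), 81L) # 3 levels ^ 4 free axes
  r <- default_scenario_ranges()
  r$ph <- list(min = 7, max = 7) # freeze one axis
  sc2 <- generate_scenarios(scenario_spec(ranges = r, design = "grid",
                                          n_levels = 3, seed = 1))
  expect_identical(nrow(sc2), 27L)
  expect_true(all(sc2$ph == 7))
})

test_that("invalid ranges are rejected", {
  bad <- default_scenario_ranges()
  bad$temperature_k <- list(min = 300, max = 280)
  expect_error(scenario_spec(ranges = bad), "min <= max")
  bad2 <- default_scenario_ranges()
  bad2$activities$ch4_g <- list(min = -1, max = 1)
  expect_error(scenario_spec(ranges = bad2), "> 0")
  expect_error(scenario_spec(n_scenarios = 0), ">= 1")
})

test_that("feasibility summary counts are exact fractions", {
  sc <- generate_scenarios(scenario_spec(n_scenarios = 200, seed = 42))
  fs <- feasibility_screen(16, "methanogenic", sc)
  expect_identical(fs$n_scenarios, 200L)
  expect_identical(fs$fraction_exergonic, fs$n_exergonic / fs$n_scenarios)
  expect_true(fs$dG_min_kJ <= fs$dG_median_kJ &&
                fs$dG_median_kJ <= fs$dG_max_kJ)
  details <- tidy(fs)
  expect_identical(nrow(details), 200L)
  expect_identical(sum(details$exergonic), fs$n_exergonic)
})

test_that("complete oxidation at 1 bar H2 is never exergonic at the seep", {
  sc <- generate_scenarios(scenario_spec(n_scenarios = 200, seed = 42))
  fs <- feasibility_screen(16, "complete_oxidation", sc)
  expect_identical(fs$fraction_exergonic, 0)
  expect_gt(fs$dG_min_kJ, 0)
})

test_that("a single standard-state scenario recovers the dG0' value", {
  sc <- tibble::tibble(scenario = 1L, temperature_k = 298.15, ph = 7,
                       ch4_g = 1, co2_aq = 1)
  fs <- feasibility_screen(16, "methanogenic", sc)
  ref <- glance(energy_report(16, "methanogenic"))$per_mol_alkane_kJ
  expect_equal(fs$dG_min_kJ, ref, tolerance = 1e-10)
  expect_equal(fs$dG_max_kJ, ref, tolerance = 1e-10)
  expect_equal(fs$dG_median_kJ, ref, tolerance = 1e-10)
})

test_that("lowering p(CH4) never makes the methanogenic fate less exergonic", {
  base <- tibble::tibble(scenario = 1L, temperature_k = 285, ph = 7.2,
                         ch4_g = 1, co2_aq = 0.5)
  dgs <- vapply(c(1, 0.1, 0.01, 0.001), function(p) {
    sc <- base; sc$ch4_g <- p
    feasibility_screen(16, "methanogenic", sc)$dG_min_kJ
  }, numeric(1))
  expect_true(all(diff(dgs) < 0))
})

test_that("a biological energy quantum shifts the exergonicity threshold", {
  sc <- tibble::tibble(scenario = 1L, temperature_k = 298.15, ph = 7,
                       ch4_g = 1, co2_aq = 1)
  strict <- feasibility_screen(16, "methanogenic", sc)
  quantum <- feasibility_screen(16, "methanogenic", sc,
                                threshold_kJ = -1000)
  expect_identical(strict$n_exergonic, 1L)
  expect_identical(quantum$n_exergonic, 0L)
  expect_identical(quantum$threshold_kJ, -1000)
})

test_that("feasibility screen rejects an empty scenario list", {
  empty <- tibble::tibble(scenario = integer(), temperature_k = numeric(),
                          ph = numeric(), ch4_g = numeric(),
                          co2_aq = numeric())
  expect_error(feasibility_screen(16, "methanogenic", empty), "empty")
})
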