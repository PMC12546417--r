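test_that("energy allocation factors follow the yield-weighted energy shares", {
  expect_equal(energy_allocation_factors(coproduct_spec(0.2, 0.05, 20, 20)),
               c(meal = 0.8, oil = 0.2))
  expect_equal(energy_allocation_factors(coproduct_spec(0.5, 0.5, 18, 18)),
               c(meal = 0.5, oil = 0.5))
  f <- energy_allocation_factors(coproduct_spec(0.2, 0.05, 18.5, 39.0))
  expect_equal(unname(f), c(3.7, 1.95) / 5.65, tolerance = 1e-12)  # 0.6549 / 0.3451
  expect_equal(round(unname(f), 4), c(0.6549, 0.3451))
})

test_that("coproduct specifications are validated", {
  expect_error(coproduct_spec(0, 0.05, 20, 40), "positive")
  expect_error(coproduct_spec(0.2, 0.05, -1, 40), "positive")
  expect_error(coproduct_spec(0.7, 0.5, 20, 40), "<= 1")
})

test_that("energy allocation divides the fresh burden per the coproduct formulas", {
  res <- allocate_energy(10, coproduct_spec(0.2, 0.05, 20, 20))
  expect_equal(res$nppu_meal$value_kg, 40)
  expect_equal(res$nppu_oil$value_kg, 40)

  res2 <- allocate_energy(10, coproduct_spec(0.2, 0.05, 20, 40))
  expect_equal(res2$factor_meal, 2 / 3)
  expect_equal(res2$nppu_meal$value_kg, 10 / 0.2 * 2 / 3)  # 33.33
  expect_equal(res2$nppu_oil$value_kg, 10 / 0.05 * 1 / 3)  # 66.67
  expect_identical(res2$nppu_meal$basis, "ingredient")
  expect_identical(res2$nppu_meal$allocation_label, "energy")
})

test_that("mass allocation spreads the fresh burden over coproduct masses", {
  res <- allocate_mass(10, coproduct_spec(0.2, 0.05, 18.5, 39))
  expect_equal(res$nppu_meal$value_kg, 10 / 0.25)  # fresh / (Y_meal + Y_oil)
  expect_equal(res$nppu_oil$value_kg, 10 / 0.25)
  res_narrow <- allocate_mass(10, coproduct_spec(0.2, 0.025, 18.5, 39))
  expect_equal(res_narrow$nppu_meal$value_kg, 44.44, tolerance = 1e-3)
  res2 <- allocate_mass(10, coproduct_spec(0.5, 0.5, 18.5, 39))
  expect_equal(res2$nppu_meal$value_kg, 10)
  expect_equal(res2$nppu_oil$value_kg, 10)
})

test_that("custom-weight allocation reduces to energy and mass allocation", {
  spec <- coproduct_spec(0.2, 0.05, 18.5, 39)
  cus <- allocate_custom(10, spec, 18.5, 39)
  en <- allocate_energy(10, spec)
  expect_equal(cus$factor_meal, en$factor_meal)
  expect_equal(cus$nppu_meal$value_kg, en$nppu_meal$value_kg)

  eq <- allocate_custom(10, spec, 1, 1)
  ms <- allocate_mass(10, spec)
  expect_equal(eq$nppu_meal$value_kg, ms$nppu_meal$value_kg)
  expect_equal(eq$nppu_oil$value_kg, ms$nppu_oil$value_kg)

  expect_error(allocate_custom(10, spec, 1, 0), "positive")
  expect_error(allocate_custom(10, spec, -2, 1), "positive")
})

test_that("mass balance holds for every allocation method on random specs", {
  specs <- generate_coproduct_specs(200, seed = 5)
  for (spec in specs) {
    fresh <- 12.5
    for (res in list(allocate_mass(fresh, spec), allocate_energy(fresh, spec),
                     allocate_custom(fresh, spec, 2.5, 7))) {
      back <- spec$yield_meal * res$nppu_meal$value_kg +
        spec$yield_oil * res$nppu_oil$value_kg
      expect_lt(rel_diff(back, fresh), 1e-9)
      expect_equal(res$factor_meal + res$factor_oil, 1, tolerance = 1e-9)
    }
  }
})

test_that("allocation factors are invariant under rescaling energies or weights", {
  for (k in c(0.001, 3, 1e4)) {
    a <- energy_allocation_factors(coproduct_spec(0.22, 0.07, 18.5, 39))
    b <- energy_allocation_factors(coproduct_spec(0.22, 0.07, 18.5 * k, 39 * k))
    expect_equal(a, b)
    ca <- allocate_custom(10, coproduct_spec(0.22, 0.07, 18.5, 39), 2, 5)
    cb <- allocate_custom(10, coproduct_spec(0.22, 0.07, 18.5, 39), 2 * k, 5 * k)
    expect_equal(ca$factor_meal, cb$factor_meal)
  }
})

test_that("processing concentrates the burden when yields do not exhaust the fish", {
  specs <- generate_coproduct_specs(100, seed = 17)
  for (spec in specs) {
    res <- allocate_mass(10, spec)
    expect_gte(res$nppu_meal$value_kg, 10)
    expect_gte(res$nppu_oil$value_kg, 10)
  }
})

test_that("allocation rejects NPPU values not on the fresh basis", {
  ing <- nppu_value(500, basis = "ingredient")
  expect_error(allocate_mass(ing, coproduct_spec(0.2, 0.05, 18, 39)), "fresh")
})

test_that("tier-by-yield matrix produces the labelled variant set", {
  rec <- species_record("sp", trophic_parameters(TL = 3.2, TE = 0.119),
                        C_specific = 105.0)
  spec_g <- coproduct_spec(0.225, 0.05, 18.5, 39, "generic")
  spec_s <- coproduct_spec(0.20, 0.08, 18.5, 39, "specific")

  m <- tier_yield_matrix(rec, spec_g, spec_s, method = "energy")
  expect_equal(m$label, c("T11", "T12", "T21", "T22", "T31", "T32"))

  # definitional consistency of one entry
  fresh <- nppu_for_class(rec, tier_policy("marine", "T1"))
  direct <- allocate_energy(fresh, spec_g)
  expect_equal(m$nppu_meal_kg[m$label == "T11"], direct$nppu_meal$value_kg)
  expect_equal(m$nppu_oil_kg[m$label == "T11"], direct$nppu_oil$value_kg)

  # degenerate matrix: no specific data to differ on, identical specs
  bare <- species_record("sp", trophic_parameters(TL = 3.2, TE = 0.10),
                         C_specific = 111.1)
  same <- tier_yield_matrix(bare, spec_g, spec_g, method = "energy")
  expect_equal(length(unique(round(same$nppu_meal_kg, 12))), 1)

  fw <- tier_yield_matrix(rec, spec_g, spec_s, method = "mass",
                          class = "freshwater")
  expect_equal(fw$label, c("T11", "T12", "T21", "T22"))
})

test_that("tier-by-yield matrix propagates missing-data errors", {
  bare <- species_record("sp", trophic_parameters(TL = 3.2))
  spec <- coproduct_spec(0.2, 0.05, 18.5, 39)
  expect_error(tier_yield_matrix(bare, spec, spec, method = "energy"),
               "transfer efficiency")
})
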