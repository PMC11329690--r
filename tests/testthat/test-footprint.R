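test_that("person impacts match a brute-force spreadsheet-style sum", {
  intakes <- tiny_intakes()
  fac <- tiny_factors()
  got <- person_impacts(intakes, fac)
  for (p in 1:2) {
    for (imp in c("gwp", "land_use")) {
      manual <- sum(vapply(c("a", "b", "c"), function(fid)
        intakes[p, fid] * fac[[imp]][fac$food_id == fid], numeric(1)))
      expect_equal(got[[imp]][p], manual, tolerance = 1e-12)
    }
    manual_n <- 1000 * sum(vapply(c("a", "b", "c"), function(fid)
      intakes[p, fid] * fac$marine_eutroph[fac$food_id == fid], numeric(1)))
    expect_equal(got$marine_eutroph[p], manual_n, tolerance = 1e-12)
  }
})

test_that("simple arithmetic cases: zero intake and unit conversion", {
  intakes <- data.frame(person_id = "p1", a = 0)
  fac <- tiny_factors()
  expect_equal(unlist(person_impacts(intakes, fac)[, -1]),
               c(gwp = 0, land_use = 0, marine_eutroph = 0,
                 freshwater_eutroph = 0))
  one <- data.frame(person_id = "p1", a = 100)
  fac1 <- data.frame(food_id = "a", gwp = 0.01, land_use = 0,
                     marine_eutroph = 0, freshwater_eutroph = 0)
  expect_equal(person_impacts(one, fac1)$gwp, 1.0)
})

test_that("impacts are linear in intake", {
  intakes <- tiny_intakes()
  doubled <- intakes
  doubled[, -1] <- doubled[, -1] * 2
  a <- person_impacts(intakes, tiny_factors())
  b <- person_impacts(doubled, tiny_factors())
  expect_equal(as.matrix(b[, -1]), 2 * as.matrix(a[, -1]), tolerance = 1e-15)
})

test_that("missing factors error unless configured to drop", {
  intakes <- tiny_intakes()
  fac <- tiny_factors()[1:2, ]
  expect_error(person_impacts(intakes, fac), "c")
  expect_warning(got <- person_impacts(intakes, fac, "drop"), "dropping")
  expect_equal(got$gwp, person_impacts(intakes[, 1:3], fac)$gwp)
})

test_that("group contributions decompose the total exactly", {
  spec <- small_spec(n = 120, seed = 21)
  pop <- generate_population(spec)
  fac <- generate_impact_factors(spec)
  labels <- pop$truth$cluster
  w <- pop$persons$survey_weight
  contrib <- group_contributions(pop$intakes, fac, spec$foods, labels, w)
  imp <- person_impacts(pop$intakes, fac)
  for (cl in unique(contrib$cluster)) {
    rows <- if (cl == "ALL") rep(TRUE, nrow(imp)) else labels == as.integer(cl)
    for (ic in c("gwp", "land_use", "marine_eutroph", "freshwater_eutroph")) {
      total <- sum(imp[[ic]][rows] * w[rows]) / sum(w[rows])
      decomp <- sum(contrib$contribution[contrib$cluster == cl &
                                           contrib$impact == ic])
      expect_equal(decomp, total, tolerance = 1e-9)
    }
  }
})

test_that("single cluster and single group reduces to the weighted mean total", {
  intakes <- tiny_intakes()
  reg <- tiny_registry()
  reg$food_group <- "Everything"
  w <- c(2, 1)
  contrib <- group_contributions(intakes, tiny_factors(), reg,
                                 labels = c(1, 1), weights = w)
  imp <- person_impacts(intakes, tiny_factors())
  got <- contrib$contribution[contrib$cluster == "1" & contrib$impact == "gwp"]
  expect_equal(got, sum(imp$gwp * w) / sum(w), tolerance = 1e-12)
})

test_that("meat and dairy dominate the GWP decomposition under the default spec", {
  spec <- small_spec(n = 250, seed = 31)
  pop <- generate_population(spec)
  fac <- generate_impact_factors(spec)
  contrib <- group_contributions(pop$intakes, fac, spec$foods,
                                 weights = pop$persons$survey_weight)
  gwp <- contrib[contrib$impact == "gwp", ]
  shares <- stats::setNames(gwp$contribution, gwp$food_group)
  meat_dairy <- sum(shares[c("Beef", "Pork", "Processed meat", "Poultry",
                             "Liquid dairy", "Solid dairy")])
  others <- shares[!names(shares) %in% c("Beef", "Pork", "Processed meat",
                                         "Poultry", "Liquid dairy",
                                         "Solid dairy")]
  expect_gt(meat_dairy, max(others))
})
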