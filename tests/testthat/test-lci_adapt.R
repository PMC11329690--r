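test_that("import/export ratio follows the declared conventions", {
  expect_equal(import_export_ratio(200, 100), 2.0)
  expect_equal(import_export_ratio(0, 0), 0)       # both zero -> domestic
  expect_equal(import_export_ratio(5, 0), Inf)
  expect_error(import_export_ratio(-1, 2), "non-negative")
})

test_that("origin classification puts the boundary ratio at domestic", {
  expect_identical(classify_origin(2.0), "imported")
  expect_identical(classify_origin(1.0), "domestic")
  expect_identical(classify_origin(0.3), "domestic")
  expect_identical(classify_origin(Inf), "imported")
})

adapt_fixture <- function() {
  base <- data.frame(food_id = c("f1", "f2"),
                     gwp = c(5.0, 5.0), land_use = c(2.0, 2.0),
                     marine_eutroph = c(1.0, 1.0),
                     freshwater_eutroph = c(0.5, 0.5),
                     adapted = FALSE, stringsAsFactors = FALSE)
  trade <- data.frame(food_id = c("f1", "f2"),
                      import_t = c(50, 200), export_t = c(100, 100))
  list(base = base, trade = trade)
}

ei <- function(src = 1.0, eur = 3.0, dom = 2.0) {
  data.frame(impact = c("gwp", "land_use", "marine_eutroph", "freshwater_eutroph"),
             source = src, european = eur, domestic = dom)
}

test_that("electricity substitution matches the hand-computed value", {
  fx <- adapt_fixture()
  rules <- adaptation_rules(ei(), electricity_share = 0.2)
  out <- apply_adaptation(fx$base, fx$trade, rules)
  # f1 domestic (ratio 0.5): 5.0 - 0.2*1.0 + 0.2*2.0 = 5.2
  expect_equal(out$gwp[1], 5.2, tolerance = 1e-12)
  # f2 imported (ratio 2): 5.0 - 0.2*1.0 + 0.2*3.0 = 5.4
  expect_equal(out$gwp[2], 5.4, tolerance = 1e-12)
  expect_identical(out$origin_flag, c("domestic", "imported"))
  expect_true(all(out$adapted))
})

test_that("identity rules leave factors bit-identical apart from the flags", {
  fx <- adapt_fixture()
  rules <- adaptation_rules(ei(), electricity_share = 0)
  out <- apply_adaptation(fx$base, fx$trade, rules)
  for (cl in c("gwp", "land_use", "marine_eutroph", "freshwater_eutroph"))
    expect_identical(out[[cl]], fx$base[[cl]])
})

test_that("feed factor applies multiplicatively to livestock foods only", {
  fx <- adapt_fixture()
  rules <- adaptation_rules(ei(), electricity_share = 0,
                            feed_factor = c(gwp = 0.9, land_use = 1,
                                            marine_eutroph = 1,
                                            freshwater_eutroph = 1),
                            livestock_foods = "f1")
  out <- apply_adaptation(fx$base, fx$trade, rules)
  expect_equal(out$gwp, c(4.5, 5.0), tolerance = 1e-12)
  expect_equal(out$land_use, fx$base$land_use)
})

test_that("adaptation is per-impact independent", {
  fx <- adapt_fixture()
  only_gwp <- data.frame(impact = "gwp", source = 1, european = 3, domestic = 2)
  rules <- adaptation_rules(only_gwp, electricity_share = 0.5)
  out <- apply_adaptation(fx$base, fx$trade, rules)
  expect_false(isTRUE(all.equal(out$gwp, fx$base$gwp)))
  expect_identical(out$land_use, fx$base$land_use)
  expect_identical(out$marine_eutroph, fx$base$marine_eutroph)
})

test_that("negative adapted factors clip to zero with a warning", {
  fx <- adapt_fixture()
  rules <- adaptation_rules(ei(src = 100, eur = 0, dom = 0),
                            electricity_share = 0.5)
  expect_warning(out <- apply_adaptation(fx$base, fx$trade, rules), "clipped")
  expect_true(all(out$gwp >= 0))
})

test_that("foods without trade records need a default origin", {
  fx <- adapt_fixture()
  rules <- adaptation_rules(ei(), electricity_share = 0.2)
  expect_error(apply_adaptation(fx$base, fx$trade[1, ], rules), "f2")
  out <- apply_adaptation(fx$base, fx$trade[1, ], rules,
                          default_origin = "domestic")
  expect_identical(out$origin_flag[2], "domestic")
})
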