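# Synthetic generator: determinism, planted climate anomalies, deficit
# structure, soil table.

test_that("config validation rejects impossible worlds", {
  expect_error(synthetic_config(calendar_span = c(1990, 2013)), "49")
  expect_error(synthetic_config(event_years = 1903), "41 years")
  expect_error(synthetic_config(event_years = 1990), "41 years")
  expect_error(synthetic_config(resist_deficit_dead = c(angiosperm = 1.2,
                                                        gymnosperm = 0.9)))
  expect_error(synthetic_config(true_windows = data.frame(target_month = 6,
                                                          scale = 30)),
               "1..24")
})

test_that("identical config and seed give a byte-identical bundle", {
  cfg <- synthetic_config(n_sites = 3, trees_surviving = 3, trees_dead = 2,
                          seed = 77)
  d1 <- tempfile(); d2 <- tempfile()
  suppressWarnings(generate_dataset(cfg, d1))
  suppressWarnings(generate_dataset(cfg, d2))
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("climate honours its postconditions and the planted minimum", {
  cfg <- small_config()
  for (site in c(1, 3)) {
    cl <- generate_climate(cfg, site)
    expect_true(all(cl$prcp_mm >= 0))
    expect_true(all(cl$pet_mm > 0))
    # oracle: direct aggregation + argmin over all years at the true window
    tw <- cfg$true_windows[site, ]
    bal <- data.frame(year = cl$year, month = cl$month,
                      d = cl$prcp_mm - cl$pet_mm)
    agg <- aggregate_balance(bal, tw$scale, tw$target_month)
    expect_equal(agg$year[which.min(agg$agg)], cfg$event_years[site])
    # seasonality present: winter precipitation exceeds summer on average
    expect_gt(mean(cl$prcp_mm[cl$month %in% c(12, 1, 2)]),
              mean(cl$prcp_mm[cl$month %in% 6:8]))
  }
})

test_that("zero interannual noise leaves only the planted anomaly", {
  cfg <- synthetic_config(n_sites = 1, climate_noise_sd = 0, seed = 5)
  cl <- generate_climate(cfg, 1)
  bal <- data.frame(year = cl$year, month = cl$month,
                    d = cl$prcp_mm - cl$pet_mm)
  # January is outside every true window here (month 6, scale 3)
  jan <- aggregate_balance(bal, 1, 1)
  expect_lt(stats::sd(jan$agg), 1e-9)
  jun <- aggregate_balance(bal, 3, 6)
  off <- jun$agg[jun$year != cfg$event_years[1]]
  expect_lt(stats::sd(off), 1e-9)
  expect_lt(jun$agg[jun$year == cfg$event_years[1]], min(off))
})

test_that("tree counts, statuses and death ordering are as configured", {
  cfg <- synthetic_config(n_sites = 5, trees_surviving = 10, trees_dead = 10,
                          seed = 13)
  total <- 0
  for (site in 1:5) {
    cl <- generate_climate(cfg, site)
    ts <- generate_tree_series(cfg, cl, site)
    total <- total + length(ts$series)
    status <- vapply(ts$series, `[[`, "", "status")
    expect_equal(sum(status == "surviving"), 10)
    expect_equal(sum(status == "now-dead"), 10)
    last <- vapply(ts$series, `[[`, 0, "last_year")
    expect_true(all(last[status == "now-dead"] < min(last[status == "surviving"])))
    dy <- last[status == "now-dead"] - cfg$event_years[site]
    expect_true(all(dy >= 10 & dy <= 40))
    expect_true(all(unlist(lapply(ts$series, `[[`, "trw")) > 0))
    expect_equal(nrow(ts$ledger), 20)
  }
  expect_equal(total, 100)
})

test_that("the planted resistance deficit appears in event-year widths", {
  # angiosperm site (site 1), deficit 0.7, many trees
  cfg <- synthetic_config(n_sites = 1, trees_surviving = 100, trees_dead = 100,
                          seed = 23)
  cl <- generate_climate(cfg, 1)
  ts <- generate_tree_series(cfg, cl, 1)
  ev <- cfg$event_years[1]
  w <- vapply(ts$series, function(s) s$trw[s$years == ev], numeric(1))
  status <- vapply(ts$series, `[[`, "", "status")
  ratio <- mean(w[status == "now-dead"]) / mean(w[status == "surviving"])
  expect_equal(ratio, 0.7, tolerance = 0.06)
})

test_that("larger resistance deficits mean lower dead-tree event growth", {
  ratios <- vapply(c(0.5, 0.9), function(def) {
    cfg <- synthetic_config(n_sites = 1, trees_surviving = 60, trees_dead = 60,
                            seed = 29,
                            resist_deficit_dead = c(angiosperm = def,
                                                    gymnosperm = def))
    cl <- generate_climate(cfg, 1)
    ts <- generate_tree_series(cfg, cl, 1)
    ev <- cfg$event_years[1]
    w <- vapply(ts$series, function(s) s$trw[s$years == ev], numeric(1))
    status <- vapply(ts$series, `[[`, "", "status")
    mean(w[status == "now-dead"]) / mean(w[status == "surviving"])
  }, numeric(1))
  expect_lt(ratios[1], ratios[2])
})

test_that("the null configuration makes statuses exchangeable", {
  cfg <- synthetic_config(n_sites = 1, trees_surviving = 50, trees_dead = 50,
                          seed = 31, beta_climate = 0, event_growth_drop = 0,
                          resist_deficit_dead = c(angiosperm = 1, gymnosperm = 1),
                          recov_deficit_dead = c(angiosperm = 1, gymnosperm = 1))
  cl <- generate_climate(cfg, 1)
  ts <- generate_tree_series(cfg, cl, 1)
  ev <- cfg$event_years[1]
  w <- log(vapply(ts$series, function(s) s$trw[s$years == ev], numeric(1)))
  status <- vapply(ts$series, `[[`, "", "status")
  tt <- stats::t.test(w[status == "now-dead"], w[status == "surviving"])
  expect_gt(tt$p.value, 0.001)  # no planted difference at the event year
})

test_that("the soil table carries a nitrogen-loaded fertility factor", {
  soil <- generate_soil_table(12, seed = 3)
  expect_equal(nrow(soil), 12)
  expect_equal(ncol(soil), 11)  # site + ten characteristics
  expect_equal(soil$clay + soil$silt + soil$sand, rep(100, 12))
  expect_identical(soil, generate_soil_table(12, seed = 3))
  # latent factor: nitrogen, organic carbon and AWC rise together
  expect_gt(stats::cor(soil$total_nitrogen, soil$organic_carbon), 0.5)
  expect_gt(stats::cor(soil$total_nitrogen, soil$awc), 0.3)
  expect_error(generate_soil_table(2), "at least 3")
})

test_that("generated bundles round-trip through assembly without warnings", {
  bundle <- small_bundle()
  expect_no_warning(
    assemble_dataset(bundle$paths$rwl, bundle$paths$metadata,
                     bundle$paths$climate, bundle$paths$soil, "0.001"))
  expect_equal(nrow(bundle$ledger$sites), small_config()$n_sites)
  expect_equal(nrow(bundle$ledger$trees), length(bundle$dataset$series))
})
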