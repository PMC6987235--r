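# BAI, Lloret indices, SPEI covariates, record assembly, bootstrap curves.

test_that("BAI reconstruction honours disc geometry", {
  # one ring of 1 mm with the prior radius at zero: a full disc of pi mm^2
  s1 <- ring_series("one", 2000, 1, dbh_cm = 0.2)
  b1 <- compute_bai(s1)
  expect_equal(b1$bai, pi)

  # telescoping: total BAI equals the annulus between first and last radius
  set.seed(6)
  w <- stats::runif(40, 0.5, 3)
  s <- ring_series("t", 1961:2000, w, dbh_cm = 2 * (sum(w) + 5) / 10)
  b <- compute_bai(s)
  r_last <- s$dbh_cm * 10 / 2
  r_first <- r_last - sum(w)
  expect_equal(sum(b$bai), pi * (r_last^2 - r_first^2), tolerance = 1e-9)

  # constant widths give strictly increasing BAI
  sc <- ring_series("c", 1951:2000, rep(1.5, 50), dbh_cm = 2 * (75 + 2) / 10)
  expect_true(all(diff(compute_bai(sc)$bai) > 0))

  # widths that overrun DBH/2 truncate early years with a warning
  sx <- ring_series("x", 1991:2000, rep(2, 10), dbh_cm = 2)
  expect_warning(bx <- compute_bai(sx), "truncating")
  expect_lt(nrow(bx), 10)

  # missing rings are bridged for the radius accumulation
  sm <- ring_series("m", 1991:2000, c(1, 1, NA, 1, 1, 1, 1, NA, 1, 1),
                    dbh_cm = 3)
  expect_equal(nrow(compute_bai(sm)), 10)
})

test_that("DBH back-casting removes subsequent growth", {
  s <- ring_series("d", 1991:2000, rep(2.5, 10), dbh_cm = 30)
  # rings after 1995 total 5 * 2.5 mm = 12.5 mm of radius, 2.5 cm of diameter
  expect_equal(dbh_at_year(s, 1995), 30 - 2 * 12.5 / 10)
  expect_equal(dbh_at_year(s, 2000), 30)
  d <- vapply(1991:2000, dbh_at_year, numeric(1), series = s)
  expect_true(all(diff(d) >= 0))
  expect_error(dbh_at_year(s, 1980), "outside")
  s2 <- ring_series("d2", 1991:2000, rep(9, 10), dbh_cm = 10)
  expect_error(dbh_at_year(s2, 1991), "negative DBH")
})

test_that("Lloret indices are the stated ratios with the event year excluded", {
  g <- data.frame(year = 1990:2000,
                  value = c(2, 2, 2, 2, 1, 1.5, 1.5, 1.5, 1.5, 9, 9))
  li <- lloret_indices(g, 1994, window_m = 4)
  expect_equal(li$pre_dr, 2)
  expect_equal(li$dr, 1)
  expect_equal(li$post_dr, 1.5)
  expect_equal(li$resistance, 0.5)
  expect_equal(li$recovery, 1.5)
  expect_equal(li$resilience, 0.75)

  flat <- data.frame(year = 1990:2000, value = rep(3, 11))
  lf <- lloret_indices(flat, 1995)
  expect_equal(unlist(lf[c("resistance", "recovery", "resilience")]),
               c(resistance = 1, recovery = 1, resilience = 1))

  # multiplicative identity and scale invariance on random growth
  set.seed(7)
  for (i in 1:25) {
    v <- stats::runif(11, 0.2, 5)
    gi <- data.frame(year = 1990:2000, value = v)
    li <- lloret_indices(gi, 1995)
    expect_lt(abs(li$resilience - li$resistance * li$recovery), 1e-12)
    li2 <- lloret_indices(transform(gi, value = value * 13.7), 1995)
    expect_equal(li2$resistance, li$resistance, tolerance = 1e-12)
    expect_equal(li2$recovery, li$recovery, tolerance = 1e-12)
    expect_equal(li2$resilience, li$resilience, tolerance = 1e-12)
  }

  expect_error(lloret_indices(g, 1992), "insufficient")
  expect_error(lloret_indices(g, 1995, window_m = 9), "window_m")
})

test_that("SPEI covariates difference out as defined", {
  sp <- data.frame(year = 1990:2000, spei = rep(0, 11))
  sp$spei[sp$year == 1995] <- -2
  cv <- spei_covariates(sp, 1995, 4)
  expect_equal(cv$spei_i, -2)
  expect_equal(cv$speidiff_resist, -2)
  expect_equal(cv$speidiff_recov, 2)
  expect_equal(cv$speidiff_resil, 0)

  cst <- data.frame(year = 1990:2000, spei = rep(-0.7, 11))
  cvc <- spei_covariates(cst, 1995, 4)
  expect_equal(cvc$speidiff_resist, 0)
  expect_equal(cvc$speidiff_recov, 0)
  expect_equal(cvc$speidiff_resil, 0)

  set.seed(10)
  for (i in 1:20) {
    spr <- data.frame(year = 1990:2000, spei = stats::rnorm(11))
    cr <- spei_covariates(spr, 1995, 4)
    expect_equal(cr$speidiff_resil, cr$speidiff_resist + cr$speidiff_recov,
                 tolerance = 1e-12)
  }
  expect_error(spei_covariates(sp, 1999, 4), "missing SPEI")
})

test_that("record assembly counts trees and skips short post-event coverage", {
  bundle <- small_bundle()
  ds <- bundle$dataset
  truth <- bundle$ledger$sites
  events <- data.frame(site_id = truth$site_id, year = truth$event_year)
  grids <- lapply(stats::setNames(truth$site_id, truth$site_id), function(sid) {
    i <- match(sid, truth$site_id)
    g <- spei_grid(site_climate(ds, sid), "N")
    spei_series(g, truth$target_month[i], truth$scale[i])
  })
  rec <- build_records(ds, events, grids, window_m = 4,
                       metrics = c("TRW", "BAI"))
  # every tree spans event +/- 4 here, so one record per tree and metric
  expect_equal(nrow(rec), 2 * length(ds$series))
  expect_true(all(abs(rec$resilience - rec$resistance * rec$recovery) < 1e-12))
  expect_true(all(rec$delta_time >= 10))
  expect_true(all(rec$pre_dr > 0 & rec$dr > 0 & rec$post_dr > 0))

  # a tree dying 2 years after the event: skipped at m = 4, kept at m = 1
  sid <- truth$site_id[1]
  ev <- truth$event_year[1]
  tpl <- Filter(function(s) s$site_id == sid, ds$series)[[1]]
  early <- ring_series("EARLY01", tpl$years[tpl$years <= ev + 2],
                       tpl$trw[tpl$years <= ev + 2], site_id = sid,
                       species = tpl$species, genus = tpl$genus,
                       group = tpl$group, status = "now-dead",
                       dbh_cm = tpl$dbh_cm)
  ds2 <- ds
  ds2$series <- c(ds$series, list(EARLY01 = early))
  r4 <- build_records(ds2, events[1, ], grids[sid], window_m = 4,
                      metrics = "TRW")
  expect_false("EARLY01" %in% r4$tree_id)
  expect_true("EARLY01" %in% attr(r4, "skipped")$tree_id)
  r1 <- build_records(ds2, events[1, ], grids[sid], window_m = 1,
                      metrics = "TRW")
  expect_true("EARLY01" %in% r1$tree_id)
})

test_that("planted deficits surface in the dead/surviving index ratios", {
  cfg <- synthetic_config(n_sites = 4, trees_surviving = 50, trees_dead = 50,
                          seed = 53)
  bundle <- suppressWarnings(generate_dataset(cfg, tempfile()))
  ds <- bundle$dataset
  truth <- bundle$ledger$sites
  events <- data.frame(site_id = truth$site_id, year = truth$event_year)
  grids <- lapply(stats::setNames(truth$site_id, truth$site_id), function(sid) {
    i <- match(sid, truth$site_id)
    g <- spei_grid(site_climate(ds, sid), "N")
    spei_series(g, truth$target_month[i], truth$scale[i])
  })
  rec <- build_records(ds, events, grids, metrics = "TRW")
  # angiosperm site: resistance deficit 0.7 planted
  ang <- rec[rec$group == "angiosperm", ]
  ratio_rt <- mean(ang$resistance[ang$status == "now-dead"]) /
    mean(ang$resistance[ang$status == "surviving"])
  expect_equal(ratio_rt, 0.7, tolerance = 0.07)
  # gymnosperm site: recovery deficit 0.7 planted
  gym <- rec[rec$group == "gymnosperm", ]
  ratio_rc <- mean(gym$recovery[gym$status == "now-dead"]) /
    mean(gym$recovery[gym$status == "surviving"])
  expect_equal(ratio_rc, 0.7, tolerance = 0.07)
})

test_that("bootstrap trajectories are seeded, centred and tighten with n", {
  bundle <- small_bundle()
  ds <- bundle$dataset
  truth <- bundle$ledger$sites
  events <- data.frame(site_id = truth$site_id, year = truth$event_year)

  b1 <- growth_pattern_bootstrap(ds, events, n_boot = 200, seed = 9)
  b2 <- growth_pattern_bootstrap(ds, events, n_boot = 200, seed = 9)
  expect_identical(b1, b2)
  expect_true(all(b1$lo <= b1$mean & b1$mean <= b1$hi))
  expect_setequal(unique(b1$rel_year), -4:8)

  # flat pre-drought growth: pre-window log-ratios are exactly zero
  flat <- lapply(1:6, function(i) {
    ring_series(paste0("F", i), 1940:1990,
                c(rep(2, 26), seq(2, 3, length.out = 25)), site_id = "fs",
                group = "angiosperm", status = "surviving", dbh_cm = 20)
  })
  names(flat) <- vapply(flat, `[[`, "", "tree_id")
  dsf <- list(series = flat)
  bf <- growth_pattern_bootstrap(dsf, data.frame(site_id = "fs", year = 1960),
                                 n_boot = 50, seed = 1)
  expect_equal(bf$mean[bf$rel_year < 0], rep(0, 4))

  # quadrupling the trees shrinks the CI roughly like 1/sqrt(n)
  mk <- function(n, seed) {
    set.seed(seed)
    ser <- lapply(seq_len(n), function(i) {
      ring_series(paste0("R", i), 1940:1990,
                  exp(stats::rnorm(51, 0.5, 0.3)), site_id = "rs",
                  group = "gymnosperm", status = "surviving", dbh_cm = 25)
    })
    names(ser) <- vapply(ser, `[[`, "", "tree_id")
    list(series = ser)
  }
  w_small <- with(growth_pattern_bootstrap(mk(20, 3),
                                           data.frame(site_id = "rs", year = 1960),
                                           n_boot = 400, seed = 2), mean(hi - lo))
  w_big <- with(growth_pattern_bootstrap(mk(80, 3),
                                         data.frame(site_id = "rs", year = 1960),
                                         n_boot = 400, seed = 2), mean(hi - lo))
  expect_equal(w_big / w_small, 0.5, tolerance = 0.2)

  # small strata are skipped with a warning
  expect_warning(
    growth_pattern_bootstrap(mk(3, 4), data.frame(site_id = "rs", year = 1960),
                             n_boot = 10, seed = 1),
    "skipped")
})
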