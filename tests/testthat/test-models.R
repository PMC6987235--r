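# Soil PCA and the status-contrast mixed models.

test_that("soil PC1 is a dominant, nitrogen-positive fertility axis", {
  soil <- generate_soil_table(30, seed = 3)
  pc <- soil_fertility_pc1(soil)
  expect_gt(pc$variance_fraction, 0.2)  # one latent factor >> 1/10
  expect_gt(pc$loadings[["total_nitrogen"]], 0)
  expect_gt(pc$loadings[["organic_carbon"]], 0)
  expect_gt(pc$loadings[["awc"]], 0)
  expect_equal(sum(pc$loadings^2), 1)
  expect_gt(stats::cor(pc$scores, soil$total_nitrogen), 0)

  # eigen-decomposition oracle for the variance fraction
  lam <- eigen(stats::cor(soil[, -1]))$values
  expect_equal(pc$variance_fraction, lam[1] / sum(lam), tolerance = 1e-10)

  # flipping the sign of every input leaves the oriented scores' geometry
  soil2 <- soil
  soil2[, -1] <- -soil2[, -1]
  pc2 <- soil_fertility_pc1(soil2)
  expect_equal(abs(stats::cor(pc$scores, pc2$scores)), 1, tolerance = 1e-10)

  soil3 <- soil
  soil3$ph <- 6
  expect_warning(pc3 <- soil_fertility_pc1(soil3), "constant")
  expect_length(pc3$loadings, 9)
})

test_that("designs encode the collinearity rule, coding and standardisation", {
  rec <- simulate_resilience_records(n_sites = 20, trees_per_site = 10, seed = 2)
  des_rs <- build_design(rec, "resilience")
  expect_true("speidiff_resil" %in% des_rs$terms)
  des_rt <- build_design(rec, "resistance")
  expect_false(any(grepl("speidiff", des_rt$terms)))
  des_rc <- build_design(rec, "recovery")
  expect_false(any(grepl("speidiff", des_rc$terms)))

  expect_equal(levels(des_rs$data$status), c("now-dead", "surviving"))
  for (v in c("dbh_i", "spei_i", "delta_time", "aridity", "soil_pc1")) {
    expect_equal(stats::sd(des_rs$data[[v]]), 1, tolerance = 1e-12)
  }
  expect_equal(des_rs$data$y, log(rec$resilience))

  # an exactly duplicated covariate triggers the alias error; on_alias =
  # "drop" sheds a term instead
  rec2 <- rec
  rec2$aridity <- rec2$soil_pc1
  expect_error(build_design(rec2, "resistance"), "aliased")
  w <- testthat::capture_warnings(
    des_ok <- build_design(rec2, "resistance", on_alias = "drop"))
  expect_match(w, "aliased", all = FALSE)
  expect_lt(length(des_ok$terms), length(des_rt$terms))

  # constant covariates are dropped with their interactions
  rec3 <- rec
  rec3$aridity <- 1
  expect_warning(des3 <- build_design(rec3, "resistance"), "constant")
  expect_false("aridity" %in% des3$terms)
  expect_false("status:aridity" %in% des3$terms)
})

test_that("the mixed fit collapses to OLS without grouping structure", {
  set.seed(4)
  rec <- simulate_resilience_records(n_sites = 40, trees_per_site = 10,
                                     beta_status = -0.2, sd_site = 0,
                                     sd_species = 0, sd_genus = 0,
                                     sd_resid = 0.3, seed = 4)
  des <- build_design(rec, "resilience",
                      terms = c("status", "group", "dbh_i", "spei_i"))
  fit_mm <- suppressWarnings(fit_lmm(des))       # variances shrink to ~0
  fit_ols <- fit_lmm(des, random = FALSE)
  expect_equal(fit_mm$coef$estimate, fit_ols$coef$estimate, tolerance = 1e-4)
  expect_true(fit_mm$singular)
  expect_lte(fit_mm$r2[["r2m"]], fit_mm$r2[["r2c"]])
  expect_true(all(fit_mm$r2 >= 0 & fit_mm$r2 <= 1))
})

test_that("R2 components behave at the edges", {
  # planted random structure, no fixed signal: r2m ~ 0, r2c well above it
  rec <- simulate_resilience_records(n_sites = 60, trees_per_site = 10,
                                     beta_status = 0, sd_site = 0.4,
                                     sd_resid = 0.2, seed = 6)
  des <- build_design(rec, "resilience", terms = c("status", "dbh_i"))
  fit <- suppressWarnings(fit_lmm(des))
  expect_lt(fit$r2[["r2m"]], 0.05)
  expect_gt(fit$r2[["r2c"]], 0.4)
})

test_that("a planted status effect is recovered with its AIC signature", {
  # one well-powered replicate; the 50-replicate calibration claim lives in
  # the acceptance suite
  rec <- simulate_resilience_records(n_sites = 100, trees_per_site = 30,
                                     beta_status = -0.10, seed = 8801)
  des <- build_design(rec, "resilience")
  fit <- suppressWarnings(suppressMessages(fit_lmm(des)))
  b <- fit$coef$estimate[fit$coef$term == "statussurviving"]
  expect_lt(abs(b - (-0.10)), 0.05)  # ~3 SE at this design size
  expect_gt(fit$delta_aic_status, 2)
})

test_that("reduction lowers AIC, sheds noise first and respects marginality", {
  rec <- simulate_resilience_records(n_sites = 50, trees_per_site = 16,
                                     beta_status = -0.15, seed = 21)
  des <- build_design(rec, "resilience")
  red <- suppressWarnings(reduce_model(des))
  expect_lte(red$fit$aic_ml, red$full_aic)
  # every covariate is pure noise here: the planted status effect survives
  expect_true("status" %in% red$fit$terms)
  # marginality: any main effect present in an interaction is kept
  inter_parts <- unique(unlist(strsplit(grep(":", red$fit$terms, value = TRUE),
                                        ":")))
  expect_true(all(inter_parts %in% red$fit$terms))
  # the trail only ever drops droppable terms and lowers AIC stepwise
  if (nrow(red$trail) > 0) {
    expect_true(all(red$trail$aic_after < red$trail$aic_before))
  }
  # a model already minimal is returned unchanged
  des_min <- build_design(rec, "resilience", terms = "status")
  red_min <- suppressWarnings(reduce_model(des_min))
  expect_equal(red_min$fit$terms, "status")
})

test_that("adjusted means match the balanced-design closed form", {
  # perfectly balanced nesting: 2 genera x 2 species x 2 sites x 20 trees,
  # equal status split everywhere, so GLS fixed estimates equal stratum means
  mk_balanced <- function(beta = 0.2, seed = 31) {
    set.seed(seed)
    rows <- list()
    for (g in 1:2) for (sp in 1:2) for (st in 1:2) {
      site <- sprintf("g%ds%dt%d", g, sp, st)
      status <- rep(c("surviving", "now-dead"), each = 10)
      y <- 0.1 * g - 0.05 * sp + 0.02 * st +
        beta * (status == "surviving") + stats::rnorm(20, 0, 0.3)
      rows[[site]] <- data.frame(
        tree_id = paste0(site, "_", 1:20), site_id = site,
        species = sprintf("sp%d%d", g, sp), genus = paste0("gen", g),
        group = if (g == 1) "angiosperm" else "gymnosperm",
        status = status, metric = "TRW", window_m = 4,
        resilience = exp(y), resistance = exp(y), recovery = exp(y),
        spei_i = stats::rnorm(20), speidiff_resil = stats::rnorm(20),
        dbh_i = stats::rnorm(20), delta_time = stats::runif(20, 10, 40),
        aridity = stats::rnorm(20), soil_pc1 = stats::rnorm(20))
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  }
  rec <- mk_balanced()
  des <- build_design(rec, "resilience", terms = "status")
  fit <- suppressWarnings(suppressMessages(fit_lmm(des)))
  am <- adjusted_means(fit)
  # oracle: exponentiated stratum means of the log response
  strata <- tapply(des$data$y, des$data$status, mean)
  expect_equal(am$means$mean[am$means$status == "now-dead"],
               exp(strata[["now-dead"]]), tolerance = 1e-6)
  expect_equal(am$means$mean[am$means$status == "surviving"],
               exp(strata[["surviving"]]), tolerance = 1e-6)
  expect_equal(am$means$group, c("all", "all"))
  expect_equal(am$contrasts$diff_log,
               strata[["surviving"]] - strata[["now-dead"]],
               tolerance = 1e-6)
  expect_lt(am$contrasts$p, 0.05)
  # surviving trees were planted as more resilient
  expect_gt(am$means$mean[am$means$status == "surviving"],
            am$means$mean[am$means$status == "now-dead"])

  # with a status:group term the means split by taxonomic group
  des2 <- build_design(rec, "resilience",
                       terms = c("status", "group", "status:group"))
  fit2 <- suppressWarnings(suppressMessages(fit_lmm(des2)))
  am2 <- adjusted_means(fit2)
  expect_setequal(unique(am2$means$group), c("angiosperm", "gymnosperm"))
  expect_equal(nrow(am2$means), 4)
})
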