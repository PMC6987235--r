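# Soil-fertility PCA and the status-contrast linear mixed models: design
# construction with standardised predictors, REML fits with nested random
# intercepts (site within species within genus), Wald tables, ML-based AIC
# reduction, Nakagawa marginal/conditional R2, and back-transformed adjusted
# means with pairwise status contrasts.

#' First principal component of the soil table as a fertility axis
#'
#' Standardises the ten soil characteristics and extracts PC1, with the sign
#' oriented so the total-nitrogen loading is positive (fertile = high score).
#'
#' @param soil_table data frame with a `site` column plus numeric soil
#'   columns; constant columns are dropped with a warning.
#' @return list with `scores` (named by site), `loadings`,
#'   `variance_fraction` (share of total variance on PC1).
#' @export
soil_fertility_pc1 <- function(soil_table) {
  stopifnot(nrow(soil_table) >= 3)
  num <- soil_table[, setdiff(names(soil_table), "site"), drop = FALSE]
  if (anyNA(num)) stop("soil table contains missing values")
  sds <- vapply(num, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("dropping constant soil columns: ",
            paste(names(num)[sds == 0], collapse = ", "))
    num <- num[, sds > 0, drop = FALSE]
  }
  pca <- stats::prcomp(num, center = TRUE, scale. = TRUE)
  load1 <- pca$rotation[, 1]
  scores <- pca$x[, 1]
  orient_col <- if ("total_nitrogen" %in% names(load1)) "total_nitrogen" else names(load1)[1]
  if (load1[orient_col] < 0) {
    load1 <- -load1
    scores <- -scores
  }
  names(scores) <- soil_table$site
  list(scores = scores, loadings = load1,
       variance_fraction = pca$sdev[1]^2 / sum(pca$sdev^2))
}

# Fixed-effect term list for one response: status, group, continuous
# covariates, and every status interaction. The resilience model carries both
# spei_i and speidiff_resil; resistance and recovery carry spei_i only
# (collinearity between spei_i and their own diffs).
response_terms <- function(response) {
  cont <- c("dbh_i", "spei_i",
            if (response == "resilience") "speidiff_resil",
            "delta_time", "aridity", "soil_pc1")
  others <- c("group", cont)
  c("status", others, paste0("status:", others))
}

#' Build a mixed-model design from resilience records
#'
#' Log-transforms the chosen index, codes status with now-dead as the
#' reference level, standardises continuous predictors to zero mean and unit
#' variance (so reported slopes are standardised coefficients; the intercept
#' stays on the response scale), and verifies the fixed design is full rank.
#'
#' @param records data frame from [build_records()] (or a compatible
#'   simulation).
#' @param response `"resilience"`, `"resistance"` or `"recovery"`.
#' @param metric `"TRW"` or `"BAI"`.
#' @param terms fixed-effect terms; default per the response's collinearity
#'   rule. Terms whose covariate is missing or constant in the data are
#'   dropped with a warning.
#' @param on_alias what to do when the fixed design is rank deficient:
#'   `"error"` (default) lists the aliased columns; `"drop"` removes aliased
#'   interaction (then main-effect) terms one at a time with warnings, which
#'   keeps small-site runs viable (site-level covariates plus all their
#'   status interactions can exceed the number of event sites).
#' @return list of class `lmm_design` with `data` (model frame), `terms`,
#'   `response`, `metric`.
#' @export
build_design <- function(records,
                         response = c("resilience", "resistance", "recovery"),
                         metric = "TRW", terms = NULL,
                         on_alias = c("error", "drop")) {
  response <- match.arg(response)
  on_alias <- match.arg(on_alias)
  d <- records[records$metric == metric, , drop = FALSE]
  if (nrow(d) == 0) stop("no records for metric ", metric)
  if (is.null(terms)) terms <- response_terms(response)

  df <- data.frame(
    y = log(d[[response]]),
    status = factor(d$status, levels = c("now-dead", "surviving")),
    group = factor(d$group, levels = c("angiosperm", "gymnosperm")),
    genus = factor(d$genus), species = factor(d$species),
    site = factor(d$site_id))
  base <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  drop_terms <- character()
  for (v in setdiff(base, c("status", "group"))) {
    x <- d[[v]]
    if (is.null(x) || all(is.na(x)) || stats::sd(x, na.rm = TRUE) == 0) {
      warning("dropping term ", v, ": missing or constant in the records")
      drop_terms <- c(drop_terms, v)
    } else {
      df[[v]] <- as.numeric(scale(x))
    }
  }
  if ("group" %in% base && length(unique(df$group)) < 2) {
    warning("dropping term group: single taxonomic group in the records")
    drop_terms <- c(drop_terms, "group")
  }
  if (length(drop_terms)) {
    keep <- !vapply(strsplit(terms, ":", fixed = TRUE),
                    function(p) any(p %in% drop_terms), logical(1))
    terms <- terms[keep]
  }
  repeat {
    X <- stats::model.matrix(stats::reformulate(terms), df)
    qx <- qr(X)
    if (qx$rank == ncol(X)) break
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    if (on_alias == "error") {
      stop("rank-deficient design; aliased columns: ",
           paste(aliased, collapse = ", "))
    }
    asg <- attr(X, "assign")
    labs <- attr(stats::terms(stats::reformulate(terms)), "term.labels")
    alias_terms <- unique(labs[asg[match(aliased, colnames(X))]])
    # shed interactions before main effects, last listed first
    inter <- grepl(":", alias_terms, fixed = TRUE)
    victim <- rev(c(alias_terms[!inter], alias_terms[inter]))[1]
    warning("dropping aliased term ", victim)
    terms <- setdiff(terms, victim)
    if (length(terms) == 0) stop("design fully aliased")
  }
  structure(list(data = df, terms = terms, response = response,
                 metric = metric),
            class = "lmm_design")
}

lmm_formula <- function(terms, random = TRUE) {
  rhs <- paste(terms, collapse = " + ")
  if (random) rhs <- paste(rhs, "+ (1 | genus) + (1 | genus:species) + (1 | genus:species:site)")
  stats::as.formula(paste("y ~", rhs))
}

#' Nakagawa marginal and conditional R2 of a Gaussian lmer fit
#'
#' `R2m = var_fixed / (var_fixed + var_random + var_resid)`; `R2c` adds the
#' random-intercept variance to the numerator.
#'
#' @param model a fitted `lmerMod`.
#' @return named numeric `c(r2m, r2c)`.
#' @export
r2_marginal_conditional <- function(model) {
  var_f <- stats::var(as.vector(stats::model.matrix(model) %*% lme4::fixef(model)))
  vc <- lme4::VarCorr(model)
  var_r <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
  var_e <- stats::sigma(model)^2
  tot <- var_f + var_r + var_e
  c(r2m = var_f / tot, r2c = (var_f + var_r) / tot)
}

#' Fit the status-contrast linear mixed model
#'
#' REML fit with random intercepts for site nested in species nested in
#' genus. The coefficient table reports standardised estimates with Wald 95%
#' CIs and normal-approximation p-values; AIC is taken from a maximum-
#' likelihood refit so fixed structures can be compared; `delta_aic_status`
#' is AIC(model without status terms) - AIC(model), positive when status
#' improves the model.
#'
#' @param design an `lmm_design` from [build_design()].
#' @param random include the nested random intercepts (TRUE; FALSE gives the
#'   OLS benchmark used in tests).
#' @return list of class `lmm_fit`: `model`, `coef` (table), `aic_ml`, `r2`,
#'   `varcomp`, `delta_aic_status`, `terms`, `singular`.
#' @export
fit_lmm <- function(design, random = TRUE) {
  df <- design$data
  if (random) {
    model <- lme4::lmer(lmm_formula(design$terms), data = df, REML = TRUE)
    if (lme4::isSingular(model)) {
      warning("singular random-effects fit (some variance components at zero)")
    }
    sm <- summary(model)$coefficients
    ml <- stats::update(model, REML = FALSE)
    aic_ml <- stats::AIC(ml)
    r2 <- r2_marginal_conditional(model)
    vc <- as.data.frame(lme4::VarCorr(model))
  } else {
    model <- stats::lm(stats::reformulate(design$terms, response = "y"), data = df)
    sm <- summary(model)$coefficients[, 1:3, drop = FALSE]
    aic_ml <- stats::AIC(model)
    r2 <- c(r2m = summary(model)$r.squared, r2c = summary(model)$r.squared)
    vc <- NULL
  }
  coef_tab <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                         statistic = sm[, 3],
                         p = 2 * stats::pnorm(-abs(sm[, 3])),
                         ci_lo = sm[, 1] - 1.96 * sm[, 2],
                         ci_hi = sm[, 1] + 1.96 * sm[, 2],
                         row.names = NULL)
  delta_aic <- NA_real_
  status_terms <- grepl("(^|:)status($|:)", design$terms)
  if (random && any(status_terms)) {
    no_status <- lme4::lmer(lmm_formula(design$terms[!status_terms]),
                            data = df, REML = FALSE)
    delta_aic <- stats::AIC(no_status) - aic_ml
  }
  structure(list(model = model, coef = coef_tab, aic_ml = aic_ml, r2 = r2,
                 varcomp = vc, delta_aic_status = delta_aic,
                 terms = design$terms, design = design,
                 singular = random && lme4::isSingular(model)),
            class = "lmm_fit")
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, digits = 3, ...) {
  cat("<lmm_fit> log", x$design$response, "(", x$design$metric, ") ~",
      paste(x$terms, collapse = " + "), "\n")
  print(format(x$coef, digits = digits), row.names = FALSE)
  cat(sprintf("AIC(ML) %.1f | R2m %.3f R2c %.3f | dAIC(status) %.1f\n",
              x$aic_ml, x$r2[["r2m"]], x$r2[["r2c"]], x$delta_aic_status))
  invisible(x)
}

# p-value of each model term in a fit (1-df terms map to single columns of
# the design matrix; factor terms take their minimum coefficient p).
term_pvalues <- function(fit) {
  X <- stats::model.matrix(stats::reformulate(fit$terms), fit$design$data)
  asg <- attr(X, "assign")
  labs <- attr(stats::terms(stats::reformulate(fit$terms)), "term.labels")
  p <- numeric(length(labs))
  for (i in seq_along(labs)) {
    cols <- colnames(X)[asg == i]
    p[i] <- min(fit$coef$p[fit$coef$term %in% cols])
  }
  stats::setNames(p, labs)
}

#' Backward AIC reduction of the full mixed model
#'
#' Iteratively removes the least-significant droppable term (main effects are
#' protected while any interaction containing them remains) whenever the
#' removal lowers the maximum-likelihood AIC; stops when no droppable term
#' does. Mirrors "removing the least significant terms until a minimum
#' adequate model (in terms of AIC)".
#'
#' @param design an `lmm_design`.
#' @return list with `fit` (the reduced `lmm_fit`, REML), `trail` (data frame
#'   of dropped terms and AIC steps), `full_aic`.
#' @export
reduce_model <- function(design) {
  cur <- design
  fit <- fit_lmm(cur)
  full_aic <- fit$aic_ml
  trail <- list()
  repeat {
    labs <- cur$terms
    inter <- grepl(":", labs, fixed = TRUE)
    in_inter <- unique(unlist(strsplit(labs[inter], ":", fixed = TRUE)))
    droppable <- labs[inter | !(labs %in% in_inter)]
    if (length(droppable) == 0) break
    p <- term_pvalues(fit)
    cand <- droppable[order(p[droppable], decreasing = TRUE)]
    improved <- FALSE
    for (tm in cand) {
      red <- cur
      red$terms <- setdiff(cur$terms, tm)
      if (length(red$terms) == 0) break
      red_fit <- fit_lmm(red)
      if (red_fit$aic_ml < fit$aic_ml) {
        trail[[length(trail) + 1]] <- data.frame(
          dropped = tm, p = unname(p[tm]),
          aic_before = fit$aic_ml, aic_after = red_fit$aic_ml)
        cur <- red; fit <- red_fit; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(fit = fit,
       trail = if (length(trail)) do.call(rbind, c(trail, make.row.names = FALSE))
               else data.frame(dropped = character(), p = numeric(),
                               aic_before = numeric(), aic_after = numeric()),
       full_aic = full_aic)
}

#' Back-transformed adjusted (least-square) means with status contrasts
#'
#' Predicts the fixed part of the model on a reference grid (factor levels
#' crossed, standardised covariates at zero, equal weights over non-focal
#' factor levels), back-transforms to the ratio scale by exponentiation, and
#' tests pairwise now-dead vs surviving contrasts. Means are split by
#' taxonomic group only when a status:group term is in the model.
#'
#' @param fit an `lmm_fit` with random effects.
#' @param split_by_group force/suppress the group split; default `NULL`
#'   follows the status:group rule.
#' @return list with `means` (data frame: factor levels, `mean`, `lo`, `hi`
#'   on the ratio scale) and `contrasts` (surviving - now-dead on the log
#'   scale with z and p).
#' @export
adjusted_means <- function(fit, split_by_group = NULL) {
  terms <- fit$terms
  df <- fit$design$data
  if (!"status" %in% unlist(strsplit(terms, ":"))) {
    stop("status is not in the model")
  }
  has_group <- "group" %in% unlist(strsplit(terms, ":"))
  if (is.null(split_by_group)) {
    split_by_group <- any(grepl("status:group|group:status", terms))
  }
  fac <- list(status = levels(df$status))
  if (has_group) fac$group <- levels(droplevels(df$group))
  grid <- expand.grid(fac, stringsAsFactors = FALSE)
  cont <- setdiff(unique(unlist(strsplit(terms, ":"))), c("status", "group"))
  for (v in cont) grid[[v]] <- 0
  grid$status <- factor(grid$status, levels = levels(df$status))
  if (has_group) grid$group <- factor(grid$group, levels = levels(df$group))
  X <- stats::model.matrix(stats::reformulate(terms), grid)

  beta <- lme4::fixef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  cells <- if (split_by_group && has_group) c("status", "group") else "status"
  # average grid rows (equal weights) within each cell
  key <- do.call(paste, grid[cells])
  L <- t(sapply(unique(key), function(k) colMeans(X[key == k, , drop = FALSE])))
  est <- as.vector(L %*% beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  lab <- unique(grid[cells])
  means <- cbind(lab[match(unique(key), do.call(paste, lab)), , drop = FALSE],
                 data.frame(mean = exp(est), lo = exp(est - 1.96 * se),
                            hi = exp(est + 1.96 * se)))
  if (!"group" %in% names(means)) means$group <- "all"
  means <- means[, c("status", "group", "mean", "lo", "hi")]
  rownames(means) <- NULL

  # pairwise surviving - now-dead within each group cell
  ctr <- list()
  gcells <- if (split_by_group && has_group) levels(droplevels(df$group)) else NA
  for (g in gcells) {
    in_cell <- if (is.na(g)) rep(TRUE, nrow(grid)) else grid$group == g
    sel_s <- grid$status == "surviving" & in_cell
    sel_d <- grid$status == "now-dead" & in_cell
    l <- colMeans(X[sel_s, , drop = FALSE]) - colMeans(X[sel_d, , drop = FALSE])
    d <- sum(l * beta); s <- sqrt(as.numeric(t(l) %*% V %*% l))
    ctr[[length(ctr) + 1]] <- data.frame(
      group = if (is.na(g)) "all" else g, diff_log = d, se = s, z = d / s,
      p = 2 * stats::pnorm(-abs(d / s)))
  }
  list(means = means, contrasts = do.call(rbind, c(ctr, make.row.names = FALSE)))
}

#' Simulate resilience records straight from the mixed-model process
#'
#' Generates a record table whose log index follows the status-contrast LMM
#' data-generating process directly (nested genus/species/site random
#' intercepts plus a planted status effect), bypassing the ring pipeline.
#' Used for parameter-recovery and type-I-error checks of the models module.
#'
#' @param n_sites number of sites.
#' @param trees_per_site trees per site (half surviving, half now-dead).
#' @param beta_status planted effect of surviving status on the log index
#'   (0 gives the null process).
#' @param sd_site,sd_species,sd_genus random-intercept standard deviations.
#' @param sd_resid residual standard deviation.
#' @param n_species,n_genus numbers of species and genera the sites nest in.
#' @param seed RNG seed.
#' @return data frame compatible with [build_design()] (`metric = "TRW"`,
#'   all three indices set to the simulated response).
#' @export
simulate_resilience_records <- function(n_sites = 100, trees_per_site = 30,
                                        beta_status = -0.10, sd_site = 0.10,
                                        sd_species = 0.05, sd_genus = 0.05,
                                        sd_resid = 0.30, n_species = 12,
                                        n_genus = 5, seed = 1L) {
  set.seed(seed)
  species_of_site <- sample(n_species, n_sites, replace = TRUE)
  genus_of_species <- sample(n_genus, n_species, replace = TRUE)
  u_g <- stats::rnorm(n_genus, 0, sd_genus)
  u_sp <- stats::rnorm(n_species, 0, sd_species)
  u_s <- stats::rnorm(n_sites, 0, sd_site)
  rows <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    n <- trees_per_site
    status <- rep(c("surviving", "now-dead"), length.out = n)
    sp <- species_of_site[s]; gn <- genus_of_species[sp]
    y <- u_g[gn] + u_sp[sp] + u_s[s] +
      beta_status * (status == "surviving") + stats::rnorm(n, 0, sd_resid)
    rows[[s]] <- data.frame(
      tree_id = sprintf("S%03dT%02d", s, seq_len(n)),
      site_id = sprintf("site%03d", s), species = sprintf("sp%02d", sp),
      genus = sprintf("gen%d", gn),
      group = if (gn %% 2) "gymnosperm" else "angiosperm",
      status = status, metric = "TRW", window_m = 4,
      resilience = exp(y), resistance = exp(y), recovery = exp(y),
      spei_i = stats::rnorm(n, -2, 0.3), speidiff_resil = stats::rnorm(n),
      dbh_i = stats::rnorm(n, 30, 5), delta_time = stats::runif(n, 10, 40),
      aridity = stats::rnorm(n, 0.9, 0.2), soil_pc1 = stats::rnorm(n))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
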