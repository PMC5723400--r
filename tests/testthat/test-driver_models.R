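# small fixed covariate table builder for deterministic tests
toy_covariates <- function(n = 16, seed = 1) {
  set.seed(seed)
  data.frame(
    site_id = sprintf("S%02d", 1:n), species = "sp",
    latitude = seq(-22, -15, length.out = n),
    sst = 27 + 0.6 * seq(-4, 4, length.out = n) + rnorm(n, 0, 0.2),
    cyclone_pr = runif(n, 0.05, 0.95),
    dugong = factor(rep(c("absent", "present"), length.out = n)),
    kd490 = runif(n, 0.02, 0.15),
    dist_shore = runif(n, 5, 75),
    R = runif(n), stringsAsFactors = FALSE)
}

test_that("transforms are applied once and recorded", {
  d <- apply_transforms(toy_covariates(), driver_config())
  expect_equal(d$cyclone_pr_t, sqrt(d$cyclone_pr))
  expect_equal(d$sst_t, log(d$sst))
  expect_equal(d$kd490_t, sqrt(d$kd490))
  expect_equal(d$dist_shore_t, sqrt(d$dist_shore))
  expect_equal(d$latitude_t, d$latitude)  # identity by default
  expect_named(attr(d, "transforms_applied"),
               c("cyclone_pr", "sst", "kd490", "dist_shore"))
})

test_that("collinearity prefilter drops later-priority predictors above 0.8", {
  d <- toy_covariates()
  d <- apply_transforms(d, driver_config())
  pf <- prefilter_predictors(d, driver_config())
  # SST is built to track latitude almost perfectly: latitude must go
  expect_false("latitude" %in% pf$retained)
  expect_true("sst" %in% pf$retained)
  expect_true("latitude" %in% pf$drops$dropped)
  r_drop <- pf$drops$r[pf$drops$dropped == "latitude"]
  expect_gt(abs(r_drop), 0.8)
  # mutually weakly correlated predictors are all retained
  expect_true(all(c("cyclone_pr", "dugong", "kd490") %in% pf$retained))
})

test_that("constant predictors are dropped with a warning", {
  d <- toy_covariates()
  d$kd490 <- 0.05
  d <- apply_transforms(d, driver_config())
  expect_warning(pf <- prefilter_predictors(d, driver_config()),
                 "constant")
  expect_false("kd490" %in% pf$retained)
})

test_that("candidate enumeration obeys the pairwise 0.28 rule and counts match the power-set oracle", {
  # three continuous predictors, constructed orthogonal: 1 null + 3 singles
  # + 3 pairs = 7 specs
  set.seed(21)
  n <- 16
  # orthonormal columns orthogonal to the constant: exactly zero pairwise r
  base <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  d <- data.frame(site_id = 1:n, species = "sp",
                  cyclone_pr = (base[, 1] - min(base[, 1]) + 0.01),
                  kd490 = (base[, 2] - min(base[, 2]) + 0.01),
                  dist_shore = (base[, 3] - min(base[, 3]) + 0.01),
                  R = runif(n))
  cfg <- driver_config(predictors = c("cyclone_pr", "kd490", "dist_shore"),
                       transforms = c(cyclone_pr = "identity",
                                      kd490 = "identity",
                                      dist_shore = "identity"),
                       labels = c(cyclone_pr = "cyclone_pr",
                                  kd490 = "kd490",
                                  dist_shore = "dist_shore"),
                       factors = character(0),
                       include_interactions = FALSE)
  dt <- apply_transforms(d, cfg)
  # force exact orthogonality on the transformed columns
  dt$cyclone_pr_t <- base[, 1]; dt$kd490_t <- base[, 2]
  dt$dist_shore_t <- base[, 3]
  specs <- build_candidate_models(c("cyclone_pr", "kd490", "dist_shore"),
                                  dt, cfg)
  expect_length(specs, 7L)
  sizes <- vapply(specs, function(s) length(s$predictors), integer(1))
  expect_equal(sort(sizes), c(0L, 1L, 1L, 1L, 2L, 2L, 2L))
  # oracle: power set of 3 predictors truncated at size 2
  expect_equal(length(specs), 1L + 3L + choose(3, 2))

  # a correlated pair is excluded while its singles remain
  dt$kd490_t <- dt$cyclone_pr_t * 0.8 + base[, 2] * 0.2
  specs2 <- build_candidate_models(c("cyclone_pr", "kd490", "dist_shore"),
                                   dt, cfg)
  labs <- vapply(specs2, `[[`, "", "label")
  expect_false("cyclone_pr+kd490" %in% labs)
  expect_true(all(c("cyclone_pr", "kd490") %in% labs))
})

test_that("factor/continuous pairs gain a smooth-by-factor spec when enabled", {
  d <- apply_transforms(toy_covariates(), driver_config())
  cfg <- driver_config(predictors = c("sst", "dugong"))
  specs <- build_candidate_models(c("sst", "dugong"), d, cfg)
  labs <- vapply(specs, `[[`, "", "label")
  expect_true("SST.log+dugong" %in% labs)
  expect_true("dugong+SST.log.by.dugong" %in% labs)
  inter <- specs[[which(labs == "dugong+SST.log.by.dugong")]]
  kinds <- vapply(inter$terms, `[[`, "", "kind")
  expect_setequal(kinds, c("factor", "smooth_by_factor"))
  expect_setequal(inter$predictors, c("sst", "dugong"))
})

test_that("the null model has r2 = 0 and a noiseless linear signal is fully explained", {
  d <- apply_transforms(toy_covariates(), driver_config())
  cfg <- driver_config()
  null_spec <- build_candidate_models("cyclone_pr", d, cfg)[[1]]
  f0 <- fit_additive_model(d, null_spec, cfg)
  expect_equal(f0$r2, 0)
  # exact linear response in the transformed predictor, zero noise
  d$R <- 0.2 + 0.5 * d$cyclone_pr_t
  one <- build_candidate_models("cyclone_pr", d, cfg)[[2]]
  # a perfect fit trips step-failure/perfect-fit warnings; only r2 matters
  f1 <- suppressWarnings(fit_additive_model(d, one, cfg))
  ls_r2 <- suppressWarnings(
    summary(lm(R ~ cyclone_pr_t, d))$r.squared)  # closed-form oracle
  expect_gte(f1$r2, 0.999)
  expect_gte(ls_r2, 0.999999)
})

test_that("fits refuse sample sizes too small for the basis", {
  d <- apply_transforms(toy_covariates(), driver_config())[1:5, ]
  cfg <- driver_config()
  one <- build_candidate_models("cyclone_pr", d, cfg)[[2]]
  expect_error(fit_additive_model(d, one, cfg), "too small")
})

test_that("AICc follows its defining formula and converges to AIC", {
  expect_equal(aicc(-10, 3, 16), 20 + 6 + 2 * 3 * 4 / 12)
  expect_equal(aicc(-10, 3, 4), Inf)  # n <= k + 1
  expect_lt(abs(aicc(-100, 3, 1e6) - (200 + 6)), 1e-4)
})

test_that("model ranking yields normalized weights, zero minimum delta, and parsimony", {
  d <- apply_transforms(toy_covariates(seed = 4), driver_config())
  d$R <- 0.6 - 1.5 * (d$cyclone_pr_t - 0.55)^2 + rnorm(16, 0, 0.03)
  cfg <- driver_config()
  pf <- prefilter_predictors(d, cfg)
  specs <- build_candidate_models(pf$retained, d, cfg)
  fits <- lapply(specs, fit_additive_model, data = d, config = cfg)
  tab <- rank_models(fits)
  expect_equal(sum(tab$wi), 1, tolerance = 1e-9)
  expect_equal(tab$delta_AICc[1], 0)
  expect_true(!is.unsorted(tab$AICc))
  expect_true(all(diff(tab$wi) <= 1e-12))  # weights fall with AICc
  # parsimonious model: fewest predictors among the delta <= 2 candidates
  cand <- tab[tab$candidate, ]
  expect_equal(attr(tab, "parsimonious"),
               cand$label[order(cand$n_predictors, cand$AICc)][1])
})

test_that("delta AICc is invariant to shifting all log-likelihoods", {
  mk_fit <- function(label, ll, k, n, preds) {
    structure(list(spec = structure(list(predictors = preds, terms = list(),
                                         label = label),
                                    class = "model_spec"),
                   label = label, n = n, k = k, logLik = ll,
                   AICc = aicc(ll, k, n), r2 = 0.5),
              class = "model_fit")
  }
  f1 <- list(mk_fit("a", -5, 2, 16, "x"), mk_fit("b", -7, 3, 16, "y"))
  f2 <- list(mk_fit("a", -5 + 13, 2, 16, "x"),
             mk_fit("b", -7 + 13, 3, 16, "y"))
  t1 <- rank_models(f1); t2 <- rank_models(f2)
  expect_equal(t1$delta_AICc, t2$delta_AICc)
  expect_equal(t1$wi, t2$wi)
  # two equal-AICc models share the non-distant weight symmetrically
  f3 <- list(mk_fit("a", -5, 2, 16, "x"), mk_fit("b", -5, 2, 16, "y"),
             mk_fit("c", -25, 2, 16, "z"))
  t3 <- rank_models(f3)
  expect_equal(t3$wi[1], t3$wi[2])
  expect_equal(t3$wi[1], (1 - t3$wi[3]) / 2)
})

test_that("variable importance sums weights over models containing each predictor", {
  tab <- data.frame(wi = c(0.6, 0.3, 0.1))
  tab$predictors <- list(c("a"), c("a", "b"), character(0))
  imp <- variable_importance(tab)
  expect_equal(imp$importance[imp$predictor == "a"], 0.9)
  expect_equal(imp$importance[imp$predictor == "b"], 0.3)
  imp2 <- variable_importance(tab, predictors = c("a", "b", "c"))
  expect_equal(imp2$importance[imp2$predictor == "c"], 0)  # in no model
})

test_that("importance arithmetic on the reference table reproduces its published entries", {
  tab <- seagrass_model_table()
  hu <- tab[tab$species == "Halodule uninervis", ]
  ho <- tab[tab$species == "Halophila ovalis", ]
  imp_hu <- variable_importance(hu)
  imp_ho <- variable_importance(ho)
  get <- function(imp, p) imp$importance[imp$predictor == p]
  expect_equal(get(imp_hu, "dugong"), 0.370)
  expect_equal(get(imp_hu, "cyclone_pr"), 0.572)
  expect_equal(get(imp_ho, "dugong"), 0.584)
  expect_equal(get(imp_ho, "sst"), 0.395)
  expect_equal(get(imp_ho, "kd490"), 0.130)
  expect_equal(get(imp_ho, "dist_shore"), 0.027)
})

test_that("a single varying predictor leaves only its own models", {
  d <- toy_covariates()
  d$kd490 <- 0.05; d$dist_shore <- 30; d$sst <- 27
  d$dugong <- factor(rep("absent", 16))
  d$latitude <- -18
  cfg <- driver_config()
  d <- apply_transforms(d, cfg)
  suppressWarnings(pf <- prefilter_predictors(d, cfg))
  expect_equal(pf$retained, "cyclone_pr")
  specs <- build_candidate_models(pf$retained, d, cfg)
  labs <- vapply(specs, `[[`, "", "label")
  expect_setequal(labs, c("null", "cyclone.sqrt"))
})
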