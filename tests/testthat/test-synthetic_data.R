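test_that("identical seeds reproduce identical outputs", {
  a <- simulate_clonal_population(6, n_samples = 20, seed = 99)
  b <- simulate_clonal_population(6, n_samples = 20, seed = 99)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth$sample_genet, b$truth$sample_genet)
  d1 <- simulate_driver_dataset(seed = 99)
  d2 <- simulate_driver_dataset(seed = 99)
  expect_identical(d1$covariates, d2$covariates)
  sites <- data.frame(site_id = "A", lat = -18, lon = 116)
  s1 <- simulate_storm_history(storm_scenario(), 3, sites, seed = 99)
  s2 <- simulate_storm_history(storm_scenario(), 3, sites, seed = 99)
  expect_identical(s1$series, s2$series)
})

test_that("sampled points respect spacing, plot bounds, and genet truth", {
  sim <- simulate_clonal_population(5, n_samples = 40, seed = 12)
  xy <- sim$truth$sample_xy
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  expect_gte(min(d), 2)
  expect_true(all(sqrt(rowSums(xy^2)) <= 25 + 1e-9))
  expect_length(sim$truth$sample_genet, 40L)
  expect_true(all(sim$truth$sample_genet %in% 1:5))
  # every sampled genet's true genotype is recorded
  expect_length(sim$truth$genet_genotypes, 5L)
})

test_that("infeasible packings fail with an explicit constraint error", {
  expect_error(
    simulate_clonal_population(3, n_samples = 50, min_spacing = 40,
                               seed = 1, max_tries = 2000),
    "infeasible packing")
})

test_that("a single genet yields a monoclonal site (R = 0)", {
  sim <- simulate_clonal_population(1, n_samples = 30, seed = 5)
  r <- clonal_richness(identify_mlgs(sim$genotypes))
  expect_equal(r$G, 1L)
  expect_equal(r$R, 0)
})

test_that("missing-rate injection hits the expected fraction of calls", {
  sim <- simulate_clonal_population(10, n_samples = 50,
                                    missing_rate = 0.1, seed = 31)
  frac <- mean(is.na(sim$genotypes$allele1))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / (50 * 7)))
})

test_that("storm histories: zero rate means zero exposure", {
  sites <- data.frame(site_id = "A", lat = -18, lon = 116)
  h <- simulate_storm_history(storm_scenario(storms_per_year = 0), 5,
                              sites, seed = 77)
  ev <- exposure_events(h$series$A, wave_model = default_wave_model(),
                        years = h$years)
  expect_true(all(ev$events == 0L))
  expect_equal(annual_exposure_probability(ev)$pr_exposed, 0)
})

test_that("a site nearer the storm corridor is exposed at least as often", {
  # two clustered sites pull the track-genesis centroid toward themselves,
  # leaving "far" roughly twice as distant from the storm corridor
  sites <- data.frame(site_id = c("near", "near2", "far"),
                      lat = c(-18, -18.2, -28), lon = c(116, 116.2, 128))
  sc <- storm_scenario(storms_per_year = 3, vmax = 60, rmw = 40)
  h <- simulate_storm_history(sc, 60, sites, seed = 41)
  lam <- vapply(c("near", "far"), function(s) {
    suppressMessages(annual_exposure_probability(
      exposure_events(h$series[[s]], wave_model = default_wave_model(),
                      years = h$years))$lambda)
  }, numeric(1))
  expect_gte(lam[["near"]], lam[["far"]])
  expect_gt(lam[["near"]], 0)
})

test_that("driver datasets carry the designed collinearity and stored truth", {
  d <- simulate_driver_dataset(seed = 13)
  cov <- d$covariates
  expect_equal(nrow(cov), 16L)
  expect_gte(abs(cor(cov$latitude, cov$sst)), 0.95)
  expect_true(all(cov$R >= 0 & cov$R <= 1))
  expect_s3_class(d$truth$scenario, "driver_scenario")
  expect_length(d$truth$mu, 16L)
  # correlated dist_shore knob induces the requested association
  d2 <- simulate_driver_dataset(
    driver_scenario(dist_shore_cyclone_r = 0.95), seed = 13)
  expect_gt(cor(d2$covariates$dist_shore, d2$covariates$cyclone_pr), 0.8)
})

test_that("prefilter drops dist_shore when it tracks cyclone probability", {
  set.seed(55)
  dropped <- logical(20)
  for (i in 1:20) {
    d <- simulate_driver_dataset(
      driver_scenario(dist_shore_cyclone_r = 0.95), seed = 5500 + i)
    dt <- apply_transforms(d$covariates, driver_config())
    pf <- prefilter_predictors(dt, driver_config())
    r <- cor(dt$dist_shore_t, dt$cyclone_pr_t)
    dropped[i] <- !("dist_shore" %in% pf$retained)
    if (abs(r) > 0.85) expect_true(dropped[i])
  }
  expect_gt(mean(dropped), 0.5)
})

test_that("a noiseless cyclone-only response is recovered as the top model", {
  d <- simulate_driver_dataset(driver_scenario(noise_sd = 0), seed = 303)
  res <- suppressWarnings(run_driver_analysis(d$covariates))[[1]]
  expect_equal(res$model_table$label[1], "cyclone.sqrt")
  expect_equal(res$importance$predictor[1], "cyclone_pr")
  expect_gte(res$model_table$r2[1], 0.99)
})

test_that("the end-to-end chain runs from genotypes to driver selection", {
  # populations -> richness at a handful of sites
  rich <- do.call(rbind, lapply(1:6, function(i) {
    sim <- simulate_clonal_population(sample(2:12, 1), n_samples = 20,
                                      site_id = sprintf("S%02d", i),
                                      seed = 900 + i)
    clonal_richness(identify_mlgs(sim$genotypes))
  }))
  expect_true(all(rich$R >= 0 & rich$R <= 1))
  # storms -> exposure at one site
  sites <- data.frame(site_id = "S01", lat = -18, lon = 116)
  h <- simulate_storm_history(storm_scenario(), 10, sites, seed = 906)
  rec <- suppressMessages(annual_exposure_probability(
    exposure_events(h$series$S01, wave_model = default_wave_model(),
                    years = h$years)))
  expect_true(rec$pr_exposed >= 0 && rec$pr_exposed < 1)
  # covariates -> selection
  d <- simulate_driver_dataset(seed = 907)
  res <- suppressWarnings(run_driver_analysis(d$covariates))[[1]]
  expect_s3_class(res$model_table, "model_table")
  expect_equal(sum(res$model_table$wi), 1, tolerance = 1e-9)
})
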