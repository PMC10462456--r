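test_that("simulation is deterministic given the seed", {
  cfg <- survey_config(n_samples = 20, seed = 101)
  s1 <- simulate_survey(cfg)
  s2 <- simulate_survey(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth$rel_abundance, s2$truth$rel_abundance)
  s3 <- simulate_survey(survey_config(n_samples = 20, seed = 102))
  expect_false(identical(s1$table$strain_id, s3$table$strain_id) &&
                 identical(s1$table$taxon_label, s3$table$taxon_label))
})

test_that("per-sample substreams keep early samples stable as the survey grows", {
  small <- simulate_survey(survey_config(n_samples = 10, seed = 33))$table
  big <- simulate_survey(survey_config(n_samples = 40, seed = 33))$table
  shared <- intersect(unique(small$sample_id), unique(big$sample_id))
  expect_setequal(unique(small$sample_id), shared)
  for (sid in shared) {
    expect_equal(big$taxon_label[big$sample_id == sid],
                 small$taxon_label[small$sample_id == sid])
  }
})

test_that("simulated tables validate and conserve structure", {
  sim <- simulate_survey(survey_config(n_samples = 30, seed = 9))
  tab <- sim$table
  expect_s3_class(tab, "survey_table")
  expect_equal(n_samples_collected(tab), 30)
  # every sample in the table yielded at least one isolate
  expect_true(all(table(tab$sample_id) >= 1))
  # occupancy truth matches the emitted rows sample by sample
  occ <- sim$truth$occupancy
  yielded <- names(occ)[!vapply(occ, is.null, TRUE)]
  expect_setequal(unique(tab$sample_id), yielded)
  for (sid in yielded) {
    expect_setequal(unique(tab$taxon_label[tab$sample_id == sid]), occ[[sid]])
  }
  # taxa drawn only from the configured pool
  expect_true(all(tab$taxon_label %in% names(sim$truth$rel_abundance)))
})

test_that("identity draws respect the rank band of their taxon", {
  sim <- simulate_survey(survey_config(n_samples = 40, seed = 14))
  tab <- sim$table
  rk <- assign_rank(tab$phylum, tab$identity_pct)
  expect_true(all(rk$rank != "unplaced"))
})

test_that("saturating sampling observes the whole pool", {
  cfg <- survey_config(S_true = 20, n_samples = 25,
                       abundance_model = list(model = "geometric", k = 0.1),
                       isolates_per_sample_mean = 60, p_empty_sample = 0,
                       seed = 77)
  tab <- simulate_survey(cfg)$table
  expect_equal(length(unique(tab$taxon_label)), 20)
})

test_that("true Shannon evaluates the pool's relative abundances", {
  expect_equal(true_shannon(rep(1 / 4, 4)), log(4))
  expect_equal(true_shannon(1), 0)
  q <- c(4, 2, 1) / 7 # geometric k = 0.5, S_true = 3
  expect_equal(true_shannon(q), 0.9557, tolerance = 5e-5)
  cfg <- survey_config(S_true = 3,
                       abundance_model = list(model = "geometric", k = 0.5),
                       seed = 1)
  sim <- simulate_survey(cfg)
  expect_equal(true_shannon(sim$truth), 0.9557, tolerance = 5e-5)
  expect_error(true_shannon(c(0.5, 0.2)), "sum to 1")
})

test_that("richness estimators recover the pool size under deep sampling", {
  deep <- function(seed) {
    cfg <- survey_config(S_true = 20, n_samples = 25,
                         abundance_model = list(model = "geometric", k = 0.1),
                         isolates_per_sample_mean = 50, p_empty_sample = 0,
                         seed = seed)
    tab <- simulate_survey(cfg)$table
    a <- to_abundance(tab)
    m <- to_incidence(tab, "sample")
    c(chao1 = chao1(a)$S_est, jack1 = jackknife1(m)$S_est,
      boot = bootstrap_richness(m)$S_est, sobs = a$S)
  }
  est <- t(vapply(1:20, deep, numeric(4)))
  means <- colMeans(est)
  expect_lt(abs(means["chao1"] - 20) / 20, 0.05)
  expect_lt(abs(means["jack1"] - 20) / 20, 0.05)
  expect_lt(abs(means["boot"] - 20) / 20, 0.05)

  # shallow sampling: estimators still sit at or above observed richness
  shallow <- function(seed) {
    cfg <- survey_config(S_true = 20, n_samples = 8,
                         abundance_model = list(model = "geometric", k = 0.3),
                         isolates_per_sample_mean = 3, p_empty_sample = 0.2,
                         seed = seed)
    tab <- simulate_survey(cfg)$table
    a <- to_abundance(tab)
    m <- to_incidence(tab, "sample")
    c(chao1(a)$S_est, if (nrow(m) >= 2) jackknife1(m)$S_est else a$S,
      bootstrap_richness(m)$S_est) - a$S
  }
  excess <- t(vapply(101:110, shallow, numeric(3)))
  expect_true(all(excess >= -1e-9))
})

test_that("plug-in Shannon converges to the true pool index with depth", {
  mean_bias <- vapply(c(4, 30, 300), function(depth) {
    mean(vapply(51:55, function(seed) {
      cfg <- survey_config(S_true = 15, n_samples = 20,
                           abundance_model = list(model = "geometric", k = 0.25),
                           isolates_per_sample_mean = depth, p_empty_sample = 0,
                           seed = seed)
      sim <- simulate_survey(cfg)
      abs(shannon(to_abundance(sim$table)) - true_shannon(sim$truth))
    }, 0))
  }, 0)
  expect_true(all(diff(mean_bias) < 0))
  expect_lt(mean_bias[3], 0.05)
})

test_that("producer fractions track the configured rate", {
  p <- default_trait_models()$iaa$p_producer
  frac <- vapply(1:12, function(seed) {
    tab <- simulate_survey(survey_config(n_samples = 40, seed = seed))$table
    assayed <- tab$iaa_state == "measured"
    sum(assayed & tab$iaa_value > 0) / sum(assayed)
  }, 0)
  n_mean <- 40 * (1 - 19 / 72) * 252 / 53 # expected assayed strains per run
  se <- sqrt(p * (1 - p) / n_mean)
  expect_lt(abs(mean(frac) - p), 3 * se)
})

test_that("invalid configurations name the offending field", {
  expect_error(survey_config(n_samples = 10), "seed is required")
  expect_error(survey_config(S_true = 1, seed = 1), "S_true")
  expect_error(survey_config(p_empty_sample = 1, seed = 1), "p_empty_sample")
  expect_error(survey_config(abundance_model = list(model = "geometric", k = 2),
                             seed = 1), "k")
  expect_error(survey_config(host_genus_weights = c(1, 1, 1, 1), seed = 1),
               "host_genus_weights")
})
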