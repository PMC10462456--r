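test_that("Chao1 handles singleton/doubleton structure in both variants", {
  # no singletons: nothing to add
  expect_equal(chao1(named_counts(A = 2, B = 3))$S_est, 2)
  expect_equal(chao1(named_counts(A = 2, B = 3), "classic")$S_est, 2)
  # classic form with doubletons present
  expect_equal(chao1(named_counts(A = 1, B = 1, C = 2), "classic")$S_est, 5)
  # classic falls back to the F2 = 0 correction
  expect_equal(chao1(named_counts(A = 1, B = 1, C = 3), "classic")$S_est, 4)
  # bias-corrected default
  expect_equal(chao1(named_counts(A = 1, B = 1, C = 2))$S_est,
               3 + 2 * 1 / (2 * 2))
  est <- chao1(named_counts(A = 1, B = 1, C = 2))
  expect_equal(est$components$F1, 2)
  expect_equal(est$components$F2, 1)
  expect_error(chao1(integer(0)), "empty")
})

test_that("first-order jackknife adds Q1 (m-1)/m", {
  # m=4, S_obs=5, Q1=2
  m4 <- inc(c(1, 1, 1, 1, 0), c(1, 1, 1, 0, 1), c(1, 1, 0, 0, 0),
            c(1, 1, 1, 0, 0))
  expect_equal(jackknife1(m4)$S_est, 5 + 2 * 3 / 4)
  # m=2, S_obs=3, Q1=1
  m2 <- inc(c(1, 1, 0), c(1, 1, 1))
  expect_equal(jackknife1(m2)$S_est, 3.5)
  # every taxon in >= 2 rows: estimate equals observed
  full <- inc(c(1, 1), c(1, 1), c(1, 1))
  expect_equal(jackknife1(full)$S_est, 2)
  one_row <- incidence_matrix(matrix(1L, 1, 3,
                                     dimnames = list("s1", c("A", "B", "C"))))
  expect_error(jackknife1(one_row), "fewer than 2 samples")
})

test_that("analytic bootstrap adds sum (1-p)^m", {
  full <- inc(c(1, 1), c(1, 1))
  expect_equal(bootstrap_richness(full)$S_est, 2)
  # one taxon in 1 of 2 rows beside a ubiquitous taxon: + (1/2)^2
  m2 <- inc(c(1, 1), c(1, 0))
  expect_equal(bootstrap_richness(m2)$S_est, 2 + 0.25)
  # one taxon in 1 of 4 rows: + (3/4)^4
  m4 <- inc(c(1, 1), c(1, 0), c(1, 0), c(1, 0))
  expect_equal(bootstrap_richness(m4)$S_est, 2 + 0.75^4)
})

test_that("estimators agree with vegan and never fall below S_obs", {
  s <- inventory()
  a <- to_abundance(s)
  m <- to_incidence(s, "sample")
  pool <- vegan::specpool(unclass(m))
  expect_equal(jackknife1(m)$S_est, pool$jack1)
  expect_equal(bootstrap_richness(m)$S_est, pool$boot)
  er <- vegan::estimateR(as.integer(a$counts))
  expect_equal(chao1(a)$S_est, unname(er["S.chao1"]))

  sim <- simulate_survey(survey_config(n_samples = 24, seed = 5))
  for (tab in list(s, sim$table)) {
    ai <- to_abundance(tab)
    mi <- to_incidence(tab, "sample")
    for (est in list(chao1(ai), chao1(ai, "classic"), jackknife1(mi),
                     bootstrap_richness(mi))) {
      expect_gte(est$S_est, est$S_obs)
    }
  }
})

test_that("accumulation curves pool prefixes correctly", {
  # two samples {A,B} and {B,C}: every order sees 2 taxa after one sample
  s2 <- tiny_survey(c("A", "B", "B", "C"), sample = c("s1", "s1", "s2", "s2"))
  ac <- accumulation_curve(s2, n_permutations = 50, seed = 3)
  expect_equal(ac$sobs_mean[1], 2)
  expect_equal(ac$sobs_mean[2], 3)
  expect_equal(ac$sobs_sd[2], 0)

  s <- inventory()
  ac <- accumulation_curve(s, n_permutations = 30, seed = 11)
  # pooling all samples is order-independent: exact S, zero spread,
  # and Chao1 at t = m matches the full-inventory estimate
  expect_equal(ac$sobs_mean[53], 58)
  expect_equal(ac$sobs_sd[53], 0)
  expect_equal(ac$chao1_sd[53], 0)
  expect_equal(ac$chao1_mean[53], chao1(to_abundance(s))$S_est)
  # mean observed richness never decreases with sampling effort
  expect_true(all(diff(ac$sobs_mean) >= 0))
  # estimator trajectories stay at or above the observed curve
  expect_true(all(ac$chao1_mean >= ac$sobs_mean - 1e-9))
  expect_true(all(ac$jack1_mean >= ac$sobs_mean - 1e-9))
  expect_true(all(ac$bootstrap_mean >= ac$sobs_mean - 1e-9))
})

test_that("accumulation curves are deterministic given a seed", {
  s <- inventory()
  a1 <- accumulation_curve(s, n_permutations = 5, seed = 21)
  a2 <- accumulation_curve(s, n_permutations = 5, seed = 21)
  a3 <- accumulation_curve(s, n_permutations = 5, seed = 22)
  expect_identical(a1, a2)
  expect_false(identical(a1$sobs_mean, a3$sobs_mean))
  expect_error(accumulation_curve(s, n_permutations = 5),
               "seed is required")
  one <- tiny_survey(c("A", "B"), sample = c("s1", "s1"))
  expect_error(accumulation_curve(one, seed = 1), "at least 2 samples")
})
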