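test_that("fixed-effect pooling matches direct summation and simple cases", {
  # equal standard errors reduce to the arithmetic mean
  ep <- make_effects(z = c(0.2, 0.4), se = c(0.1, 0.1))
  fx <- pool_fixed(ep)
  expect_equal(fx$z_fixed, 0.3)
  # hand-picked three-study instance against the independent oracle
  z <- c(0.15, 0.42, 0.28); se <- c(0.05, 0.12, 0.08)
  fx <- pool_fixed(make_effects(z, se))
  orc <- oracle_pool(z, se)
  expect_equal(fx$z_fixed, orc$z_fixed, tolerance = 1e-12)
  expect_equal(fx$Q, orc$Q, tolerance = 1e-12)
  # per-study components sum to Q exactly
  expect_equal(sum(fx$contributions$q_component), fx$Q)
  expect_error(pool_fixed(make_effects(0.3, 0.1)), "at least 2")
})

test_that("pooled quantities agree with the direct-summation oracle to 1e-10", {
  set.seed(11)
  for (k in 2:5) {
    z <- rnorm(k, 0.3, 0.2)
    se <- runif(k, 0.04, 0.3)
    pr <- pool_random(make_effects(z, se))
    orc <- oracle_pool(z, se)
    expect_equal(pr$z_fixed, orc$z_fixed, tolerance = 1e-10)
    expect_equal(pr$Q, orc$Q, tolerance = 1e-10)
    expect_equal(pr$tau2, orc$tau2, tolerance = 1e-10)
    expect_equal(pr$z_random, orc$z_random, tolerance = 1e-10)
    expect_equal(pr$se_random, orc$se_random, tolerance = 1e-10)
    expect_equal(pr$ci_z, orc$ci_z, tolerance = 1e-10)
    expect_equal(pr$i2, orc$i2, tolerance = 1e-10)
    expect_equal(pr$r, tanh(orc$z_random), tolerance = 1e-10)
    expect_equal(pr$ci_r, tanh(orc$ci_z), tolerance = 1e-10)
  }
})

test_that("DL tau2 truncates at zero and matches the hand formula", {
  # near-identical effects: Q below k - 1, so tau2 = 0 and models coincide
  ep <- make_effects(z = c(0.30, 0.301, 0.299), se = c(0.1, 0.12, 0.11))
  pr <- pool_random(ep)
  expect_equal(pr$tau2, 0)
  expect_equal(pr$z_random, pr$z_fixed)
  # all effects identical: Q = 0 exactly, pooled value is that effect
  same <- make_effects(z = rep(0.42, 4), se = c(0.1, 0.2, 0.05, 0.3))
  pr2 <- pool_random(same)
  expect_equal(pr2$Q, 0)
  expect_equal(pr2$tau2, 0)
  expect_equal(pr2$z_random, 0.42)
  # heterogeneous three-study instance against the hand-computed formula
  z <- c(0.1, 0.5, 0.9); se <- c(0.05, 0.1, 0.05)
  w <- se^-2
  zf <- sum(w * z) / sum(w)
  Q <- sum(w * (z - zf)^2)
  tau2_hand <- max(0, (Q - 2) / (sum(w) - sum(w^2) / sum(w)))
  expect_equal(dl_tau2(make_effects(z, se)), tau2_hand, tolerance = 1e-12)
})

test_that("Q is order-invariant and unmoved by a study at the pooled value", {
  set.seed(3)
  z <- rnorm(12, 0.3, 0.25); se <- runif(12, 0.05, 0.2)
  ep <- make_effects(z, se)
  fx <- pool_fixed(ep)
  perm <- sample(12)
  fx_perm <- pool_fixed(make_effects(z[perm], se[perm]))
  expect_equal(fx_perm$z_fixed, fx$z_fixed)
  expect_equal(fx_perm$Q, fx$Q)
  # append a study sitting exactly at z_fixed: estimate and Q unchanged
  fx_aug <- pool_fixed(make_effects(c(z, fx$z_fixed), c(se, 0.07)))
  expect_equal(fx_aug$z_fixed, fx$z_fixed)
  expect_equal(fx_aug$Q, fx$Q)
})

test_that("I-squared follows its closed form on published and boundary values", {
  expect_equal(round(i_squared(8.992, 5), 3), 55.518, tolerance = 0.002)
  expect_equal(round(i_squared(1212.594, 77), 3), 93.732)
  expect_equal(i_squared(4, 5), 0)     # Q = k - 1
  expect_equal(i_squared(0, 5), 0)     # degenerate Q
  expect_true(i_squared(1e6, 2) < 100)
})

test_that("pooling the 77-study table agrees with an independent DL implementation", {
  skip_if_not_installed("metafor")
  ep <- read_effect_fixture()
  pr <- pool_random(ep)
  m <- metafor::rma(yi = ep$z, sei = ep$se_z, method = "DL")
  expect_equal(pr$z_random, unname(coef(m)), tolerance = 1e-8)
  expect_equal(pr$tau2, m$tau2, tolerance = 1e-8)
  expect_equal(pr$Q, m$QE, tolerance = 1e-8)
  expect_equal(pr$i2, m$I2, tolerance = 1e-4)
  # the printed per-study Q components (3-decimal inputs) are reproduced
  expect_equal(pr$contributions$q_component[1], 2.350, tolerance = 0.02)
  # and the whole published component column sums to our Q
  expect_equal(pr$Q, 1221.361, tolerance = 0.15)
})

test_that("subgroup pooling estimates heterogeneity independently per group", {
  ep <- read_effect_fixture()
  sg <- pool_subgroups(ep)
  expect_named(sg, c("China", "Other countries"))
  expect_equal(sg$China$k, 32)
  expect_equal(sg$`Other countries`$k, 45)
  # per-group results equal pooling the subset directly
  china <- pool_random(ep[ep$country == "China", ])
  expect_equal(sg$China$r, china$r)
  expect_equal(sg$China$tau2, china$tau2)
  # one group holding every study reproduces the overall pooling
  all_one <- pool_subgroups(ep, groups = rep("all", nrow(ep)))
  expect_equal(all_one$all$r, pool_random(ep)$r)
  expect_error(pool_subgroups(ep, groups = c("a", rep("b", 76))),
               "fewer than 2")
})

test_that("two-group synthetic corpora recover their distinct true means", {
  spec <- corpus_spec(
    tau = 0.1, n_range = c(200, 400), seed = 404,
    group_specs = list(
      list(label = "China", true_r = 0.45, n_studies = 25),
      list(label = "Elsewhere", true_r = 0.20, n_studies = 25)))
  recs <- generate_corpus(spec)
  ep <- effect_points(recs, quiet = TRUE)
  sg <- pool_subgroups(ep, groups = ep$country)
  for (g in list(c("China", 0.45), c("Elsewhere", 0.20))) {
    pr <- sg[[g[1]]]
    truth <- as.numeric(g[2])
    expect_gt(truth, pr$ci_r[1])
    expect_lt(truth, pr$ci_r[2])
  }
})

test_that("DL interval coverage sits in the expected band over many corpora", {
  # 500 simulated corpora at the reference conditions; DL under-coverage at
  # high tau keeps the band below the nominal 95%
  n_rep <- 500
  true_r <- 0.34
  hits <- logical(n_rep)
  est <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    spec <- corpus_spec(true_r = true_r, tau = 0.25, n_studies = 77,
                        n_range = c(100, 500), seed = 5000 + i)
    ep <- effect_points(generate_corpus(spec), quiet = TRUE)
    pr <- pool_random(ep)
    hits[i] <- pr$ci_r[1] < true_r && true_r < pr$ci_r[2]
    est[i] <- pr$r
  }
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.98)
  # estimator calibration: centered on the truth within 2 Monte-Carlo SEs
  mc_se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - true_r), 2 * mc_se + 1e-12)
})
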