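test_that("multiplicative-odds genotype probabilities behave at the boundaries", {
  null <- genotype_probs(0.35, 1)
  expect_equal(null$case, null$control, tolerance = 1e-12)
  expect_equal(sum(null$control), 1, tolerance = 1e-12)

  huge <- genotype_probs(0.5, 1e8)
  expect_gt(huge$case[["AA"]], 1 - 1e-6)

  expect_error(genotype_probs(0, 2), "inside")
  expect_error(genotype_probs(1, 2), "inside")
  expect_error(genotype_probs(0.5, -1), "positive")
})

test_that("case allele odds are exactly psi times the control allele odds", {
  # hence psi solving a 54.2% case frequency from f = 0.365 in closed form
  f <- 0.365
  psi <- (0.542 / 0.458) / (f / (1 - f))
  pr <- genotype_probs(f, psi)
  f_case <- pr$case[["AA"]] + pr$case[["AG"]] / 2
  expect_equal(f_case, 0.542, tolerance = 1e-12)
  # and the allelic odds ratio implied by the two frequencies is psi itself
  or_allelic <- (f_case / (1 - f_case)) / (f / (1 - f))
  expect_equal(or_allelic, psi, tolerance = 1e-12)
  expect_equal(psi, 2.06, tolerance = 0.005)
})

test_that("study simulation is reproducible and respects its configuration", {
  cfg <- synthetic_config(k = 6, f_control = 0.3, psi = 2, tau = 0.2,
                          n_cases = c(50, 200), n_controls = 150, seed = 99)
  s1 <- simulate_study(cfg, 3)
  s2 <- simulate_study(cfg, 3)
  expect_identical(s1$study, s2$study)
  expect_identical(s1$study$ctrl_AA + s1$study$ctrl_AG + s1$study$ctrl_GG, 150L)
  expect_true(s1$study$case_AA + s1$study$case_AG + s1$study$case_GG >= 50)
  expect_error(simulate_study(cfg, 9), "out of range")

  # growing k leaves earlier studies untouched
  big <- synthetic_config(k = 12, f_control = 0.3, psi = 2, tau = 0.2,
                          n_cases = c(50, 200), n_controls = 150, seed = 99)
  expect_identical(simulate_study(big, 3)$study, s1$study)
})

test_that("simulated meta-analyses have the right shape and seed behavior", {
  cfg <- synthetic_config(k = 8, seed = 7)
  sim <- simulate_meta(cfg)
  expect_identical(nrow(sim$studies), 8L)
  expect_identical(nrow(sim$truth), 8L)
  expect_false(any(duplicated(sim$studies$study_id)))
  expect_equal(rowSums(sim$truth[, c("ctrl_AA", "ctrl_AG", "ctrl_GG")]),
               rep(1, 8), tolerance = 1e-12, ignore_attr = TRUE)

  other <- simulate_meta(synthetic_config(k = 8, seed = 8))
  expect_identical(dim(other$studies), dim(sim$studies))
  expect_false(identical(other$studies$case_AA, sim$studies$case_AA))

  expect_error(synthetic_config(k = 0), "positive integer")
  expect_error(synthetic_config(k = 5, n_cases = 5), "10")
})

test_that("a null effect at large n yields an allelic odds ratio near 1", {
  cfg <- synthetic_config(k = 10, f_control = 0.4, psi = 1, tau = 0,
                          n_cases = 5000, n_controls = 5000, seed = 31)
  sim <- simulate_meta(cfg)
  fit <- pool_auto(sim$studies, "allelic")
  expect_equal(fit$or, 1, tolerance = 0.05)
})

test_that("distorted control arms are caught by the recomputed HWE filter", {
  cfg <- synthetic_config(k = 1, f_control = 0.35, psi = 1.5,
                          n_cases = 300, n_controls = 300,
                          hwe_violation = 0.3, violate = 1, seed = 5)
  reject <- vapply(1:1000, function(i) {
    cfg$seed <- i
    st <- simulate_study(cfg, 1)$study
    hwe_test(st$ctrl_AA, st$ctrl_AG, st$ctrl_GG)$p < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.9)
  # and the same arms without distortion are rarely rejected
  cfg$violate <- integer(0)
  keep <- vapply(1:1000, function(i) {
    cfg$seed <- i
    st <- simulate_study(cfg, 1)$study
    hwe_test(st$ctrl_AA, st$ctrl_AG, st$ctrl_GG)$p >= 0.05
  }, logical(1))
  expect_gt(mean(keep), 0.9)
})

test_that("a fixture-sized synthetic set runs through the whole pipeline", {
  cfg <- synthetic_config(k = 33, f_control = 0.35, psi = 2.5, tau = 0.1,
                          seed = 17)
  sim <- simulate_meta(cfg)
  rep <- run_analysis(sim$studies,
                      config = analysis_config(models = c("allelic", "dom"),
                                               subgroup_keys = "ethnicity"))
  expect_true(all(dplyr::filter(rep$rows, k >= 2)$pooled))
  sizes <- sim$studies$case_AA + sim$studies$case_AG + sim$studies$case_GG
  expect_true(all(sizes >= 46 & sizes <= 1335))
})

test_that("the pooled Z-test holds its size under the null", {
  reject <- vapply(1:1200, function(i) {
    cfg <- synthetic_config(k = 10, f_control = 0.35, psi = 1, tau = 0,
                            n_cases = c(100, 500), n_controls = c(100, 500),
                            seed = 50000 + i)
    fit <- pool_auto(simulate_meta(cfg)$studies, "allelic")
    fit$p < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("two-proportion power: null level, published inputs, consistency", {
  expect_equal(power_two_proportions(0.3, 0.3, 100, 100), 0.05,
               tolerance = 1e-12)
  # pooled allele counts of the screened analysis give essentially certain power
  expect_gte(power_two_proportions(0.542, 0.365, 2 * 8101, 2 * 7215), 0.995)
  expect_gt(power_two_proportions(0.35, 0.40, 1e6, 1e6), 0.9999)
  expect_gt(power_two_proportions(0.35, 0.40, 500, 500),
            power_two_proportions(0.35, 0.40, 100, 100))
  expect_error(power_two_proportions(0, 0.5, 10, 10), "inside")
})
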