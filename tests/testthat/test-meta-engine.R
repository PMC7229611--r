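test_that("per-study odds ratios follow ad/bc with Woolf standard errors", {
  est <- study_effects(toy_tables(102, 172, 11, 179))
  expect_equal(est$or, 102 * 179 / (172 * 11), tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / 102 + 1 / 172 + 1 / 11 + 1 / 179),
               tolerance = 1e-12)

  sym <- study_effects(toy_tables(5, 5, 5, 5))
  expect_equal(sym$or, 1, tolerance = 1e-12)
  expect_equal(sym$ci_low * sym$ci_high, 1, tolerance = 1e-12)  # symmetric about 1

  expect_equal(study_effects(toy_tables(14.5, 11.5, 0.5, 5.5))$or,
               13.87, tolerance = 0.005)
  expect_error(study_effects(toy_tables(1, 0, 2, 3)), "continuity")
})

test_that("swapping exposure labels inverts every odds ratio exactly", {
  set.seed(7)
  tab <- toy_tables(sample(5:50, 6), sample(5:50, 6), sample(5:50, 6),
                    sample(5:50, 6))
  swapped <- dplyr::mutate(tab, tmp = a, a = b, b = tmp,
                           tmp2 = c, c = d, d = tmp2)[, names(tab)]
  e1 <- study_effects(tab)
  e2 <- study_effects(swapped)
  expect_equal(e2$log_or, -e1$log_or, tolerance = 1e-12)
  expect_equal(e2$ci_low, 1 / e1$ci_high, tolerance = 1e-12)
  for (pool in list(pool_mh, pool_dl, pool_iv)) {
    expect_equal(pool(swapped)$log_or, -pool(tab)$log_or, tolerance = 1e-10)
  }
})

test_that("Cochran's Q matches its defining sum and handles degenerate input", {
  same <- cochran_q(c(0.4, 0.4), c(0.1, 0.1))
  expect_equal(same$q, 0, tolerance = 1e-12)
  expect_equal(same$p_het, 1, tolerance = 1e-12)
  expect_identical(same$tau2, 0)
  expect_identical(same$i2, 0)

  y <- c(0.2, 0.7, -0.1); s <- c(0.15, 0.3, 0.2)
  got <- cochran_q(y, s)
  w <- 1 / s^2                                   # brute-force oracle
  q_direct <- sum(w * (y - sum(w * y) / sum(w))^2)
  expect_equal(got$q, q_direct, tolerance = 1e-12)
  expect_equal(got$p_het, pchisq(q_direct, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(got$tau2,
               max(0, (q_direct - 2) / (sum(w) - sum(w^2) / sum(w))),
               tolerance = 1e-12)
  expect_error(cochran_q(0.5, 0.1), "at least 2")
})

test_that("the real-time-PCR pair reproduces the printed heterogeneity", {
  rt <- dplyr::filter(table1, method == "RT-PCR")
  eff <- study_effects(contrast_tables(rt, "hom"))
  expect_equal(cochran_q(eff$log_or, eff$se)$p_het, 0.817, tolerance = 0.005)
})

test_that("Mantel-Haenszel pooling: identity, replication invariance, RBG interval", {
  one <- toy_tables(30, 20, 10, 40)
  expect_equal(pool_mh(one)$or, study_effects(one)$or, tolerance = 1e-12)
  many <- one[rep(1, 7), ]
  expect_equal(pool_mh(many)$or, pool_mh(one)$or, tolerance = 1e-12)

  # printed RT-PCR homozygote row: OR 9.83 (5.18-18.65), fixed effect
  rt <- dplyr::filter(table1, method == "RT-PCR")
  fit <- pool_mh(contrast_tables(rt, "hom"))
  expect_equal(fit$or, 9.83, tolerance = 0.01)
  expect_equal(fit$ci_low, 5.18, tolerance = 0.01)
  expect_equal(fit$ci_high, 18.65, tolerance = 0.015)

  degenerate <- toy_tables(c(2, 3), c(1, 1), c(0, 0), c(4, 5))
  expect_error(pool_mh(apply_continuity(degenerate, increment = 0)),
               "continuity")
})

test_that("DerSimonian-Laird pooling matches a step-by-step oracle", {
  tab <- toy_tables(c(30, 55, 18), c(20, 35, 30), c(12, 40, 25), c(38, 50, 22))
  fit <- pool_dl(tab)
  eff <- study_effects(tab)
  w <- 1 / eff$se^2                                # oracle: DL by hand
  ybar <- sum(w * eff$log_or) / sum(w)
  q <- sum(w * (eff$log_or - ybar)^2)
  tau2 <- max(0, (q - 2) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (eff$se^2 + tau2)
  expect_equal(fit$log_or, sum(ws * eff$log_or) / sum(ws), tolerance = 1e-12)
  expect_equal(fit$se, 1 / sqrt(sum(ws)), tolerance = 1e-12)
  expect_equal(fit$het$tau2, tau2, tolerance = 1e-12)
  expect_error(pool_dl(tab[1, ]), "at least 2")
})

test_that("with Q <= df random effects collapses to inverse-variance fixed pooling", {
  tab <- toy_tables(c(30, 31), c(20, 19), c(12, 13), c(38, 37))
  dl <- pool_dl(tab)
  iv <- pool_iv(tab)
  expect_identical(dl$het$tau2, 0)
  expect_equal(dl$log_or, iv$log_or, tolerance = 1e-12)
  expect_equal(dl$se, iv$se, tolerance = 1e-12)
})

test_that("pooled estimates stay inside the span of the study estimates", {
  set.seed(42)
  for (i in 1:20) {
    tab <- toy_tables(sample(1:60, 5), sample(1:60, 5),
                      sample(1:60, 5), sample(1:60, 5))
    tab <- apply_continuity(tab)
    ors <- study_effects(tab)$or
    for (fit in list(pool_mh(tab), pool_dl(tab), pool_iv(tab))) {
      expect_gte(fit$or, min(ors) - 1e-9)
      expect_lte(fit$or, max(ors) + 1e-9)
    }
  }
})

test_that("Z statistic and its two-sided normal P agree with a tail oracle", {
  fit <- pool_dl(toy_tables(c(30, 55), c(20, 35), c(12, 40), c(38, 50)))
  expect_equal(fit$z, abs(fit$log_or) / fit$se, tolerance = 1e-12)
  # independent tail evaluation via the error function identity
  phi_tail <- 0.5 * (1 - pracma::erf(fit$z / sqrt(2)))
  expect_equal(fit$p, 2 * phi_tail, tolerance = 1e-12)
})

test_that("pooling agrees with metafor on the published allelic analysis", {
  skip_if_not_installed("metafor")
  tab <- contrast_tables(hwe33, "allelic")
  eff <- study_effects(tab)
  oracle <- metafor::rma(yi = eff$log_or, vi = eff$se^2, method = "DL")
  fit <- pool_dl(tab)
  expect_equal(fit$log_or, as.numeric(oracle$beta), tolerance = 1e-10)
  expect_equal(fit$se, oracle$se, tolerance = 1e-10)
  expect_equal(fit$het$tau2, oracle$tau2, tolerance = 1e-10)

  mh_oracle <- metafor::rma.mh(ai = tab$a, bi = tab$b, ci = tab$c, di = tab$d,
                               correct = FALSE, add = 0)
  mh <- pool_mh(tab)
  expect_equal(mh$log_or, as.numeric(mh_oracle$beta), tolerance = 1e-10)
  expect_equal(mh$se, mh_oracle$se, tolerance = 1e-8)
})

test_that("pool_auto dispatches on the heterogeneity P threshold", {
  # sequencing subgroup: P_het 0.237 > 0.1 -> fixed effect, OR 2.84
  seq14 <- dplyr::filter(hwe33, normalize_method(method) == "Sequencing")
  fit <- pool_auto(seq14, "allelic")
  expect_identical(fit$method, "MH_fixed")
  expect_identical(fit$k, 14L)
  expect_equal(fit$or, 2.84, tolerance = 0.01)
  expect_equal(fit$het$p_het, 0.237, tolerance = 0.005)

  # Asian subgroup: P_het < 0.001 -> random effects, OR 2.51
  asian <- dplyr::filter(hwe33, ethnicity == "Asian")
  fit2 <- pool_auto(asian, "allelic")
  expect_identical(fit2$method, "DL_random")
  expect_identical(fit2$k, 19L)
  expect_equal(fit2$or, 2.51, tolerance = 0.01)

  # near-zero threshold forces the fixed-effect branch everywhere
  fit3 <- pool_auto(asian, "allelic", het_threshold = 1e-12)
  expect_identical(fit3$method, "MH_fixed")

  expect_identical(glance(fit2)$n_case, 3424L)
  expect_identical(glance(fit2)$n_ctrl, 4004L)
  expect_identical(nrow(tidy(fit2)), 19L)
  expect_equal(sum(tidy(fit2)$weight_pct), 100, tolerance = 1e-9)
})
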