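test_that("Mann-Whitney reproduces worked exact p-values", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6), tail = "two_sided")
  expect_equal(res$p, 0.10)
  expect_equal(res$U, 0)
  expect_equal(res$method, "exact")

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3), tail = "two_sided")
  expect_equal(same$p, 1.0)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p agrees with enumeration on random small instances", {
  set.seed(101)
  for (i in 1:40) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    # half the instances carry ties through rounding
    vals <- if (i %% 2) round(runif(na + nb, 0, 5)) else runif(na + nb)
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    tail <- if (i %% 3) "two_sided" else "one_sided_greater"
    got <- mann_whitney(a, b, tail = tail)
    expect_equal(got$method, "exact")
    expect_equal(got$U, oracle_u(a, b))
    expect_equal(got$p, oracle_mw_p(a, b, tail), tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney agrees with wilcox.test on tie-free data", {
  set.seed(55)
  a <- rnorm(5); b <- rnorm(6, 1)
  got <- mann_whitney(a, b, tail = "two_sided")
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("approximate Mann-Whitney tracks wilcox.test with continuity correction", {
  set.seed(66)
  a <- rnorm(12); b <- rnorm(14, 0.8)
  got <- mann_whitney(a, b, tail = "two_sided")
  expect_equal(got$method, "normal")
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
})

test_that("a planted 3-sigma shift is detected in most 7-vs-4 replicates", {
  set.seed(202)
  hits <- 0
  n_rep <- 500
  for (i in seq_len(n_rep)) {
    a <- rnorm(7, 3, 1)
    b <- rnorm(4, 0, 1)
    if (mann_whitney(a, b, tail = "one_sided_greater")$p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})

exact_v_prob <- function(r, v) {
  vs <- 0
  for (ri in r) vs <- c(vs, vs + ri)
  mean(abs(vs - v) < 1e-9)
}

test_that("Wilcoxon signed-rank reproduces worked exact p-values", {
  res <- wilcoxon_paired(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6),
                         tail = "one_sided_greater")
  expect_equal(res$p, 1 / 32)
  expect_equal(res$method, "exact")

  expect_warning(out <- wilcoxon_paired(1:5, 1:5), "zero")
  expect_equal(out$p, 1)

  # sign flip mirrors the one-sided p under the exact null
  set.seed(9)
  pre <- rnorm(8); post <- pre + rnorm(8, 0.4)
  p_up <- wilcoxon_paired(pre, post, tail = "one_sided_greater")$p
  p_down <- wilcoxon_paired(post, pre, tail = "one_sided_greater")$p
  d <- post - pre
  r <- rank(abs(d))
  # P(V >= v) + P(V >= sum(r) - v) = 1 + P(V == v) under the symmetric null
  expect_equal(p_up + p_down, 1 + exact_v_prob(r, sum(r[d > 0])),
               tolerance = 1e-12)

  expect_error(wilcoxon_paired(1:3, 2:4), "at least 5")
})

test_that("exact Wilcoxon p agrees with enumeration on random small instances", {
  set.seed(303)
  for (i in 1:30) {
    n <- sample(5:9, 1)
    pre <- round(runif(n, 0, 6))
    post <- round(pre + rnorm(n, 0.5, 1.5))
    if (all(post == pre)) post[1] <- pre[1] + 1
    tail <- if (i %% 2) "two_sided" else "one_sided_greater"
    got <- suppressWarnings(wilcoxon_paired(pre, post, tail = tail))
    if (got$method == "degenerate") next
    expect_equal(got$p, oracle_wilcoxon_p(pre, post, tail), tolerance = 1e-12)
  }
})

test_that("response report computes group changes and directional tests", {
  mk <- function(id, group, pre_tdv, post_tdv, pre_med, post_med) {
    data.frame(patient_id = id, group = group,
               pre_tdv_ml = pre_tdv, post_tdv_ml = post_tdv,
               pre_gadc_median = pre_med, post_gadc_median = post_med,
               pre_gadc_variance = 0.03e-6, post_gadc_variance = 0.05e-6,
               pre_gadc_skewness = 0.8, post_gadc_skewness = 0.1,
               pre_gadc_kurtosis = 2.3, post_gadc_kurtosis = -0.4)
  }
  cohort <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      mk(paste0("R", i), "responder", 100 + i, (100 + i) / 2, 0.8e-3, 1.0e-3))),
    do.call(rbind, lapply(1:3, function(i)
      mk(paste0("N", i), "non-responder", 200 + i, (200 + i) * 2, 0.8e-3, 0.78e-3))))
  rep <- response_report(cohort)
  pats <- rep$patients
  expect_equal(unname(pats$percent_change_tdv[pats$group == "responder"]),
               rep(-50, 4))
  expect_equal(unname(pats$percent_change_tdv[pats$group == "non-responder"]),
               rep(100, 3))
  gs <- rep$group_summary
  expect_equal(gs$responder_median[gs$metric == "percent_change_tdv"], -50)
  expect_equal(gs$nonresponder_median[gs$metric == "percent_change_tdv"], 100)
  tests <- rep$tests
  expect_true(tests$significant[tests$metric == "percent_change_tdv"])
  expect_equal(tests$tail[tests$metric == "delta_gadc_median"],
               "one_sided_greater")
  expect_false(rep$small_sample)

  # single-patient group: small-sample caveat flagged
  tiny <- rbind(mk("R1", "responder", 100, 50, 0.8e-3, 1.0e-3),
                mk("N1", "non-responder", 100, 150, 0.8e-3, 0.8e-3),
                mk("N2", "non-responder", 100, 160, 0.8e-3, 0.8e-3))
  expect_true(response_report(tiny)$small_sample)

  # a missing timepoint drops the patient with a warning
  broken <- cohort
  broken$post_tdv_ml[1] <- NA
  expect_warning(rep2 <- response_report(broken), "missing")
  expect_equal(nrow(rep2$patients), nrow(cohort) - 1)
})
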