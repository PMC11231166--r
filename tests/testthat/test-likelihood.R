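test_that("binomial diagnose-time prior has the right shape", {
  pr <- binomial_time_prior(0.3, 10)
  expect_equal(sum(pr$pmf * 0:10), 3.0)
  expect_equal(sum(pr$pmf), 1, tolerance = 1e-12)
  expect_equal(binomial_time_prior(0, 10)$pmf, c(1, rep(0, 10)))
  set.seed(1)
  for (p in runif(20))
    expect_equal(sum(binomial_time_prior(p, 10)$pmf), 1, tolerance = 1e-12)
  expect_error(binomial_time_prior(1.5, 10), "\\[0, 1\\]")
})

test_that("observation matrix factorizes the confusion table over levels", {
  ss1 <- enumerate_states(1)
  B <- build_observation_matrix(modality("CT"), ss1)
  expect_equal(B, matrix(c(0.76, 0.19, 0.24, 0.81), 2, 2))
  # perfect test observes the hidden state exactly
  expect_equal(build_observation_matrix(modality("pathology"),
                                        enumerate_states(3)),
               diag(8))
  set.seed(2)
  for (rep in 1:20) {
    m <- modality("x", sensitivity = runif(1), specificity = runif(1))
    B <- build_observation_matrix(m, enumerate_states(3))
    expect_equal(rowSums(B), rep(1, 8), tolerance = 1e-12)
  }
})

test_that("modality registry carries the literature values", {
  reg <- default_modalities()
  expect_equal(reg$specificity[reg$name == "CT"], 0.76)
  expect_equal(reg$sensitivity[reg$name == "CT"], 0.81)
  expect_equal(reg$sensitivity[reg$name == "pathology"], 1)
  expect_error(modality("ultrasound"), "unknown modality")
})

test_that("state distribution marginalizes the diagnose time correctly", {
  g1 <- spread_graph("A")
  p1 <- model_params(g1, b = c(A = 0.25), p_late = 0.45, t_max = 8)
  for (tc in c("early", "late")) {
    dist <- state_distribution(g1, p1, t_category = tc)
    pmf <- binomial_time_prior(if (tc == "early") 0.3 else 0.45, 8)$pmf
    # closed form for a single level: P(involved) = sum_t pmf * (1-(1-b)^t)
    expect_equal(dist[2], sum(pmf * (1 - 0.75^(0:8))), tolerance = 1e-12)
    expect_equal(sum(dist), 1, tolerance = 1e-12)
  }
  # no spread: the all-healthy state keeps all the mass
  p0 <- model_params(g1, b = c(A = 0), p_late = 0.45)
  expect_equal(state_distribution(g1, p0, t_category = "late"), c(1, 0))
})

test_that("late diagnose-time priors dominate early ones level-wise", {
  g <- winning_graph()
  p <- winning_graph_params()
  ss <- enumerate_states(g)
  de <- state_distribution(g, p, t_category = "early")
  dl <- state_distribution(g, p, t_category = "late")
  marg_e <- colSums(de * ss$states)
  marg_l <- colSums(dl * ss$states)
  expect_true(all(marg_l >= marg_e))
  # level II marginal for advanced T-category is close to 80%
  expect_equal(marg_l[["II"]], 0.79, tolerance = 0.02)
})

test_that("diagnosis likelihood vector normalizes and matches closed forms", {
  g1 <- spread_graph("A")
  p1 <- model_params(g1, b = c(A = 0.3), p_late = 0.5, t_max = 5)
  m <- modality("scan", sensitivity = 0.8, specificity = 0.7)
  l <- diagnosis_likelihoods(g1, p1, m, "late")
  pmf <- binomial_time_prior(0.5, 5)$pmf
  p_inv <- sum(pmf * (1 - 0.7^(0:5)))
  expect_equal(l[2], p_inv * 0.8 + (1 - p_inv) * 0.3, tolerance = 1e-12)
  expect_equal(sum(l), 1, tolerance = 1e-12)
  # perfect modality: likelihood vector is the hidden-state distribution
  toy <- toy_chain2()
  expect_equal(
    diagnosis_likelihoods(toy$graph, toy$params, modality("pathology"),
                          "late"),
    state_distribution(toy$graph, toy$params, t_category = "late"))
  set.seed(3)
  for (rep in 1:1000) {
    inst <- random_instance(V = 3)
    mm <- modality("x", sensitivity = runif(1), specificity = runif(1))
    l <- diagnosis_likelihoods(inst$graph, inst$params, mm,
                               sample(c("early", "late"), 1))
    expect_lt(abs(sum(l) - 1), 1e-10)
  }
})

test_that("cohort log-likelihood equals exhaustive enumeration on V=2 toys", {
  toy <- toy_chain2(b_a = 0.35, b_b = 0.15, t_ab = 0.4, p_late = 0.55,
                    t_max = 4)
  mod <- modality("scan", sensitivity = 0.85, specificity = 0.75)
  coh <- data.frame(
    patient_id = sprintf("p%d", 1:6),
    t_category = c("early", "early", "late", "late", "early", "late"),
    scan_A = c(1, 0, 1, NA, 0, 1),
    scan_B = c(0, 0, 1, 1, NA, NA),
    stringsAsFactors = FALSE)
  pmf_by_cat <- list(
    early = binomial_time_prior(0.3, 4)$pmf,
    late = binomial_time_prior(0.55, 4)$pmf)
  expect_equal(
    cohort_log_likelihood(toy$graph, toy$params, coh, mod),
    oracle_cohort_loglik(toy$lnls, toy$parents, toy$b, toy$tt,
                         pmf_by_cat, coh, "scan", 0.85, 0.75),
    tolerance = 1e-10)
})

test_that("incomplete diagnoses marginalize exactly", {
  toy <- toy_chain2()
  mod <- modality("scan", sensitivity = 0.8, specificity = 0.9)
  base <- data.frame(patient_id = "p", t_category = "late",
                     scan_A = 1, scan_B = NA, stringsAsFactors = FALSE)
  ll_part <- cohort_log_likelihood(toy$graph, toy$params, base, mod)
  probs <- vapply(0:1, function(z) {
    coh <- base
    coh$scan_B <- z
    exp(cohort_log_likelihood(toy$graph, toy$params, coh, mod))
  }, numeric(1))
  expect_equal(exp(ll_part), sum(probs), tolerance = 1e-12)
  # a fully unknown patient carries no information
  allna <- data.frame(patient_id = "p", t_category = "late",
                      scan_A = NA, scan_B = NA)
  expect_equal(cohort_log_likelihood(toy$graph, toy$params, allna, mod), 0)
  # empty cohort: log of an empty product
  expect_equal(cohort_log_likelihood(toy$graph, toy$params, allna[0, ], mod),
               0)
})

test_that("cohort log-likelihood is additive over patients", {
  toy <- toy_chain2()
  mod <- modality("pathology")
  coh <- data.frame(patient_id = c("a", "b"),
                    t_category = c("early", "late"),
                    pathology_A = c(1, 0), pathology_B = c(0, 0),
                    stringsAsFactors = FALSE)
  ll_both <- cohort_log_likelihood(toy$graph, toy$params, coh, mod)
  ll_sum <- sum(vapply(1:2, function(i) {
    cohort_log_likelihood(toy$graph, toy$params, coh[i, ], mod)
  }, numeric(1)))
  expect_equal(ll_both, ll_sum, tolerance = 1e-12)
})

test_that("all-healthy diagnosis gets less likely as tumor spread grows", {
  set.seed(4)
  g <- spread_graph(c("A", "B", "C"), c("A->B", "B->C"))
  coh <- data.frame(patient_id = "p", t_category = "early",
                    pathology_A = 0, pathology_B = 0, pathology_C = 0)
  for (rep in 1:20) {
    b0 <- setNames(runif(3, 0.05, 0.5), c("A", "B", "C"))
    tt <- setNames(runif(2), c("A->B", "B->C"))
    for (lv in c("A", "B", "C")) {
      b_hi <- b0
      b_hi[lv] <- b0[lv] + 0.2
      ll_lo <- cohort_log_likelihood(
        g, model_params(g, b = b0, t = tt, p_late = 0.5), coh,
        modality("pathology"))
      ll_hi <- cohort_log_likelihood(
        g, model_params(g, b = b_hi, t = tt, p_late = 0.5), coh,
        modality("pathology"))
      expect_lt(ll_hi, ll_lo)
    }
  }
})

test_that("compiled core agrees with the plain-R probability path on V=6", {
  g <- winning_graph()
  p <- winning_graph_params()
  mod <- modality("CT")
  coh <- simulate_cohort(g, p, n = 120, mod = mod, seed = 5)
  ss <- enumerate_states(g)
  ll_r <- 0
  for (tc in c("early", "late")) {
    sub <- coh[coh$t_category == tc, ]
    dist <- state_distribution(g, p, t_category = tc)
    for (i in seq_len(nrow(sub))) {
      d <- as.numeric(sub[i, paste0("CT_", g$lnl_names)])
      names(d) <- g$lnl_names
      ll_r <- ll_r + log(sum(diagnosis_obs_probs(d, mod, ss) * dist))
    }
  }
  expect_equal(cohort_log_likelihood(g, p, coh, mod), ll_r,
               tolerance = 1e-10)
})

test_that("cohort validation reports informative data errors", {
  toy <- toy_chain2()
  coh <- data.frame(patient_id = "p", t_category = "late", scan_A = 2,
                    scan_B = 0)
  expect_error(
    cohort_log_likelihood(toy$graph, toy$params, coh,
                          modality("scan", 0.8, 0.8)),
    "0, 1 or empty")
  coh2 <- data.frame(patient_id = "p", t_category = "late", other_A = 1)
  expect_error(
    cohort_log_likelihood(toy$graph, toy$params, coh2,
                          modality("scan", 0.8, 0.8)),
    "lacks column")
})
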