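test_that("perfect modality collapses the state posterior onto the diagnosis", {
  toy <- toy_chain2()
  post <- posterior_state_distribution(toy$graph, toy$params,
                                       c(A = 1, B = 0), "late",
                                       modality("pathology"))
  ss <- enumerate_states(toy$graph)
  expect_equal(post, as.numeric(seq_len(4) == state_index(ss, c(1, 0))))
})

test_that("state posterior is normalized and matches brute-force Bayes", {
  toy <- toy_chain2(b_a = 0.3, b_b = 0.2, t_ab = 0.6, p_late = 0.5,
                    t_max = 4)
  mod <- modality("scan", sensitivity = 0.8, specificity = 0.7)
  ss <- enumerate_states(toy$graph)
  for (diag in list(c(A = 1, B = 0), c(A = 0, B = 0), c(A = 1))) {
    post <- posterior_state_distribution(toy$graph, toy$params, diag,
                                         "late", mod)
    expect_equal(sum(post), 1, tolerance = 1e-12)
    # brute force: P(state | diag) over all states, diagnosis completions
    # and times, evaluated with the independent enumeration oracle
    pmf <- binomial_time_prior(0.5, 4)$pmf
    A <- oracle_transition_matrix(toy$lnls, toy$parents, toy$b, toy$tt)
    pi_t <- c(1, 0, 0, 0)
    prior <- pmf[1] * pi_t
    for (tstep in 1:4) {
      pi_t <- as.numeric(A %*% pi_t)
      prior <- prior + pmf[tstep + 1] * pi_t
    }
    d <- setNames(rep(NA_real_, 2), toy$lnls)
    d[names(diag)] <- diag
    lik <- vapply(1:4, function(k) {
      p <- 1
      for (v in 1:2) {
        if (is.na(d[v])) next
        x <- oracle_bit(k, v, 2)
        p <- p * if (x == 1) (if (d[v] == 1) 0.8 else 0.2)
                 else (if (d[v] == 1) 0.3 else 0.7)
      }
      p
    }, numeric(1))
    expect_equal(post, lik * prior / sum(lik * prior), tolerance = 1e-12)
  }
})

test_that("impossible diagnoses raise an error naming the pattern", {
  g <- spread_graph("A")
  p <- model_params(g, b = c(A = 0), p_late = 0.5)
  expect_error(
    posterior_state_distribution(g, p, c(A = 1), "late",
                                 modality("pathology")),
    "probability zero.*A=1")
})

test_that("involvement patterns marginalize via the indicator dot product", {
  ss <- enumerate_states(spread_graph(c("A", "B")))
  post <- c(0.5, 0.2, 0.2, 0.1)
  expect_equal(marginal_risk(post, c(), ss), 1)          # ignore everything
  expect_equal(marginal_risk(post, c(A = 1), ss), 0.3)
  expect_equal(marginal_risk(post, c(A = 1, B = 0), ss), 0.2)
  expect_equal(marginal_risk(post, c(B = 0), ss), 0.7)
  expect_error(marginal_risk(post, c(C = 1), ss), "unknown level")
})

test_that("occult risks rank by T-category and by severity of the diagnosis", {
  g <- winning_graph()
  p <- winning_graph_params()
  ct <- modality("CT")
  scen <- risk_scenarios()
  for (lv in c("I", "III", "IV", "V")) {
    for (s in names(scen)) {
      if (!is.null(scen[[s]]) && lv %in% names(scen[[s]])) next
      r_early <- occult_risk(g, p, lv, scen[[s]], "early", ct)
      r_late <- occult_risk(g, p, lv, scen[[s]], "late", ct)
      expect_gte(r_late, r_early)
    }
  }
  # occult level III risk grows when level II is clinically involved
  for (tc in c("early", "late"))
    expect_gt(occult_risk(g, p, "III", c(II = 1), tc, ct),
              occult_risk(g, p, "III", c(), tc, ct))
})

test_that("risk over posterior samples propagates parameter uncertainty", {
  g <- winning_graph()
  th <- params_to_vector(winning_graph_params(), g)
  const <- matrix(rep(th, each = 50), 50, length(th),
                  dimnames = list(NULL, names(th)))
  diag_full <- setNames(c(0, 1, 0, 0, 0, 0), g$lnl_names)
  rr <- risk_over_samples(g, const, diag_full, "late", modality("CT"),
                          pattern = c(III = 1), subsample_fraction = 0.2)
  expect_equal(rr$std, 0)
  expect_equal(rr$mean,
               occult_risk(g, winning_graph_params(), "III", c(II = 1),
                           "late", modality("CT")),
               tolerance = 1e-12)
  # jittered draws: subsample mean close to full-sample mean
  set.seed(31)
  jit <- pmin(pmax(const + rnorm(length(const), 0, 0.01), 0.001), 0.999)
  full <- risk_over_samples(g, jit, c(II = 1), "late", modality("CT"),
                            pattern = c(III = 1), subsample_fraction = 1)
  half <- risk_over_samples(g, jit, c(II = 1), "late", modality("CT"),
                            pattern = c(III = 1), subsample_fraction = 0.5,
                            seed = 2)
  expect_lt(abs(full$mean - half$mean), 3 * full$std / sqrt(half$n) + 0.002)
  expect_error(risk_over_samples(g, const[0, ], c(), "late",
                                 modality("CT"), c(III = 1)),
               "empty")
})

test_that("true-parameter risk is calibrated against a recovered posterior", {
  toy <- toy_chain2(b_a = 0.3, b_b = 0.1, t_ab = 0.4, p_late = 0.5,
                    t_max = 10)
  coh <- simulate_cohort(toy$graph, toy$params, n = 800, seed = 37)
  fit <- sample_posterior(toy$graph, coh,
                          sampler_config(burn_in = 500, seed = 41),
                          t_max = 10)
  truth <- occult_risk(toy$graph, toy$params, "B", c(A = 1), "late",
                       modality("CT"))
  rr <- risk_over_samples(toy$graph, fit, c(A = 1, B = 0), "late",
                          modality("CT"), pattern = c(B = 1),
                          t_max = 10)
  q <- quantile(rr$values, c(0.005, 0.995))
  expect_gte(truth, q[[1]])
  expect_lte(truth, q[[2]])
})

test_that("predicted prevalences agree with simulated cohort frequencies", {
  g <- winning_graph()
  p <- winning_graph_params()
  prev <- predicted_prevalence(g, p, c(II = 1), "late")
  n <- 200000
  coh <- simulate_cohort(g, p, n = n, fraction_late = 1,
                         mod = modality("pathology"), seed = 43)
  emp <- mean(coh$pathology_II)
  se <- sqrt(prev * (1 - prev) / n)
  expect_lt(abs(emp - prev), 3 * se)
  # a pattern needing spread that cannot happen has prevalence zero
  p0 <- model_params(g, b = setNames(rep(0, 6), g$lnl_names),
                     t = p$t, p_late = 0.5)
  expect_equal(predicted_prevalence(g, p0, c(II = 1), "late"), 0)
})

test_that("beta posterior over a prevalence peaks at the raw frequency", {
  bp <- beta_posterior_prevalence(100, 423)
  expect_equal(bp$shape1, 101)
  expect_equal(bp$shape2, 324)
  expect_equal(bp$mode, 100 / 423, tolerance = 1e-12)
  expect_equal(beta_posterior_prevalence(0, 0)$shape1, 1)
  expect_equal(beta_posterior_prevalence(0, 0)$shape2, 1)
  expect_equal(beta_posterior_prevalence(5, 10)$mode, 0.5)
  expect_error(beta_posterior_prevalence(4, 3), "count <= total")
})
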