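#' Posterior over hidden states given an observed diagnosis
#'
#' Bayes inversion of the observation model: the prior over hidden states
#' comes from the time-marginalized Markov evolution for the patient's
#' T-category, the likelihood from the modality's sensitivity/specificity;
#' levels with unknown status in the diagnosis are marginalized exactly.
#' With a perfect modality and a fully specified diagnosis the posterior
#' collapses onto the diagnosed state.
#'
#' @inheritParams diagnosis_likelihoods
#' @param diagnosis Named 0/1/NA vector over the graph's levels (levels not
#'   mentioned count as unknown), e.g. `c(II = 1, III = 0)`.
#' @return Probability vector of length `2^V` over hidden states.
#' @export
#' @examples
#' posterior_state_distribution(winning_graph(), winning_graph_params(),
#'                              diagnosis = c(II = 1), t_category = "late",
#'                              mod = modality("CT"))
posterior_state_distribution <- function(graph, params, diagnosis,
                                         t_category, mod) {
  ss <- enumerate_states(graph)
  prior <- state_distribution(graph, params, t_category = t_category)
  lik <- diagnosis_obs_probs(diagnosis, mod, ss)
  post <- lik * prior
  z <- sum(post)
  if (z <= 0) {
    d <- as_diagnosis(diagnosis, graph$lnl_names)
    stop("diagnosis has probability zero under the model: ",
         paste(sprintf("%s=%s", names(d), ifelse(is.na(d), "?", d)),
               collapse = ", "))
  }
  post / z
}

#' Marginalize a state distribution over an involvement pattern
#'
#' An involvement pattern fixes some levels to 0/1 and ignores
#' (marginalizes) the rest; the marginal probability is the dot product of
#' the distribution with the 0/1 indicator of the compatible states.
#'
#' @param state_posterior Probability vector over the `2^V` hidden states.
#' @param pattern Named 0/1/NA vector over the levels (NA or omitted =
#'   marginalize).
#' @param state_space The matching [enumerate_states()] object (or a
#'   [spread_graph()]).
#' @return The marginal probability.
#' @export
#' @examples
#' ss <- enumerate_states(spread_graph(c("II", "III")))
#' marginal_risk(c(0.5, 0.2, 0.2, 0.1), c(II = 1), ss)
marginal_risk <- function(state_posterior, pattern, state_space) {
  if (inherits(state_space, "spread_graph"))
    state_space <- enumerate_states(state_space)
  stopifnot(inherits(state_space, "state_space"),
            length(state_posterior) == state_space$n_states)
  pat <- as_diagnosis(pattern, colnames(state_space$states))
  m <- rep(1, state_space$n_states)
  for (v in names(pat)) {
    if (is.na(pat[[v]])) next
    m <- m * (state_space$states[, v] == pat[[v]])
  }
  sum(m * state_posterior)
}

#' Risk of occult involvement of one level
#'
#' Probability that level `level` truly harbors (possibly microscopic)
#' metastases given the clinical diagnosis: the posterior over hidden
#' states is marginalized for `X_level = 1`.  For an occult-disease
#' question the diagnosis reports `level` as clinically negative; levels
#' absent from `diagnosis` default to 0 (a level is either reported
#' involved or counts as clinically negative in these scenarios).
#'
#' @inheritParams posterior_state_distribution
#' @param level Level label whose true involvement is queried.
#' @param diagnosis Named 0/1 vector of the clinically involved levels;
#'   unmentioned levels are taken as clinically negative.
#' @return Probability of true involvement of `level`.
#' @export
#' @examples
#' # early T-category, clinically N0 neck, CT diagnosis
#' occult_risk(winning_graph(), winning_graph_params(), "II",
#'             diagnosis = c(), t_category = "early", mod = modality("CT"))
occult_risk <- function(graph, params, level, diagnosis = c(),
                        t_category, mod) {
  if (!level %in% graph$lnl_names) stop("unknown level: ", level)
  full <- setNames(rep(0, length(graph$lnl_names)), graph$lnl_names)
  if (length(diagnosis)) {
    d <- as_diagnosis(diagnosis, graph$lnl_names)
    full[!is.na(d)] <- d[!is.na(d)]
  }
  post <- posterior_state_distribution(graph, params, full, t_category, mod)
  marginal_risk(post, setNames(1, level), enumerate_states(graph))
}

#' Distribution of a risk over posterior parameter samples
#'
#' Evaluates [marginal_risk()] of `pattern` given `diagnosis` for a random
#' subsample of posterior parameter draws, propagating parameter
#' uncertainty into the risk estimate.
#'
#' @inheritParams posterior_state_distribution
#' @param samples A [sample_posterior()] result, or an `S x k` matrix of
#'   parameter vectors in [param_names()] layout.
#' @param pattern Involvement pattern whose probability is evaluated (see
#'   [marginal_risk()]).
#' @param subsample_fraction Fraction of draws evaluated (default 0.1).
#' @param seed Seed for the subsampling.
#' @param p_early,t_max Fixed model settings used to rebuild parameters
#'   from each draw.
#' @return Object of class `risk_result`: list with `values` (risk per
#'   evaluated draw), `mean`, `std`, `n`.
#' @export
risk_over_samples <- function(graph, samples, diagnosis, t_category, mod,
                              pattern, subsample_fraction = 0.1, seed = 1L,
                              p_early = 0.3, t_max = 10L) {
  draws <- if (inherits(samples, "posterior_samples")) samples$samples
           else as.matrix(samples)
  if (!nrow(draws)) stop("`samples` is empty")
  set.seed(seed)
  n_eval <- max(1L, round(subsample_fraction * nrow(draws)))
  rows <- sample(nrow(draws), n_eval)
  ss <- enumerate_states(graph)
  vals <- vapply(rows, function(i) {
    pars <- vector_to_params(draws[i, ], graph, p_early, t_max)
    post <- posterior_state_distribution(graph, pars, diagnosis,
                                         t_category, mod)
    marginal_risk(post, pattern, ss)
  }, numeric(1))
  structure(list(values = vals, mean = mean(vals), std = sd(vals),
                 n = n_eval),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("Risk over %d posterior draws: %.2f%% +- %.2f%%\n",
              x$n, 100 * x$mean, 100 * x$std))
  invisible(x)
}

#' Predicted prevalence of an involvement pattern
#'
#' Probability of a (possibly partial) true-involvement pattern under the
#' model's prior for a T-category — the quantity compared against observed
#' cohort frequencies, since consensus involvement is treated as an
#' observation of the true hidden state.
#'
#' @inheritParams posterior_state_distribution
#' @param pattern Named 0/1/NA vector over levels (NA = marginalize).
#' @return The pattern's probability.
#' @export
#' @examples
#' predicted_prevalence(winning_graph(), winning_graph_params(),
#'                      c(II = 1), "late")  # about 0.80
predicted_prevalence <- function(graph, params, pattern, t_category) {
  dist <- state_distribution(graph, params, t_category = t_category)
  marginal_risk(dist, pattern, enumerate_states(graph))
}

#' Beta posterior over an observed prevalence
#'
#' With a uniform prior and a binomial likelihood, observing `count`
#' patients with a pattern out of `total` gives a `Beta(count + 1,
#' total - count + 1)` posterior over the pattern's prevalence, whose mode
#' is the raw frequency `count / total`.
#'
#' @param count Number of patients showing the pattern.
#' @param total Cohort size; `total = 0` returns the uniform prior.
#' @return List with `shape1`, `shape2`, `mode` and a quantile function
#'   `qf(p)`.
#' @export
#' @examples
#' beta_posterior_prevalence(100, 423)$mode  # 0.236
beta_posterior_prevalence <- function(count, total) {
  if (count < 0 || total < 0 || count > total)
    stop("need 0 <= count <= total")
  shape1 <- count + 1
  shape2 <- total - count + 1
  list(shape1 = shape1, shape2 = shape2,
       mode = if (total > 0) count / total else NA_real_,
       qf = function(p) qbeta(p, shape1, shape2))
}

#' Standard diagnosis scenarios for occult-risk reporting
#'
#' The four clinical presentations used throughout the package's risk
#' summaries: a clinically node-negative neck (`cN0`), involvement of
#' level II only, of levels II and III, and extensive involvement of
#' levels II, III and IV.  Levels not listed are clinically negative.
#'
#' @return Named list of diagnosis vectors for [occult_risk()].
#' @export
risk_scenarios <- function() {
  list(cN0 = c(),
       "II" = c(II = 1),
       "II+III" = c(II = 1, III = 1),
       "II+III+IV" = c(II = 1, III = 1, IV = 1))
}
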