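#' Binomial prior over the time of diagnosis
#'
#' The number of time-steps elapsed between tumor formation and diagnosis
#' is unobserved; it is marginalized over a binomial prior
#' `Binomial(t_max, p)` whose mean is `t_max * p`.  Patients with advanced
#' T-category tumors were probably diagnosed after more time-steps, so they
#' get a larger `p` than early T-category patients.
#'
#' @param p Success probability in `[0, 1]`.
#' @param t_max Horizon (integer >= 1); the support is `0:t_max`.
#' @return An object of class `time_prior` with fields `pmf` (length
#'   `t_max + 1`), `p`, `t_max`, `support`.
#' @export
#' @examples
#' binomial_time_prior(0.3, 10)  # mean 3 time-steps
binomial_time_prior <- function(p, t_max = 10L) {
  if (!is.finite(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  t_max <- as.integer(t_max)
  if (is.na(t_max) || t_max < 1) stop("`t_max` must be an integer >= 1")
  structure(list(pmf = dbinom(0:t_max, t_max, p), p = p, t_max = t_max,
                 support = 0:t_max),
            class = "time_prior")
}

#' @export
print.time_prior <- function(x, ...) {
  cat(sprintf("Binomial diagnose-time prior: t_max = %d, p = %.4f (mean %.2f)\n",
              x$t_max, x$p, x$t_max * x$p))
  invisible(x)
}

time_prior_for <- function(params, t_category) {
  t_category <- match.arg(t_category, c("early", "late"))
  binomial_time_prior(if (t_category == "early") params$p_early
                      else params$p_late, params$t_max)
}

#' Marginal distribution over hidden states at diagnosis
#'
#' Starting from the all-healthy state at tumor formation, the hidden state
#' evolves by the transition matrix for an unknown number of steps; the
#' diagnose-time prior is marginalized out:
#' `sum_t P(t) * A^t %*% pi0`.
#'
#' @param graph A [spread_graph()].
#' @param params A [model_params()] for `graph`.
#' @param time_prior A [binomial_time_prior()]; alternatively give
#'   `t_category` to use the prior implied by `params`.
#' @param t_category `"early"` or `"late"` (ignored when `time_prior` is
#'   given).
#' @return Probability vector of length `2^V` over hidden states (sums to
#'   one).
#' @export
state_distribution <- function(graph, params, time_prior = NULL,
                               t_category = NULL) {
  stopifnot(inherits(graph, "spread_graph"), inherits(params, "model_params"))
  if (is.null(time_prior)) {
    if (is.null(t_category))
      stop("give either `time_prior` or `t_category`")
    time_prior <- time_prior_for(params, t_category)
  }
  stopifnot(inherits(time_prior, "time_prior"))
  A <- build_transition_matrix(graph, params)
  n <- nrow(A)
  pi_t <- c(1, rep(0, n - 1))
  acc <- time_prior$pmf[1] * pi_t
  for (t in seq_len(time_prior$t_max)) {
    pi_t <- as.numeric(A %*% pi_t)
    acc <- acc + time_prior$pmf[t + 1] * pi_t
  }
  acc
}

#' Likelihood of every complete diagnosis
#'
#' The vector of probabilities of each of the `2^V` possible complete
#' diagnoses under a modality and T-category:
#' `l = t(B) %*% state_distribution`, which sums to one.
#'
#' @inheritParams state_distribution
#' @param mod A [modality()].
#' @param t_category `"early"` or `"late"`.
#' @return Probability vector of length `2^V` over diagnoses.
#' @export
diagnosis_likelihoods <- function(graph, params, mod, t_category) {
  stopifnot(inherits(mod, "modality"))
  ss <- enumerate_states(graph)
  B <- build_observation_matrix(mod, ss)
  dist <- state_distribution(graph, params, t_category = t_category)
  as.numeric(crossprod(B, dist))
}

#' Log-likelihood of a patient cohort
#'
#' Sum over patients of the log-probability of their observed diagnosis
#' under the model.  Levels with unknown status are marginalized exactly
#' (the probability sums the likelihoods of all completions of the
#' unknowns).  Patients split by T-category use the corresponding
#' diagnose-time prior.  Returns `-Inf` when any record has probability
#' zero, so samplers can reject the parameter vector; an empty cohort gives
#' 0 by the empty-product convention.
#'
#' @inheritParams diagnosis_likelihoods
#' @param cohort A cohort data.frame (see [read_cohort()]) whose
#'   `<modality>_<level>` columns for `mod$name` hold the observed ternary
#'   statuses.
#' @return The scalar log-likelihood.
#' @export
#' @examples
#' g <- winning_graph()
#' p <- winning_graph_params()
#' coh <- simulate_cohort(g, p, n = 50, seed = 1)
#' cohort_log_likelihood(g, p, coh, modality("pathology"))
cohort_log_likelihood <- function(graph, params, cohort, mod) {
  ctx <- likelihood_context(graph, cohort, mod,
                            p_early = params$p_early, t_max = params$t_max)
  cohort_loglik_core(matrix(params_to_vector(params, graph), nrow = 1), ctx)[1]
}

#' Precomputed likelihood context
#'
#' Gathers everything about a (graph, cohort, modality) triple that does
#' not depend on the parameter vector: the state enumeration, the
#' parent-configuration index tables used to assemble the transition
#' matrix, and the cohort collapsed to unique (T-category, diagnosis
#' pattern) counts with their observation probabilities.  The compiled
#' likelihood core evaluates whole batches of parameter vectors against
#' such a context; it is built once per MCMC run.
#'
#' @inheritParams cohort_log_likelihood
#' @param p_early Fixed early-T diagnose-time parameter.
#' @param t_max Diagnose-time horizon.
#' @return A list consumed by [log_posterior()] and the samplers.
#' @export
likelihood_context <- function(graph, cohort, mod, p_early = 0.3,
                               t_max = 10L) {
  stopifnot(inherits(graph, "spread_graph"), inherits(mod, "modality"))
  ss <- enumerate_states(graph)
  V <- ss$V
  n <- ss$n_states
  lnls <- graph$lnl_names
  k <- n_params(graph)

  # per level: theta indices of the t-parameters of each parent subset,
  # and per source state the index of its involved-parent subset
  pn <- param_names(graph)
  psub <- matrix(0L, n, V)
  subs <- vector("list", V)
  for (vi in seq_len(V)) {
    v <- lnls[vi]
    parents <- graph_parents(graph, v)
    np <- length(parents)
    tidx <- vapply(parents,
                   function(r) match(paste0("t_", r, "->", v), pn),
                   integer(1)) - 1L  # 0-based for the compiled core
    subs[[vi]] <- lapply(0:(2L^np - 1L), function(s) {
      tidx[bitwAnd(bitwShiftR(s, seq_len(np) - 1L), 1L) == 1L]
    })
    if (np) {
      sub_id <- integer(n)
      for (pi in seq_len(np))
        sub_id <- sub_id + bitwShiftL(ss$states[, parents[pi]], pi - 1L)
      psub[, vi] <- sub_id
    }
  }

  pat <- cohort_patterns(cohort, lnls, mod$name)
  obs <- t(vapply(seq_len(nrow(pat$patterns)), function(i) {
    diagnosis_obs_probs(pat$patterns[i, ], mod, ss)
  }, numeric(n)))
  if (!nrow(pat$patterns)) obs <- matrix(0, 0, n)

  list(graph = graph, state_space = ss, mod = mod,
       bits = ss$states, psub = psub, subs = subs,
       obs = obs, count_early = pat$count_early, count_late = pat$count_late,
       p_early = p_early, t_max = as.integer(t_max),
       k = k, param_names = pn, n_patients = pat$n_patients)
}

# collapse a cohort to unique diagnosis patterns with per-T-category counts
cohort_patterns <- function(cohort, lnls, mod_name) {
  cols <- paste0(mod_name, "_", lnls)
  missing_cols <- setdiff(cols, names(cohort))
  if (nrow(cohort) && length(missing_cols))
    stop("cohort lacks column(s) for modality \"", mod_name, "\": ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(cohort)) {
    return(list(patterns = matrix(numeric(), 0, length(lnls),
                                  dimnames = list(NULL, lnls)),
                count_early = numeric(), count_late = numeric(),
                n_patients = 0L))
  }
  if (!"t_category" %in% names(cohort))
    stop("cohort lacks a `t_category` column")
  tc <- as.character(cohort$t_category)
  if (any(!tc %in% c("early", "late")))
    stop("`t_category` must be \"early\" or \"late\" (rows ",
         paste(head(which(!tc %in% c("early", "late"))), collapse = ", "),
         ")")
  m <- as.matrix(cohort[, cols, drop = FALSE])
  storage.mode(m) <- "numeric"
  bad <- !is.na(m) & !(m %in% c(0, 1))
  if (any(bad))
    stop("involvement status must be 0, 1 or empty (rows ",
         paste(head(unique(which(bad, arr.ind = TRUE)[, 1])), collapse = ", "),
         ")")
  key <- apply(m, 1, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  uk <- unique(key)
  patterns <- m[match(uk, key), , drop = FALSE]
  colnames(patterns) <- lnls
  rownames(patterns) <- NULL
  list(patterns = patterns,
       count_early = vapply(uk, function(u) sum(key == u & tc == "early"),
                            numeric(1), USE.NAMES = FALSE),
       count_late = vapply(uk, function(u) sum(key == u & tc == "late"),
                           numeric(1), USE.NAMES = FALSE),
       n_patients = nrow(cohort))
}
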