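#' MCMC sampler configuration
#'
#' Fixed-schedule ensemble sampling: `walkers_per_dim * k` walkers are run
#' for `burn_in` discarded steps, then `keep_steps` further steps of which
#' every `thin`-th is retained, yielding
#' `S = keep_steps / thin * W` draws (the default schedule keeps 20 steps
#' per walker).
#'
#' @param walkers_per_dim Walkers per parameter dimension (default 20).
#' @param burn_in Discarded initial steps (default 1000).
#' @param keep_steps Post-burn-in steps (default 200).
#' @param thin Retain every `thin`-th step (default 10); must divide
#'   `keep_steps`.
#' @param seed Integer master seed; all randomness derives from it.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(walkers_per_dim = 20L, burn_in = 1000L,
                           keep_steps = 200L, thin = 10L, seed = 1L) {
  cfg <- list(walkers_per_dim = as.integer(walkers_per_dim),
              burn_in = as.integer(burn_in),
              keep_steps = as.integer(keep_steps),
              thin = as.integer(thin),
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(walkers_per_dim, keep_steps, thin) < 1) || burn_in < 0)
      stop("sampler settings must be positive (burn_in may be 0)")
    if (keep_steps %% thin != 0)
      stop("`keep_steps` must be divisible by `thin`")
  })
  structure(cfg, class = "sampler_config")
}

#' Log power-posterior density
#'
#' Under the uniform prior on the unit hypercube the (unnormalized) power
#' posterior is `beta * log-likelihood` inside the cube and `-Inf` outside.
#' At `beta = 0` it reduces to the flat prior.
#'
#' @param theta Numeric parameter vector of length `n_params(graph)`, or a
#'   matrix with one vector per row.
#' @inheritParams cohort_log_likelihood
#' @param beta Inverse temperature in `[0, 1]`.
#' @param ctx Optional [likelihood_context()]; when given, `graph`,
#'   `cohort` and `mod` are ignored (used to avoid rebuilding the context
#'   in tight loops).
#' @param p_early,t_max Fixed model settings (see [model_params()]).
#' @return Log-density value(s); `-Inf` signals rejection, never an error.
#' @export
log_posterior <- function(theta, graph = NULL, cohort = NULL,
                          mod = modality("pathology"), beta = 1,
                          ctx = NULL, p_early = 0.3, t_max = 10L) {
  if (is.null(ctx))
    ctx <- likelihood_context(graph, cohort, mod, p_early, t_max)
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1)
  if (ncol(theta) != ctx$k)
    stop("`theta` must have length ", ctx$k)
  ll <- cohort_loglik_core(theta, ctx)
  # outside the cube the compiled core already returns -Inf; a finite-ll
  # point scaled by beta = 0 must map to the flat prior (0), so scale only
  # finite values
  ifelse(is.finite(ll), beta * ll, -Inf)
}

#' Sample the (power) posterior with an affine-invariant ensemble
#'
#' Runs an ensemble of `W = walkers_per_dim * k` parallel chains whose
#' proposals are differential-evolution moves: a walker jumps along the
#' difference vector of two randomly chosen walkers of the complementary
#' half-ensemble, scaled by `gamma = 2.38 / sqrt(2 k)` (with a small
#' jitter), and occasionally by `gamma = 1` to allow mode-to-mode jumps.
#' Because proposals are built from the ensemble's own geometry the scheme
#' is affine invariant: rescaling any parameter axis leaves its behaviour
#' unchanged.  Walkers start uniformly in the unit cube unless `init` is
#' given.
#'
#' @inheritParams log_posterior
#' @param config A [sampler_config()].
#' @param init Optional `W x k` matrix of starting positions (used to
#'   warm-start, e.g. between thermodynamic-integration rungs).
#' @param reseed Set `FALSE` to continue from the current RNG state instead
#'   of seeding from `config$seed` (used internally for chained runs).
#' @return An object of class `posterior_samples`: list with `samples`
#'   (`S x k` matrix), `log_likelihoods` (length `S`, always the
#'   unpowered data log-likelihood), `parameter_names`, `final_positions`
#'   and `final_log_likelihoods` (for warm-starting), `acceptance_rate`,
#'   `beta`, `config`.
#' @export
#' @examples
#' g <- spread_graph("II")
#' coh <- simulate_cohort(g, model_params(g, b = c(II = 0.4), p_late = 0.5),
#'                        n = 30, seed = 7)
#' fit <- sample_posterior(g, coh, sampler_config(burn_in = 50, seed = 1))
#' colMeans(fit$samples)
sample_posterior <- function(graph, cohort, config, beta = 1, init = NULL,
                             mod = modality("pathology"), ctx = NULL,
                             p_early = 0.3, t_max = 10L, reseed = TRUE) {
  stopifnot(inherits(config, "sampler_config"))
  if (is.null(ctx))
    ctx <- likelihood_context(graph, cohort, mod, p_early, t_max)
  res <- run_de_ensemble(
    log_lik = function(th) cohort_loglik_core(th, ctx),
    k = ctx$k, config = config, beta = beta, init = init,
    seed = if (reseed) config$seed else NULL)
  colnames(res$samples) <- ctx$param_names
  structure(c(res, list(parameter_names = ctx$param_names,
                        beta = beta, config = config)),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("Posterior samples: S = %d draws, k = %d parameters, beta = %g\n",
              nrow(x$samples), ncol(x$samples), x$beta))
  cat(sprintf("  acceptance rate %.2f; posterior means:\n", x$acceptance_rate))
  print(round(colMeans(x$samples), 4))
  invisible(x)
}

# Differential-evolution ensemble sampler on [0,1]^k.
# log_lik takes an n x k matrix and returns n data log-likelihoods;
# the target at inverse temperature beta is beta * log_lik inside the cube.
run_de_ensemble <- function(log_lik, k, config, beta = 1, init = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- config$walkers_per_dim * k
  if (W %% 2 == 1) W <- W + 1L
  if (W < 2 * k + 2 || W < 6)
    stop("the ensemble needs at least max(2k + 2, 6) walkers; got ", W,
         " for k = ", k)
  X <- init
  if (is.null(X)) {
    X <- matrix(runif(W * k), W, k)
  } else {
    X <- as.matrix(X)
    if (nrow(X) != W || ncol(X) != k)
      stop("`init` must be a ", W, " x ", k, " matrix")
  }
  ll <- log_lik(X)
  lp <- ifelse(is.finite(ll), beta * ll, -Inf)
  gamma0 <- 2.38 / sqrt(2 * k)
  halves <- list(seq_len(W %/% 2), (W %/% 2 + 1):W)
  n_acc <- 0
  n_prop <- 0
  n_kept <- config$keep_steps %/% config$thin
  keep_X <- vector("list", n_kept)
  keep_ll <- vector("list", n_kept)
  kept <- 0L

  one_step <- function() {
    for (h in 1:2) {
      idx <- halves[[h]]
      comp <- halves[[3 - h]]
      nh <- length(idx)
      a <- sample(comp, nh, replace = TRUE)
      b <- sample(comp, nh, replace = TRUE)
      clash <- which(b == a)
      while (length(clash)) {               # resample until pairs distinct
        b[clash] <- sample(comp, length(clash), replace = TRUE)
        clash <- clash[b[clash] == a[clash]]
      }
      g <- gamma0 * (1 + rnorm(nh, 0, 1e-4))
      g[runif(nh) < 0.1] <- 1               # occasional full-length jump
      prop <- X[idx, , drop = FALSE] +
        g * (X[a, , drop = FALSE] - X[b, , drop = FALSE])
      ll_p <- log_lik(prop)
      lp_p <- ifelse(is.finite(ll_p), beta * ll_p, -Inf)
      acc <- log(runif(nh)) < lp_p - lp[idx]
      acc[!is.finite(lp_p) & !is.finite(lp[idx])] <- FALSE
      if (any(acc)) {
        X[idx[acc], ] <<- prop[acc, , drop = FALSE]
        ll[idx[acc]] <<- ll_p[acc]
        lp[idx[acc]] <<- lp_p[acc]
      }
      n_acc <<- n_acc + sum(acc)
      n_prop <<- n_prop + nh
    }
  }

  for (s in seq_len(config$burn_in)) one_step()
  for (s in seq_len(config$keep_steps)) {
    one_step()
    if (s %% config$thin == 0) {
      kept <- kept + 1L
      keep_X[[kept]] <- X
      keep_ll[[kept]] <- ll
    }
  }
  list(samples = do.call(rbind, keep_X),
       log_likelihoods = unlist(keep_ll),
       final_positions = X,
       final_log_likelihoods = ll,
       acceptance_rate = if (n_prop) n_acc / n_prop else NA_real_,
       n_walkers = W)
}

#' Persist posterior samples
#'
#' `write_samples()` serializes a [sample_posterior()] result (RDS);
#' `read_samples()` restores it; `export_samples_csv()` writes the draws
#' with their log-likelihoods as a plain CSV for interoperability.
#'
#' @param samples A `posterior_samples` object.
#' @param path Output file.
#' @return `read_samples` returns the restored object; the writers return
#'   `path` invisibly.
#' @export
write_samples <- function(samples, path) {
  stopifnot(inherits(samples, "posterior_samples"))
  saveRDS(samples, path)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  samples <- readRDS(path)
  stopifnot(inherits(samples, "posterior_samples"))
  samples
}

#' @rdname write_samples
#' @export
export_samples_csv <- function(samples, path) {
  stopifnot(inherits(samples, "posterior_samples"))
  df <- as.data.frame(samples$samples)
  df$log_likelihood <- samples$log_likelihoods
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
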