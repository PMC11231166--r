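# Independent brute-force oracles.  These re-derive the model's
# probabilities by direct enumeration from the conditional-probability
# tables, sharing no code with the package's matrix implementation; they
# are only feasible for small V.

# bit of level v (1-based, first level most significant) in state index i
oracle_bit <- function(i, v, V) (i - 1) %/% 2^(V - v) %% 2

# naive transition matrix: A[i, j] = P(state_i | state_j)
# parents: named list level -> character vector of parents
oracle_transition_matrix <- function(lnls, parents, b, tt) {
  V <- length(lnls)
  n <- 2^V
  A <- matrix(0, n, n)
  for (j in 1:n) for (i in 1:n) {
    pr <- 1
    for (v in 1:V) {
      cur <- oracle_bit(j, v, V)
      nxt <- oracle_bit(i, v, V)
      if (cur == 1) {
        pr <- pr * as.numeric(nxt == 1)
      } else {
        q <- 1 - b[[lnls[v]]]
        for (r in parents[[lnls[v]]] %||% character())
          if (oracle_bit(j, match(r, lnls), V) == 1)
            q <- q * (1 - tt[[paste0(r, "->", lnls[v])]])
        pr <- pr * if (nxt == 1) 1 - q else q
      }
    }
    A[i, j] <- pr
  }
  A
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# probability of one (possibly incomplete) diagnosis by exhaustive
# enumeration over times, hidden states and completions of the unknowns
oracle_patient_prob <- function(lnls, parents, b, tt, pmf, diag, s_n, s_p) {
  V <- length(lnls)
  n <- 2^V
  A <- oracle_transition_matrix(lnls, parents, b, tt)
  pi_t <- c(1, rep(0, n - 1))
  total <- 0
  for (tstep in seq_along(pmf) - 1) {
    if (tstep > 0) pi_t <- as.numeric(A %*% pi_t)
    for (k in 1:n) for (l in 1:n) {      # hidden state k, full diagnosis l
      matches <- TRUE
      pz <- 1
      for (v in 1:V) {
        z <- oracle_bit(l, v, V)
        d <- diag[[lnls[v]]]
        if (!is.na(d) && d != z) { matches <- FALSE; break }
        x <- oracle_bit(k, v, V)
        pz <- pz * if (x == 1) (if (z == 1) s_n else 1 - s_n)
                   else (if (z == 1) 1 - s_p else s_p)
      }
      if (matches) total <- total + pmf[tstep + 1] * pi_t[k] * pz
    }
  }
  total
}

oracle_cohort_loglik <- function(lnls, parents, b, tt, pmf_by_cat, cohort,
                                 mod_name, s_n, s_p) {
  tot <- 0
  for (r in seq_len(nrow(cohort))) {
    diag <- as.numeric(cohort[r, paste0(mod_name, "_", lnls)])
    names(diag) <- lnls
    tot <- tot + log(oracle_patient_prob(
      lnls, parents, b, tt, pmf_by_cat[[cohort$t_category[r]]],
      diag, s_n, s_p))
  }
  tot
}

# --- shared toy fixtures -------------------------------------------------

toy_chain2 <- function(b_a = 0.2, b_b = 0.1, t_ab = 0.5, p_late = 0.6,
                       t_max = 3) {
  g <- spread_graph(c("A", "B"), "A->B")
  list(graph = g,
       params = model_params(g, b = c(A = b_a, B = b_b),
                             t = c("A->B" = t_ab),
                             p_late = p_late, t_max = t_max),
       lnls = c("A", "B"),
       parents = list(A = character(), B = "A"),
       b = c(A = b_a, B = b_b),
       tt = c("A->B" = t_ab))
}

# random acyclic graph + params for property checks
random_instance <- function(V = 4) {
  lnls <- LETTERS[seq_len(V)]
  arcs <- character()
  for (i in seq_len(V - 1)) for (j in (i + 1):V)
    if (runif(1) < 0.4) arcs <- c(arcs, paste0(lnls[i], "->", lnls[j]))
  g <- spread_graph(lnls, arcs)
  p <- model_params(g,
                    b = setNames(runif(V), lnls),
                    t = setNames(runif(length(arcs)), arcs),
                    p_late = runif(1), t_max = sample(2:6, 1))
  list(graph = g, params = p)
}

# Bernoulli observation toy: a single level, one time-step always taken,
# perfect modality, so P(involved) = b and the cohort likelihood is
# b^n_pos * (1-b)^(n - n_pos) -- conjugate to a uniform prior on b.
bernoulli_toy <- function(n_pos, n) {
  g <- spread_graph("A")
  coh <- data.frame(patient_id = sprintf("p%d", seq_len(n)),
                    t_category = "early",
                    pathology_A = rep(c(1, 0), c(n_pos, n - n_pos)),
                    stringsAsFactors = FALSE)
  list(graph = g, cohort = coh, p_early = 1, t_max = 1)
}
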