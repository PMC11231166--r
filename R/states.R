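#' Enumerate the hidden-state space
#'
#' The hidden state of a patient is a binary vector over the V lymph node
#' levels (0 = healthy, 1 = involved, including occult disease).  States are
#' enumerated in binary counting order with the first listed level as the
#' most significant bit, so index 1 is the all-healthy state and index
#' `2^V` the all-involved state.
#'
#' @param V Number of levels (1 to 12), or a [spread_graph()] whose levels
#'   are used (their labels become the column names).
#' @return An object of class `state_space`: a list with `V`, `n_states`
#'   and `states`, a `2^V x V` 0/1 integer matrix with one row per state.
#' @export
#' @examples
#' enumerate_states(2)$states
enumerate_states <- function(V) {
  labels <- NULL
  if (inherits(V, "spread_graph")) {
    labels <- V$lnl_names
    V <- length(labels)
  }
  V <- as.integer(V)
  if (is.na(V) || V < 1 || V > 12)
    stop("`V` must be an integer between 1 and 12")
  n <- 2L^V
  states <- matrix(0L, n, V)
  for (v in seq_len(V))
    states[, v] <- bitwAnd(bitwShiftR(0:(n - 1L), V - v), 1L)
  colnames(states) <- labels %||% paste0("L", seq_len(V))
  structure(list(V = V, n_states = n, states = states),
            class = "state_space")
}

#' Index of a hidden state
#'
#' @param state_space A [enumerate_states()] object.
#' @param state 0/1 vector of length V.
#' @return 1-based index of `state` in the enumeration.
#' @export
state_index <- function(state_space, state) {
  stopifnot(inherits(state_space, "state_space"),
            length(state) == state_space$V)
  sum(as.integer(state) * 2L^((state_space$V - 1):0)) + 1L
}

#' Per-level transition probability
#'
#' One factor of the transition kernel: the probability that level `level`
#' moves from `current` to `next_state` in one time-step, given the current
#' involvement of its parent levels.  An involved level stays involved (no
#' self-healing).  A healthy level becomes involved with probability
#' `1 - (1 - b_v) * prod over involved parents r of (1 - t_{r->v})`,
#' i.e. it escapes infection only if neither the tumor nor any involved
#' parent seeds it.
#'
#' @param graph A [spread_graph()].
#' @param params A [model_params()] for `graph`.
#' @param level Level label.
#' @param parent_states 0/1 vector over `graph_parents(graph, level)`, in
#'   that order.
#' @param current,next_state Bits (0/1) for the level's state now and after
#'   the step.
#' @return A probability.
#' @export
#' @examples
#' g <- spread_graph(c("II", "III"), "II->III")
#' p <- model_params(g, b = c(II = 0.2, III = 0.1), t = c("II->III" = 0.5),
#'                   p_late = 0.5)
#' node_transition_prob(g, p, "III", parent_states = 1,
#'                      current = 0, next_state = 1)  # b + t - b*t
node_transition_prob <- function(graph, params, level, parent_states,
                                 current, next_state) {
  stopifnot(inherits(graph, "spread_graph"), inherits(params, "model_params"))
  parents <- graph_parents(graph, level)
  if (length(parent_states) != length(parents))
    stop("`parent_states` must match the parents of ", level, ": ",
         paste(parents, collapse = ", "))
  if (!current %in% 0:1 || !next_state %in% 0:1)
    stop("`current` and `next_state` must be bits")
  if (current == 1) return(as.numeric(next_state == 1))
  q <- 1 - params$b[[level]]
  involved <- parents[parent_states == 1]
  for (r in involved) q <- q * (1 - params$t[[paste0(r, "->", level)]])
  if (next_state == 1) 1 - q else q
}

#' Build the hidden-state transition matrix
#'
#' `A[i, j] = P(X[t+1] = state_i | X[t] = state_j)`: columns index the
#' source state, rows the destination, so every column sums to one and a
#' column distribution evolves as `A %*% pi`.  Entries factorize over
#' levels via [node_transition_prob()]; the no-self-healing constraint
#' zeroes every transition that would heal a level, which makes the
#' all-involved state absorbing.
#'
#' @param graph A [spread_graph()].
#' @param params A [model_params()] for `graph`.
#' @return A `2^V x 2^V` dense matrix.
#' @export
build_transition_matrix <- function(graph, params) {
  stopifnot(inherits(graph, "spread_graph"), inherits(params, "model_params"))
  ss <- enumerate_states(graph)
  n <- ss$n_states
  bits <- ss$states
  A <- matrix(1, n, n)
  for (v in graph$lnl_names) {
    vb <- bits[, v]
    # spread probability into v from each source state
    q <- rep(1 - params$b[[v]], n)
    for (r in graph_parents(graph, v))
      q <- q * ifelse(bits[, r] == 1, 1 - params$t[[paste0(r, "->", v)]], 1)
    sp <- 1 - q
    cur <- matrix(vb, n, n, byrow = TRUE)   # source state bit
    nxt <- matrix(vb, n, n)                 # destination state bit
    spm <- matrix(sp, n, n, byrow = TRUE)
    A <- A * ifelse(cur == 1, nxt, ifelse(nxt == 1, spm, 1 - spm))
  }
  if (any(A < 0 | A > 1))
    stop("transition probabilities outside [0, 1]; check the parameters")
  dimnames(A) <- NULL
  A
}
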