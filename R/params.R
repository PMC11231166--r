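#' Model parameters for a spread graph
#'
#' Bundles the per-time-step spread probabilities with the diagnose-time
#' parameters.  `b[v]` is the probability that the tumor seeds level `v`
#' during one time-step; `t[r->v]` the probability that an involved parent
#' level `r` seeds its child `v`.  The unobserved number of time-steps
#' elapsed at diagnosis follows a binomial prior with success probability
#' `p_early` (fixed, not sampled) or `p_late` and horizon `t_max`, so its
#' mean is `t_max * p`.
#'
#' @param graph A [spread_graph()].
#' @param b Named numeric vector of tumor-spread probabilities, one entry
#'   per level of `graph`.
#' @param t Named numeric vector of inter-level spread probabilities, names
#'   `"parent->child"`, exactly matching the graph's arcs.  May be omitted
#'   for a graph without level-to-level arcs.
#' @param p_late Diagnose-time parameter for advanced (T3/T4) tumors.
#' @param p_early Diagnose-time parameter for early (T0-T2) tumors;
#'   conventionally fixed at 0.3.
#' @param t_max Latest considered time-step (integer >= 1).
#'
#' @return An object of class `model_params`.
#' @seealso [params_to_vector()], [winning_graph_params()]
#' @export
#' @examples
#' g <- spread_graph(c("A", "B"), "A->B")
#' model_params(g, b = c(A = 0.2, B = 0.1), t = c("A->B" = 0.5),
#'              p_late = 0.5)
model_params <- function(graph, b, t = numeric(), p_late,
                         p_early = 0.3, t_max = 10L) {
  stopifnot(inherits(graph, "spread_graph"))
  arcs <- arc_labels(graph$lnl_arcs)
  if (!setequal(names(b), graph$lnl_names) ||
      length(b) != length(graph$lnl_names))
    stop("`b` must have exactly one entry per level: ",
         paste(graph$lnl_names, collapse = ", "))
  if (!setequal(names(t) %||% character(), arcs) || length(t) != length(arcs))
    stop("`t` must have exactly one entry per arc: ",
         if (length(arcs)) paste(arcs, collapse = ", ") else "(no arcs)")
  b <- unlist(b)[graph$lnl_names]
  t <- if (length(arcs)) unlist(t)[arcs] else setNames(numeric(), character())
  probs <- c(b, t, p_late = p_late, p_early = p_early)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all spread and diagnose-time probabilities must lie in [0, 1]")
  t_max <- as.integer(t_max)
  if (is.na(t_max) || t_max < 1) stop("`t_max` must be an integer >= 1")
  structure(list(b = b, t = t, p_late = as.numeric(p_late),
                 p_early = as.numeric(p_early), t_max = t_max),
            class = "model_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (t_max =", x$t_max, ")\n")
  cat("  b      :", paste(sprintf("%s=%.4f", names(x$b), x$b),
                          collapse = ", "), "\n")
  if (length(x$t))
    cat("  t      :", paste(sprintf("%s=%.4f", names(x$t), x$t),
                            collapse = ", "), "\n")
  cat(sprintf("  p_early=%.4f (fixed), p_late=%.4f\n", x$p_early, x$p_late))
  invisible(x)
}

#' Flatten / rebuild the sampled parameter vector
#'
#' The sampled vector theta has length `n_params(graph)` and the fixed
#' layout of [param_names()]: tumor-spread probabilities, inter-level
#' probabilities, then `p_late`.  `p_early` and `t_max` are not sampled and
#' must be supplied when rebuilding.
#'
#' @param params A [model_params()] object.
#' @param graph A [spread_graph()].
#' @param theta Numeric vector of length `n_params(graph)`.
#' @inheritParams model_params
#' @return `params_to_vector` returns a named numeric vector;
#'   `vector_to_params` a [model_params()] object.
#' @export
params_to_vector <- function(params, graph) {
  stopifnot(inherits(params, "model_params"))
  setNames(c(params$b, params$t, params$p_late), param_names(graph))
}

#' @rdname params_to_vector
#' @export
vector_to_params <- function(theta, graph, p_early = 0.3, t_max = 10L) {
  k <- n_params(graph)
  if (length(theta) != k)
    stop("`theta` must have length ", k, " for this graph")
  V <- length(graph$lnl_names)
  arcs <- arc_labels(graph$lnl_arcs)
  model_params(graph,
               b = setNames(theta[seq_len(V)], graph$lnl_names),
               t = setNames(theta[V + seq_along(arcs)], arcs),
               p_late = theta[k], p_early = p_early, t_max = t_max)
}

#' Posterior-mean parameters of the winning graph
#'
#' Posterior means of the spread probabilities of the [winning_graph()]
#' model, estimated by ensemble MCMC from a multi-institutional cohort of
#' 686 oropharyngeal cancer patients (consensus involvement treated as the
#' true hidden state).  They are the package's reference parameter set for
#' risk prediction: e.g. the tumor seeds level II with probability 0.38 per
#' time-step, while skip metastases to III and IV are rare (small `b_III`,
#' `b_IV`) compared to stepwise spread along II->III->IV.
#'
#' @return A [model_params()] object for the winning graph
#'   (`p_early = 0.3`, `t_max = 10`).
#' @export
#' @examples
#' winning_graph_params()
winning_graph_params <- function() {
  model_params(
    winning_graph(),
    b = c(I = 0.0265, II = 0.3767, III = 0.0810,
          IV = 0.0110, V = 0.0213, VII = 0.0216),
    t = c("I->II" = 0.6676, "II->III" = 0.0949,
          "III->IV" = 0.1448, "IV->V" = 0.1457),
    p_late = 0.3834)
}

#' Read / write model parameters as a config file
#'
#' YAML (or JSON) with keys `b` (map level -> probability), `t` (map
#' `"parent->child"` -> probability), `p_late`, and optionally `p_early`
#' and `t_max`.
#'
#' @param path File path; `.json` selects JSON, anything else YAML.
#' @param graph The [spread_graph()] the parameters belong to.
#' @param params A [model_params()] object.
#' @return `read_params` returns a [model_params()]; `write_params`
#'   returns `path` invisibly.
#' @export
read_params <- function(path, graph) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  model_params(graph,
               b = unlist(spec$b),
               t = unlist(spec$t) %||% numeric(),
               p_late = spec$p_late,
               p_early = spec$p_early %||% 0.3,
               t_max = spec$t_max %||% 10L)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  spec <- list(b = as.list(params$b), t = as.list(params$t),
               p_late = params$p_late, p_early = params$p_early,
               t_max = params$t_max)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(spec, path)
  }
  invisible(path)
}
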