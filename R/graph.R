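#' Directed spread graph over lymph node levels
#'
#' A spread graph abstracts the lymphatic network of the neck: the primary
#' tumor seeds each lymph node level (LNL) directly, and involved levels can
#' seed their downstream neighbours along directed arcs.  Each arc carries a
#' per-time-step spread probability (see [model_params()]).
#'
#' Every LNL receives a direct tumor arc: levels are observed metastatic in
#' isolation, which a model without direct seeding would assign probability
#' zero.  The LNL-to-LNL arcs must form a directed acyclic graph.
#'
#' @param lnl_names Character vector of level labels in display order, e.g.
#'   `c("I", "II", "III", "IV", "V", "VII")`.  The first label maps to the
#'   most significant bit of the hidden-state index (see
#'   [enumerate_states()]).
#' @param lnl_arcs Character vector of directed level-to-level arcs written
#'   `"parent->child"` (e.g. `"II->III"`), or a two-column matrix /
#'   data.frame with columns `parent` and `child`.
#'
#' @return An object of class `spread_graph` with elements `lnl_names`,
#'   `tumor_arcs` (always all levels) and `lnl_arcs` (data.frame with
#'   columns `parent`, `child`, in the order given).
#' @seealso [base_graph()], [winning_graph()], [read_graph()]
#' @export
#' @examples
#' g <- spread_graph(c("II", "III", "IV"), c("II->III", "III->IV"))
#' graph_parents(g, "III")
spread_graph <- function(lnl_names, lnl_arcs = character()) {
  lnl_names <- as.character(lnl_names)
  if (length(lnl_names) < 1 || anyDuplicated(lnl_names))
    stop("`lnl_names` must be a non-empty set of distinct level labels")
  arcs <- parse_arcs(lnl_arcs)
  if (nrow(arcs)) {
    bad <- !(arcs$parent %in% lnl_names) | !(arcs$child %in% lnl_names)
    if (any(bad))
      stop("unknown level in arc(s): ",
           paste(arc_labels(arcs[bad, , drop = FALSE]), collapse = ", "))
    if (anyDuplicated(arc_labels(arcs)))
      stop("duplicate arcs in `lnl_arcs`")
    if (any(arcs$parent == arcs$child))
      stop("self-loop arcs are not allowed")
  }
  g <- structure(
    list(lnl_names = lnl_names,
         tumor_arcs = lnl_names,
         lnl_arcs = arcs),
    class = "spread_graph")
  assert_acyclic(g)
  g
}

parse_arcs <- function(lnl_arcs) {
  if (is.character(lnl_arcs)) {
    if (!length(lnl_arcs))
      return(data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE))
    parts <- strsplit(lnl_arcs, "->", fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("arcs must be written \"parent->child\"")
    data.frame(parent = trimws(vapply(parts, `[`, "", 1)),
               child  = trimws(vapply(parts, `[`, "", 2)),
               stringsAsFactors = FALSE)
  } else {
    arcs <- as.data.frame(lnl_arcs, stringsAsFactors = FALSE)
    if (ncol(arcs) != 2)
      stop("`lnl_arcs` must have two columns (parent, child)")
    names(arcs) <- c("parent", "child")
    arcs$parent <- as.character(arcs$parent)
    arcs$child <- as.character(arcs$child)
    arcs
  }
}

arc_labels <- function(arcs) {
  if (!nrow(arcs)) return(character())
  paste0(arcs$parent, "->", arcs$child)
}

assert_acyclic <- function(graph) {
  # Kahn's algorithm; leftover nodes imply a directed cycle
  nodes <- graph$lnl_names
  arcs <- graph$lnl_arcs
  repeat {
    indeg <- table(factor(arcs$child, levels = nodes))
    leaves <- nodes[indeg == 0]
    if (!length(leaves)) break
    nodes <- setdiff(nodes, leaves)
    arcs <- arcs[!(arcs$parent %in% leaves), , drop = FALSE]
    if (!length(nodes)) return(invisible(TRUE))
  }
  stop("the level-to-level arcs contain a cycle: ",
       paste(nodes, collapse = ", "))
}

#' @export
print.spread_graph <- function(x, ...) {
  cat("Spread graph over", length(x$lnl_names), "LNLs:",
      paste(x$lnl_names, collapse = ", "), "\n")
  cat("  tumor arcs : tumor->", paste(x$tumor_arcs, collapse = ", tumor->"),
      "\n", sep = "")
  cat("  level arcs : ",
      if (nrow(x$lnl_arcs)) paste(arc_labels(x$lnl_arcs), collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Parents of a level in a spread graph
#'
#' @param graph A [spread_graph()].
#' @param level A level label.
#' @return Character vector of parent levels (possibly empty), in arc order.
#' @export
graph_parents <- function(graph, level) {
  stopifnot(inherits(graph, "spread_graph"))
  if (!level %in% graph$lnl_names) stop("unknown level: ", level)
  graph$lnl_arcs$parent[graph$lnl_arcs$child == level]
}

#' Number of sampled parameters of a graph's model
#'
#' One tumor-spread probability per level, one spread probability per
#' level-to-level arc, plus the late-T-category diagnose-time parameter.
#' The early diagnose-time parameter is fixed, not sampled.
#'
#' @param graph A [spread_graph()].
#' @return Integer dimensionality k of the parameter space.
#' @export
n_params <- function(graph) {
  stopifnot(inherits(graph, "spread_graph"))
  length(graph$lnl_names) + nrow(graph$lnl_arcs) + 1L
}

#' Names of the sampled parameter vector
#'
#' Fixed layout used everywhere a flat parameter vector appears (MCMC,
#' thermodynamic integration): first the tumor-spread probabilities
#' `b_<level>` in `lnl_names` order, then the inter-level probabilities
#' `t_<parent>-><child>` in arc order, and finally `p_late`.
#'
#' @param graph A [spread_graph()].
#' @return Character vector of length [n_params()].
#' @export
param_names <- function(graph) {
  stopifnot(inherits(graph, "spread_graph"))
  c(paste0("b_", graph$lnl_names),
    if (nrow(graph$lnl_arcs)) paste0("t_", arc_labels(graph$lnl_arcs)),
    "p_late")
}

#' Standard spread graphs for oropharyngeal cancer
#'
#' `base_graph()` is the minimal graph for the six ipsilateral LNLs: the
#' tumor seeds every level directly, and the main lymphatic pathway is
#' represented by the arcs II->III and III->IV.  `winning_graph()` extends
#' it with the arcs I->II and IV->V, the structure selected by Bayesian
#' model comparison on a multi-institutional cohort: the extra arcs capture
#' that level I involvement almost always comes with level II involvement,
#' and that level V metastases concentrate in patients with involved level
#' IV.
#'
#' @return A [spread_graph()] over levels I, II, III, IV, V, VII.
#' @export
base_graph <- function() {
  spread_graph(c("I", "II", "III", "IV", "V", "VII"),
               c("II->III", "III->IV"))
}

#' @rdname base_graph
#' @export
winning_graph <- function() {
  spread_graph(c("I", "II", "III", "IV", "V", "VII"),
               c("I->II", "II->III", "III->IV", "IV->V"))
}

#' Read / write a spread graph as a config file
#'
#' The file maps each node to the list of its children; the tumor node is
#' keyed `tumor` and must list every level (direct tumor seeding of all
#' levels is a structural requirement of the model).  The order of the level
#' keys in the file defines `lnl_names`.  YAML (`.yml`/`.yaml`) and JSON
#' (`.json`) dialects are supported.
#'
#' @param path File path; format chosen from the extension.
#' @param graph A [spread_graph()] (for `write_graph`).
#' @return `read_graph` returns a [spread_graph()]; `write_graph` returns
#'   `path` invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_graph(winning_graph(), f)
#' read_graph(f)
read_graph <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$tumor))
    stop("graph file must contain a `tumor` node: ", path)
  lnls <- setdiff(names(spec), "tumor")
  missing_tumor <- setdiff(lnls, unlist(spec$tumor))
  if (length(missing_tumor))
    stop("every level needs a direct tumor arc; missing: ",
         paste(missing_tumor, collapse = ", "))
  extra <- setdiff(unlist(spec$tumor), lnls)
  if (length(extra))
    stop("tumor arc to unknown level: ", paste(extra, collapse = ", "))
  arcs <- do.call(rbind, lapply(lnls, function(p) {
    ch <- unlist(spec[[p]])
    if (length(ch)) data.frame(parent = p, child = as.character(ch),
                               stringsAsFactors = FALSE)
  }))
  if (is.null(arcs))
    arcs <- data.frame(parent = character(), child = character())
  spread_graph(lnls, arcs)
}

#' @rdname read_graph
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "spread_graph"))
  spec <- c(list(tumor = as.list(graph$tumor_arcs)),
            setNames(lapply(graph$lnl_names, function(p) {
              as.list(graph$lnl_arcs$child[graph$lnl_arcs$parent == p])
            }), graph$lnl_names))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(spec, path, auto_unbox = FALSE)
  } else {
    yaml::write_yaml(spec, path)
  }
  invisible(path)
}
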