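#' Read and write patient cohorts
#'
#' The native cohort dialect is a flat CSV with one row per patient: a
#' `patient_id` column, a `t_category` column, and one `<modality>_<level>`
#' column per reported modality and level (e.g. `CT_II`,
#' `pathology_IV`) holding `0` (healthy), `1` (metastatic) or an empty cell
#' (unknown — such levels are marginalized by the likelihood).  T-category
#' is binarized at ingest: values `early`/`late` are kept, T-stages
#' `T0`-`T2` (or `0`-`2`) map to `early` and `T3`/`T4` (or `3`/`4`) to
#' `late`.
#'
#' @param path CSV file path.
#' @param cohort A cohort data.frame.
#' @return `read_cohort` returns the cohort data.frame (unknowns as `NA`);
#'   `write_cohort` writes unknowns as empty cells and returns `path`
#'   invisibly.  The two are inverse to each other.
#' @export
#' @examples
#' coh <- simulate_cohort(winning_graph(), winning_graph_params(),
#'                        n = 5, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_cohort(coh, f)
#' identical(read_cohort(f)$t_category, coh$t_category)
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  if (!"t_category" %in% names(df))
    stop("cohort file lacks a `t_category` column: ", path)
  df$t_category <- map_t_category(df$t_category)
  status_cols <- setdiff(names(df), c("patient_id", "t_category"))
  for (col in status_cols) {
    x <- trimws(df[[col]])
    x[x == ""] <- NA
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & (is.na(num) | !(num %in% c(0, 1))))
    if (length(bad))
      stop("unparseable status in column ", col, ", row(s) ",
           paste(head(bad), collapse = ", "), " of ", path)
    df[[col]] <- num
  }
  df
}

map_t_category <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("early", "late")] <- x[x %in% c("early", "late")]
  stage <- suppressWarnings(as.integer(sub("^[Tt]", "", x)))
  out[is.na(out) & !is.na(stage) & stage %in% 0:2] <- "early"
  out[is.na(out) & !is.na(stage) & stage %in% 3:4] <- "late"
  bad <- which(is.na(out))
  if (length(bad))
    stop("unparseable `t_category` value(s) in row(s) ",
         paste(head(bad), collapse = ", "), ": ",
         paste(head(unique(x[bad])), collapse = ", "))
  out
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Simulate a cohort from the generative model
#'
#' Draws patients exactly as the model assumes they arise: a T-category
#' (late with probability `fraction_late`), a diagnose time from the
#' matching binomial prior, a hidden involvement state evolved from
#' all-healthy through `t_D` Markov steps of the spread process, and an
#' observed diagnosis produced by corrupting the hidden state with the
#' modality's sensitivity and specificity.
#'
#' @inheritParams cohort_log_likelihood
#' @param n Number of patients.
#' @param fraction_late Probability of the late T-category (default 0.5).
#' @param seed Integer seed; the same seed reproduces the same cohort.
#' @return A cohort data.frame with columns `patient_id`, `t_category` and
#'   `<mod$name>_<level>`.  The generating diagnose times (never used by
#'   inference) are attached as attribute `"t_diagnosis"`, and provenance
#'   (`"source"`, `"seed"`) as attributes.
#' @export
#' @examples
#' simulate_cohort(winning_graph(), winning_graph_params(), n = 3, seed = 42)
simulate_cohort <- function(graph, params, n, fraction_late = 0.5,
                            mod = modality("pathology"), seed = 1L) {
  stopifnot(inherits(graph, "spread_graph"), inherits(params, "model_params"),
            inherits(mod, "modality"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("`n` must be a positive integer")
  if (fraction_late < 0 || fraction_late > 1)
    stop("`fraction_late` must lie in [0, 1]")
  set.seed(seed)
  lnls <- graph$lnl_names
  V <- length(lnls)
  late <- runif(n) < fraction_late
  t_d <- rbinom(n, params$t_max, ifelse(late, params$p_late, params$p_early))
  X <- matrix(0L, n, V, dimnames = list(NULL, lnls))
  for (step in seq_len(max(t_d, 0))) {
    active <- t_d >= step
    if (!any(active)) break
    Xold <- X
    for (v in lnls) {
      q <- rep(1 - params$b[[v]], n)
      for (r in graph_parents(graph, v))
        q <- q * ifelse(Xold[, r] == 1L,
                        1 - params$t[[paste0(r, "->", v)]], 1)
      newly <- active & Xold[, v] == 0L & (runif(n) < 1 - q)
      X[newly, v] <- 1L
    }
  }
  p_obs1 <- ifelse(X == 1L, mod$sensitivity, 1 - mod$specificity)
  Z <- matrix(as.integer(runif(n * V) < p_obs1), n, V)
  colnames(Z) <- paste0(mod$name, "_", lnls)
  cohort <- data.frame(patient_id = sprintf("S%05d", seq_len(n)),
                       t_category = ifelse(late, "late", "early"),
                       Z, check.names = FALSE, stringsAsFactors = FALSE)
  attr(cohort, "t_diagnosis") <- t_d
  attr(cohort, "source") <- "simulated"
  attr(cohort, "seed") <- seed
  cohort
}

#' Per-level consensus across diagnostic modalities
#'
#' Combines conflicting modality reports into a single ternary consensus
#' per level and patient: a pathology report, when present, is taken as
#' the truth and overrules everything else; otherwise the consensus is the
#' state (healthy/metastatic) maximizing the product over reporting
#' modalities of `P(report | state)` under the registry's sensitivities
#' and specificities.  Exact likelihood ties resolve to metastatic (the
#' clinically conservative choice).  Levels reported by no modality stay
#' unknown.  The result is invariant to the order of the modality columns.
#'
#' @param cohort A cohort data.frame with `<modality>_<level>` columns.
#' @param registry Modality registry data.frame (see
#'   [default_modalities()]).
#' @return The cohort with one `consensus_<level>` column added (or
#'   replaced) per level found in the modality columns.
#' @export
resolve_consensus <- function(cohort, registry = default_modalities()) {
  cols <- parse_modality_columns(names(cohort), registry$name)
  if (!nrow(cols)) stop("no `<modality>_<level>` columns found")
  lnls <- unique(cols$level)
  for (lnl in lnls) {
    mods <- cols[cols$level == lnl, , drop = FALSE]
    cons <- rep(NA_real_, nrow(cohort))
    l1 <- rep(1, nrow(cohort))  # product of P(report | involved)
    l0 <- rep(1, nrow(cohort))  # product of P(report | healthy)
    any_report <- rep(FALSE, nrow(cohort))
    path_val <- rep(NA_real_, nrow(cohort))
    for (i in seq_len(nrow(mods))) {
      z <- cohort[[mods$column[i]]]
      have <- !is.na(z)
      if (mods$modality[i] %in% c("pathology", "consensus")) {
        path_val[have & is.na(path_val)] <- z[have & is.na(path_val)]
        next
      }
      reg <- registry[registry$name == mods$modality[i], ]
      l1[have] <- l1[have] * ifelse(z[have] == 1, reg$sensitivity,
                                    1 - reg$sensitivity)
      l0[have] <- l0[have] * ifelse(z[have] == 1, 1 - reg$specificity,
                                    reg$specificity)
      any_report <- any_report | have
    }
    cons[any_report] <- as.numeric(l1[any_report] >= l0[any_report])
    cons[!is.na(path_val)] <- path_val[!is.na(path_val)]
    cohort[[paste0("consensus_", lnl)]] <- cons
  }
  cohort
}

parse_modality_columns <- function(col_names, modality_names) {
  out <- do.call(rbind, lapply(col_names, function(cn) {
    for (m in modality_names) {
      prefix <- paste0(m, "_")
      if (startsWith(cn, prefix))
        return(data.frame(column = cn, modality = m,
                          level = substring(cn, nchar(prefix) + 1),
                          stringsAsFactors = FALSE))
    }
    NULL
  }))
  if (is.null(out))
    data.frame(column = character(), modality = character(),
               level = character(), stringsAsFactors = FALSE)
  else out
}

#' Convert a three-row-header involvement table to the flat dialect
#'
#' Public lymphatic-progression datasets ship as CSVs with a three-row
#' header (`top,middle,field`), e.g. `patient,#,id`, `tumor,1,t_stage`,
#' `<modality>,ipsi,<level>`.  This converter flattens such a table into
#' the native cohort dialect: ipsilateral modality columns become
#' `<modality>_<level>`, `t_stage` is binarized to `t_category`, and a
#' patient identifier column is carried over when present.
#'
#' @param path CSV file with a three-row header.
#' @param modalities Modality names to extract (default: the registry
#'   names plus `diagnostic_consensus`, mapped to `consensus`).
#' @return A cohort data.frame in the native dialect.
#' @export
read_lydata <- function(path,
                        modalities = c(default_modalities()$name,
                                       "diagnostic_consensus")) {
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character")
  if (nrow(raw) < 4) stop("expected a three-row header plus data: ", path)
  hdr <- lapply(1:3, function(i) trimws(as.character(raw[i, ])))
  body <- raw[-(1:3), , drop = FALSE]
  out <- data.frame(row.names = seq_len(nrow(body)))
  id_col <- which(hdr[[3]] == "id")[1]
  out$patient_id <- if (!is.na(id_col)) body[[id_col]]
                    else sprintf("P%05d", seq_len(nrow(body)))
  t_col <- which(hdr[[3]] == "t_stage")[1]
  if (is.na(t_col)) stop("no `t_stage` field in header: ", path)
  out$t_category <- map_t_category(body[[t_col]])
  for (j in seq_along(hdr[[1]])) {
    top <- hdr[[1]][j]
    if (!(top %in% modalities) || hdr[[2]][j] != "ipsi") next
    name <- if (top == "diagnostic_consensus") "consensus" else top
    x <- trimws(body[[j]])
    x[x %in% c("", "NA", "None")] <- NA
    x[tolower(x) %in% c("true", "t")] <- "1"
    x[tolower(x) %in% c("false", "f")] <- "0"
    num <- suppressWarnings(as.numeric(x))
    if (any(!is.na(x) & is.na(num)))
      stop("unparseable involvement value(s) in column ", j, " of ", path)
    out[[paste0(name, "_", hdr[[3]][j])]] <- num
  }
  rownames(out) <- NULL
  out
}
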