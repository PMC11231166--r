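#' Diagnostic modalities and their observation model
#'
#' A modality links the hidden involvement of a level to its observed
#' status through sensitivity `s_N = P(Z=1 | X=1)` and specificity
#' `s_P = P(Z=0 | X=0)`.  `modality(name)` looks the pair up in the
#' built-in registry of literature values (percent):
#'
#' | modality  | specificity | sensitivity |
#' |-----------|------------:|------------:|
#' | CT        | 76          | 81          |
#' | PET       | 86          | 79          |
#' | MRI       | 63          | 81          |
#' | FNA       | 98          | 80          |
#' | pathology | 100         | 100         |
#' | consensus | 100         | 100         |
#'
#' `pathology` (and its alias `consensus`, the per-level consensus of all
#' available modalities) is treated as an observation of the true hidden
#' state.  Model fitting conventionally uses this perfect modality, while
#' risk prediction for a new patient uses the imperfect clinical modality
#' that produced the diagnosis.
#'
#' @param name Modality name; free-form when both `sensitivity` and
#'   `specificity` are given, otherwise a registry name.
#' @param sensitivity,specificity Probabilities in `[0, 1]`; override the
#'   registry.
#' @return An object of class `modality` with fields `name`, `sensitivity`,
#'   `specificity`.
#' @export
#' @examples
#' modality("CT")
#' modality("scan", sensitivity = 0.9, specificity = 0.7)
modality <- function(name, sensitivity = NULL, specificity = NULL) {
  if (is.null(sensitivity) != is.null(specificity))
    stop("give both `sensitivity` and `specificity`, or neither")
  if (is.null(sensitivity)) {
    reg <- default_modalities()
    row <- reg[reg$name == name, ]
    if (!nrow(row))
      stop("unknown modality \"", name, "\"; registry has: ",
           paste(reg$name, collapse = ", "))
    sensitivity <- row$sensitivity
    specificity <- row$specificity
  }
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1)
    stop("sensitivity and specificity must lie in [0, 1]")
  structure(list(name = name, sensitivity = sensitivity,
                 specificity = specificity),
            class = "modality")
}

#' @export
print.modality <- function(x, ...) {
  cat(sprintf("Modality \"%s\": sensitivity %.2f, specificity %.2f\n",
              x$name, x$sensitivity, x$specificity))
  invisible(x)
}

#' @rdname modality
#' @return `default_modalities` returns the registry as a data.frame with
#'   columns `name`, `specificity`, `sensitivity`.
#' @export
default_modalities <- function() {
  data.frame(
    name        = c("CT", "PET", "MRI", "FNA", "pathology", "consensus"),
    specificity = c(0.76, 0.86, 0.63, 0.98, 1.00, 1.00),
    sensitivity = c(0.81, 0.79, 0.81, 0.80, 1.00, 1.00),
    stringsAsFactors = FALSE)
}

#' Observation matrix of a modality
#'
#' `B[k, l] = P(Z = diagnosis_l | X = state_k)`: the probability of each
#' complete diagnosis given each hidden state, a product over levels of the
#' 2x2 confusion table `[[s_P, 1-s_N], [1-s_P, s_N]]` (rows: hidden 0/1).
#' Rows sum to one; a perfect modality gives the identity.
#'
#' @param mod A [modality()].
#' @param state_space An [enumerate_states()] object (diagnoses are
#'   enumerated like hidden states).
#' @return A `2^V x 2^V` matrix, rows = hidden states, columns = diagnoses.
#' @export
build_observation_matrix <- function(mod, state_space) {
  stopifnot(inherits(mod, "modality"), inherits(state_space, "state_space"))
  bits <- state_space$states
  n <- state_space$n_states
  B <- matrix(1, n, n)
  for (v in seq_len(state_space$V)) {
    x <- matrix(bits[, v], n, n)           # hidden bit (rows)
    z <- matrix(bits[, v], n, n, byrow = TRUE)  # observed bit (cols)
    B <- B * ifelse(x == 1,
                    ifelse(z == 1, mod$sensitivity, 1 - mod$sensitivity),
                    ifelse(z == 1, 1 - mod$specificity, mod$specificity))
  }
  B
}

#' Observation probabilities of a (possibly incomplete) diagnosis
#'
#' Probability of observing `diagnosis` from each hidden state; levels with
#' `NA` status contribute no factor, which marginalizes them exactly (the
#' two completions of an unknown level always sum to one).
#'
#' @param diagnosis Named 0/1/NA vector over the state space's levels (a
#'   full or partial clinical N-stage pattern).
#' @inheritParams build_observation_matrix
#' @return Numeric vector of length `2^V` over hidden states.
#' @export
diagnosis_obs_probs <- function(diagnosis, mod, state_space) {
  stopifnot(inherits(mod, "modality"), inherits(state_space, "state_space"))
  lnls <- colnames(state_space$states)
  diagnosis <- as_diagnosis(diagnosis, lnls)
  p <- rep(1, state_space$n_states)
  for (v in lnls) {
    z <- diagnosis[[v]]
    if (is.na(z)) next
    x <- state_space$states[, v]
    p <- p * ifelse(x == 1,
                    if (z == 1) mod$sensitivity else 1 - mod$sensitivity,
                    if (z == 1) 1 - mod$specificity else mod$specificity)
  }
  p
}

# normalize a user diagnosis to a named 0/1/NA vector over `lnls`;
# levels not mentioned are treated as unknown
as_diagnosis <- function(diagnosis, lnls) {
  if (!length(diagnosis))
    return(setNames(rep(NA_real_, length(lnls)), lnls))
  if (is.null(names(diagnosis))) {
    if (length(diagnosis) != length(lnls))
      stop("unnamed diagnosis must cover all levels: ",
           paste(lnls, collapse = ", "))
    names(diagnosis) <- lnls
  }
  unknown <- setdiff(names(diagnosis), lnls)
  if (length(unknown))
    stop("diagnosis refers to unknown level(s): ",
         paste(unknown, collapse = ", "))
  out <- setNames(rep(NA_real_, length(lnls)), lnls)
  out[names(diagnosis)] <- as.numeric(diagnosis)
  bad <- !is.na(out) & !(out %in% c(0, 1))
  if (any(bad))
    stop("diagnosis status must be 0, 1 or NA (levels: ",
         paste(lnls[bad], collapse = ", "), ")")
  out
}
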