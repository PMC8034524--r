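#' @import methods
#' @importFrom stats setNames
NULL

#' Parameter model: values, probability groups and rates
#'
#' Holds the named parameters of a machine: a (possibly partial) numeric
#' assignment, the constraint partition into mutually exclusive probability
#' groups (each group sums to 1), non-negative rate parameters, and free
#' parameters (everything else).
#'
#' @slot values Named numeric vector of assigned parameter values
#'   (unassigned parameters stay symbolic and are simply absent).
#' @slot probGroups List of character vectors; disjoint groups each
#'   constrained to sum to 1.
#' @slot rates Character vector of rate (non-negative) parameter names.
#' @export
setClass("ParamModel", representation(
  values = "numeric",
  probGroups = "list",
  rates = "character"))

#' @param values Named numeric vector of parameter assignments.
#' @param probGroups List of character vectors (probability groups).
#' @param rates Character vector of rate parameter names.
#' @return A `ParamModel` object.
#' @rdname ParamModel-class
#' @export
ParamModel <- function(values = numeric(0), probGroups = list(),
                       rates = character(0)) {
  if (length(values) && is.null(names(values)))
    stop("parameter values must be named")
  new("ParamModel", values = values,
      probGroups = lapply(probGroups, as.character),
      rates = as.character(rates))
}

validParamModel <- function(object) {
  errs <- character(0)
  groups <- object@probGroups
  all.grouped <- unlist(groups)
  if (anyDuplicated(all.grouped))
    errs <- c(errs, "probability groups are not disjoint")
  if (length(intersect(all.grouped, object@rates)))
    errs <- c(errs, "a parameter appears in both a probability group and rates")
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    if (all(g %in% names(object@values))) {
      s <- sum(object@values[g])
      if (abs(s - 1) > 1e-9)
        errs <- c(errs, sprintf(
          "probability group %d sums to %.12g, not 1 (tolerance 1e-9)", i, s))
    }
  }
  neg <- names(object@values)[object@values < 0 |
                              !is.finite(object@values)]
  if (length(neg))
    errs <- c(errs, paste0("parameter(s) not finite non-negative: ",
                           paste(neg, collapse = ", ")))
  if (length(errs)) errs else TRUE
}
setValidity("ParamModel", validParamModel)

#' Weighted finite-state machine
#'
#' A machine is a tuple of an input alphabet, an output alphabet, an ordered
#' non-empty list of states (the first is the start state, the last the end
#' state; they coincide only for a single-state machine), a set of weighted
#' transitions labelled with input and/or output symbols (either label may
#' be the empty string epsilon), and a parameter model.  A machine defines a
#' weight for every (input sequence, output sequence) pair: the total weight
#' of all start-to-end transition paths whose label projections equal the
#' pair.  A machine with an empty input alphabet is a generator; with an
#' empty output alphabet, a recognizer.
#'
#' @slot inputAlphabet Character vector of input symbols (may be empty).
#' @slot outputAlphabet Character vector of output symbols (may be empty).
#' @slot states Character vector of state identifiers, in order.
#' @slot transitions A data.frame with columns `from`, `input`, `output`,
#'   `to` (character; `NA` for an epsilon label) and `weight` (list of
#'   `WeightExpr`).
#' @slot params A [ParamModel].
#' @export
setClass("Machine", representation(
  inputAlphabet = "character",
  outputAlphabet = "character",
  states = "character",
  transitions = "data.frame",
  params = "ParamModel"))

emptyTransitions <- function() {
  data.frame(from = character(0), input = character(0),
             output = character(0), to = character(0),
             weight = I(list()), stringsAsFactors = FALSE)
}

#' Build a transition table
#'
#' Convenience constructor for the transition data.frame consumed by
#' [Machine()].  `NA` in `input` or `output` denotes epsilon.
#'
#' @param from,to Character vectors of state ids.
#' @param input,output Character vectors of symbols, `NA` for epsilon.
#' @param weight List of weight expressions, or a numeric vector.
#' @return A transitions data.frame.
#' @export
transitionTable <- function(from, to, input = NA, output = NA, weight = 1) {
  n <- max(length(from), length(to), length(input), length(output))
  from <- rep_len(as.character(from), n)
  to <- rep_len(as.character(to), n)
  input <- rep_len(as.character(input), n)
  output <- rep_len(as.character(output), n)
  if (!is.list(weight)) weight <- as.list(rep_len(weight, n))
  else if (length(weight) != n) weight <- rep_len(weight, n)
  weight <- lapply(weight, asWeight)
  data.frame(from = from, input = input, output = output, to = to,
             weight = I(weight), stringsAsFactors = FALSE)
}

#' Construct a machine
#'
#' @param states Character vector of state ids; the first is the start
#'   state, the last the end state.
#' @param transitions A data.frame as built by [transitionTable()] (or a
#'   list of such data.frames, which are row-bound).
#' @param inputAlphabet,outputAlphabet Character vectors of symbols.
#' @param params A [ParamModel].
#' @param check If `TRUE` (default), stop if [validateMachine()] reports
#'   violations.
#' @return A `Machine`.
#' @examples
#' m <- Machine(states = c("s", "e"),
#'              transitions = transitionTable("s", "e", "A", "A", 1),
#'              inputAlphabet = "A", outputAlphabet = "A")
#' machineStats(m)
#' @export
Machine <- function(states, transitions = emptyTransitions(),
                    inputAlphabet = character(0),
                    outputAlphabet = character(0),
                    params = ParamModel(), check = TRUE) {
  if (is.list(transitions) && !is.data.frame(transitions))
    transitions <- do.call(rbind, transitions)
  if (is.null(transitions) || nrow(transitions) == 0L)
    transitions <- emptyTransitions()
  transitions$weight <- I(lapply(transitions$weight, asWeight))
  rownames(transitions) <- NULL
  m <- new("Machine", inputAlphabet = as.character(inputAlphabet),
           outputAlphabet = as.character(outputAlphabet),
           states = as.character(states),
           transitions = transitions, params = params)
  if (check) {
    v <- validateMachine(m)
    if (length(v)) stop("invalid machine:\n  ", paste(v, collapse = "\n  "))
  }
  m
}

#' Machine accessors
#'
#' @param m A [Machine].
#' @return `inputAlphabet`/`outputAlphabet`: character vectors of symbols;
#'   `machineStates`: the ordered state ids; `transitions`: the transition
#'   data.frame; `machineParams`: the [ParamModel]; `startState`/`endState`:
#'   single state ids; `isGenerator`/`isRecognizer`: logicals.
#' @name machine-accessors
NULL

#' @rdname machine-accessors
#' @export
inputAlphabet <- function(m) m@inputAlphabet

#' @rdname machine-accessors
#' @export
outputAlphabet <- function(m) m@outputAlphabet

#' @rdname machine-accessors
#' @export
machineStates <- function(m) m@states

#' @rdname machine-accessors
#' @export
transitions <- function(m) m@transitions

#' @rdname machine-accessors
#' @export
machineParams <- function(m) m@params

#' @rdname machine-accessors
#' @export
startState <- function(m) m@states[1L]

#' @rdname machine-accessors
#' @export
endState <- function(m) m@states[length(m@states)]

#' @rdname machine-accessors
#' @export
isGenerator <- function(m) length(m@inputAlphabet) == 0L

#' @rdname machine-accessors
#' @export
isRecognizer <- function(m) length(m@outputAlphabet) == 0L

#' Set parameter values on a machine
#'
#' @param m A [Machine].
#' @param values Named numeric vector; merged over existing assignments.
#' @return The machine with updated parameter values.
#' @export
setParams <- function(m, values) {
  v <- m@params@values
  v[names(values)] <- values
  m@params@values <- v
  validObject(m@params)
  m
}

#' Validate a machine
#'
#' Checks every structural invariant and returns a character vector of
#' violation descriptions; a valid machine yields `character(0)`.  Checked:
#' non-empty state list; unique state ids; transition endpoints name
#' declared states; non-epsilon labels belong to the corresponding
#' alphabets; every referenced parameter appears in the parameter model
#' (assigned, or declared in a probability group or as a rate); parameter
#' model consistency.
#'
#' @param m A [Machine].
#' @return Character vector of violations (empty if valid).
#' @export
validateMachine <- function(m) {
  errs <- character(0)
  if (length(m@states) == 0L) {
    return("machine has no states")
  }
  if (anyDuplicated(m@states))
    errs <- c(errs, "duplicate state identifiers")
  if (anyDuplicated(m@inputAlphabet))
    errs <- c(errs, "duplicate input alphabet symbols")
  if (anyDuplicated(m@outputAlphabet))
    errs <- c(errs, "duplicate output alphabet symbols")
  tr <- m@transitions
  bad <- which(!(tr$from %in% m@states))
  for (i in bad)
    errs <- c(errs, sprintf(
      "transition %d: source state '%s' is not declared", i, tr$from[i]))
  bad <- which(!(tr$to %in% m@states))
  for (i in bad)
    errs <- c(errs, sprintf(
      "transition %d: destination state '%s' is not declared", i, tr$to[i]))
  bad <- which(!is.na(tr$input) & !(tr$input %in% m@inputAlphabet))
  for (i in bad)
    errs <- c(errs, sprintf(
      "transition %d: input label '%s' not in input alphabet", i, tr$input[i]))
  bad <- which(!is.na(tr$output) & !(tr$output %in% m@outputAlphabet))
  for (i in bad)
    errs <- c(errs, sprintf(
      "transition %d: output label '%s' not in output alphabet", i,
      tr$output[i]))
  declared <- c(names(m@params@values), unlist(m@params@probGroups),
                m@params@rates)
  for (i in seq_len(nrow(tr))) {
    missing <- setdiff(weightParams(tr$weight[[i]]), declared)
    if (length(missing))
      errs <- c(errs, sprintf(
        "transition %d: weight references undeclared parameter(s) %s", i,
        paste(missing, collapse = ", ")))
  }
  pv <- validParamModel(m@params)
  if (!isTRUE(pv)) errs <- c(errs, pv)
  errs
}

## Cheap structural validity only; the full invariant check is
## validateMachine(), invoked by the Machine() constructor.  Algebra
## constructors create many intermediate machines, so new() must stay
## inexpensive.
setValidity("Machine", function(object) {
  if (length(object@states) == 0L) return("machine has no states")
  need <- c("from", "input", "output", "to", "weight")
  if (!all(need %in% names(object@transitions)))
    return("transition table must have columns from, input, output, to, weight")
  TRUE
})

#' Machine size summary
#'
#' Counts states, transitions and IO-conditioned transitions (those carrying
#' a non-epsilon label on both tapes), the reporting convention used for
#' describing model complexity.
#'
#' @param m A [Machine].
#' @return A list with elements `nStates`, `nTransitions`,
#'   `nIoConditioned`.
#' @export
machineStats <- function(m) {
  tr <- m@transitions
  list(nStates = length(m@states),
       nTransitions = nrow(tr),
       nIoConditioned = sum(!is.na(tr$input) & !is.na(tr$output)))
}

isSilentTr <- function(tr) is.na(tr$input) & is.na(tr$output)

setMethod("show", "Machine", function(object) {
  st <- machineStats(object)
  cat(sprintf(
    "Weighted finite-state machine: %d state%s, %d transition%s (%d IO-conditioned)\n",
    st$nStates, if (st$nStates == 1) "" else "s",
    st$nTransitions, if (st$nTransitions == 1) "" else "s",
    st$nIoConditioned))
  fmtAlpha <- function(a) if (length(a)) paste(a, collapse = "") else "(empty)"
  cat("  input alphabet:  ", fmtAlpha(object@inputAlphabet), "\n")
  cat("  output alphabet: ", fmtAlpha(object@outputAlphabet), "\n")
  cat("  start: ", startState(object), "  end: ", endState(object), "\n")
  np <- length(unique(c(names(object@params@values),
                        unlist(object@params@probGroups),
                        object@params@rates)))
  if (np) cat("  parameters: ", np, "\n")
  invisible(object)
})

setMethod("show", "ParamModel", function(object) {
  cat("ParamModel:", length(object@values), "assigned value(s),",
      length(object@probGroups), "probability group(s),",
      length(object@rates), "rate(s)\n")
  invisible(object)
})

## Merge the parameter models of two machines (shared names must agree).
mergeParams <- function(p1, p2) {
  v <- p1@values
  for (nm in names(p2@values)) {
    if (nm %in% names(v) && abs(v[[nm]] - p2@values[[nm]]) > 1e-12)
      stop("parameter '", nm, "' has conflicting values in the two machines")
    v[nm] <- p2@values[[nm]]
  }
  groups <- p1@probGroups
  for (g in p2@probGroups) {
    if (!any(vapply(groups, function(h) setequal(h, g), logical(1))))
      groups <- c(groups, list(g))
  }
  ParamModel(values = v, probGroups = groups,
             rates = union(p1@rates, p2@rates))
}

## Rename states (used by algebra constructions); ids map old -> new.
renameStates <- function(m, map) {
  m@states <- unname(map[m@states])
  if (nrow(m@transitions)) {
    m@transitions$from <- unname(map[m@transitions$from])
    m@transitions$to <- unname(map[m@transitions$to])
  }
  m
}

## Split a sequence argument into a character vector of single symbols.
## Accepts a single string, a character vector of symbols, or "" / NULL /
## character(0) for the empty sequence.
asSymbols <- function(x) {
  if (is.null(x)) return(character(0))
  x <- as.character(x)
  if (length(x) == 1L) {
    if (!nzchar(x)) return(character(0))
    return(strsplit(x, "", fixed = TRUE)[[1L]])
  }
  x
}
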