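# Random machine fixtures, generated under the caller's RNG state.  All
# random machines keep the silent subgraph acyclic (silent transitions
# only go to strictly later states) so the Forward precondition holds by
# construction.

# General random transducer: nStates states, random labelled transitions,
# weights in (0.1, 1).  acyclic = TRUE restricts every transition to go
# strictly forward in state order, which bounds path (and label) lengths.
randomMachine <- function(nStates = 4, inAlpha = c("a", "b"),
                          outAlpha = c("x", "y"), nTrans = 3 * nStates,
                          acyclic = FALSE) {
  states <- paste0("s", seq_len(nStates))
  rows <- list()
  pick <- function(v) v[sample.int(length(v), 1L)]
  for (k in seq_len(nTrans)) {
    if (acyclic && nStates < 2) break
    f <- if (acyclic) sample.int(nStates - 1L, 1L) else sample.int(nStates, 1L)
    t <- if (acyclic) pick(seq(f + 1L, nStates)) else sample.int(nStates, 1L)
    kinds <- c(if (length(inAlpha) && length(outAlpha)) "both",
               if (length(inAlpha)) "in",
               if (length(outAlpha)) "out",
               if (t > f) "silent")
    kind <- pick(kinds)
    inSym <- if (kind %in% c("both", "in")) pick(inAlpha) else NA
    outSym <- if (kind %in% c("both", "out")) pick(outAlpha) else NA
    rows[[length(rows) + 1L]] <- wfst::transitionTable(
      states[f], states[t], inSym, outSym, stats::runif(1, 0.1, 1))
  }
  wfst::Machine(states, rows, inAlpha, outAlpha, check = FALSE)
}

# Random recognizer (empty output tape).
randomRecognizer <- function(nStates = 4, alphabet = c("a", "b"),
                             nTrans = 3 * nStates, acyclic = TRUE) {
  randomMachine(nStates, inAlpha = alphabet, outAlpha = character(0),
                nTrans = nTrans, acyclic = acyclic)
}

# Random substochastic generator: per-state outgoing weights rescaled to a
# random total below 1, so prefix search is exact on it.
randomSubstochasticGenerator <- function(nStates = 4, alphabet = c("x", "y"),
                                         nTrans = 3 * nStates) {
  m <- randomMachine(nStates, inAlpha = character(0), outAlpha = alphabet,
                     nTrans = nTrans, acyclic = TRUE)
  tr <- wfst::transitions(m)
  w <- vapply(tr$weight, wfst::evaluateWeight, numeric(1))
  for (s in wfst::machineStates(m)) {
    idx <- which(tr$from == s)
    if (!length(idx)) next
    target <- stats::runif(1, 0.4, 0.95)
    tr$weight[idx] <- lapply(w[idx] / sum(w[idx]) * target, wfst::wConst)
  }
  wfst::Machine(wfst::machineStates(m), tr, character(0), alphabet,
                check = FALSE)
}

# Random weight expression tree of bounded depth over the given parameter
# names; leaning on operations that keep values positive so evaluation
# stays in-domain at the test point.
randomWeightExpr <- function(depth, paramNames) {
  if (depth <= 0 || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.5 && length(paramNames))
      return(wfst::wParam(sample(paramNames, 1L)))
    return(wfst::wConst(round(stats::runif(1, 0.1, 2), 3)))
  }
  op <- sample(c("sum", "prod", "diffp", "quot", "pow", "exp", "log"), 1L)
  a <- randomWeightExpr(depth - 1L, paramNames)
  b <- randomWeightExpr(depth - 1L, paramNames)
  switch(op,
    sum = wfst::wSum(a, b),
    prod = wfst::wProd(a, b),
    diffp = wfst::wDiff(wfst::wSum(a, 3), b),  # keep the result positive
    quot = wfst::wQuot(a, wfst::wSum(b, 0.5)),
    pow = wfst::wPow(wfst::wSum(a, 0.1), wfst::wConst(sample(1:3, 1L))),
    exp = wfst::wExp(wfst::wProd(a, 0.3)),
    log = wfst::wLog(wfst::wSum(a, 1.5)))
}

# The three-state generator used for EM parameter-recovery tests: state s
# emits a symbol from one distribution (or stops), state m replies with a
# symbol from a second distribution.
emRecoveryMachine <- function(pA = 0.7, qA = 0.2, cont = 0.8) {
  wfst::Machine(
    c("s", "m", "e"),
    list(
      wfst::transitionTable("s", "m", NA, c("A", "B"),
        list(wfst::wProd(wfst::wParam("cont"), wfst::wParam("pA")),
             wfst::wProd(wfst::wParam("cont"), wfst::wParam("pB")))),
      wfst::transitionTable("m", "s", NA, c("A", "B"),
        list(wfst::wParam("qA"), wfst::wParam("qB"))),
      wfst::transitionTable("s", "e", NA, NA, list(wfst::wParam("stop")))),
    character(0), c("A", "B"),
    wfst::ParamModel(
      values = c(pA = pA, pB = 1 - pA, qA = qA, qB = 1 - qA,
                 cont = cont, stop = 1 - cont),
      probGroups = list(c("pA", "pB"), c("qA", "qB"), c("cont", "stop"))))
}

# Two-output mixture generator: "AC" with weight wAC, "GG" with 1 - wAC;
# substochastic and normalized, used by decoding and sampling tests.
mixtureGenerator <- function(wAC = 0.6) {
  wfst::Machine(c("s", "p", "q", "e"), list(
    wfst::transitionTable("s", "p", NA, "A", wAC),
    wfst::transitionTable("p", "e", NA, "C", 1),
    wfst::transitionTable("s", "q", NA, "G", 1 - wAC),
    wfst::transitionTable("q", "e", NA, "G", 1)),
    character(0), c("A", "C", "G"))
}

randomStringOver <- function(alphabet, maxLen) {
  n <- sample(0:maxLen, 1L)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
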