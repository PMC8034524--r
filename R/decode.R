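## Searching for high-weight output sequences.  A search hypothesis is an
## output prefix together with the log-weights, per machine state, of all
## paths consistent with that prefix; its score is the log-sum-exp of the
## state weights.  On a substochastic machine (per-state outgoing weight
## sums <= 1) the score can only decrease as the prefix is extended, so it
## is an admissible bound and best-first expansion (prefix search) is
## exact.  Beam search keeps the top-W prefixes per output length, summing
## over paths like CTC decoding rather than following a single Viterbi
## path.

## Generator view of a machine: if an input sequence is supplied, compose
## a generator of that sequence onto the input tape; the result emits the
## machine's outputs for that fixed input.
generatorView <- function(m, x, params) {
  if (!is.null(x) && length(m@inputAlphabet)) {
    m <- composeMachines(seqGenerator(x, alphabet = m@inputAlphabet), m)
  } else if (!isGenerator(m)) {
    stop("machine has a non-empty input alphabet; supply the input sequence x")
  }
  compileMachine(m, params)
}

checkSubstochastic <- function(cm) {
  sums <- tapply(exp(cm$logw), factor(cm$from, levels = seq_len(cm$n)), sum,
                 default = 0)
  bad <- which(sums > 1 + 1e-9)
  if (length(bad))
    stop("machine is not substochastic: state '",
         cm$machine@states[bad[1L]], "' has outgoing weight sum ",
         format(sums[bad[1L]]))
}

## Initial hypothesis state-weight vector: start state, silent-closed.
initStateWeights <- function(cm) {
  v <- rep(-Inf, cm$n)
  v[1L] <- 0
  silentClose(cm, v)
}

silentClose <- function(cm, v) {
  for (t in cm$silentOrder) {
    src <- v[cm$from[t]]
    if (src > -Inf) {
      d <- cm$to[t]
      v[d] <- logaddexp(v[d], src + cm$logw[t])
    }
  }
  v
}

## Extend a hypothesis by one output symbol (index into the output
## alphabet), returning the new silent-closed state-weight vector.
extendStateWeights <- function(cm, v, sym) {
  v2 <- rep(-Inf, cm$n)
  emit <- which(cm$outIdx == sym)
  for (t in emit) {
    src <- v[cm$from[t]]
    if (src > -Inf) {
      d <- cm$to[t]
      v2[d] <- logaddexp(v2[d], src + cm$logw[t])
    }
  }
  silentClose(cm, v2)
}

hypScore <- function(v) {
  mx <- max(v)
  if (mx == -Inf) -Inf else mx + log(sum(exp(v - mx)))
}

defaultMaxLen <- function(cm, x) 2L * (length(asSymbols(x)) + 1L) * cm$n

#' Exact best-output search (prefix search)
#'
#' Finds the output sequence maximizing the total (Forward) weight
#' `Forward(m, x, y)` by best-first expansion of output prefixes.  Each
#' hypothesis carries per-state accumulated weights; its score (log-sum-exp
#' over states) cannot increase under extension because the machine is
#' required to be substochastic, so the search is exact.  Ties are broken
#' toward the lexicographically smallest output.
#'
#' @param m A [Machine].
#' @param x Input sequence, or `NULL` for a generator.
#' @param params Parameter assignments.
#' @param maxLen Maximum output length searched (default
#'   `2 * (|x| + 1) * nStates`, a safety bound).
#' @return A list with `output` (string), `logWeight`, and `found`
#'   (`FALSE` when no output has positive weight within `maxLen`, in which
#'   case `output` is `NA`).
#' @export
prefixSearch <- function(m, x = NULL, params = machineParams(m),
                         maxLen = NULL) {
  cm <- generatorView(m, x, params)
  checkSubstochastic(cm)
  if (is.null(maxLen)) maxLen <- defaultMaxLen(cm, x)
  alpha <- cm$machine@outputAlphabet
  nsym <- length(alpha)
  prefixes <- list(character(0))
  weights <- list(initStateWeights(cm))
  scores <- hypScore(weights[[1L]])
  bestW <- -Inf
  bestOut <- NULL
  while (length(scores)) {
    top <- which(scores == max(scores))
    if (length(top) > 1L) {
      strs <- vapply(prefixes[top], paste, character(1), collapse = "")
      top <- top[order(strs)[1L]]
    }
    p <- prefixes[[top]]; v <- weights[[top]]; sc <- scores[top]
    prefixes <- prefixes[-top]; weights <- weights[-top]
    scores <- scores[-top]
    if (sc < bestW - 1e-12) break
    cw <- v[cm$endIdx]
    if (cw > bestW + 1e-12 ||
        (cw > bestW - 1e-12 && !is.null(bestOut) &&
         paste(p, collapse = "") < paste(bestOut, collapse = ""))) {
      bestW <- cw
      bestOut <- p
    }
    if (length(p) >= maxLen) next
    for (s in seq_len(nsym)) {
      v2 <- extendStateWeights(cm, v, s)
      sc2 <- hypScore(v2)
      if (sc2 == -Inf || sc2 < bestW - 1e-12) next
      prefixes[[length(prefixes) + 1L]] <- c(p, alpha[s])
      weights[[length(weights) + 1L]] <- v2
      scores <- c(scores, sc2)
    }
  }
  if (is.null(bestOut) || bestW == -Inf)
    return(list(output = NA_character_, logWeight = -Inf, found = FALSE))
  list(output = paste(bestOut, collapse = ""), logWeight = bestW,
       found = TRUE)
}

#' Beam-search decoding
#'
#' Breadth-synchronous (by output length) heuristic search keeping the top
#' `width` output-prefix hypotheses per length.  Hypotheses with identical
#' output prefixes are merged by summing state weights, so the search sums
#' over paths per label sequence (CTC-style decoding) rather than tracking
#' a single best path.  As `width` grows the result approaches
#' [prefixSearch()] (and equals it on substochastic machines once every
#' live prefix is kept).
#'
#' @inheritParams prefixSearch
#' @param width Beam width (>= 1).
#' @return A list with `output`, `logWeight`, `found`, as for
#'   [prefixSearch()].
#' @export
beamSearch <- function(m, x = NULL, params = machineParams(m),
                       width = 5L, maxLen = NULL) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("beam width must be >= 1")
  cm <- generatorView(m, x, params)
  if (is.null(maxLen)) maxLen <- defaultMaxLen(cm, x)
  alpha <- cm$machine@outputAlphabet
  nsym <- length(alpha)
  hyps <- list(list(prefix = character(0), v = initStateWeights(cm)))
  bestW <- hyps[[1L]]$v[cm$endIdx]
  bestOut <- if (bestW > -Inf) character(0) else NULL
  len <- 0L
  while (length(hyps) && len < maxLen) {
    len <- len + 1L
    children <- list()
    sc <- numeric(0)
    for (h in hyps) for (s in seq_len(nsym)) {
      v2 <- extendStateWeights(cm, h$v, s)
      s2 <- hypScore(v2)
      if (s2 == -Inf) next
      children[[length(children) + 1L]] <-
        list(prefix = c(h$prefix, alpha[s]), v = v2)
      sc <- c(sc, s2)
    }
    if (!length(children)) break
    strs <- vapply(children, function(h) paste(h$prefix, collapse = ""),
                   character(1))
    keep <- order(-sc, strs)[seq_len(min(width, length(children)))]
    hyps <- children[keep]
    for (h in hyps) {
      cw <- h$v[cm$endIdx]
      out <- paste(h$prefix, collapse = "")
      if (cw > bestW + 1e-12 ||
          (cw > bestW - 1e-12 && cw > -Inf &&
           (is.null(bestOut) || out < paste(bestOut, collapse = ""))))
        { bestW <- cw; bestOut <- h$prefix }
    }
  }
  if (is.null(bestOut) || bestW == -Inf)
    return(list(output = NA_character_, logWeight = -Inf, found = FALSE))
  list(output = paste(bestOut, collapse = ""), logWeight = bestW,
       found = TRUE)
}

#' Sample output sequences by weight
#'
#' Draws i.i.d. output sequences with probability proportional to their
#' total path weight, by exact backward-weighted transition sampling: the
#' tail weight `Z[s]` (total weight of all accepting continuations from
#' state `s`) is obtained by solving the linear system `Z = A Z + stop`,
#' and transitions are drawn with probability `w * Z[to] / Z[from]`.
#' Requires a (sub)stochastic machine whose tail weights converge and whose
#' end state is reachable from every retained state.
#'
#' @inheritParams prefixSearch
#' @param n Number of samples.
#' @param seed Integer seed; the sample list is reproducible given the
#'   seed.
#' @return Character vector of `n` output strings.
#' @export
sampleOutputs <- function(m, x = NULL, params = machineParams(m), n = 1L,
                          seed = NULL) {
  cm <- generatorView(m, x, params)
  checkSubstochastic(cm)
  ns <- cm$n
  A <- matrix(0, ns, ns)
  for (t in seq_len(cm$nt))
    A[cm$from[t], cm$to[t]] <- A[cm$from[t], cm$to[t]] + exp(cm$logw[t])
  stop.vec <- numeric(ns)
  stop.vec[cm$endIdx] <- 1
  Z <- tryCatch(solve(diag(ns) - A, stop.vec), error = function(e)
    stop("tail weights do not converge; machine is not normalizable for sampling"))
  if (any(Z < -1e-12) || Z[1L] <= 0)
    stop("end state unreachable or non-convergent tail weights; cannot sample")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  byState <- split(seq_len(cm$nt), factor(cm$from, levels = seq_len(ns)))
  out <- character(n)
  for (k in seq_len(n)) {
    s <- 1L
    syms <- character(0)
    steps <- 0L
    repeat {
      steps <- steps + 1L
      if (steps > 1e6) stop("sampling walk exceeded 1e6 steps")
      ts <- byState[[s]]
      w <- exp(cm$logw[ts]) * Z[cm$to[ts]]
      if (s == cm$endIdx) w <- c(w, 1)       # stop option
      pick <- sample.int(length(w), 1L, prob = w)
      if (s == cm$endIdx && pick == length(w)) break
      t <- ts[pick]
      if (cm$outIdx[t] > 0L)
        syms <- c(syms, cm$machine@outputAlphabet[cm$outIdx[t]])
      s <- cm$to[t]
    }
    out[k] <- paste(syms, collapse = "")
  }
  out
}

#' Best-path transduction of an input sequence
#'
#' Viterbi decoding with a free output tape: finds the single
#' highest-weight transition path whose input projection equals `x` (the
#' output is unconstrained) and returns its output projection.  This is
#' the natural way to run a deterministic or unambiguous transducer
#' forwards (encoding) and, applied to the transpose, backwards
#' (decoding).  The input-epsilon subgraph must be acyclic so the output
#' length is bounded.
#'
#' @param m A [Machine].
#' @param x Input sequence.
#' @param params Parameter assignments.
#' @return A list with `output` (string), `logWeight` and `path` (the
#'   traversed transition rows); `logWeight` is `-Inf` with `output = NA`
#'   when no path consumes `x`.
#' @export
bestTransduction <- function(m, x, params = machineParams(m)) {
  cm <- compileMachine(m, params)
  m <- cm$machine
  xi <- symbolIndices(x, m@inputAlphabet, "input")
  nx <- length(xi)
  ns <- cm$n
  epsIn <- which(cm$inIdx == 0L)
  ord <- topoStateOrder(ns, cm$from[epsIn], cm$to[epsIn])
  if (is.null(ord))
    stop("input-epsilon transitions form a cycle; output length is unbounded")
  pos <- match(seq_len(ns), ord)
  epsIn <- epsIn[order(pos[cm$from[epsIn]])]
  consume <- which(cm$inIdx > 0L)
  V <- matrix(-Inf, nx + 1L, ns)
  BP <- matrix(0L, nx + 1L, ns)
  for (i in 0:nx) {
    v <- rep(-Inf, ns)
    b <- integer(ns)
    if (i == 0L) v[1L] <- 0
    if (i > 0L) for (t in consume) {
      if (cm$inIdx[t] != xi[i]) next
      src <- V[i, cm$from[t]]
      if (src == -Inf) next
      cand <- src + cm$logw[t]
      if (cand > v[cm$to[t]]) { v[cm$to[t]] <- cand; b[cm$to[t]] <- t }
    }
    for (t in epsIn) {
      src <- v[cm$from[t]]
      if (src == -Inf) next
      cand <- src + cm$logw[t]
      if (cand > v[cm$to[t]]) { v[cm$to[t]] <- cand; b[cm$to[t]] <- t }
    }
    V[i + 1L, ] <- v
    BP[i + 1L, ] <- b
  }
  best <- V[nx + 1L, cm$endIdx]
  if (best == -Inf)
    return(list(output = NA_character_, logWeight = -Inf,
                path = m@transitions[0, ]))
  path <- integer(0)
  i <- nx; s <- cm$endIdx
  repeat {
    t <- BP[i + 1L, s]
    if (t == 0L) break
    path <- c(t, path)
    if (cm$inIdx[t] > 0L) i <- i - 1L
    s <- cm$from[t]
  }
  outs <- cm$outIdx[path]
  list(output = paste(m@outputAlphabet[outs[outs > 0L]], collapse = ""),
       logWeight = best, path = m@transitions[path, , drop = FALSE])
}

## Kahn topological order over edges (f[i] -> t[i]) on nStates vertices;
## NULL if cyclic.  Stable (lowest index first).
topoStateOrder <- function(nStates, f, t) {
  indeg <- integer(nStates)
  for (v in t) indeg[v] <- indeg[v] + 1L
  adj <- split(t, factor(f, levels = seq_len(nStates)))
  avail <- which(indeg == 0L)
  ord <- integer(0)
  while (length(avail)) {
    u <- avail[1L]; avail <- avail[-1L]
    ord <- c(ord, u)
    for (v in adj[[u]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) avail <- sort(c(avail, v))
    }
  }
  if (length(ord) != nStates) NULL else ord
}
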