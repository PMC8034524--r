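## Dynamic programming over (machine, input sequence, output sequence).
## All recurrences run in natural-log space with log-sum-exp accumulation;
## zero weight is the -Inf sentinel.  The DP table is the full
## (|x|+1) x (|y|+1) x |states| array; cells are filled in lexicographic
## (i, j) order, and within a cell silent transitions are applied in
## topological state order, which is why the silent subgraph must be
## acyclic (see toposortSilent).

logaddexp <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log(exp(a - m) + exp(b - m))
}

## Evaluate transition weights numerically and index states/symbols.
## Returns the machine re-sorted so the silent subgraph is topological.
compileMachine <- function(m, params = machineParams(m)) {
  m <- ensureSilentOrder(m)
  tr <- m@transitions
  n <- length(m@states)
  nt <- nrow(tr)
  from <- match(tr$from, m@states)
  to <- match(tr$to, m@states)
  inIdx <- match(tr$input, m@inputAlphabet)   # NA for epsilon
  outIdx <- match(tr$output, m@outputAlphabet)
  inIdx[is.na(tr$input)] <- 0L
  outIdx[is.na(tr$output)] <- 0L
  if (anyNA(inIdx) || anyNA(outIdx))
    stop("transition label not in alphabet; validate the machine")
  logw <- vapply(tr$weight, function(e)
    log(evaluateWeight(e, params)), numeric(1))
  silent <- inIdx == 0L & outIdx == 0L
  sOrd <- which(silent)[order(from[silent])]
  list(machine = m, n = n, nt = nt, from = from, to = to,
       inIdx = inIdx, outIdx = outIdx, logw = logw,
       silent = silent, silentOrder = sOrd,
       endIdx = n)
}

symbolIndices <- function(seq, alphabet, tape) {
  s <- asSymbols(seq)
  idx <- match(s, alphabet)
  if (anyNA(idx))
    stop(tape, " sequence contains symbol(s) not in the ", tape,
         " alphabet: ", paste(unique(s[is.na(idx)]), collapse = ", "))
  idx
}

## Core DP.  mode "sum" for Forward, "max" for Viterbi (with backpointers).
dpTable <- function(cm, xi, yi, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  nx <- length(xi); ny <- length(yi); n <- cm$n
  F <- array(-Inf, dim = c(nx + 1L, ny + 1L, n))
  bp <- if (mode == "max") array(0L, dim = c(nx + 1L, ny + 1L, n)) else NULL
  consuming <- which(!cm$silent)
  for (i in 0:nx) for (j in 0:ny) {
    v <- rep(-Inf, n)
    b <- integer(n)
    if (i == 0L && j == 0L) v[1L] <- 0
    for (t in consuming) {
      di <- as.integer(cm$inIdx[t] > 0L)
      dj <- as.integer(cm$outIdx[t] > 0L)
      if (di > i || dj > j) next
      if (di == 1L && cm$inIdx[t] != xi[i]) next
      if (dj == 1L && cm$outIdx[t] != yi[j]) next
      src <- F[i - di + 1L, j - dj + 1L, cm$from[t]]
      if (src == -Inf) next
      cand <- src + cm$logw[t]
      d <- cm$to[t]
      if (mode == "sum") v[d] <- logaddexp(v[d], cand)
      else if (cand > v[d]) { v[d] <- cand; b[d] <- t }
    }
    for (t in cm$silentOrder) {
      src <- v[cm$from[t]]
      if (src == -Inf) next
      cand <- src + cm$logw[t]
      d <- cm$to[t]
      if (mode == "sum") v[d] <- logaddexp(v[d], cand)
      else if (cand > v[d]) { v[d] <- cand; b[d] <- t }
    }
    F[i + 1L, j + 1L, ] <- v
    if (mode == "max") bp[i + 1L, j + 1L, ] <- b
  }
  list(F = F, bp = bp)
}

## Backward table: B[i+1, j+1, s] = log weight of all paths from state s,
## having consumed (i, j), to acceptance at the end state with everything
## consumed.
dpBackward <- function(cm, xi, yi) {
  nx <- length(xi); ny <- length(yi); n <- cm$n
  B <- array(-Inf, dim = c(nx + 1L, ny + 1L, n))
  consuming <- which(!cm$silent)
  revSilent <- rev(cm$silentOrder)
  for (i in nx:0) for (j in ny:0) {
    v <- rep(-Inf, n)
    if (i == nx && j == ny) v[cm$endIdx] <- 0
    for (t in consuming) {
      di <- as.integer(cm$inIdx[t] > 0L)
      dj <- as.integer(cm$outIdx[t] > 0L)
      if (i + di > nx || j + dj > ny) next
      if (di == 1L && cm$inIdx[t] != xi[i + 1L]) next
      if (dj == 1L && cm$outIdx[t] != yi[j + 1L]) next
      dst <- B[i + di + 1L, j + dj + 1L, cm$to[t]]
      if (dst == -Inf) next
      s <- cm$from[t]
      v[s] <- logaddexp(v[s], cm$logw[t] + dst)
    }
    ## silent transitions within the same cell, reverse topological order
    for (t in revSilent) {
      dst <- v[cm$to[t]]
      if (dst == -Inf) next
      s <- cm$from[t]
      v[s] <- logaddexp(v[s], cm$logw[t] + dst)
    }
    B[i + 1L, j + 1L, ] <- v
  }
  B
}

#' Forward algorithm: total path weight of a sequence pair
#'
#' Computes the natural log of the total weight of all start-to-end
#' transition paths whose input label is `x` and output label is `y`, by
#' the Forward recurrence over (input position, output position, state).
#' Runs in `O(|x| * |y| * n_transitions)` time.  A pair with no accepting
#' path has weight zero, reported as `-Inf`.
#'
#' @param m A [Machine].
#' @param x Input sequence (string or character vector; `""` for empty).
#' @param y Output sequence.
#' @param params Parameter assignments (named numeric or [ParamModel]).
#' @return A list of class `DPResult` with element `logWeight`.
#' @examples
#' id <- identityMachine(c("A", "C"))
#' forwardScore(id, "AC", "AC")$logWeight   # log 1 = 0
#' forwardScore(id, "AC", "CA")$logWeight   # -Inf
#' @export
forwardScore <- function(m, x, y, params = machineParams(m)) {
  cm <- compileMachine(m, params)
  xi <- symbolIndices(x, m@inputAlphabet, "input")
  yi <- symbolIndices(y, m@outputAlphabet, "output")
  tab <- dpTable(cm, xi, yi, mode = "sum")
  lw <- tab$F[length(xi) + 1L, length(yi) + 1L, cm$endIdx]
  structure(list(logWeight = lw), class = "DPResult")
}

#' Viterbi algorithm: best single path for a sequence pair
#'
#' Same recurrence as [forwardScore()] with max in place of sum; recovers
#' one maximizing path by traceback.  Ties are broken toward the transition
#' earliest in the machine's transition table, so results are
#' deterministic.
#'
#' @inheritParams forwardScore
#' @return A list of class `DPResult` with elements `bestLogWeight` and
#'   `bestPath` (a data.frame of traversed transition rows, in order;
#'   empty if no accepting path exists, in which case `bestLogWeight`
#'   is `-Inf`).
#' @export
viterbiPath <- function(m, x, y, params = machineParams(m)) {
  cm <- compileMachine(m, params)
  m <- cm$machine
  xi <- symbolIndices(x, m@inputAlphabet, "input")
  yi <- symbolIndices(y, m@outputAlphabet, "output")
  tab <- dpTable(cm, xi, yi, mode = "max")
  nx <- length(xi); ny <- length(yi)
  best <- tab$F[nx + 1L, ny + 1L, cm$endIdx]
  path <- integer(0)
  if (best > -Inf) {
    i <- nx; j <- ny; s <- cm$endIdx
    repeat {
      t <- tab$bp[i + 1L, j + 1L, s]
      if (t == 0L) break
      path <- c(t, path)
      if (!cm$silent[t]) {
        i <- i - as.integer(cm$inIdx[t] > 0L)
        j <- j - as.integer(cm$outIdx[t] > 0L)
      }
      s <- cm$from[t]
    }
  }
  structure(list(bestLogWeight = best,
                 bestPath = m@transitions[path, , drop = FALSE]),
            class = "DPResult")
}

#' Forward-Backward: expected transition counts and parameter gradients
#'
#' Computes, for a sequence pair, the posterior expected number of uses of
#' every transition over accepting paths, and the raw derivatives of the
#' total pair weight with respect to every assigned parameter (assembled
#' from expected transition flows and the symbolic derivatives of the
#' weight expressions).  All transition weights must be numeric under
#' `params`.
#'
#' @inheritParams forwardScore
#' @return A list of class `DPResult` with `logWeight`, `expectedCounts`
#'   (numeric, one entry per transition row) and `gradients` (named
#'   numeric, the derivative of the pair weight w.r.t. each assigned
#'   parameter).
#' @export
forwardBackward <- function(m, x, y, params = machineParams(m)) {
  cm <- compileMachine(m, params)
  m <- cm$machine
  xi <- symbolIndices(x, m@inputAlphabet, "input")
  yi <- symbolIndices(y, m@outputAlphabet, "output")
  nx <- length(xi); ny <- length(yi)
  F <- dpTable(cm, xi, yi, mode = "sum")$F
  B <- dpBackward(cm, xi, yi)
  logZ <- F[nx + 1L, ny + 1L, cm$endIdx]
  ## Per-transition flow G_t = log sum over cells of F[src cell, from] +
  ## B[dst cell, to], EXCLUDING the transition weight itself.
  G <- rep(-Inf, cm$nt)
  for (t in seq_len(cm$nt)) {
    di <- as.integer(cm$inIdx[t] > 0L)
    dj <- as.integer(cm$outIdx[t] > 0L)
    if (nx - di < 0L || ny - dj < 0L) { G[t] <- -Inf; next }
    acc <- -Inf
    for (i in 0:(nx - di)) for (j in 0:(ny - dj)) {
      if (di == 1L && cm$inIdx[t] != xi[i + 1L]) next
      if (dj == 1L && cm$outIdx[t] != yi[j + 1L]) next
      a <- F[i + 1L, j + 1L, cm$from[t]]
      if (a == -Inf) next
      b <- B[i + di + 1L, j + dj + 1L, cm$to[t]]
      if (b == -Inf) next
      acc <- logaddexp(acc, a + b)
    }
    G[t] <- acc
  }
  counts <- exp(cm$logw + G - logZ)
  counts[!is.finite(counts)] <- 0
  vals <- paramValues(params)
  grads <- setNames(numeric(length(vals)), names(vals))
  for (t in seq_len(cm$nt)) {
    if (G[t] == -Inf) next
    refs <- weightParams(m@transitions$weight[[t]])
    for (nm in intersect(refs, names(vals))) {
      dEx <- differentiateWeight(m@transitions$weight[[t]], nm)
      dv <- evalWeightRec(dEx, vals)
      grads[nm] <- grads[nm] + dv * exp(G[t])
    }
  }
  structure(list(logWeight = logZ, expectedCounts = counts,
                 gradients = grads),
            class = "DPResult")
}

#' @export
print.DPResult <- function(x, ...) {
  for (f in names(x)) {
    if (is.data.frame(x[[f]]))
      cat(f, ": path of ", nrow(x[[f]]), " transitions\n", sep = "")
    else if (length(x[[f]]) == 1L)
      cat(f, ": ", format(x[[f]]), "\n", sep = "")
    else cat(f, ": ", paste(format(x[[f]], digits = 4), collapse = " "),
             "\n", sep = "")
  }
  invisible(x)
}

#' Constrained Baum-Welch EM parameter fitting
#'
#' Fits the probability-group parameters of a machine to a set of
#' (input, output) sequence pairs by expectation-maximization.  The E-step
#' accumulates expected transition counts with [forwardBackward()]; the
#' M-step renormalizes the accumulated counts within each probability
#' group, which is the closed-form maximizer when every trainable
#' transition weight is a monomial (a constant times a product of powers of
#' parameters).  Non-monomial trainable weights are rejected.  Rate
#' parameters are accepted in machines but are not trainable.  The total
#' log-likelihood is non-decreasing across iterations.
#'
#' @param m A [Machine] whose trainable parameters belong to probability
#'   groups of its parameter model.
#' @param data A list of pairs; each element is a list or character vector
#'   with the input sequence first and the output sequence second.
#' @param p0 Starting [ParamModel] (defaults to the machine's).
#' @param maxIters Maximum EM iterations.
#' @param tol Stop when the log-likelihood improves by less than this.
#' @return A list with `params` (fitted [ParamModel]) and `logLik`
#'   (numeric vector, total log-likelihood after each iteration).
#' @export
fitBaumWelch <- function(m, data, p0 = machineParams(m),
                         maxIters = 100L, tol = 1e-6) {
  trainable <- unlist(p0@probGroups)
  if (!length(trainable)) stop("no probability groups to train")
  tr <- m@transitions
  mono <- vector("list", nrow(tr))
  for (t in seq_len(nrow(tr))) {
    refs <- weightParams(tr$weight[[t]])
    if (!length(intersect(refs, trainable))) next
    mn <- asMonomial(tr$weight[[t]])
    if (is.null(mn))
      stop("transition ", t, " ('", tr$from[t], "' -> '", tr$to[t],
           "') has a non-monomial weight referencing trainable parameters; ",
           "closed-form EM update is not available")
    mono[[t]] <- mn
  }
  params <- p0
  ll <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(maxIters)) {
    counts <- setNames(numeric(length(trainable)), trainable)
    total <- 0
    for (k in seq_along(data)) {
      pair <- data[[k]]
      fb <- forwardBackward(m, pair[[1L]], pair[[2L]], params)
      if (fb$logWeight == -Inf)
        stop("data pair ", k, " has zero likelihood under the current parameters")
      total <- total + fb$logWeight
      for (t in seq_len(nrow(tr))) {
        mn <- mono[[t]]
        if (is.null(mn)) next
        for (nm in intersect(names(mn$powers), trainable))
          counts[nm] <- counts[nm] + mn$powers[[nm]] * fb$expectedCounts[t]
      }
    }
    ll <- c(ll, total)
    v <- params@values
    for (g in p0@probGroups) {
      gc <- counts[g]
      if (sum(gc) > 0) v[g] <- gc / sum(gc)
    }
    params@values <- v
    if (total - prev < tol && iter > 1L) break
    prev <- total
  }
  list(params = params, logLik = ll)
}
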