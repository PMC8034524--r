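# Independent brute-force oracles.  These never use the package's dynamic
# programming: sequence-pair weights are computed by depth-first
# enumeration of all labelled transition paths, so they can cross-check
# the Forward/Viterbi recurrences and the algebra constructions.

# Total weight of all start-to-end paths with input label x and output
# label y.  maxSilentRun caps consecutive silent steps (for machines with
# silent cycles this truncates the path sum; acyclic-silent machines are
# exact because a silent run cannot revisit a state).
enumForward <- function(m, x, y, params = wfst::machineParams(m),
                        maxSilentRun = 30) {
  xs <- if (is.character(x) && length(x) == 1L && nzchar(x))
    strsplit(x, "")[[1L]] else if (is.character(x) && length(x) > 1L) x
    else character(0)
  ys <- if (is.character(y) && length(y) == 1L && nzchar(y))
    strsplit(y, "")[[1L]] else if (is.character(y) && length(y) > 1L) y
    else character(0)
  tr <- wfst::transitions(m)
  w <- vapply(tr$weight, wfst::evaluateWeight, numeric(1), params = params)
  states <- wfst::machineStates(m)
  endS <- states[length(states)]
  byFrom <- split(seq_len(nrow(tr)), factor(tr$from, levels = states))
  total <- 0
  rec <- function(s, i, j, acc, silentRun) {
    if (s == endS && i == length(xs) && j == length(ys))
      total <<- total + acc
    for (t in byFrom[[s]]) {
      if (w[t] == 0) next
      di <- !is.na(tr$input[t]); dj <- !is.na(tr$output[t])
      if (di && (i >= length(xs) || xs[i + 1L] != tr$input[t])) next
      if (dj && (j >= length(ys) || ys[j + 1L] != tr$output[t])) next
      sr <- if (!di && !dj) silentRun + 1L else 0L
      if (sr > maxSilentRun) next
      rec(tr$to[t], i + di, j + dj, acc * w[t], sr)
    }
  }
  rec(states[1L], 0L, 0L, 1, 0L)
  total
}

# Best single-path weight, same enumeration.
enumViterbi <- function(m, x, y, params = wfst::machineParams(m),
                        maxSilentRun = 30) {
  xs <- if (nzchar(x[1L]) || length(x) > 1L) unlist(strsplit(x, ""))
    else character(0)
  ys <- if (nzchar(y[1L]) || length(y) > 1L) unlist(strsplit(y, ""))
    else character(0)
  tr <- wfst::transitions(m)
  w <- vapply(tr$weight, wfst::evaluateWeight, numeric(1), params = params)
  states <- wfst::machineStates(m)
  endS <- states[length(states)]
  byFrom <- split(seq_len(nrow(tr)), factor(tr$from, levels = states))
  best <- 0
  rec <- function(s, i, j, acc, silentRun) {
    if (s == endS && i == length(xs) && j == length(ys) && acc > best)
      best <<- acc
    for (t in byFrom[[s]]) {
      if (w[t] == 0) next
      di <- !is.na(tr$input[t]); dj <- !is.na(tr$output[t])
      if (di && (i >= length(xs) || xs[i + 1L] != tr$input[t])) next
      if (dj && (j >= length(ys) || ys[j + 1L] != tr$output[t])) next
      sr <- if (!di && !dj) silentRun + 1L else 0L
      if (sr > maxSilentRun) next
      rec(tr$to[t], i + di, j + dj, acc * w[t], sr)
    }
  }
  rec(states[1L], 0L, 0L, 1, 0L)
  best
}

# All strings over an alphabet with length <= maxLen (including "").
allStrings <- function(alphabet, maxLen) {
  out <- ""
  layer <- ""
  for (len in seq_len(maxLen)) {
    layer <- as.vector(outer(layer, alphabet, paste0))
    out <- c(out, layer)
  }
  out
}

# Exhaustive CTC collapse oracle: sums frame-path weights per collapsed
# label sequence for a T x (K+1) matrix (last column = blank).
ctcOracle <- function(probMatrix) {
  Tn <- nrow(probMatrix)
  syms <- colnames(probMatrix)
  blank <- "blank"
  labels <- setdiff(syms, blank)
  paths <- expand.grid(rep(list(syms), Tn), stringsAsFactors = FALSE)
  weights <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(paths))) {
    frames <- unlist(paths[r, ], use.names = FALSE)
    w <- prod(probMatrix[cbind(seq_len(Tn), match(frames, syms))])
    if (w == 0) next
    merged <- frames[c(TRUE, frames[-1L] != frames[-Tn])]
    lab <- paste(merged[merged != blank], collapse = "")
    weights[[paste0("y", lab)]] <-
      (if (is.null(weights[[paste0("y", lab)]])) 0
       else weights[[paste0("y", lab)]]) + w
  }
  out <- sapply(ls(weights), function(k) weights[[k]])
  names(out) <- sub("^y", "", names(out))
  out
}
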