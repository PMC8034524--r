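## Matrix-like and string-like operations on machines.  Viewing a machine
## as an infinite matrix indexed by (input sequence, output sequence),
## composition is matrix multiplication, addition is elementwise sum,
## intersection is the elementwise (point) product, and exchanging the
## tapes is transposition.  String-like operations (concatenation,
## reversal, reverse-complement, repetition, Kleene closure, local
## matching) treat machines as weighted languages.

prefixRename <- function(m, prefix) {
  map <- setNames(paste0(prefix, m@states), m@states)
  renameStates(m, map)
}

mulWeights <- function(a, b) simplifyWeight(wProd(a, b))

#' Compose (multiply) two machines
#'
#' Returns the machine product `TU` with `(TU)[x, z] = sum over y of
#' T[x, y] * U[y, z]`: the output tape of `t` is matched against the input
#' tape of `u`.  Composite states are (t-state, u-state) pairs with an
#' epsilon-phase flag that canonicalizes interleavings of t's output-silent
#' moves and u's input-silent moves, so each joint path is counted exactly
#' once: from phase 0 both move kinds are allowed; taking a u input-epsilon
#' move enters phase 1, where t output-epsilon moves are disallowed until a
#' synchronized symbol exchange resets phase 0.  Unreachable composite
#' states are pruned.
#'
#' @param t,u [Machine] objects with `outputAlphabet(t)` equal (as a set)
#'   to `inputAlphabet(u)`.
#' @return The composed [Machine] with input alphabet of `t` and output
#'   alphabet of `u`.
#' @examples
#' m <- composeMachines(seqGenerator("TCGA"), dnaToRna())
#' exp(forwardScore(m, "", "UCGA")$logWeight)   # 1
#' @export
composeMachines <- function(t, u) {
  if (!setequal(t@outputAlphabet, u@inputAlphabet))
    stop("output alphabet of the first machine must equal the input alphabet of the second")
  tTr <- t@transitions
  uTr <- u@transitions
  tBy <- split(seq_len(nrow(tTr)), factor(tTr$from, levels = t@states))
  uBy <- split(seq_len(nrow(uTr)), factor(uTr$from, levels = u@states))
  sid <- function(i, j, ph) paste0(i, "|", j, "|", ph)
  startId <- sid(startState(t), startState(u), 0L)
  seen <- new.env(parent = emptyenv())
  assign(startId, TRUE, envir = seen)
  order <- startId
  queue <- list(c(startState(t), startState(u), "0"))
  rows <- list()
  push <- function(i, j, ph) {
    id <- sid(i, j, ph)
    if (!exists(id, envir = seen)) {
      assign(id, TRUE, envir = seen)
      order <<- c(order, id)
      queue[[length(queue) + 1L]] <<- c(i, j, ph)
    }
    id
  }
  addRow <- function(fromId, toId, input, output, w) {
    rows[[length(rows) + 1L]] <<- transitionTable(fromId, toId, input,
                                                  output, list(w))
  }
  while (length(queue)) {
    st <- queue[[1L]]; queue <- queue[-1L]
    i <- st[1L]; j <- st[2L]; ph <- st[3L]
    here <- sid(i, j, ph)
    ti <- tBy[[i]]; uj <- uBy[[j]]
    ## synchronized exchange: t outputs b, u consumes b
    for (a in ti) {
      b <- tTr$output[a]
      if (is.na(b)) next
      for (c in uj) {
        if (is.na(uTr$input[c]) || uTr$input[c] != b) next
        dest <- push(tTr$to[a], uTr$to[c], "0")
        addRow(here, dest, tTr$input[a], uTr$output[c],
               mulWeights(tTr$weight[[a]], uTr$weight[[c]]))
      }
    }
    ## t moves with silent output (allowed only in phase 0)
    if (ph == "0") {
      for (a in ti) {
        if (!is.na(tTr$output[a])) next
        dest <- push(tTr$to[a], j, "0")
        addRow(here, dest, tTr$input[a], NA, tTr$weight[[a]])
      }
    }
    ## u moves with silent input (enter phase 1)
    for (c in uj) {
      if (!is.na(uTr$input[c])) next
      dest <- push(i, uTr$to[c], "1")
      addRow(here, dest, NA, uTr$output[c], uTr$weight[[c]])
    }
  }
  endId <- uniqueStateId("end.", order)
  for (ph in c("0", "1")) {
    id <- sid(endState(t), endState(u), ph)
    if (exists(id, envir = seen))
      rows[[length(rows) + 1L]] <- transitionTable(id, endId, NA, NA, 1)
  }
  m <- Machine(c(order, endId), rows, t@inputAlphabet, u@outputAlphabet,
               mergeParams(t@params, u@params), check = FALSE)
  tidyMachine(m)
}

#' Add two machines
#'
#' Elementwise sum in the matrix view: `Forward(t + u, x, y) =
#' Forward(t, x, y) + Forward(u, x, y)`, realized by a fresh start state
#' with silent weight-1 branches into both machines and a fresh shared end
#' state.
#'
#' @param t,u [Machine] objects with equal input alphabets and equal output
#'   alphabets.
#' @return The sum [Machine].
#' @export
addMachines <- function(t, u) {
  if (!setequal(t@inputAlphabet, u@inputAlphabet) ||
      !setequal(t@outputAlphabet, u@outputAlphabet))
    stop("machines must share input and output alphabets to be added")
  tt <- prefixRename(t, "L.")
  uu <- prefixRename(u, "R.")
  s <- "S"; e <- "E"
  rows <- list(
    tt@transitions, uu@transitions,
    transitionTable(s, startState(tt), NA, NA, 1),
    transitionTable(s, startState(uu), NA, NA, 1),
    transitionTable(endState(tt), e, NA, NA, 1),
    transitionTable(endState(uu), e, NA, NA, 1))
  m <- Machine(c(s, tt@states, uu@states, e), rows,
               t@inputAlphabet, t@outputAlphabet,
               mergeParams(t@params, u@params), check = FALSE)
  tidyMachine(m)
}

#' Intersect (point product) two machines
#'
#' Elementwise product in the matrix view: `Forward(t . u, x, y) =
#' Forward(t, x, y) * Forward(u, x, y)`.  The two machines advance in
#' lockstep on identically labelled transitions; silent moves of either
#' machine are interleaved under the same epsilon-phase canonicalization as
#' [composeMachines()].  The construction must not produce silent cycles
#' (checked).
#'
#' @param t,u [Machine] objects with equal input and output alphabets.
#' @return The intersection [Machine].
#' @export
intersectMachines <- function(t, u) {
  if (!setequal(t@inputAlphabet, u@inputAlphabet) ||
      !setequal(t@outputAlphabet, u@outputAlphabet))
    stop("machines must share input and output alphabets to be intersected")
  tTr <- t@transitions
  uTr <- u@transitions
  tBy <- split(seq_len(nrow(tTr)), factor(tTr$from, levels = t@states))
  uBy <- split(seq_len(nrow(uTr)), factor(uTr$from, levels = u@states))
  sid <- function(i, j, ph) paste0(i, "|", j, "|", ph)
  startId <- sid(startState(t), startState(u), 0L)
  seen <- new.env(parent = emptyenv())
  assign(startId, TRUE, envir = seen)
  order <- startId
  queue <- list(c(startState(t), startState(u), "0"))
  rows <- list()
  push <- function(i, j, ph) {
    id <- sid(i, j, ph)
    if (!exists(id, envir = seen)) {
      assign(id, TRUE, envir = seen)
      order <<- c(order, id)
      queue[[length(queue) + 1L]] <<- c(i, j, ph)
    }
    id
  }
  while (length(queue)) {
    st <- queue[[1L]]; queue <- queue[-1L]
    i <- st[1L]; j <- st[2L]; ph <- st[3L]
    here <- sid(i, j, ph)
    ti <- tBy[[i]]; uj <- uBy[[j]]
    for (a in ti) {
      silentA <- is.na(tTr$input[a]) && is.na(tTr$output[a])
      if (silentA) {
        if (ph == "0") {
          dest <- push(tTr$to[a], j, "0")
          rows[[length(rows) + 1L]] <- transitionTable(
            here, dest, NA, NA, list(tTr$weight[[a]]))
        }
        next
      }
      for (c in uj) {
        if (!identical(tTr$input[a], uTr$input[c]) ||
            !identical(tTr$output[a], uTr$output[c])) next
        dest <- push(tTr$to[a], uTr$to[c], "0")
        rows[[length(rows) + 1L]] <- transitionTable(
          here, dest, tTr$input[a], tTr$output[a],
          list(mulWeights(tTr$weight[[a]], uTr$weight[[c]])))
      }
    }
    for (c in uj) {
      if (!(is.na(uTr$input[c]) && is.na(uTr$output[c]))) next
      dest <- push(i, uTr$to[c], "1")
      rows[[length(rows) + 1L]] <- transitionTable(
        here, dest, NA, NA, list(uTr$weight[[c]]))
    }
  }
  endId <- uniqueStateId("end.", order)
  for (ph in c("0", "1")) {
    id <- sid(endState(t), endState(u), ph)
    if (exists(id, envir = seen))
      rows[[length(rows) + 1L]] <- transitionTable(id, endId, NA, NA, 1)
  }
  m <- Machine(c(order, endId), rows, t@inputAlphabet, t@outputAlphabet,
               mergeParams(t@params, u@params), check = FALSE)
  m <- pruneMachine(m, warn = FALSE)
  cyc <- findSilentCycle(m)
  if (!is.null(cyc))
    stop("intersection produced a silent cycle: ",
         paste(cyc, collapse = " -> "))
  ensureSilentOrder(m)
}

#' Transpose a machine
#'
#' Exchanges the input and output tapes: every transition's labels are
#' swapped and the alphabets exchanged, so `Forward(t(T), y, x) =
#' Forward(T, x, y)`.  The transpose of a generator is a recognizer and
#' vice versa.
#'
#' @param m A [Machine].
#' @return The transposed [Machine].
#' @export
transposeMachine <- function(m) {
  tr <- m@transitions
  tmp <- tr$input
  tr$input <- tr$output
  tr$output <- tmp
  new("Machine", inputAlphabet = m@outputAlphabet,
      outputAlphabet = m@inputAlphabet, states = m@states,
      transitions = tr, params = m@params)
}

#' Concatenate two machines
#'
#' Joins the end of `t` to the start of `u` by a silent weight-1
#' transition: `Forward(concat, x, y)` sums `Forward(t, x1, y1) *
#' Forward(u, x2, y2)` over all splits `x = x1 x2`, `y = y1 y2`.
#'
#' @param t,u [Machine] objects with equal input alphabets and equal output
#'   alphabets (either may be empty).
#' @return The concatenated [Machine].
#' @export
concatMachines <- function(t, u) {
  if (!setequal(t@inputAlphabet, u@inputAlphabet) ||
      !setequal(t@outputAlphabet, u@outputAlphabet))
    stop("machines must share input and output alphabets to be concatenated")
  tt <- prefixRename(t, "L.")
  uu <- prefixRename(u, "R.")
  rows <- list(tt@transitions, uu@transitions,
               transitionTable(endState(tt), startState(uu), NA, NA, 1))
  m <- Machine(c(tt@states, uu@states), rows,
               t@inputAlphabet, t@outputAlphabet,
               mergeParams(t@params, u@params), check = FALSE)
  tidyMachine(m)
}

#' Reverse a machine
#'
#' Flips every transition (source and destination exchanged, labels kept)
#' and swaps the start and end states, so `Forward(rev(t), rev(x), rev(y))
#' = Forward(t, x, y)`.
#'
#' @param m A [Machine].
#' @return The reversed [Machine].
#' @export
reverseMachine <- function(m) {
  tr <- m@transitions
  tmp <- tr$from
  tr$from <- tr$to
  tr$to <- tmp
  m@transitions <- tr
  m@states <- rev(m@states)
  if (!is.null(findSilentCycle(m))) m else ensureSilentOrder(m)
}

NUC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

complementFor <- function(alphabet) {
  if (length(alphabet) == 0L) return(NULL)
  if (all(alphabet %in% names(NUC_COMPLEMENT))) return(NUC_COMPLEMENT)
  if (all(alphabet %in% names(RNA_COMPLEMENT))) return(RNA_COMPLEMENT)
  stop("alphabet {", paste(alphabet, collapse = ","),
       "} is not nucleic; cannot reverse-complement")
}

#' Reverse-complement a machine
#'
#' Reverses the machine and substitutes Watson-Crick complements on every
#' tape whose alphabet is nucleic (DNA or RNA).  A tape with an empty
#' alphabet is left alone; a non-empty non-nucleic alphabet is an error.
#'
#' @param m A [Machine] over nucleic alphabets.
#' @return The reverse-complemented [Machine].
#' @export
reverseComplementMachine <- function(m) {
  compIn <- complementFor(m@inputAlphabet)
  compOut <- complementFor(m@outputAlphabet)
  m <- reverseMachine(m)
  tr <- m@transitions
  if (!is.null(compIn)) {
    ok <- !is.na(tr$input)
    tr$input[ok] <- unname(compIn[tr$input[ok]])
  }
  if (!is.null(compOut)) {
    ok <- !is.na(tr$output)
    tr$output[ok] <- unname(compOut[tr$output[ok]])
  }
  m@transitions <- tr
  m
}

#' Kleene closure of a machine
#'
#' Builds `t* = sum over n >= 0 of t^n` with a silent bypass (the `n = 0`
#' term) and a silent back transition from the end of `t` to its start.
#' If `t` accepts the empty pair with weight `w >= 1` the closure diverges;
#' with numeric weights this is detected (and any resulting silent cycle is
#' marginalized exactly), with symbolic weights the machine is returned
#' unguarded and divergence detection is deferred to
#' [eliminateSilentCycles()].
#'
#' @param m A [Machine].
#' @return The closure [Machine].
#' @export
kleeneStar <- function(m) {
  mm <- prefixRename(m, "M.")
  s <- "S"; e <- "E"
  rows <- list(mm@transitions,
               transitionTable(s, startState(mm), NA, NA, 1),
               transitionTable(s, e, NA, NA, 1),
               transitionTable(endState(mm), startState(mm), NA, NA, 1),
               transitionTable(endState(mm), e, NA, NA, 1))
  out <- Machine(c(s, mm@states, e), rows, m@inputAlphabet,
                 m@outputAlphabet, m@params, check = FALSE)
  numeric.wts <- all(vapply(m@transitions$weight, function(e2)
    all(weightParams(e2) %in% names(m@params@values)), logical(1)))
  if (numeric.wts) {
    eps <- exp(forwardScore(m, character(0), character(0))$logWeight)
    if (eps >= 1 - 1e-12)
      stop(sprintf(
        "Kleene closure diverges: machine accepts the empty pair with weight %.6g >= 1",
        eps))
    if (!is.null(findSilentCycle(out)))
      out <- eliminateSilentCycles(out, m@params)
  }
  tidyMachine(out)
}

#' Repeat a machine n times
#'
#' The n-fold concatenation of a machine with itself.
#'
#' @param m A [Machine].
#' @param n Positive integer repeat count.
#' @return The repeated [Machine].
#' @export
repeatMachine <- function(m, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("repeat count must be a positive integer")
  out <- m
  for (k in seq_len(n - 1L)) out <- concatMachines(out, m)
  out
}

#' Scale a machine by a scalar
#'
#' Multiplies every sequence-pair weight by `alpha`, realized by a silent
#' entry transition of weight `alpha` before the original start state.
#' `alpha` may be a non-negative number or a parameter name / weight
#' expression.
#'
#' @param alpha Non-negative numeric scalar, parameter name, or
#'   `WeightExpr`.
#' @param m A [Machine].
#' @return The scaled [Machine].
#' @export
scaleMachine <- function(alpha, m) {
  if (is.numeric(alpha) && alpha < 0) stop("scale factor must be non-negative")
  w <- asWeight(alpha)
  s <- uniqueStateId("S.", m@states)
  rows <- list(transitionTable(s, startState(m), NA, NA, list(w)),
               m@transitions)
  Machine(c(s, m@states), rows, m@inputAlphabet, m@outputAlphabet,
          m@params, check = FALSE)
}

#' Identity machine over an alphabet
#'
#' The matrix identity: `Forward(id, x, y)` is 1 when `x == y` and 0
#' otherwise.  A single state (both start and end) with one weight-1
#' self-loop `a/a` per symbol.
#'
#' @param alphabet Non-empty character vector of symbols.
#' @return The identity [Machine].
#' @export
identityMachine <- function(alphabet) {
  alphabet <- as.character(alphabet)
  if (!length(alphabet)) stop("alphabet must be non-empty")
  Machine("id", transitionTable("id", "id", alphabet, alphabet, 1),
          alphabet, alphabet)
}

#' Pad a pattern machine with wildcard flanks for local matching
#'
#' Concatenates a recognizer (or generator) between two wildcard self-loop
#' machines (weight-1 loops over every symbol of the non-empty tape), so
#' the pattern matches anywhere within a longer sequence.
#'
#' @param m A recognizer or generator (exactly one empty alphabet).
#' @return The flanked [Machine].
#' @export
localFlank <- function(m) {
  gen <- isGenerator(m)
  rec <- isRecognizer(m)
  if (gen == rec)
    stop("local matching needs a recognizer or a generator (one empty alphabet)")
  alpha <- if (rec) m@inputAlphabet else m@outputAlphabet
  wild <- Machine("w",
                  if (rec) transitionTable("w", "w", alpha, NA, 1)
                  else transitionTable("w", "w", NA, alpha, 1),
                  m@inputAlphabet, m@outputAlphabet)
  concatMachines(concatMachines(wild, m), wild)
}
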