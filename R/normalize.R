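## Transition-graph hygiene: the Forward recurrence requires the silent
## (epsilon/epsilon) subgraph to be acyclic and topologically sorted, so
## that within one dynamic-programming cell states can be filled in a single
## pass.  This file provides the sort, exact silent-cycle elimination by
## marginalization, the approximate cycle breaker, pruning, and
## probabilistic normalization.

silentEdgeIdx <- function(m) which(isSilentTr(m@transitions))

## Adjacency list of the silent subgraph over state indices.
silentAdj <- function(m) {
  n <- length(m@states)
  idx <- match(m@states, m@states)  # identity, but keeps names straight
  adj <- vector("list", n)
  tr <- m@transitions
  for (i in silentEdgeIdx(m)) {
    f <- match(tr$from[i], m@states)
    t <- match(tr$to[i], m@states)
    adj[[f]] <- c(adj[[f]], t)
  }
  adj
}

## Find one cycle in the silent subgraph, or NULL if acyclic.
findSilentCycle <- function(m) {
  n <- length(m@states)
  adj <- silentAdj(m)
  color <- integer(n)            # 0 white, 1 grey, 2 black
  parent <- integer(n)
  cyc <- NULL
  visit <- function(u, stack) {
    if (!is.null(cyc)) return()
    color[u] <<- 1L
    for (v in adj[[u]]) {
      if (!is.null(cyc)) return()
      if (color[v] == 1L) {
        pos <- match(v, stack)
        cyc <<- m@states[c(stack[pos:length(stack)], v)]
        return()
      }
      if (color[v] == 0L) visit(v, c(stack, v))
    }
    color[u] <<- 2L
  }
  for (u in seq_len(n)) if (color[u] == 0L && is.null(cyc)) visit(u, u)
  cyc
}

#' Topologically sort the silent subgraph
#'
#' Reorders states so that every silent (epsilon/epsilon) transition goes
#' from a lower to a higher state index, the precondition of the Forward
#' recurrence.  The start state stays first and the end state last; among
#' otherwise unconstrained states the prior relative order is preserved
#' (stable sort), so serialized output is reproducible.
#'
#' @param m A [Machine].
#' @return The machine with states reordered; transitions are unchanged.
#' @export
toposortSilent <- function(m) {
  cyc <- findSilentCycle(m)
  if (!is.null(cyc))
    stop("silent cycle: ", paste(cyc, collapse = " -> "))
  n <- length(m@states)
  if (n <= 2L) return(m)
  tr <- m@transitions
  sIdx <- silentEdgeIdx(m)
  if (length(sIdx)) {
    f <- match(tr$from[sIdx], m@states)
    t <- match(tr$to[sIdx], m@states)
    if (any(t == 1L))
      stop("silent transition into the start state cannot be topologically sorted with the start state first")
    if (any(f == n))
      stop("silent transition out of the end state cannot be topologically sorted with the end state last")
  }
  ## Stable Kahn's algorithm over interior states; start pinned first,
  ## end pinned last.
  indeg <- integer(n)
  adj <- silentAdj(m)
  for (u in seq_len(n)) for (v in adj[[u]]) indeg[v] <- indeg[v] + 1L
  avail <- setdiff(which(indeg == 0L), c(1L, n))
  done <- c(1L)
  for (v in adj[[1L]]) {
    indeg[v] <- indeg[v] - 1L
    if (indeg[v] == 0L && v != n) avail <- c(avail, v)
  }
  avail <- sort(unique(avail))
  while (length(avail)) {
    u <- avail[1L]            # lowest original index first: stability
    avail <- avail[-1L]
    done <- c(done, u)
    for (v in adj[[u]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L && v != n) avail <- sort(c(avail, v))
    }
  }
  done <- c(done, n)
  if (length(done) != n)
    stop("silent cycle among states: ",
         paste(m@states[setdiff(seq_len(n), done)], collapse = ", "))
  m@states <- m@states[done]
  m
}

## TRUE if state order already satisfies the silent topological property.
silentSorted <- function(m) {
  tr <- m@transitions
  idx <- silentEdgeIdx(m)
  if (!length(idx)) return(TRUE)
  f <- match(tr$from[idx], m@states)
  t <- match(tr$to[idx], m@states)
  all(f < t)
}

## Sort if needed; error (with a cycle listed) if impossible.
ensureSilentOrder <- function(m) {
  if (silentSorted(m)) m else toposortSilent(m)
}

#' Eliminate silent cycles by marginalization
#'
#' Replaces each strongly connected component of the silent subgraph by its
#' closure: if `S` is the component's silent weight matrix, every transition
#' entering a component state `i` is redistributed over component states `j`
#' with multiplier `(I - S)^(-1)[i, j]` (the geometric series over silent
#' round trips), and the intra-component silent transitions are deleted.
#' Forward weights are preserved exactly for every sequence pair.  Requires
#' numeric weights on the cyclic transitions and spectral radius of `S`
#' below 1.
#'
#' @param m A [Machine].
#' @param params Parameter assignments used to evaluate cyclic weights.
#' @return The machine, silent-acyclic and topologically sorted.
#' @export
eliminateSilentCycles <- function(m, params = machineParams(m)) {
  repeat {
    comps <- silentCycleComponents(m)
    if (!length(comps)) break
    m <- marginalizeComponent(m, comps[[1L]], params)
  }
  toposortSilent(m)
}

## List of components (integer state-index vectors) that contain a silent
## cycle: non-trivial SCCs, or single states with a silent self-loop.
silentCycleComponents <- function(m) {
  n <- length(m@states)
  tr <- m@transitions
  idx <- silentEdgeIdx(m)
  if (!length(idx)) return(list())
  f <- match(tr$from[idx], m@states)
  t <- match(tr$to[idx], m@states)
  g <- igraph::graph_from_edgelist(cbind(f, t), directed = TRUE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  memb <- igraph::components(g, mode = "strong")$membership
  out <- list()
  for (cm in unique(memb)) {
    states <- which(memb == cm)
    if (length(states) > 1L) out <- c(out, list(states))
    else if (any(f == states & t == states)) out <- c(out, list(states))
  }
  out
}

marginalizeComponent <- function(m, comp, params) {
  tr <- m@transitions
  sIdx <- silentEdgeIdx(m)
  n <- length(comp)
  compStates <- m@states[comp]
  ## silent weight matrix within the component
  S <- matrix(0, n, n, dimnames = list(compStates, compStates))
  internal <- integer(0)
  for (i in sIdx) {
    if (tr$from[i] %in% compStates && tr$to[i] %in% compStates) {
      e <- tr$weight[[i]]
      if (length(weightParams(e)))
        w <- tryCatch(evaluateWeight(e, params), error = function(err)
          stop("silent cycle through '", tr$from[i],
               "' has a symbolic weight; assign its parameters or use breakSilentCycles()"))
      else w <- evaluateWeight(e)
      S[tr$from[i], tr$to[i]] <- S[tr$from[i], tr$to[i]] + w
      internal <- c(internal, i)
    }
  }
  sr <- max(Mod(eigen(S, only.values = TRUE)$values))
  if (sr >= 1 - 1e-12)
    stop(sprintf(
      "silent cycle diverges: spectral radius %.6g >= 1 for component {%s}",
      sr, paste(compStates, collapse = ", ")))
  Cl <- solve(diag(n) - S)     # closure: entry i, exit j multipliers
  ## Redistribute every transition that ENTERS a component state (including
  ## non-silent and external ones) across the closure, then drop internal
  ## silent transitions.
  keep <- setdiff(seq_len(nrow(tr)), internal)
  newRows <- list()
  dropped <- integer(0)
  for (i in keep) {
    j <- match(tr$to[i], compStates)
    if (is.na(j)) next
    dropped <- c(dropped, i)
    for (k in seq_len(n)) {
      cw <- Cl[j, k]
      if (cw == 0) next
      w <- if (cw == 1 && j == k) tr$weight[[i]] else
        simplifyWeight(wProd(tr$weight[[i]], wConst(cw)))
      newRows[[length(newRows) + 1L]] <- transitionTable(
        tr$from[i], compStates[k], tr$input[i], tr$output[i], list(w))
    }
  }
  keep <- setdiff(keep, dropped)
  ## If the start state itself is in the component, initial mass must also
  ## be redistributed: prepend a fresh start with silent closure edges.
  extra <- list()
  states <- m@states
  if (m@states[1L] %in% compStates) {
    j <- match(m@states[1L], compStates)
    newStart <- uniqueStateId("S.", states)
    for (k in seq_len(n)) {
      cw <- Cl[j, k]
      if (cw == 0) next
      extra[[length(extra) + 1L]] <- transitionTable(
        newStart, compStates[k], NA, NA, list(wConst(cw)))
    }
    states <- c(newStart, states)
  }
  newTr <- do.call(rbind, c(list(tr[keep, , drop = FALSE]), newRows, extra))
  Machine(states, newTr, m@inputAlphabet, m@outputAlphabet, m@params,
          check = FALSE)
}

uniqueStateId <- function(prefix, existing) {
  i <- 0L
  repeat {
    id <- paste0(prefix, i)
    if (!(id %in% existing)) return(id)
    i <- i + 1L
  }
}

#' Break silent cycles by deleting back transitions
#'
#' The approximate alternative to [eliminateSilentCycles()]: silent
#' transitions from a later to an earlier (or the same) state in the current
#' ordering are deleted, in decreasing source-index order, re-checking after
#' each deletion, until the silent subgraph is acyclic.  Forward weights may
#' decrease (paths through deleted transitions are lost); the deleted
#' transitions are reported in the `"deleted"` attribute.
#'
#' @param m A [Machine].
#' @return The machine with an acyclic silent subgraph; attribute
#'   `"deleted"` holds the removed transition rows.
#' @export
breakSilentCycles <- function(m) {
  deleted <- emptyTransitions()
  repeat {
    if (is.null(findSilentCycle(m))) break
    tr <- m@transitions
    idx <- silentEdgeIdx(m)
    f <- match(tr$from[idx], m@states)
    t <- match(tr$to[idx], m@states)
    back <- idx[t <= f]
    if (!length(back))
      stop("silent cycle remains but no back transition to delete; toposort first")
    victim <- back[which.max(f[match(back, idx)])]
    deleted <- rbind(deleted, tr[victim, , drop = FALSE])
    m@transitions <- tr[-victim, , drop = FALSE]
    rownames(m@transitions) <- NULL
  }
  attr(m, "deleted") <- deleted
  m
}

#' Prune unreachable and dead-end states
#'
#' Removes states that are not reachable from the start state or cannot
#' reach the end state.  Forward weights are unchanged for every sequence
#' pair.  If the start state cannot reach the end state at all, the machine
#' is equivalent to the zero machine; a two-state machine with no
#' transitions is returned with a warning.
#'
#' @param m A [Machine].
#' @param warn Warn when the result is the zero machine.
#' @return The pruned machine.
#' @export
pruneMachine <- function(m, warn = TRUE) {
  n <- length(m@states)
  tr <- m@transitions
  f <- match(tr$from, m@states)
  t <- match(tr$to, m@states)
  reach <- function(src, fwd, bwd) {
    seen <- logical(n)
    seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nxt <- bwd[fwd == u]
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    seen
  }
  fromStart <- reach(1L, f, t)
  toEnd <- reach(n, t, f)
  keep <- fromStart & toEnd
  if (!keep[n] || !keep[1L] || !fromStart[n]) {
    if (warn) warning("start state cannot reach end state; returning the zero machine")
    zero <- Machine(states = c(m@states[1L],
                               if (n > 1L) m@states[n] else
                               uniqueStateId("end.", m@states[1L])),
                    transitions = emptyTransitions(),
                    inputAlphabet = m@inputAlphabet,
                    outputAlphabet = m@outputAlphabet,
                    params = m@params, check = FALSE)
    return(zero)
  }
  keepTr <- keep[f] & keep[t]
  m@states <- m@states[keep]
  m@transitions <- tr[keepTr, , drop = FALSE]
  rownames(m@transitions) <- NULL
  m
}

#' Normalize outgoing transition weights to probabilities
#'
#' Rescales the outgoing transition weights of each non-end state to sum
#' to 1.  All weights must be numeric.  The per-state scaling factors
#' (the original outgoing sums) are returned alongside the machine.
#'
#' @param m A [Machine] with numeric weights.
#' @param params Parameter assignments for evaluating weights.
#' @return A list with elements `machine` (the rescaled machine) and
#'   `factors` (named numeric, the original per-state outgoing sums;
#'   1 where no rescaling happened).
#' @export
normalizeProbabilistic <- function(m, params = machineParams(m)) {
  tr <- m@transitions
  w <- vapply(tr$weight, evaluateWeight, numeric(1), params = params)
  factors <- setNames(rep(1, length(m@states)), m@states)
  nonEnd <- setdiff(m@states, endState(m))
  for (s in nonEnd) {
    idx <- which(tr$from == s)
    if (!length(idx)) next
    tot <- sum(w[idx])
    if (tot <= 0)
      stop("state '", s, "' has zero total outgoing weight; cannot normalize")
    factors[s] <- tot
    for (i in idx) tr$weight[[i]] <- wConst(w[i] / tot)
  }
  m@transitions <- tr
  list(machine = m, factors = factors)
}

## Standard hygiene applied by the algebra constructors: prune silently,
## then make the silent subgraph sorted (erroring on silent cycles is left
## to the caller's context; constructors that can create silent cycles
## marginalize first when weights are numeric).
tidyMachine <- function(m) {
  m <- pruneMachine(m, warn = FALSE)
  if (is.null(findSilentCycle(m))) m <- ensureSilentOrder(m)
  m
}
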