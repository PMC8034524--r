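# Transition-graph hygiene: topological sorting, silent-cycle elimination
# (exact and approximate), pruning, probabilistic normalization.

fwd <- function(m, x, y) exp(forwardScore(m, x, y)$logWeight)

test_that("silent transitions are topologically sorted, stably", {
  m <- Machine(c("s0", "s1", "s2", "s3"), list(
    transitionTable("s0", "s2", NA, NA, 1),
    transitionTable("s2", "s1", NA, NA, 1),
    transitionTable("s1", "s3", NA, "X", 1)),
    character(0), "X", check = FALSE)
  sorted <- toposortSilent(m)
  st <- machineStates(sorted)
  expect_identical(st[1], "s0")
  expect_identical(st[4], "s3")
  expect_lt(match("s2", st), match("s1", st))
  # transitions themselves are untouched
  expect_identical(transitions(sorted), transitions(m))
  # machines without silent transitions keep their order
  id <- seqGenerator("AC")
  expect_identical(machineStates(toposortSilent(id)), machineStates(id))
})

test_that("silent cycles are detected and named", {
  m <- Machine(c("s", "a", "b", "e"), list(
    transitionTable("s", "a", NA, "X", 1),
    transitionTable("a", "b", NA, NA, 1),
    transitionTable("b", "a", NA, NA, 1),
    transitionTable("b", "e", NA, "X", 1)),
    character(0), "X", check = FALSE)
  expect_error(toposortSilent(m), "a -> b -> a|b -> a -> b")
})

test_that("a silent self-loop marginalizes to the geometric series", {
  m <- Machine(c("s", "a", "e"), list(
    transitionTable("s", "a", NA, NA, 1),
    transitionTable("a", "a", NA, NA, 0.5),
    transitionTable("a", "e", NA, "X", 1)),
    character(0), "X")
  me <- eliminateSilentCycles(m)
  expect_equal(fwd(me, "", "X"), 1 / (1 - 0.5), tolerance = 1e-12)
  expect_null(wfst:::findSilentCycle(me))
})

test_that("a two-state silent cycle marginalizes to the matrix closure", {
  m <- Machine(c("s", "a", "b", "e"), list(
    transitionTable("s", "a", NA, NA, 1),
    transitionTable("a", "b", NA, NA, 0.5),
    transitionTable("b", "a", NA, NA, 0.5),
    transitionTable("a", "e", NA, "X", 1),
    transitionTable("b", "e", NA, "Y", 1)),
    character(0), c("X", "Y"))
  me <- eliminateSilentCycles(m)
  # truncated path-sum oracle: up to 30 silent steps
  expect_equal(fwd(me, "", "X"), enumForward(m, "", "X", maxSilentRun = 60),
               tolerance = 1e-9)
  expect_equal(fwd(me, "", "Y"), enumForward(m, "", "Y", maxSilentRun = 60),
               tolerance = 1e-9)
  expect_equal(fwd(me, "", "X"), 1 / (1 - 0.25), tolerance = 1e-12)
})

test_that("divergent silent cycles raise an error", {
  m <- Machine(c("s", "a", "e"), list(
    transitionTable("s", "a", NA, NA, 1),
    transitionTable("a", "a", NA, NA, 1.0),
    transitionTable("a", "e", NA, "X", 1)),
    character(0), "X")
  expect_error(eliminateSilentCycles(m), "diverges")
  m2 <- Machine(c("s", "a", "e"), list(
    transitionTable("s", "a", NA, NA, 1),
    transitionTable("a", "a", NA, NA, list(wParam("p"))),
    transitionTable("a", "e", NA, "X", 1)),
    character(0), "X",
    ParamModel(probGroups = list("p")))
  expect_error(eliminateSilentCycles(m2), "breakSilentCycles")
})

test_that("breaking silent cycles deletes back transitions and only lowers
           Forward", {
  m <- Machine(c("s", "a", "b", "e"), list(
    transitionTable("s", "a", NA, NA, 1),
    transitionTable("a", "b", NA, NA, 0.5),
    transitionTable("b", "a", NA, NA, 0.5),
    transitionTable("a", "e", NA, "X", 1),
    transitionTable("b", "e", NA, "Y", 1)),
    character(0), c("X", "Y"))
  broken <- breakSilentCycles(m)
  expect_null(wfst:::findSilentCycle(broken))
  expect_equal(nrow(attr(broken, "deleted")), 1L)
  # acyclic machines come back unchanged
  g <- seqGenerator("ACG")
  gb <- breakSilentCycles(g)
  expect_equal(nrow(attr(gb, "deleted")), 0L)
  expect_identical(transitions(gb), transitions(g))
  # approximation property: never exceeds the exact closure
  exact <- eliminateSilentCycles(m)
  for (y in c("X", "Y"))
    expect_lte(fwd(broken, "", y), fwd(exact, "", y) + 1e-12)
})

test_that("pruning removes orphans without changing Forward", {
  m <- Machine(c("s", "mid", "orphan", "dead", "e"), list(
    transitionTable("s", "mid", NA, "X", 1),
    transitionTable("mid", "e", NA, "Y", 0.5),
    transitionTable("orphan", "e", NA, "X", 1),   # unreachable
    transitionTable("s", "dead", NA, "X", 1)),    # cannot reach end
    character(0), c("X", "Y"))
  p <- pruneMachine(m)
  expect_setequal(machineStates(p), c("s", "mid", "e"))
  for (y in c("XY", "X", "", "YX"))
    expect_equal(fwd(p, "", y), fwd(m, "", y))
  # fully live machines are unchanged
  g <- seqGenerator("AC")
  expect_identical(machineStates(pruneMachine(g)), machineStates(g))
  set.seed(83)
  for (k in seq_len(10)) {
    r <- randomMachine(5, acyclic = TRUE)
    pr <- pruneMachine(r, warn = FALSE)
    x <- randomStringOver(c("a", "b"), 3)
    y <- randomStringOver(c("x", "y"), 3)
    expect_equal(fwd(pr, x, y), fwd(r, x, y), tolerance = 1e-12)
  }
})

test_that("an unsatisfiable machine prunes to the zero machine with a
           warning", {
  m <- Machine(c("s", "e"), list(transitionTable("e", "s", NA, "X", 1)),
               character(0), "X", check = FALSE)
  expect_warning(z <- pruneMachine(m), "zero machine")
  expect_equal(fwd(z, "", ""), 0)
  expect_equal(fwd(z, "", "X"), 0)
})

test_that("probabilistic normalization rescales outgoing weights to 1", {
  m <- Machine(c("s", "e"), list(
    transitionTable("s", "e", NA, "X", 2),
    transitionTable("s", "e", NA, "Y", 6)),
    character(0), c("X", "Y"))
  r <- normalizeProbabilistic(m)
  expect_equal(fwd(r$machine, "", "X"), 0.25)
  expect_equal(fwd(r$machine, "", "Y"), 0.75)
  expect_equal(unname(r$factors["s"]), 8)
  # already-stochastic machines are unchanged, all factors 1
  r2 <- normalizeProbabilistic(r$machine)
  expect_true(all(r2$factors == 1))
  # postcondition: per-state outgoing sums are 1
  set.seed(89)
  g <- pruneMachine(randomMachine(4, acyclic = TRUE), warn = FALSE)
  rn <- normalizeProbabilistic(g)$machine
  tr <- transitions(rn)
  w <- vapply(tr$weight, evaluateWeight, numeric(1))
  for (s in setdiff(machineStates(rn), endState(rn))) {
    idx <- which(tr$from == s)
    if (length(idx)) expect_equal(sum(w[idx]), 1, tolerance = 1e-9)
  }
  # zero outgoing weight is an error
  bad <- Machine(c("s", "m", "e"), list(
    transitionTable("s", "m", NA, "X", 0),
    transitionTable("m", "e", NA, "X", 1)),
    character(0), "X")
  expect_error(normalizeProbabilistic(bad), "zero total outgoing")
})

test_that("elimination preserves Forward against the truncated-path oracle
           on random cyclic-silent machines", {
  set.seed(97)
  for (k in seq_len(6)) {
    base <- pruneMachine(randomMachine(4, acyclic = TRUE), warn = FALSE)
    st <- machineStates(base)
    if (length(st) < 3) next
    # inject a silent back edge with weight below 1
    extra <- transitionTable(st[3], st[2], NA, NA, runif(1, 0.1, 0.8))
    cyc <- Machine(st, rbind(transitions(base), extra),
                   inputAlphabet(base), outputAlphabet(base), check = FALSE)
    if (is.null(wfst:::findSilentCycle(cyc))) next
    elim <- eliminateSilentCycles(cyc)
    for (r in seq_len(4)) {
      x <- randomStringOver(c("a", "b"), 2)
      y <- randomStringOver(c("x", "y"), 2)
      expect_equal(fwd(elim, x, y),
                   enumForward(cyc, x, y, maxSilentRun = 40),
                   tolerance = 1e-8)
    }
  }
})
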