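# Matrix-like and string-like operations, checked against their defining
# identities via the path-enumeration oracle.

fwd <- function(m, x, y) exp(forwardScore(m, x, y)$logWeight)

test_that("composition reproduces the DNA-to-RNA worked example", {
  m <- composeMachines(seqGenerator("TCGA"), dnaToRna())
  expect_equal(fwd(m, "", "UCGA"), 1)
  expect_equal(fwd(m, "", "UCGG"), 0)
})

test_that("composing with the identity preserves Forward", {
  set.seed(31)
  for (k in seq_len(10)) {
    t <- randomMachine(4, inAlpha = c("a", "b"), outAlpha = c("x", "y"),
                       acyclic = TRUE)
    tc <- composeMachines(t, identityMachine(c("x", "y")))
    for (r in seq_len(5)) {
      x <- randomStringOver(c("a", "b"), 3)
      y <- randomStringOver(c("x", "y"), 3)
      expect_equal(fwd(tc, x, y), fwd(t, x, y), tolerance = 1e-9)
    }
  }
})

test_that("composition equals the matrix-product sum over intermediate
           sequences", {
  set.seed(37)
  mids <- allStrings(c("m", "n"), 6)
  for (k in seq_len(15)) {
    t <- randomMachine(sample(2:4, 1), inAlpha = c("a", "b"),
                       outAlpha = c("m", "n"), acyclic = TRUE)
    u <- randomMachine(sample(2:4, 1), inAlpha = c("m", "n"),
                       outAlpha = c("x", "y"), acyclic = TRUE)
    tu <- composeMachines(t, u)
    x <- randomStringOver(c("a", "b"), 3)
    z <- randomStringOver(c("x", "y"), 3)
    want <- sum(vapply(mids, function(y)
      enumForward(t, x, y) * enumForward(u, y, z), numeric(1)))
    expect_equal(fwd(tu, x, z), want, tolerance = 1e-9,
                 label = sprintf("case %d x='%s' z='%s'", k, x, z))
  }
})

test_that("composition is associative under Forward", {
  set.seed(41)
  for (k in seq_len(5)) {
    t <- randomMachine(3, c("a", "b"), c("m", "n"), acyclic = TRUE)
    u <- randomMachine(3, c("m", "n"), c("p", "q"), acyclic = TRUE)
    v <- randomMachine(3, c("p", "q"), c("x", "y"), acyclic = TRUE)
    left <- composeMachines(composeMachines(t, u), v)
    right <- composeMachines(t, composeMachines(u, v))
    for (r in seq_len(4)) {
      x <- randomStringOver(c("a", "b"), 2)
      z <- randomStringOver(c("x", "y"), 2)
      expect_equal(fwd(left, x, z), fwd(right, x, z), tolerance = 1e-9)
    }
  }
})

test_that("addition is elementwise and respects identities", {
  g <- addMachines(seqGenerator("A", c("A", "C")),
                   seqGenerator("C", c("A", "C")))
  expect_equal(fwd(g, "", "A"), 1)
  expect_equal(fwd(g, "", "C"), 1)
  set.seed(43)
  t <- randomMachine(4, acyclic = TRUE)
  zero <- Machine(c("s", "e"), inputAlphabet = c("a", "b"),
                  outputAlphabet = c("x", "y"))
  tz <- addMachines(t, zero)
  mix <- addMachines(scaleMachine(0.3, t), scaleMachine(0.7, t))
  for (r in seq_len(8)) {
    x <- randomStringOver(c("a", "b"), 3)
    y <- randomStringOver(c("x", "y"), 3)
    expect_equal(fwd(tz, x, y), fwd(t, x, y), tolerance = 1e-9)
    expect_equal(fwd(mix, x, y), fwd(t, x, y), tolerance = 1e-9)
  }
})

test_that("addition is commutative and associative under Forward", {
  set.seed(47)
  t <- randomMachine(3, acyclic = TRUE)
  u <- randomMachine(3, acyclic = TRUE)
  v <- randomMachine(3, acyclic = TRUE)
  ab <- addMachines(t, u); ba <- addMachines(u, t)
  l <- addMachines(addMachines(t, u), v)
  r <- addMachines(t, addMachines(u, v))
  for (k in seq_len(8)) {
    x <- randomStringOver(c("a", "b"), 3)
    y <- randomStringOver(c("x", "y"), 3)
    expect_equal(fwd(ab, x, y), fwd(ba, x, y), tolerance = 1e-9)
    expect_equal(fwd(l, x, y), fwd(r, x, y), tolerance = 1e-9)
  }
})

test_that("intersection is the pointwise product", {
  r1 <- seqRecognizer("ACG")
  expect_equal(fwd(intersectMachines(r1, seqRecognizer("ACG")), "ACG", ""), 1)
  r2 <- seqRecognizer("TTT", c("A", "C", "G", "T"))
  r3 <- seqRecognizer("ACG", c("A", "C", "G", "T"))
  both <- intersectMachines(r3, r2)
  for (x in c("ACG", "TTT", "AC"))
    expect_equal(fwd(both, x, ""), 0)
  set.seed(53)
  for (k in seq_len(10)) {
    a <- randomRecognizer(4, c("a", "b"))
    b <- randomRecognizer(4, c("a", "b"))
    ab <- intersectMachines(a, b)
    for (x in allStrings(c("a", "b"), 4))
      expect_equal(fwd(ab, x, ""),
                   enumForward(a, x, "") * enumForward(b, x, ""),
                   tolerance = 1e-9)
  }
})

test_that("transposition exchanges the tapes", {
  tg <- transposeMachine(seqGenerator("AC"))
  expect_true(isRecognizer(tg))
  expect_equal(fwd(tg, "AC", ""), 1)
  set.seed(59)
  for (k in seq_len(25)) {
    m <- randomMachine(4)
    expect_equal(fwd(transposeMachine(transposeMachine(m)), "ab", "xy"),
                 fwd(m, "ab", "xy"), tolerance = 1e-12)
    x <- randomStringOver(c("a", "b"), 3)
    y <- randomStringOver(c("x", "y"), 3)
    expect_equal(fwd(transposeMachine(m), y, x), fwd(m, x, y),
                 tolerance = 1e-12)
  }
})

test_that("concatenation splits sequences across the two machines", {
  g <- concatMachines(seqGenerator("AC", c("A", "C", "G", "T")),
                      seqGenerator("GT", c("A", "C", "G", "T")))
  expect_equal(fwd(g, "", "ACGT"), 1)
  expect_equal(fwd(g, "", "AC"), 0)
  # unit: concatenation with the empty-sequence machine
  eps <- seqGenerator("", c("A", "C", "G", "T"))
  ge <- concatMachines(seqGenerator("AC", c("A", "C", "G", "T")), eps)
  expect_equal(fwd(ge, "", "AC"), 1)
  # weights multiply across the split
  h <- concatMachines(scaleMachine(0.5, seqGenerator("A")),
                      scaleMachine(0.5, seqGenerator("A")))
  expect_equal(fwd(h, "", "AA"), 0.25)
  # oracle: all splits
  set.seed(61)
  for (k in seq_len(8)) {
    t <- randomMachine(3, acyclic = TRUE)
    u <- randomMachine(3, acyclic = TRUE)
    tu <- concatMachines(t, u)
    x <- randomStringOver(c("a", "b"), 3)
    y <- randomStringOver(c("x", "y"), 3)
    xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
    want <- 0
    for (i in 0:length(xs)) for (j in 0:length(ys)) {
      x1 <- paste(xs[seq_len(i)], collapse = "")
      x2 <- paste(xs[setdiff(seq_along(xs), seq_len(i))], collapse = "")
      y1 <- paste(ys[seq_len(j)], collapse = "")
      y2 <- paste(ys[setdiff(seq_along(ys), seq_len(j))], collapse = "")
      want <- want + enumForward(t, x1, y1) * enumForward(u, x2, y2)
    }
    expect_equal(fwd(tu, x, y), want, tolerance = 1e-9)
  }
})

test_that("reversal flips sequences", {
  g <- reverseMachine(seqGenerator("ACG"))
  expect_equal(fwd(g, "", "GCA"), 1)
  set.seed(67)
  for (k in seq_len(15)) {
    m <- randomMachine(4, acyclic = TRUE)
    rr <- reverseMachine(reverseMachine(m))
    x <- randomStringOver(c("a", "b"), 3)
    y <- randomStringOver(c("x", "y"), 3)
    expect_equal(fwd(rr, x, y), fwd(m, x, y), tolerance = 1e-12)
    rx <- paste(rev(strsplit(x, "")[[1]]), collapse = "")
    ry <- paste(rev(strsplit(y, "")[[1]]), collapse = "")
    expect_equal(fwd(reverseMachine(m), rx, ry), fwd(m, x, y),
                 tolerance = 1e-12)
  }
})

test_that("reverse-complement respects Watson-Crick pairing", {
  expect_equal(fwd(reverseComplementMachine(seqGenerator("AC", c("A","C","G","T"))),
                   "", "GT"), 1)
  # the TaqI site TCGA is its own reverse complement
  taq <- reverseComplementMachine(seqGenerator("TCGA"))
  expect_equal(fwd(taq, "", "TCGA"), 1)
  m <- seqGenerator("ACGT")
  expect_equal(fwd(reverseComplementMachine(reverseComplementMachine(m)),
                   "", "ACGT"), 1)
  expect_error(reverseComplementMachine(seqGenerator("xy")), "not nucleic")
})

test_that("Kleene closure sums over repetition counts", {
  expect_equal(fwd(kleeneStar(seqGenerator("A")), "", "AAA"), 1)
  half <- kleeneStar(scaleMachine(0.5, seqGenerator("A")))
  expect_equal(fwd(half, "", "AAA"), 0.125)
  expect_equal(fwd(half, "", ""), 1)
  diverging <- scaleMachine(1, seqGenerator("", "A"))
  expect_error(kleeneStar(diverging), "diverges")
})

test_that("repetition is iterated concatenation", {
  g <- repeatMachine(seqGenerator("AC"), 3)
  expect_equal(fwd(g, "", "ACACAC"), 1)
  t <- seqGenerator("A")
  expect_equal(fwd(repeatMachine(t, 1), "", "A"), fwd(t, "", "A"))
  expect_error(repeatMachine(t, 0), "positive")
  set.seed(71)
  m <- randomMachine(3, acyclic = TRUE)
  r2 <- repeatMachine(m, 2)
  cc <- concatMachines(m, m)
  for (k in seq_len(6)) {
    x <- randomStringOver(c("a", "b"), 3)
    y <- randomStringOver(c("x", "y"), 3)
    expect_equal(fwd(r2, x, y), fwd(cc, x, y), tolerance = 1e-9)
  }
})

test_that("scalar multiplication scales every pair weight", {
  expect_equal(fwd(scaleMachine(0.5, seqGenerator("A")), "", "A"), 0.5)
  t <- seqGenerator("AC")
  expect_equal(fwd(scaleMachine(1, t), "", "AC"), fwd(t, "", "AC"))
  expect_error(scaleMachine(-2, t), "non-negative")
  # symbolic scale factor, assigned afterwards
  st <- scaleMachine(wParam("a"), t)
  st <- setParams(st, c(a = 2))
  expect_equal(fwd(st, "", "AC"), 2)
})

test_that("the identity machine is the matrix identity", {
  id <- identityMachine(c("A", "C", "G"))
  expect_equal(fwd(id, "ACG", "ACG"), 1)
  expect_equal(fwd(id, "ACG", "ACA"), 0)
  ii <- composeMachines(id, id)
  for (x in c("", "A", "ACG", "GGA"))
    expect_equal(fwd(ii, x, x), 1)
  expect_equal(fwd(ii, "AC", "CA"), 0)
  expect_error(identityMachine(character(0)), "non-empty")
})

test_that("local flanking matches the pattern anywhere", {
  lf <- localFlank(seqRecognizer("TCGA"))
  expect_gte(fwd(lf, "GGTCGAGG", ""), 1)
  expect_equal(fwd(lf, "TCGA", ""), 1)
  expect_equal(fwd(lf, "GGTGGA", ""), 0)
  expect_error(localFlank(dnaToRna()), "one empty alphabet")
})
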