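# Preset machines: generators/recognizers, regular expressions, the DNA
# storage code family, Hamming coding, error models, protein translation,
# CTC recognizers, Jukes-Cantor, de Bruijn motif avoidance.

fwd <- function(m, x, y) exp(forwardScore(m, x, y)$logWeight)

test_that("generators and recognizers emit and accept exactly their
           sequence", {
  g <- seqGenerator("TCGA")
  expect_equal(fwd(g, "", "TCGA"), 1)
  expect_equal(fwd(g, "", "TCG"), 0)
  r <- seqRecognizer("TCGA")
  expect_equal(fwd(r, "TCGA", ""), 1)
  expect_true(isRecognizer(r) && isGenerator(g))
  # empty sequence: the single-state machine
  e <- seqGenerator("", "A")
  expect_equal(fwd(e, "", ""), 1)
  expect_equal(fwd(e, "", "A"), 0)
})

test_that("every preset machine validates cleanly", {
  presets <- list(seqGenerator("ACGT"), seqRecognizer("ACGT"),
                  regexMachine("AC*G"), dnaToRna(), binaryToTernary(TRUE),
                  binaryToTernary(FALSE), ternaryToDna(), storageCode(),
                  hamming74(), bitflipChannel(0.1), errorModelSCI(),
                  errorModelACD(), proteinToCodon(),
                  jukesCantorMachine(0.5), deBruijnGenerator(2, "AA"))
  for (m in presets)
    expect_identical(validateMachine(m), character(0))
})

test_that("regex recognizers agree with a standard regex engine on all
           short strings", {
  cases <- list(list(pat = "AC*G", alpha = c("A", "C", "G")),
                list(pat = "A|C", alpha = c("A", "C", "G")),
                list(pat = "[AG].T", alpha = c("A", "C", "G", "T")),
                list(pat = "(AC)+T?", alpha = c("A", "C", "T")))
  for (cs in cases) {
    m <- regexMachine(cs$pat, cs$alpha)
    for (x in allStrings(cs$alpha, 4)) {
      want <- grepl(paste0("^(", cs$pat, ")$"), x)
      got <- fwd(m, x, "") > 0
      expect_identical(got, want,
                       label = sprintf("pattern '%s' on '%s'", cs$pat, x))
    }
  }
  expect_error(regexMachine("A(C"), "malformed")
  expect_error(regexMachine("*A"), "malformed")
})

test_that("dnaToRna maps T to U and nothing else", {
  m <- dnaToRna()
  expect_equal(fwd(m, "T", "U"), 1)
  expect_equal(fwd(m, "T", "A"), 0)
  expect_equal(fwd(composeMachines(seqGenerator("TCGA"), m), "", "UCGA"), 1)
})

test_that("binary-to-ternary batches three bits into two trits", {
  b2t <- binaryToTernary(withEof = FALSE)
  expect_equal(fwd(b2t, "000", "00"), 1)
  expect_equal(fwd(b2t, "111", "21"), 1)
  expect_equal(fwd(b2t, "101", "12"), 1)   # v = 5 -> base 3 "12"
  # length not divisible by three is rejected without the EOF marker
  expect_equal(exp(bestTransduction(b2t, "10")$logWeight), 0)
  # with EOF, "22" terminates the message
  b2te <- binaryToTernary(withEof = TRUE)
  expect_equal(fwd(b2te, "000", "0022"), 1)
  expect_equal(fwd(b2te, "000", "00"), 0)
})

test_that("no data batch ever emits the trit pair 22", {
  b2te <- binaryToTernary(withEof = TRUE)
  for (len in c(3, 6, 9)) {
    for (bits in allStrings(c("0", "1"), len)) {
      if (nchar(bits) != len) next
      trits <- bestTransduction(b2te, bits)$output
      body <- substr(trits, 1, nchar(trits) - 2)   # strip the EOF marker
      pairs <- substring(body, seq(1, nchar(body), 2),
                         seq(2, nchar(body), 2))
      expect_false(any(pairs == "22"),
                   label = paste("bits", bits, "->", trits))
    }
  }
})

test_that("ternary-to-DNA follows the previous-base exclusion rule", {
  t2d <- ternaryToDna()
  expect_equal(fwd(t2d, "00", "AC"), 1)
  expect_equal(fwd(t2d, "0", "A"), 1)
  expect_equal(fwd(t2d, "2", "G"), 1)    # start: previous base deemed T
  # outputs never repeat a base adjacently
  for (trits in allStrings(c("0", "1", "2"), 5)) {
    if (!nzchar(trits)) next
    dna <- bestTransduction(t2d, trits)$output
    expect_equal(nchar(dna), nchar(trits))
    expect_false(grepl("(.)\\1", dna), label = paste(trits, "->", dna))
  }
})

test_that("the storage code round-trips binary messages through
           repeat-free DNA", {
  sc <- storageCode()
  for (bits in allStrings(c("0", "1"), 6)) {
    enc <- storageEncode(bits, code = sc)
    expect_false(grepl("(.)\\1", enc$dna))
    dec <- storageDecode(enc$dna, code = sc, bitLength = nchar(bits))
    expect_true(dec$ok)
    expect_identical(dec$bits, bits, label = paste("message", bits))
  }
  # DNA outside the code's image is flagged
  expect_false(storageDecode("AAAA", code = sc)$ok)
})

test_that("Hamming(7,4) produces the standard codewords and the channel
           flips bits", {
  expect_identical(hammingEncode("1011"), "0110011")
  expect_identical(hammingEncode("0000"), "0000000")
  expect_identical(hammingEncode("1111"), "1111111")
  q0 <- bitflipChannel(0)
  expect_equal(fwd(q0, "0110011", "0110011"), 1)
  expect_equal(fwd(q0, "0110011", "0110010"), 0)
  q <- bitflipChannel(0.1)
  expect_equal(fwd(q, "01", "01"), 0.81, tolerance = 1e-12)
  expect_equal(fwd(q, "01", "00"), 0.09, tolerance = 1e-12)
  expect_error(bitflipChannel(1.5), "\\[0, 1\\]")
})

test_that("Viterbi decoding corrects every single-bit error in every
           codeword", {
  channel <- composeMachines(hamming74(), bitflipChannel(0.05))
  datawords <- allStrings(c("0", "1"), 4)
  datawords <- datawords[nchar(datawords) == 4]
  for (d in datawords) {
    cw <- hammingEncode(d)
    for (pos in 1:7) {
      flipped <- cw
      substr(flipped, pos, pos) <- if (substr(cw, pos, pos) == "0") "1" else "0"
      expect_identical(hammingDecode(flipped, channel = channel), d,
                       label = sprintf("word %s, flip %d", d, pos))
    }
  }
})

test_that("error models have the documented architecture", {
  expect_equal(machineStats(errorModelACD())$nStates, 50L)
  expect_equal(machineStats(errorModelSCI())$nStates, 5L)
  # degenerate parameters: identity substitution, no gaps
  sci <- errorModelSCI(sub = diag(4), gapOpen = 0, gapExtend = 0)
  expect_equal(fwd(sci, "ACGT", "ACGT"), 1)
  expect_equal(fwd(sci, "ACGT", "ACGA"), 0)
  # the context-dependent model scores alignments with plausible weights
  acd <- errorModelACD()
  expect_gt(fwd(acd, "ACGT", "ACGT"), fwd(acd, "ACGT", "TTTT"))
  expect_gt(fwd(acd, "ACGT", "ACGT"), 0)
})

test_that("protein-to-codon translation follows the standard genetic
           code", {
  p2c <- proteinToCodon()
  expect_equal(fwd(p2c, "M", "ATG"), 1)
  expect_equal(fwd(p2c, "W", "TGG"), 1)
  expect_equal(fwd(p2c, "F", "TTT"), 0.5)   # two synonymous codons
  expect_equal(fwd(p2c, "F", "TTC"), 0.5)
  expect_equal(fwd(p2c, "M", "ATA"), 0)
  expect_equal(fwd(p2c, "MW", "ATGTGG"), 1)
  expect_error(proteinToCodon(list(M = c(ATG = 0.9))), "sum to 1")
  expect_error(proteinToCodon(list(M = c(TGG = 1))), "wrong amino acid")
})

test_that("CTC recognizers merge repeats across frames unless a blank
           intervenes", {
  onehot <- function(syms) {
    pm <- matrix(0, length(syms), 5,
                 dimnames = list(NULL, c("A", "C", "G", "T", "blank")))
    pm[cbind(seq_along(syms), match(syms, colnames(pm)))] <- 1
    pm
  }
  m1 <- ctcRecognizer(onehot(c("A", "A")))
  expect_equal(fwd(m1, "A", ""), 1)
  expect_equal(fwd(m1, "AA", ""), 0)
  m2 <- ctcRecognizer(onehot(c("A", "blank", "A")))
  expect_equal(fwd(m2, "AA", ""), 1)
  expect_equal(fwd(m2, "A", ""), 0)
})

test_that("CTC recognizers agree with the exhaustive collapse oracle", {
  set.seed(127)
  for (k in seq_len(2)) {
    pm <- matrix(runif(4 * 5), 4, 5,
                 dimnames = list(NULL, c("A", "C", "G", "T", "blank")))
    m <- ctcRecognizer(pm)
    want <- ctcOracle(pm)
    for (y in allStrings(c("A", "C", "G", "T"), 4)) {
      i <- match(y, names(want))
      expected <- if (is.na(i)) 0 else unname(want[[i]])
      expect_equal(fwd(m, y, ""), expected, tolerance = 1e-9,
                   label = paste("label sequence", y))
    }
  }
})

test_that("Jukes-Cantor weights interpolate identity and the uniform
           limit", {
  jc0 <- jukesCantorMachine(0)
  expect_equal(fwd(jc0, "A", "A"), 1)
  expect_equal(fwd(jc0, "A", "C"), 0)
  jcInf <- jukesCantorMachine(1000)
  for (b in c("A", "C", "G", "T"))
    expect_equal(fwd(jcInf, "A", b), 0.25, tolerance = 1e-9)
  jc <- jukesCantorMachine(0.7, rate = 0.3)
  tot <- sum(vapply(c("A", "C", "G", "T"), function(b)
    fwd(jc, "A", b), numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
  expect_error(jukesCantorMachine(-1), "non-negative")
})

test_that("de Bruijn generators never emit a prohibited k-mer", {
  for (cfg in list(list(k = 2, bad = c("AA", "CC", "GG", "TT")),
                   list(k = 3, bad = c("TCG", "GAA")))) {
    m <- deBruijnGenerator(cfg$k, cfg$bad)
    for (y in allStrings(c("A", "C", "G", "T"), 5)) {
      hasBad <- any(vapply(cfg$bad, grepl, logical(1), x = y, fixed = TRUE))
      expect_identical(fwd(m, "", y) > 0, !hasBad,
                       label = paste("k =", cfg$k, "output", y))
    }
  }
})

test_that("the rate calculator reproduces the code's information
           budget", {
  eff3 <- codeEfficiency(3)
  expect_equal(eff3$trits, 2L)
  expect_equal(eff3$bitTritRatio, 3 / 2)
  expect_equal(eff3$expansion, log(9) / log(8), tolerance = 1e-12)
  eff11 <- codeEfficiency(11)
  expect_equal(eff11$trits, 7L)
  expect_equal(eff11$bitTritRatio, 11 / 7, tolerance = 1e-12)
  expect_equal(outputCapacity(ternaryToDna()), log2(3), tolerance = 1e-9)
  rates <- storageCodeRates()
  expect_equal(rates$ternaryToDna, log(4) / log(3), tolerance = 1e-9)
  expect_equal(rates$composite, 4 / 3, tolerance = 1e-9)
})
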