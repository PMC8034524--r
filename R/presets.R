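## Preset machines: sequence generators/recognizers, regular expressions,
## DNA->RNA conversion, the repeat-avoiding DNA storage code family
## (binary->ternary and ternary->non-repeating-DNA converters, Hamming(7,4)
## parity coding, motif-avoiding de Bruijn codes), sequencing-error models,
## protein->codon translation, CTC merge-repeats recognizers, and the
## Jukes-Cantor substitution model.

DNA_ALPHABET <- c("A", "C", "G", "T")
RNA_ALPHABET <- c("A", "C", "G", "U")
BIT_ALPHABET <- c("0", "1")
TRIT_ALPHABET <- c("0", "1", "2")

#' Sequence generator and recognizer
#'
#' A generator emits exactly the given sequence with weight 1 (its input
#' alphabet is empty); a recognizer accepts exactly that sequence (the
#' transpose of the generator).
#'
#' @param seq The sequence (string or character vector of symbols; `""`
#'   for the empty sequence).
#' @param alphabet Symbol alphabet; defaults to the distinct symbols of
#'   `seq`.
#' @return A [Machine].
#' @examples
#' g <- seqGenerator("TCGA")
#' exp(forwardScore(g, "", "TCGA")$logWeight)   # 1
#' @export
seqGenerator <- function(seq, alphabet = NULL) {
  syms <- asSymbols(seq)
  if (is.null(alphabet)) alphabet <- unique(syms)
  if (!all(syms %in% alphabet))
    stop("sequence contains symbols outside the declared alphabet")
  n <- length(syms)
  states <- paste0("g", 0:n)
  rows <- if (n) transitionTable(states[1:n], states[2:(n + 1L)],
                                 NA, syms, 1) else emptyTransitions()
  Machine(states, rows, character(0), as.character(alphabet))
}

#' @rdname seqGenerator
#' @export
seqRecognizer <- function(seq, alphabet = NULL) {
  transposeMachine(seqGenerator(seq, alphabet))
}

#' Recognizer for a restricted regular expression
#'
#' Thompson construction over the pattern grammar: literal symbols,
#' character classes `[...]`, the wildcard `.`, postfix `*`, `+`, `?`,
#' alternation `|` and grouping `(...)`.  The result accepts exactly the
#' pattern's language, with weight 1 per accepted string for unambiguous
#' patterns (an ambiguous pattern such as `A|A` accepts with multiplicity).
#'
#' @param pattern The pattern string.
#' @param alphabet Symbol alphabet (required for `.`; defaults to the
#'   literals appearing in the pattern).
#' @return A recognizer [Machine].
#' @export
regexMachine <- function(pattern, alphabet = NULL) {
  chars <- asSymbols(pattern)
  meta <- c("(", ")", "[", "]", "|", "*", "+", "?", ".")
  if (is.null(alphabet)) alphabet <- unique(setdiff(chars, meta))
  alphabet <- as.character(alphabet)
  pos <- 1L
  counter <- 0L
  rows <- list()
  newState <- function() {
    counter <<- counter + 1L
    paste0("q", counter)
  }
  edge <- function(from, to, sym = NA)
    rows[[length(rows) + 1L]] <<- transitionTable(from, to, sym, NA, 1)
  peek <- function() if (pos <= length(chars)) chars[pos] else NA
  advance <- function() { pos <<- pos + 1L }
  expect <- function(ch) {
    if (!identical(peek(), ch))
      stop("malformed pattern: expected '", ch, "' at position ", pos)
    advance()
  }
  parseAtom <- function() {
    ch <- peek()
    if (is.na(ch)) stop("malformed pattern: unexpected end")
    if (ch == "(") {
      advance()
      f <- parseAlt()
      expect(")")
      return(f)
    }
    if (ch == "[") {
      advance()
      cls <- character(0)
      while (!identical(peek(), "]")) {
        if (is.na(peek())) stop("malformed pattern: unterminated class")
        cls <- c(cls, peek()); advance()
      }
      advance()
      if (!length(cls)) stop("malformed pattern: empty character class")
      if (!all(cls %in% alphabet))
        stop("character class symbol outside the alphabet")
      s <- newState(); e <- newState()
      for (c in cls) edge(s, e, c)
      return(list(s = s, e = e))
    }
    if (ch == ".") {
      advance()
      if (!length(alphabet)) stop("wildcard '.' needs a declared alphabet")
      s <- newState(); e <- newState()
      for (c in alphabet) edge(s, e, c)
      return(list(s = s, e = e))
    }
    if (ch %in% c(")", "]", "|", "*", "+", "?"))
      stop("malformed pattern: unexpected '", ch, "' at position ", pos)
    advance()
    if (!(ch %in% alphabet)) stop("literal '", ch, "' outside the alphabet")
    s <- newState(); e <- newState()
    edge(s, e, ch)
    list(s = s, e = e)
  }
  parseFactor <- function() {
    f <- parseAtom()
    repeat {
      ch <- peek()
      if (identical(ch, "*")) {
        advance()
        s <- newState(); e <- newState()
        edge(s, f$s); edge(f$e, e); edge(s, e); edge(f$e, f$s)
        f <- list(s = s, e = e)
      } else if (identical(ch, "+")) {
        advance()
        s <- newState(); e <- newState()
        edge(s, f$s); edge(f$e, e); edge(f$e, f$s)
        f <- list(s = s, e = e)
      } else if (identical(ch, "?")) {
        advance()
        s <- newState(); e <- newState()
        edge(s, f$s); edge(f$e, e); edge(s, e)
        f <- list(s = s, e = e)
      } else break
    }
    f
  }
  parseConcat <- function() {
    f <- parseFactor()
    while (!is.na(peek()) && !(peek() %in% c("|", ")"))) {
      g <- parseFactor()
      edge(f$e, g$s)
      f <- list(s = f$s, e = g$e)
    }
    f
  }
  parseAlt <- function() {
    branches <- list(parseConcat())
    while (identical(peek(), "|")) {
      advance()
      branches <- c(branches, list(parseConcat()))
    }
    if (length(branches) == 1L) return(branches[[1L]])
    s <- newState(); e <- newState()
    for (b in branches) { edge(s, b$s); edge(b$e, e) }
    list(s = s, e = e)
  }
  frag <- parseAlt()
  if (!is.na(peek()))
    stop("malformed pattern: trailing '", peek(), "' at position ", pos)
  ids <- paste0("q", seq_len(counter))
  ids <- c(frag$s, setdiff(ids, c(frag$s, frag$e)), frag$e)
  m <- Machine(ids, rows, alphabet, character(0), check = FALSE)
  tidyMachine(m)
}

#' DNA to RNA conversion machine
#'
#' Single looping-state transducer mapping A, C, G to themselves and T to
#' U, each with weight 1.  Composing a DNA motif generator with this
#' machine yields the corresponding RNA motif generator.
#'
#' @return A [Machine] from DNA to RNA.
#' @export
dnaToRna <- function() {
  rows <- list(
    transitionTable("s", "s", DNA_ALPHABET, RNA_ALPHABET, 1),
    transitionTable("s", "e", NA, NA, 1))
  Machine(c("s", "e"), rows, DNA_ALPHABET, RNA_ALPHABET)
}

#' Binary-to-ternary converter
#'
#' Batches the binary input into groups of three bits and outputs pairs of
#' ternary digits: a batch with integer value `v` (most significant bit
#' first) emits the two-digit base-3 representation (`v %/% 3`, then
#' `v %% 3`).  Since `v <= 7`, the trit pair "22" is never produced from
#' data; with `withEof = TRUE` the machine emits "22" as an end-of-message
#' marker before terminating, so message length need not be known in
#' advance.  Input whose length is not a multiple of 3 is rejected
#' (weight 0).
#'
#' @param withEof Emit the "22" end-of-file marker before terminating.
#' @return A [Machine] from bits to trits.
#' @export
binaryToTernary <- function(withEof = TRUE) {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- transitionTable(...)
  for (b in BIT_ALPHABET) add("S", paste0("B", b), b, NA, 1)
  for (b in BIT_ALPHABET) for (b2 in BIT_ALPHABET)
    add(paste0("B", b), paste0("B", b, b2), b2, NA, 1)
  for (b in BIT_ALPHABET) for (b2 in BIT_ALPHABET) for (b3 in BIT_ALPHABET) {
    v <- strtoi(paste0(b, b2, b3), base = 2L)
    t1 <- v %/% 3L
    t2 <- v %% 3L
    add(paste0("B", b, b2), paste0("E", t2), b3, as.character(t1), 1)
  }
  for (t2 in 0:2) add(paste0("E", t2), "S", NA, as.character(t2), 1)
  states <- c("S", "B0", "B1", "B00", "B01", "B10", "B11",
              "E0", "E1", "E2")
  if (withEof) {
    add("S", "F1", NA, "2", 1)
    add("F1", "F2", NA, "2", 1)
    states <- c(states, "F1", "F2")
  } else {
    add("S", "F", NA, NA, 1)
    states <- c(states, "F")
  }
  Machine(states, rows, BIT_ALPHABET, TRIT_ALPHABET)
}

#' Ternary-to-repeat-free-DNA converter
#'
#' Converts a ternary sequence into DNA with no two equal adjacent bases:
#' after emitting base `b`, the three available next bases are the
#' alphabetically ordered elements of `{A,C,G,T} \ {b}`, and trit `t`
#' (0-based) selects the `t`-th of them.  At the start the previous base
#' is deemed T, so the first trit maps onto `(A, C, G)`.  The output can
#' therefore never repeat a base, which avoids the homopolymer runs that
#' DNA sequencers misread.
#'
#' @return A [Machine] from trits to DNA.
#' @export
ternaryToDna <- function() {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- transitionTable(...)
  stateFor <- function(b) if (b == "T") "S" else paste0("p", b)
  for (b in DNA_ALPHABET) {
    src <- stateFor(b)
    allowed <- setdiff(DNA_ALPHABET, b)
    for (t in 0:2)
      add(src, paste0("p", allowed[t + 1L]), as.character(t),
          allowed[t + 1L], 1)
  }
  ## "S" doubles as previous-base-T, so pT is only needed as an emission
  ## target; give it the same outgoing rule via stateFor("T") == "S" --
  ## but a T can be emitted mid-sequence, so pT needs its own copy.
  allowed <- setdiff(DNA_ALPHABET, "T")
  for (t in 0:2)
    add("pT", paste0("p", allowed[t + 1L]), as.character(t),
        allowed[t + 1L], 1)
  add("S", "F", NA, NA, 1)
  for (b in DNA_ALPHABET) add(paste0("p", b), "F", NA, NA, 1)
  Machine(c("S", "pA", "pC", "pG", "pT", "F"), rows,
          TRIT_ALPHABET, DNA_ALPHABET)
}

#' The repeat-avoiding DNA storage code
#'
#' The composition of [binaryToTernary()] and [ternaryToDna()]: a machine
#' converting binary messages into DNA with no repeated adjacent
#' nucleotide.  With the end-of-file marker the trit pair "22" (never
#' produced from data) is appended before termination and maps to two
#' final nucleotides.  Asymptotically the bit:nucleotide length ratio
#' approaches 3/2.
#'
#' @param withEof Include the "22" end-of-message marker.
#' @return A [Machine] from bits to DNA.
#' @export
storageCode <- function(withEof = TRUE) {
  composeMachines(binaryToTernary(withEof), ternaryToDna())
}

#' Encode and decode binary messages as repeat-free DNA
#'
#' `storageEncode` runs the storage-code machine forwards on a bit string
#' ([bestTransduction()]): the message is zero-padded to a whole 3-bit
#' batch, converted to trits, terminated with the "22" marker and emitted
#' as repeat-free DNA.  `storageDecode` runs the transposed machine on a
#' DNA string; supply `bitLength` to strip the padding (the encoder cannot
#' mark it in-band, so the original bit length travels out-of-band, e.g.
#' in a header field).
#'
#' @param bits Bit string (characters 0/1).
#' @param dna DNA string.
#' @param code The storage-code machine (built once and reused when
#'   encoding many messages).
#' @param bitLength Original message length in bits, to strip padding.
#' @return `storageEncode`: list with `dna`, `bitLength`, `padded`.
#'   `storageDecode`: list with `bits` (`NA` if the DNA is not in the
#'   code's image), `ok`.
#' @examples
#' enc <- storageEncode("101100")
#' enc$dna
#' storageDecode(enc$dna, bitLength = enc$bitLength)$bits
#' @export
storageEncode <- function(bits, code = storageCode()) {
  syms <- asSymbols(bits)
  if (!all(syms %in% BIT_ALPHABET)) stop("message must be a bit string")
  n <- length(syms)
  pad <- (3L - n %% 3L) %% 3L
  padded <- c(syms, rep("0", pad))
  res <- bestTransduction(code, padded)
  if (res$logWeight == -Inf) stop("encoding failed; is the code machine intact?")
  list(dna = res$output, bitLength = n, padded = pad)
}

#' @rdname storageEncode
#' @export
storageDecode <- function(dna, code = storageCode(), bitLength = NULL) {
  res <- bestTransduction(transposeMachine(code), dna)
  if (res$logWeight == -Inf)
    return(list(bits = NA_character_, ok = FALSE))
  bits <- res$output
  if (!is.null(bitLength)) bits <- substr(bits, 1L, bitLength)
  list(bits = bits, ok = TRUE)
}

hammingCodeword <- function(d) {
  # d: integer vector of 4 data bits -> 7-bit codeword p1 p2 d1 p3 d2 d3 d4
  p1 <- (d[1] + d[2] + d[4]) %% 2L   # even parity over positions 1,3,5,7
  p2 <- (d[1] + d[3] + d[4]) %% 2L   # positions 2,3,6,7
  p3 <- (d[2] + d[3] + d[4]) %% 2L   # positions 4,5,6,7
  c(p1, p2, d[1], p3, d[2], d[3], d[4])
}

#' Hamming(7,4) parity coder and a bit-flip channel
#'
#' `hamming74` maps each 4-bit batch `d1 d2 d3 d4` to the 7-bit codeword
#' `p1 p2 d1 p3 d2 d3 d4` with even parity bits (`p1` over codeword
#' positions 1,3,5,7; `p2` over 2,3,6,7; `p3` over 4,5,6,7).
#' `bitflipChannel` is a one-looping-state transducer passing each bit
#' with weight `1 - q` and flipping it with weight `q`.  Best-path
#' decoding through the composition corrects any single flipped bit per
#' block when `q < 0.5` (minimum-distance 3).
#'
#' @param q Flip probability in [0, 1].
#' @return A [Machine].
#' @export
hamming74 <- function() {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- transitionTable(...)
  states <- "R"
  prefixes <- c("", "0", "1", "00", "01", "10", "11")
  for (p in setdiff(prefixes, ""))
    states <- c(states, paste0("d", p))
  stateFor <- function(p) if (p == "") "R" else paste0("d", p)
  for (p in prefixes) for (b in BIT_ALPHABET)
    if (nchar(p) < 2L) add(stateFor(p), stateFor(paste0(p, b)), b, NA, 1)
  ## length-3 prefixes
  for (p in c("000","001","010","011","100","101","110","111")) {
    states <- c(states, paste0("d", p))
    add(stateFor(substr(p, 1, 2)), paste0("d", p), substr(p, 3, 3), NA, 1)
  }
  ## fourth bit: emit the 7-bit codeword via a chain of emitting states
  for (p in c("000","001","010","011","100","101","110","111"))
    for (b in BIT_ALPHABET) {
      d <- as.integer(asSymbols(paste0(p, b)))
      cw <- as.character(hammingCodeword(d))
      word <- paste0(p, b)
      chain <- paste0("w", word, ".", 1:6)
      states <- c(states, chain)
      add(paste0("d", p), chain[1L], b, cw[1L], 1)
      for (k in 1:5) add(chain[k], chain[k + 1L], NA, cw[k + 1L], 1)
      add(chain[6L], "R", NA, cw[7L], 1)
    }
  add("R", "F", NA, NA, 1)
  Machine(c(states, "F"), rows, BIT_ALPHABET, BIT_ALPHABET)
}

#' @rdname hamming74
#' @export
bitflipChannel <- function(q) {
  if (!is.numeric(q) || q < 0 || q > 1) stop("flip probability must be in [0, 1]")
  rows <- list(
    transitionTable("s", "s", c("0", "1"), c("0", "1"), 1 - q),
    transitionTable("s", "s", c("0", "1"), c("1", "0"), q),
    transitionTable("s", "e", NA, NA, 1))
  Machine(c("s", "e"), rows, BIT_ALPHABET, BIT_ALPHABET)
}

#' @param bits Data-bit string, length a multiple of 4 (`hammingEncode`).
#' @param observed Received 7n-bit string (`hammingDecode`).
#' @param code,channel Prebuilt machines, for reuse across calls.
#' @rdname hamming74
#' @export
hammingEncode <- function(bits, code = hamming74()) {
  res <- bestTransduction(code, bits)
  if (res$logWeight == -Inf)
    stop("input length must be a multiple of 4 bits")
  res$output
}

#' @rdname hamming74
#' @export
hammingDecode <- function(observed, q = 0.05,
                          channel = composeMachines(hamming74(),
                                                    bitflipChannel(q))) {
  res <- bestTransduction(transposeMachine(channel), observed)
  if (res$logWeight == -Inf)
    stop("observed length must be a multiple of 7 bits")
  res$output
}

defaultSubMatrix <- function(pMismatch = 0.03) {
  m <- matrix(pMismatch, 4, 4, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  diag(m) <- 1 - 3 * pMismatch
  m
}

#' Symmetric context-independent sequencing-error model
#'
#' A DNA-to-DNA transducer with one match, one insert and one delete state
#' (plus start and end): matches emit a read base from a 4x4 substitution
#' table; insertions and deletions share a single gap open/extend
#' parameter pair (`gapOpen`, `gapExtend`), kept symbolic in the parameter
#' model so they can be refit.
#'
#' @param sub 4x4 row-stochastic substitution matrix (true base in rows,
#'   read base in columns).
#' @param gapOpen,gapExtend Initial gap parameter values.
#' @return A 5-state [Machine].
#' @export
errorModelSCI <- function(sub = defaultSubMatrix(), gapOpen = 0.05,
                          gapExtend = 0.3) {
  if (!all(dim(sub) == c(4, 4))) stop("substitution matrix must be 4x4")
  if (any(sub < 0)) stop("substitution weights must be non-negative")
  dimnames(sub) <- list(DNA_ALPHABET, DNA_ALPHABET)
  g <- wParam("gapOpen"); e <- wParam("gapExtend")
  noGap <- wDiff(1, wProd(2, g))
  stay <- wDiff(1, e)
  rows <- list(transitionTable("S", "M", NA, NA, 1))
  add <- function(...) rows[[length(rows) + 1L]] <<- transitionTable(...)
  for (a in DNA_ALPHABET) for (b in DNA_ALPHABET) {
    add("M", "M", a, b, list(simplifyWeight(wProd(noGap, sub[a, b]))))
    add("I", "M", a, b, list(simplifyWeight(wProd(stay, sub[a, b]))))
    add("D", "M", a, b, list(simplifyWeight(wProd(stay, sub[a, b]))))
  }
  for (b in DNA_ALPHABET) {
    add("M", "I", NA, b, list(wProd(g, 0.25)))
    add("I", "I", NA, b, list(wProd(e, 0.25)))
  }
  for (a in DNA_ALPHABET) {
    add("M", "D", a, NA, list(g))
    add("D", "D", a, NA, list(e))
  }
  add("M", "E", NA, NA, 1)
  add("I", "E", NA, NA, 1)
  add("D", "E", NA, NA, 1)
  Machine(c("S", "M", "I", "D", "E"), rows, DNA_ALPHABET, DNA_ALPHABET,
          ParamModel(values = c(gapOpen = gapOpen, gapExtend = gapExtend)))
}

ctxName <- function(p, c) paste0(p, c)
ctxParam <- function(x, ctx) {
  if (length(x) == 1L) unname(x) else {
    if (!(ctx %in% names(x))) stop("missing value for context ", ctx)
    unname(x[[ctx]])
  }
}

#' Asymmetric context-dependent sequencing-error model
#'
#' A richer DNA-to-DNA error model with separate insertion and deletion
#' probabilities (asymmetric) that depend on the local reference bases
#' (context-dependent): the match/insert/delete state triple is replicated
#' once per dinucleotide flanking context (previous reference base x
#' current reference base, 16 contexts), giving 48 interior states plus
#' dedicated start and end states -- 50 states in total.  At the start of
#' the reference the previous base is deemed A.
#'
#' @param pSub Per-context mismatch probability (scalar, or named vector
#'   over the 16 contexts "AA", "AC", ...); a mismatching read base has
#'   probability `pSub`, a matching one `1 - 3 * pSub`.
#' @param pIns,pDel Per-context insertion-open and deletion probabilities.
#' @param pInsExt Insertion extension probability.
#' @return A 50-state [Machine].
#' @export
errorModelACD <- function(pSub = 0.02, pIns = 0.02, pDel = 0.02,
                          pInsExt = 0.2) {
  contexts <- as.vector(outer(DNA_ALPHABET, DNA_ALPHABET, ctxName))
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- transitionTable(...)
  emitP <- function(ctx, true, read) {
    ps <- ctxParam(pSub, ctx)
    if (read == true) 1 - 3 * ps else ps
  }
  ## transitions out of an interior state in context (p, c): advance to the
  ## next reference base c2 (new context (c, c2)), open an insertion, or
  ## terminate.  leave = probability of not (re)entering the insert state.
  interiorOut <- function(src, c, leave, insOpen) {
    for (b in DNA_ALPHABET)
      add(src, paste0("I", ctxName(substr(src, 2, 2), c)), NA, b,
          insOpen * 0.25)
    for (c2 in DNA_ALPHABET) {
      ctx2 <- ctxName(c, c2)
      pd <- ctxParam(pDel, ctx2)
      for (b in DNA_ALPHABET)
        add(src, paste0("M", ctx2), c2, b,
            leave * (1 - pd) * emitP(ctx2, c2, b))
      add(src, paste0("D", ctx2), c2, NA, leave * pd)
    }
    add(src, "E", NA, NA, leave)
  }
  for (p in DNA_ALPHABET) for (c in DNA_ALPHABET) {
    ctx <- ctxName(p, c)
    pi <- ctxParam(pIns, ctx)
    interiorOut(paste0("M", ctx), c, 1 - pi, pi)
    interiorOut(paste0("D", ctx), c, 1 - pi, pi)
    interiorOut(paste0("I", ctx), c, 1 - pInsExt, pInsExt)
  }
  ## start: previous reference base deemed A
  for (c in DNA_ALPHABET) {
    ctx <- ctxName("A", c)
    pd <- ctxParam(pDel, ctx)
    for (b in DNA_ALPHABET)
      add("S", paste0("M", ctx), c, b, (1 - pd) * emitP(ctx, c, b))
    add("S", paste0("D", ctx), c, NA, pd)
  }
  add("S", "E", NA, NA, 1)
  states <- c("S",
              as.vector(t(outer(c("M", "I", "D"), contexts, paste0))),
              "E")
  Machine(states, rows, DNA_ALPHABET, DNA_ALPHABET)
}

#' Protein-to-codon translation machine
#'
#' Reads one amino-acid symbol and emits its codon as three nucleotides
#' (via two intermediate states per codon), weighted by a per-amino-acid
#' distribution over synonymous codons.  Composing with a sequencing-error
#' model yields a protein-to-noisy-DNA aligner.
#'
#' @param codonWeights Named list: for each amino acid (one-letter code), a
#'   named numeric vector of weights over its codons, summing to 1.
#'   Defaults to the uniform distribution over the synonymous codons of
#'   the standard genetic code.
#' @return A [Machine] from amino acids to DNA.
#' @export
proteinToCodon <- function(codonWeights = NULL) {
  gc <- Biostrings::GENETIC_CODE
  if (is.null(codonWeights)) {
    codonWeights <- lapply(split(names(gc), gc), function(cods)
      setNames(rep(1 / length(cods), length(cods)), cods))
    codonWeights[["*"]] <- NULL
  }
  for (aa in names(codonWeights)) {
    w <- codonWeights[[aa]]
    if (!length(w) || is.null(names(w)))
      stop("codon weights for amino acid '", aa, "' are missing or unnamed")
    if (abs(sum(w) - 1) > 1e-9)
      stop("codon weights for amino acid '", aa, "' do not sum to 1")
    if (!all(gc[names(w)] == aa))
      stop("codon assigned to the wrong amino acid: '", aa, "'")
  }
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- transitionTable(...)
  states <- "R"
  for (aa in names(codonWeights)) {
    w <- codonWeights[[aa]]
    for (cod in names(w)) {
      n <- asSymbols(cod)
      s1 <- paste0("c", cod, ".1"); s2 <- paste0("c", cod, ".2")
      states <- c(states, s1, s2)
      add("R", s1, aa, n[1L], w[[cod]])
      add(s1, s2, NA, n[2L], 1)
      add(s2, "R", NA, n[3L], 1)
    }
  }
  add("R", "F", NA, NA, 1)
  Machine(c(states, "F"), rows, names(codonWeights), DNA_ALPHABET)
}

#' CTC merge-repeats recognizer from per-position probabilities
#'
#' Builds the recognizer corresponding to a neural network's framewise
#' output: given a T x (K+1) matrix of per-frame weights over K labels
#' plus a blank, the machine's weight for a label sequence `y` is the sum,
#' over all length-T frame paths that collapse to `y` under the CTC rule
#' (merge adjacent repeats, then delete blanks), of the product of frame
#' weights.  States track (frame index, last frame symbol), so a repeated
#' label is merged unless a blank separates the two copies.
#'
#' @param probMatrix Numeric matrix, one row per frame; column names are
#'   the label symbols plus a column named `blank` (if unnamed, the last
#'   column is the blank).
#' @return A recognizer [Machine] over the label alphabet.
#' @export
ctcRecognizer <- function(probMatrix) {
  probMatrix <- as.matrix(probMatrix)
  if (!nrow(probMatrix) || !ncol(probMatrix)) stop("empty probability matrix")
  if (any(probMatrix < 0)) stop("frame weights must be non-negative")
  cn <- colnames(probMatrix)
  if (is.null(cn)) {
    cn <- c(LETTERS[seq_len(ncol(probMatrix) - 1L)], "blank")
    colnames(probMatrix) <- cn
  }
  blankCol <- if ("blank" %in% cn) "blank" else cn[length(cn)]
  labels <- setdiff(cn, blankCol)
  Tn <- nrow(probMatrix)
  sid <- function(t, sym) paste0("t", t, ".", sym)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- transitionTable(...)
  states <- sid(0L, "-")
  lastSyms <- "-"
  for (t in seq_len(Tn)) {
    newLast <- c("-", labels)
    for (sym in newLast) states <- c(states, sid(t, sym))
    for (prev in lastSyms) {
      src <- sid(t - 1L, prev)
      ## blank frame: nothing consumed
      add(src, sid(t, "-"), NA, NA, probMatrix[t, blankCol])
      for (lab in labels) {
        w <- probMatrix[t, lab]
        if (lab == prev)   # adjacent repeat merges: no label consumed
          add(src, sid(t, lab), NA, NA, w)
        else               # new label
          add(src, sid(t, lab), lab, NA, w)
      }
    }
    lastSyms <- newLast
  }
  for (sym in lastSyms) add(sid(Tn, sym), "END", NA, NA, 1)
  m <- Machine(c(states, "END"), rows, labels, character(0), check = FALSE)
  tidyMachine(m)
}

#' Jukes-Cantor substitution machine
#'
#' One-looping-state DNA-to-DNA transducer whose substitution weights are
#' the Jukes-Cantor conditional probabilities after time `t` at the given
#' substitution rate: same base `1/4 + 3/4 exp(-4 rate t / 3)`, different
#' base `1/4 - 1/4 exp(-4 rate t / 3)`.  Rows sum to 1 for any `t`.
#'
#' @param t Non-negative divergence time.
#' @param rate Substitution rate (> 0).
#' @return A [Machine].
#' @export
jukesCantorMachine <- function(t, rate = 1) {
  if (!is.numeric(t) || t < 0) stop("time must be non-negative")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  ex <- exp(-4 * rate * t / 3)
  same <- 0.25 + 0.75 * ex
  diff <- 0.25 - 0.25 * ex
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- transitionTable(...)
  for (a in DNA_ALPHABET) for (b in DNA_ALPHABET)
    add("s", "s", a, b, if (a == b) same else diff)
  add("s", "e", NA, NA, 1)
  Machine(c("s", "e"), rows, DNA_ALPHABET, DNA_ALPHABET)
}

#' Motif-avoiding de Bruijn code generator
#'
#' A generator of all sequences containing none of the prohibited k-mers:
#' the transition graph is the de Bruijn graph over (k-1)-mers with the
#' edges completing a prohibited k-mer deleted.  Useful for designing DNA
#' storage codes that avoid, e.g., restriction sites.
#'
#' @param k K-mer length (>= 1).
#' @param prohibited Character vector of prohibited k-mers.
#' @param alphabet Symbol alphabet (default DNA).
#' @return A generator [Machine]; every emitted sequence avoids all
#'   prohibited k-mers.
#' @export
deBruijnGenerator <- function(k, prohibited = character(0),
                              alphabet = DNA_ALPHABET) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  prohibited <- toupper(as.character(prohibited))
  if (length(prohibited) && any(nchar(prohibited) != k))
    stop("every prohibited motif must have length k")
  ctxs <- ""
  for (i in seq_len(k - 1L))
    ctxs <- c(ctxs, as.vector(outer(ctxs[nchar(ctxs) == i - 1L], alphabet,
                                    paste0)))
  sid <- function(ctx) paste0("c.", ctx)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- transitionTable(...)
  for (ctx in ctxs) {
    for (b in alphabet) {
      word <- paste0(ctx, b)
      if (nchar(word) >= k && word %in% prohibited) next
      nctx <- if (nchar(word) >= k) substr(word, nchar(word) - k + 2L,
                                           nchar(word)) else word
      if (k == 1L) nctx <- ""
      add(sid(ctx), sid(nctx), NA, b, 1)
    }
    add(sid(ctx), "F", NA, NA, 1)
  }
  Machine(c(sid(ctxs), "F"), rows, character(0), alphabet)
}

#' Batched base-conversion efficiency
#'
#' For a binary-to-ternary converter batching `bitsPerBatch` input bits,
#' computes the smallest number of trits whose 3^t combinations cover the
#' 2^b batch values, the resulting bit:trit length ratio, and the
#' expansion of the output relative to a perfect (non-finite-state)
#' radix conversion, `(t log 3) / (b log 2)`.
#'
#' @param bitsPerBatch Bits per input batch (>= 1).
#' @return List with `bits`, `trits`, `bitTritRatio`, `expansion`.
#' @examples
#' codeEfficiency(3)$expansion     # log(9)/log(8), ~1.06
#' codeEfficiency(11)$bitTritRatio # 11/7, ~1.57
#' @export
codeEfficiency <- function(bitsPerBatch) {
  b <- as.integer(bitsPerBatch)
  if (is.na(b) || b < 1L) stop("bitsPerBatch must be a positive integer")
  t <- 0L
  while (3^t < 2^b) t <- t + 1L
  list(bits = b, trits = t, bitTritRatio = b / t,
       expansion = (t * log(3)) / (b * log(2)))
}

#' Shannon capacity of a machine's output language
#'
#' The asymptotic information content of the machine's outputs, in bits
#' per symbol: `log2` of the spectral radius of the state-to-state count
#' matrix of emitting transitions (the growth rate of the number of
#' distinct length-n outputs).  For the repeat-free DNA machine this is
#' `log2(3) ~ 1.58` bits per nucleotide: three choices at every position.
#'
#' @param m A [Machine].
#' @return Bits per output symbol (numeric).
#' @export
outputCapacity <- function(m) {
  n <- length(m@states)
  A <- matrix(0, n, n)
  tr <- m@transitions
  emit <- which(!is.na(tr$output))
  for (i in emit) {
    f <- match(tr$from[i], m@states)
    t <- match(tr$to[i], m@states)
    A[f, t] <- A[f, t] + 1
  }
  lam <- max(Mod(eigen(A, only.values = TRUE)$values))
  log2(lam)
}

#' Inefficiency budget of the storage code
#'
#' Computes, from the component machines, the expansion factors of the
#' storage code: the batched binary-to-ternary step (output longer than a
#' perfect radix conversion by `log 9 / log 8`), the ternary-to-repeat-free
#' DNA step (longer than unconstrained DNA by `log 4 / log 3`, i.e. 2 bits
#' per nucleotide versus the repeat-free capacity from
#' [outputCapacity()]), and their product (the composed machine's DNA
#' output versus the 2-bits-per-nucleotide Shannon-optimal length).
#'
#' @return List with `binaryToTernary`, `ternaryToDna`, `composite`,
#'   `repeatFreeCapacity` (bits/nucleotide).
#' @export
storageCodeRates <- function() {
  b2t <- codeEfficiency(3)$expansion
  cap <- outputCapacity(ternaryToDna())
  t2d <- 2 / cap
  list(binaryToTernary = b2t, ternaryToDna = t2d,
       composite = b2t * t2d, repeatFreeCapacity = cap)
}
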