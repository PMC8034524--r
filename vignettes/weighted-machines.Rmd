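---
title: "Weighted finite-state machines as algebraic objects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted finite-state machines as algebraic objects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfst)
```

## The model

A weighted finite-state machine in this package is a tuple of an input
alphabet, an output alphabet, an ordered non-empty list of states (first =
start, last = end), a set of transitions, and a parameter model.  Each
transition carries an input label, an output label (either may be the empty
string, epsilon), and a weight: a closed-form differentiable expression over
named non-negative parameters (constants, parameter references, sums,
products, differences, quotients, powers, `exp`, `log`).  For an input
sequence `x` and output sequence `y`, the machine assigns the pair the total
weight of all start-to-end paths whose label projections equal `(x, y)`.

The productive way to think about such a machine is as an *infinite matrix*
whose rows are indexed by input sequences and columns by output sequences.
Then:

* `composeMachines(T, U)` is the matrix product: `(TU)[x, z] = sum_y
  T[x, y] U[y, z]`.  This is how sequence transformations chain — e.g. a
  DNA motif generator times a DNA-to-RNA converter is an RNA motif
  generator.
* `addMachines` is elementwise addition, `intersectMachines` the
  elementwise (point) product, `transposeMachine` exchanges the tapes, and
  `scaleMachine` is scalar multiplication.
* A machine with an empty input alphabet is a *generator* (a row vector —
  a distribution over sequences); with an empty output alphabet a
  *recognizer* (a column vector).  Each is the transpose of the other.

String-like operations complete the toolkit: concatenation, reversal,
reverse-complement (on nucleic tapes), `n`-fold repetition, Kleene closure
and local-match flanking.

## Inference

`forwardScore` computes the log pair weight by the Forward recurrence over
(input position, output position, state), in `O(|x| |y| |transitions|)`
time with the full DP table in memory; this is a prototyping-scale choice —
checkpointed or linear-space variants are deliberately out of scope.
`viterbiPath` is the same recurrence with max and traceback;
`forwardBackward` yields posterior expected transition counts and exact
derivatives of the pair weight with respect to every assigned parameter
(assembled from expected transition flows and the symbolic derivatives of
the weight expressions).  All dynamic programming runs in natural-log space
with log-sum-exp; zero weight is the `-Inf` sentinel.

The Forward recurrence requires the *silent* subgraph (transitions with
epsilon on both tapes) to be acyclic and topologically sorted.  The algebra
constructors maintain this invariant where they can; `toposortSilent`
restores the order (stably, so serialized output is reproducible),
`eliminateSilentCycles` removes silent cycles exactly by marginalization
(each silent strongly connected component with weight matrix `S` is
replaced by its closure `(I - S)^(-1)`, valid when the spectral radius of
`S` is below 1; we treat a radius above `1 - 1e-12` as divergent), and
`breakSilentCycles` is the approximate fallback that deletes
back-transitions — useful when weights are symbolic and the closure cannot
be evaluated.  A third conceivable fallback — leaving silent cycles in
place and accepting a slightly wrong Forward value — is deliberately not
offered: every inference entry point insists on an acyclic silent
subgraph.

Composition deserves a note on epsilon handling.  Composite states are
(left state, right state, phase) triples: from phase 0 both the left
machine's output-silent moves and the right machine's input-silent moves
are allowed, but taking a right-machine silent move enters phase 1, where
left-machine silent moves are blocked until a synchronized symbol exchange
resets phase 0.  This is the standard epsilon-filter canonicalization: the
two kinds of silent move commute, so forcing left-before-right between
exchanges counts every joint path exactly once.  Intersection synchronizes
transitions with identical label pairs and reuses the same filter; its
contract therefore holds for machines whose label splitting agrees
(recognizers and generators built from per-symbol transitions, the main use
case), and the construction refuses to proceed if it would create a silent
cycle.

## Parameter fitting

`fitBaumWelch` implements constrained EM.  The E-step accumulates expected
transition counts with Forward–Backward; the M-step renormalizes counts
within each *probability group* (a set of parameters constrained to sum
to 1).  This update is the exact maximizer of the EM surrogate only when
every trainable weight is a *monomial* in the parameters — a constant times
a product of parameter powers — so non-monomial trainable weights are
rejected outright rather than silently mis-fit.  Rate parameters may appear
in machines but are not trainable.  Convergence defaults: stop when the
total log-likelihood improves by less than `1e-6`, or after 100
iterations.  The log-likelihood trace is non-decreasing, which the test
suite asserts on every fitting fixture.

## Decoding

The decoding problem is: given a machine and (optionally) an input
sequence, find the output sequence with the greatest *total* weight — a sum
over paths, not a single best path.  A search hypothesis is an output
prefix plus the vector of accumulated log weights per machine state; its
score is the log-sum-exp over states.

* `prefixSearch` is exact best-first search.  It requires the machine to be
  substochastic (per-state outgoing weight sums at most 1), which makes the
  score non-increasing under extension and hence an admissible bound.
  Ties are broken toward the lexicographically smallest output.
* `beamSearch` is the heuristic variant, synchronized by output length
  (the natural axis for label sequences; frame-synchronous search would
  require a time-indexed machine), keeping the top-`width` prefixes per
  length and merging hypotheses with equal prefixes by summing state
  weights.  The merge is what makes this CTC-style decoding rather than
  Viterbi: weight is pooled per label sequence.  As the width grows the
  result converges to `prefixSearch`.
* `sampleOutputs` draws output sequences with probability proportional to
  their weight, exactly, by solving the linear system `Z = A Z + stop` for
  per-state tail weights and sampling transitions proportional to
  `w * Z[to]`.
* `bestTransduction` is Viterbi with a free output tape: the single
  heaviest path consuming a given input, which is the right tool for
  running deterministic or unambiguous transducers forwards (encoding) and,
  via the transpose, backwards (decoding).  The default search bound for
  prefix and beam search is `2 * (|x| + 1) * |states|`, a safety valve
  against runaway expansion on pathological machines.

## The DNA storage code family

The preset machines reproduce a complete repeat-avoiding DNA storage code:

* `binaryToTernary()` batches three input bits (most significant first) and
  emits the two-digit base-3 representation of the batch value, high digit
  first.  Eight of the nine trit pairs are used; "22" never arises from
  data, so with `withEof = TRUE` the machine appends "22" as an
  end-of-message marker before terminating.  The batching costs a factor
  `log 9 / log 8 ≈ 1.06` in output length over a perfect radix conversion
  (`codeEfficiency(3)`); perfect conversion between indivisible bases is
  impossible for a finite-state machine, and the next batch size that
  improves the bit:trit ratio is 11 bits to 7 trits (`codeEfficiency(11)`,
  ratio `11/7`), at the cost of order `2^11` states.
* `ternaryToDna()` maps each trit to one nucleotide, excluding the
  previously emitted base: after base `b`, trit `t` selects the `t`-th
  (0-based) of the alphabetically ordered bases other than `b`.  At the
  start the previous base is deemed T, which makes the start rule identical
  to the generic rule — a uniformity convention; the first trit maps onto
  (A, C, G).  The output can never repeat a base, the failure mode most
  sequencers are worst at.  Repeat-free DNA carries `log2 3 ≈ 1.58` bits
  per symbol, computed in `outputCapacity()` as the log spectral radius of
  the emitting-transition count matrix.
* `storageCode()` is the composition of the two.  Its two inefficiencies
  multiply to exactly `4/3` of the Shannon-optimal (2 bits/nucleotide) DNA
  length (`storageCodeRates()`).  Encoding is `storageEncode` (messages are
  zero-padded to whole 3-bit batches; the decoder cannot distinguish the
  padding in-band, so the original bit length travels out-of-band, as in
  the CLI's `--bit-length` option); decoding runs the transposed machine.
* `hamming74()` and `bitflipChannel(q)` add error correction: best-path
  decoding through their composition corrects every single-bit flip per
  7-bit block whenever `q < 0.5`.
* `deBruijnGenerator(k, prohibited)` generalizes repeat avoidance to
  arbitrary motif avoidance by deleting prohibited k-mers from a de Bruijn
  transition graph.

Two layout notes, recorded as design choices: the trit-pair and bit orders
within a batch are most-significant-first (a convention is needed for
byte-exact tests; the figure-level description does not pin one down), and
the ternary-to-DNA machine uses six states — start, one per last-emitted
base, and a dedicated end state reached silently — because with the
first/last start/end convention a five-state layout cannot accept outputs
ending in every base.

## Error models and other presets

`errorModelSCI()` is the symmetric context-independent sequencing-error
model: match, insert and delete states (plus start and end — five states)
with a 4x4 substitution table and a shared, symbolic gap open/extend pair.
`errorModelACD()` is the asymmetric context-dependent model: the
match/insert/delete triple replicated over the 16 dinucleotide flanking
contexts (previous reference base x current reference base), plus start
and end — 50 states.  Insertions and deletions get separate, per-context
probabilities.  At the reference start the previous base is deemed A (a
convention; the context of the first position is otherwise undefined).
Default per-context values (mismatch 0.02, insertion 0.02, deletion 0.02,
insertion extension 0.2) are in the range reported for nanopore-class
instruments; they are starting points for fitting, not claims.

`ctcRecognizer(probMatrix)` turns a per-frame probability matrix (one row
per frame, one column per label plus a blank) into the recognizer whose
weight for a label sequence is the summed weight of all frame paths that
collapse to it — merge adjacent repeats, then delete blanks.  States track
(frame, last frame symbol), so a repeated label merges unless a blank
separates the copies.  `proteinToCodon()` translates amino acids to codons
through two intermediate states per codon, defaulting to uniform synonymous
codon usage under the standard genetic code; `jukesCantorMachine(t, rate)`
is the classic one-state substitution model, and `regexMachine` builds
recognizers from restricted regular expressions by Thompson construction
(unambiguous patterns accept with weight exactly 1; ambiguous ones, like
`A|A`, with multiplicity — exact-multiplicity normalization of ambiguous
patterns is out of scope).

## What the synthetic fixtures do and do not show

The test suite builds every input it needs: random machines (with silent
subgraphs kept acyclic by construction), random substochastic generators,
random CTC frame matrices, binary messages, and a miniature HMMER3 profile
written from code.  Correctness is established against independent oracles
— brute-force path enumeration, exhaustive CTC collapse, splits-sum
identities, the standard regex engine, and closed-form MLEs — rather than
against the package's own dynamic programming.  Problem sizes were chosen
at desk scale: machines of at most 5 states and label strings of length at
most 4 for enumeration oracles; 100 random machines for the Forward oracle
sweep; 500 sampled sequences for EM parameter recovery (tolerance 0.05
absolute); exhaustive round trips for all messages up to 12 bits and all
ternary inputs up to 8 trits; all 16 x 7 single-bit error corrections; a
fixed 3,000-bit message for the asymptotic code-rate check.  What passing
these suites shows is that the algebra, inference, and code machinery
implement their mathematical contracts; it does not show anything about
error rates on real sequencing reads — the error-model and CTC presets are
architecturally faithful, but their empirical performance on instrument
data depends on fitted parameters and real signal, which are outside the
package's remit.

## Numerical choices

* Log-space DP throughout; `-Inf` is the zero-weight sentinel.
* "Sums to 1" checks use absolute tolerance `1e-9` (double-precision
  headroom); the silent-closure divergence threshold is a spectral radius
  of `1 - 1e-12`.
* Viterbi ties prefer the transition earliest in the transition table;
  search ties prefer the lexicographically smallest output; topological
  sorting is stable.  All three make outputs byte-reproducible.
* Degenerate inputs: the single-state machine maps empty to empty with
  weight 1; pruning an unsatisfiable machine returns the zero machine with
  a warning; a state with zero outgoing weight cannot be probabilistically
  normalized (error).
* "IO-conditioned" (in `machineStats`) counts transitions with non-epsilon
  labels on both tapes, the convention used when quoting model sizes.
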