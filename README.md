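# wfst: weighted finite-state machines for sequence analysis

Bioinformatics is full of state machines — pair HMMs for alignment,
profile HMMs for domain search, error models for sequencing instruments,
CTC decoders for neural basecallers, coding schemes for DNA data storage.
Inference libraries for these models abound; what is usually missing is the
ability to treat the machines themselves as *manipulable mathematical
objects*.  `wfst` fills that gap in R: it implements weighted finite-state
machines (input/output automata with weighted, possibly epsilon-labelled
transitions) together with the algebra that combines them, the dynamic
programming that scores them, the EM that fits them, and the searches that
decode them.  It is aimed at people who prototype sequence models: build a
machine from modular parts in a few lines, check it against brute force,
then decide whether a bespoke optimized implementation is worth writing.

## The formalism

A machine `T` defines a weight for every pair of sequences: `T[x, y]` is
the total weight of all start-to-end transition paths with input label `x`
and output label `y`.  Viewed as an infinite matrix indexed by sequences,

* `composeMachines(T, U)` is the matrix product
  `(TU)[x, z] = Σ_y T[x, y] U[y, z]`,
* `addMachines`, `intersectMachines`, `transposeMachine`, `scaleMachine`
  are elementwise sum, elementwise (point) product, transpose and scalar
  multiple,
* a *generator* (empty input alphabet) is a row vector — a weighted
  language; a *recognizer* (empty output alphabet) is a column vector,

and string-like operations (`concatMachines`, `reverseMachine`,
`reverseComplementMachine`, `repeatMachine`, `kleeneStar`, `localFlank`)
act on machines as weighted languages.  `forwardScore`, `viterbiPath` and
`forwardBackward` implement the Forward, Viterbi and Forward–Backward
recurrences (log-space, `O(|x|·|y|·|τ|)`); `fitBaumWelch` is
constrained Baum–Welch EM; `prefixSearch` / `beamSearch` /
`sampleOutputs` / `bestTransduction` find or sample high-weight output
sequences.  Machines serialize to a validatable JSON format, import from
FASTA, CSV and HMMER3 profiles, and export to GraphViz; `wfstCLI()` (with
a thin Rscript wrapper in `inst/cli/`) exposes everything as shell
subcommands.

## Worked example

Convert a DNA motif to RNA by multiplication, then store a binary message
as repeat-free DNA:

```r
library(wfst)

## TaqI site generator x DNA-to-RNA converter = RNA motif generator
rna <- composeMachines(seqGenerator("TCGA"), dnaToRna())
forwardScore(rna, "", "UCGA")$logWeight
#> [1] 0                     # log weight 0: "UCGA" has weight exactly 1

prefixSearch(rna)$output    # best output of the composed generator
#> [1] "UCGA"

## DNA storage: 3 bits -> 2 trits -> 2 non-repeating nucleotides
enc <- storageEncode("110010111001")
enc$dna
#> [1] "GACTGCAGTG"          # 12 bits -> 10 nt (8 data + 2 end-of-message)
storageDecode(enc$dna, bitLength = enc$bitLength)$bits
#> [1] "110010111001"        # round trip is the identity

unlist(storageCodeRates())
#>    binaryToTernary       ternaryToDna          composite repeatFreeCapacity
#>           1.056642           1.261860           1.333333           1.584963
```

The rates line reads: the batched binary-to-ternary step inflates the
message by `log 9 / log 8 ≈ 1.06`, the repeat-free constraint by
`log 4 / log 3 ≈ 1.26`, so the encoded DNA is exactly 4/3 of the
Shannon-optimal length; a repeat-free nucleotide carries `log2 3 ≈ 1.58`
bits.  Asymptotically the code stores 3 bits per 2 nucleotides: a
3,000-bit message encodes to 2,002 nt (2,000 data + 2 end-of-message).

Sequencing-error models are machines too:

```r
machineStats(errorModelACD())
#> $nStates          [1] 50    # match/insert/delete x 16 contexts + start/end
#> $nTransitions     [1] 1221
#> $nIoConditioned   [1] 784
```

Composing `proteinToCodon()` with an error model gives a
protein-to-noisy-DNA aligner; composing `hamming74()` with
`bitflipChannel(q)` gives an error-correcting storage channel whose
best-path decode fixes any single flipped bit per block.

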