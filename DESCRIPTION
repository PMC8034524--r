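Package: wfst
Title: Weighted Finite-State Machines for Sequence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construct, algebraically combine, normalize, fit and decode
    weighted finite-state machines (input/output automata) for biological
    sequence analysis.  Machines are treated as infinite matrices indexed by
    sequences: they can be multiplied (composed), added, intersected,
    transposed, concatenated, reversed, reverse-complemented and repeated.
    Inference is by Forward, Viterbi and Forward-Backward dynamic
    programming, with constrained Baum-Welch EM for parameter fitting, and
    exact prefix search, CTC-style beam search and stochastic sampling for
    finding high-weight output sequences.  Preset machines include DNA
    data-storage codes (binary-to-ternary and ternary-to-repeat-free-DNA
    converters, Hamming(7,4) parity coding, motif-avoiding de Bruijn codes),
    context-dependent sequencing-error models, CTC merge-repeats
    recognizers built from per-position symbol probabilities, protein-to-codon
    translators and the Jukes-Cantor substitution model.  Machines are
    serialized to a validatable JSON format, importable from FASTA, CSV and
    HMMER3 profiles, and exportable to GraphViz.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
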