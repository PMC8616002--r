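Package: pHdisorder
Title: pH-Dependent Prediction of Protein Intrinsic Disorder and
    Order-Disorder Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the folding state of proteins as a function of solution
    pH from sequence alone. Per-residue net charge is computed with the
    Henderson-Hasselbalch equation and combined with a pH-dependent,
    protonation-weighted lipophilicity scale through the linear
    charge-hydrophobicity boundary, yielding a signed disorder score (the
    DispH score) at every pH of a user-defined grid. Sign changes of the
    score outside a confidence band are reported as conditional folding or
    unfolding transitions, with interpolated crossing pH values and
    acid/neutral/basic classification, for single sequences or whole FASTA
    batches. Includes deterministic synthetic-sequence fixtures with designed
    titration behaviour, CSV/JSON result serialization and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
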