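Package: pegsite
Title: Criteria-Driven PEGylation Site Engineering and Enzyme Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@pegsite.dev",
    role = c("aut", "cre"))
Description: Rational design of amine-targeted PEGylation for therapeutic
    enzymes. Computes per-residue structural features (Shrake-Rupley solvent
    accessibility, C-alpha secondary structure, salt bridges, active-site
    proximity, B-factor flexibility) and alignment-based conservation, and
    applies an engineer-in (arginine-to-lysine) / engineer-out
    (lysine-to-arginine) criteria engine with a full per-criterion audit
    trail. Also designs N-terminal truncation constructs from structural
    disorder, proline stalling motifs and ortholog comparison, models PEG-mer
    mass ladders, fits steady-state Michaelis-Menten kinetics, and generates
    synthetic fixtures with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
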