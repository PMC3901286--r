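Package: petrinetr
Title: Petri-Net Analysis of Metabolic Networks: Invariants, Modules and
    Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models metabolic reaction networks as place/transition Petri
    nets and detects functional modules by steady-state and connectivity
    methods.  Computes minimal transition and place invariants (elementary
    flux modes and conservation relations) by Fourier-Motzkin elimination
    over the integers, decides coverage by t-invariants (CTI) both directly
    and via the Farkas dual system, derives maximal common transition sets,
    enzyme subsets, hierarchical t-clusters under the Tanimoto support
    distance, and minimal cut sets, scores partitions of the bipartite
    directed net by Q-modularity and optimizes them with a genetic
    algorithm, and reduces networks by common and invariant transition
    pairs while preserving the CTI property, with lift-back of invariants
    to the original net.  Reads and writes PNML, a METATOOL-style reaction
    format, and incidence matrices as TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    tools,
    utils,
    xml2
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
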