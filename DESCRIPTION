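Package: motorprep
Title: Optimal-Control Analysis of Motor Preparation in Recurrent Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to study when and why preparatory neural activity arises in
    recurrent rate-network models of primary motor cortex that drive an
    effector (a planar two-link arm, or a one-dimensional toy plant) through
    delayed reaches and reach sequences. The package generates
    inhibition-stabilized and simpler motif networks, solves for minimum-cost
    control inputs with an iterative linear-quadratic regulator (iLQR),
    quantifies reliance on the delay period with a preparation index, relates
    preparation to Gramian-based controllability and observability summaries
    of the network, and decomposes population activity into orthogonal
    preparatory and movement subspaces with occupancy time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite
Config/testthat/edition: 3
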