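Package: moldiff
Title: Discrete Mask-and-Replace Diffusion for Molecular Graph Generation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Generative modelling of 2D molecular graphs with an
    absorbing-state ("mask-and-replace") discrete denoising diffusion
    process. Molecules are encoded as fixed-size categorical graphs of
    atom types, formal charges and bond types (with padding and mask
    vocabulary), corrupted by per-step transition matrices that keep,
    uniformly replace or mask each entry, and denoised by a graph
    transformer with random node initialization trained on a variational
    bound plus auxiliary cross-entropy. Supports unconditional sampling,
    property-conditioned sampling, and scaffold-preserving molecular
    optimization by clamping a sub-molecule during reverse diffusion,
    together with standard generation metrics (validity, uniqueness,
    novelty, internal diversity, QED/SAS/logP/TPSA panels, mean absolute
    deviation from a conditioning target). Chemistry primitives
    (SMILES parsing, sanitization, descriptors, circular fingerprints)
    are delegated to RDKit through a bundled batched Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with rdkit, on the PATH as 'python'
Config/testthat/edition: 3
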