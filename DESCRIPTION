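Package: ceapain
Title: Agent-Based Simulation of PKC-delta and Somatostatin Neurons in the
    Central Amygdala
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based model of the two major inhibitory neuron populations
    of the central nucleus of the amygdala (CeA), protein kinase C-delta
    (PKCd) and somatostatin (SOM) expressing neurons, in the left and right
    hemispheres. Neurons accumulate damage during noxious stimulation,
    become sensitized, sample firing rates from truncated normal
    distributions, and inhibit one another through a stochastically
    generated directed network. The model outputs an emergent pain measure
    before, during, and after simulated injury. Includes an experiment
    layer for replicate batches, cell-type silencing (chemogenetic
    inhibition), local sensitivity analysis, and Hedges' g standardized
    effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
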