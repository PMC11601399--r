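Package: pbwmchunk
Title: Chunk-Augmented Prefrontal-Basal Ganglia Working Memory Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rate-coded simulation of a prefrontal cortex-basal ganglia
    working memory circuit augmented with a ring-attractor chunking layer.
    The network performs a continuous-report (color wheel) delayed
    estimation task, learns striatal input and output gating policies via
    dopaminergic three-factor reinforcement learning, and can merge
    ("chunk") similar memoranda into a shared prefrontal stripe. Includes
    the behavioral analysis suite: error histograms with mixture-model
    guess rates, out-of-cluster variance analysis, stripe usage, gating
    policy traces, dopamine gain sweeps, recency curves, and analytic
    chance-recall probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, stats, utils, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
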