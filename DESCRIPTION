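Package: ganet
Title: Fast Mutual-Information Gene Association Networks with
    Condition-Specific Edge Annotation
Version: 0.1.0
Authors@R:
    person("ganet", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs genome-scale gene association networks from
    normalized expression compendia using a closed-form Spearman-transform
    mutual information estimator, removes likely indirect edges with
    ARACNE-style data processing inequality filtering, partitions networks
    into functional subnetworks by Markov clustering, and annotates each
    inferred association with the experimental conditions (chips) under
    which it operates via a leave-one-condition-out z-test.  Includes a
    synthetic steady-state expression simulator over known regulatory
    topologies and an AUROC/precision-recall benchmarking harness, plus a
    command-line interface covering the full build/refine/cluster/annotate
    workflow.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
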