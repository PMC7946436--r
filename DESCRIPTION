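Package: iplparc
Title: Consensus Parcellation, Task Decoding and Connectivity Analysis of
    Inferior Parietal Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying functional specialization of the inferior
    parietal lobe (IPL) from trial-wise activity estimates across attention,
    semantic and social-cognition tasks. Implements ensemble k-means
    parcellation of region-of-interest voxels with majority voting over a
    battery of cluster validity indices and stability-based consensus
    labelling; leave-one-subject-out one-vs-rest logistic decoding of task
    identity from subregion-averaged activity with trial balancing,
    deconfounding and run-wise standardization; beta-series functional
    connectivity between subregions and cortical parcels tested against a
    pooled permutation baseline with seven-network aggregation; and a
    random-effects permutation test for task-specific effective-connectivity
    modulations. A synthetic-data module generates trial designs, voxel and
    parcel activity, and modulation matrices with planted ground truth so the
    entire pipeline is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
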