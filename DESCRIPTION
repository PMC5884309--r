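Package: apathynet
Title: Structural Connectome Analysis of Apathy in Cerebral Small Vessel Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline linking apathy to the efficiency of
    an a-priori reward sub-network in structural brain connectomes, of the
    kind studied in cerebral small vessel disease. Provides deterministic
    tensor tractography on voxelized direction/FA fields with angle and FA
    termination rules, length-weighted 90-node connectome construction,
    the network-based statistic (NBS) with permutation family-wise error
    control, weighted global efficiency and sum-of-weights on reward, motor
    and visual sub-networks of the AAL-90 parcellation, apathy scoring from
    six Geriatric Depression Scale items, and partial-correlation
    specificity testing. A synthetic-cohort generator with configurable
    planted effects makes every stage testable end-to-end without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
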