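Package: knitparc
Title: Connectivity-Profile Parcellation of the Infant Thalamus with
    Bootstrap Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parcellates a seed brain structure (designed for the neonatal
    thalamus) from resting-state BOLD fMRI by clustering per-voxel functional
    connectivity profiles to a set of cortical and subcortical regions with
    spherical (cosine-distance) k-means. Provides the conventional
    winner-takes-all baseline driven by partial correlations to merged lobes,
    Hungarian matching of cluster identities across bootstrap replicates,
    majority-vote consensus parcellations with voxel-wise uncertainty maps,
    coefficient-of-variation-of-IoU and silhouette diagnostics for choosing
    the number of clusters, and developmental summary metrics (relative
    cluster volumes, bilateral symmetry index, ipsilateral/contralateral
    connectivity ratios, global and region-to-region connectivity). A
    synthetic multi-subject BOLD phantom with planted, bilaterally symmetric
    clusters makes the whole pipeline testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    signal,
    cluster,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
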