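# knitparc

Connectivity-profile parcellation of the infant thalamus from resting-state
BOLD fMRI, with bootstrap uncertainty quantification and a winner-takes-all
baseline.

## What it does, and for whom

Thalamic nuclei are functionally distinct but nearly invisible on neonatal
structural MRI. What distinguishes them is their *connectivity profile*: the
vector of functional connectivity (FC) values between a thalamic voxel and a
set of R brain regions,

    p(v) = ( corr(x_v, ROI_1), ..., corr(x_v, ROI_R) ),

where each entry is the Pearson correlation between the voxel's BOLD series
and every voxel of the ROI, averaged across the ROI, then Fisher-Z
transformed (z = ½ ln((1+r)/(1−r))) before group averaging. `knitparc`
clusters these profiles with **spherical k-means** (cosine distance:
profiles are unit-normalized, centroids renormalized), so voxels group by
*where* they connect, not by how strongly.

Robustness is quantified by resampling: subject bootstraps (75% of
subjects, 40 replicates) and timepoint bootstraps (75% of timepoints for a
fixed subject subset, 10 replicates), with replicate cluster identities
aligned by the Hungarian algorithm, a per-voxel majority-vote consensus,
and the uncertainty map

    U(v) = 1 − N_c*(v) / N_total,

the complement of the majority-label proportion across replicates. Model
order (k) is assessed with the coefficient of variation of
intersection-over-union across replicate pairs (CoV of IoU) and the cosine
silhouette. Developmental summary metrics — relative cluster volumes,
bilateral symmetry index, ipsilateral/contralateral connectivity ratios
Ri = FC(RT→RH)/FC(LT→LH) and Rc = FC(RT→LH)/FC(LT→RH), global thalamic
connectivity and ROI-ROI matrices — are included, along with the
conventional **winner-takes-all** baseline (argmax over partial
correlations to five merged lobes) for comparison.

Everything is exercisable without any data download: a synthetic
multi-subject 4D phantom plants spatially contiguous, bilaterally symmetric
clusters whose FC profiles are known mixing weights, so every stage can be
tested against ground truth. The package is aimed at developmental
neuroimaging groups who want a reproducible, fully seeded implementation of
profile-based parcellation with honest uncertainty reporting.

## Worked example

A small phantom end to end — simulate 6 subjects, preprocess (discard 5
timepoints, 3 mm FWHM smoothing, 0.08 Hz low-pass, z-score), compute
profiles, bootstrap, build the consensus and compare against the planted
truth:

```r
library(knitparc)

spec <- phantomSpec(dims = c(20L, 20L, 20L), nRois = 6L, kTrue = 3L,
                    profileMatrix = phantomProfileMatrix(3L, 6L),
                    nTimepoints = 300L, seed = 7L)
cfg <- knitConfig(phantom = list(spec = spec, nSubjects = 6L), k = 3L,
                  nSubjectBootstraps = 20L, masterSeed = 42L)
run <- runPipeline(cfg)
run$consensus
run$uncertainty
compareMethods(run)$report
relativeVolumes(run$ensemble)$table
```

which prints:

```
Parcellation [consensus]: k=3, 1200 labelled voxels (400/400/400)
UncertaintyMap: 1200 voxels, mean U=0.0003, uBar=0.0500 (N_total=20)
  method k symmetry ari largestVolume
1   knit 3    1.000   1         0.334
2    wta 3    0.993   1         0.337
  cluster  mean       sd
1       1 0.333 0.000392
2       2 0.334 0.000392
3       3 0.333 0.000000
```

Reading this: the consensus recovers the three planted clusters exactly
(ARI = 1 against the ground truth, border-blend voxels excluded), the
parcellation is mirror-symmetric (symmetry index 1.0), per-voxel
uncertainty is essentially zero away from cluster borders, and each cluster
occupies a third of the seed structure with near-zero variation across the
20 bootstrap replicates. On harder phantoms (weaker planted weights, mixed
two-lobe profiles) the KNIT and WTA rows separate — see the acceptance
script below.

A thin CLI for shell use lives at `inst/scripts/knit.R`
(`simulate` / `run` / `compare` subcommands).

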