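# cladedelim

Mitochondrial clade delimitation and diversity analysis for DNA-barcode
data in R.

Deeply structured mitochondrial datasets — the motivating case is the
human head/body louse, whose COI and cytb sequences fall into five clades
up to ~10–14% divergent while the host species varies by under 1% — raise
a recurring analysis chain: are the clusters real species-level units, how
diverse is each, how is variation partitioned geographically, and how fast
are the parasites diverging relative to their hosts? `cladedelim` packages
that chain for anyone working with COI-5′/cytb barcode data: molecular
ecologists, parasitologists and barcoding labs.

## What it computes

* **K2P distances with pairwise deletion.** Only columns where both
  members of a pair are unambiguous bases are compared;
  `d = -½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` with transition/transversion
  proportions `P`, `Q`. Distance histograms report empty "barcode gap"
  intervals; per-group summaries give intra-clade maxima and
  nearest-neighbour (NN) distances.
* **OTU delimitation by two methods.** A refined-single-linkage clusterer
  (single linkage at 2.2% → Markov clustering refinement → silhouette
  selection) and a barcode-gap partitioner (initial + recursive splitting
  over a sweep of prior intraspecific divergences, X = 1.5), with a
  concordance table and adjusted Rand agreement between methods.
* **NJ trees** with column-resampling bootstrap supports, monophyly
  checks, and a simple strict-clock age linearisation from one calibration
  split.
* **Population genetics.** Haplotype collapsing (complete deletion),
  `n, S, k, π, h, Hd`, Tajima's D, Fu & Li's D and D*, hierarchical AMOVA
  with Φ statistics and permutation tests, and minimum spanning haplotype
  networks (union of all MSTs, optional epsilon relaxation).
* **Host–parasite comparison.** Pairwise divergences across a labelled
  host/parasite accession panel, amino-acid substitution counts under the
  appropriate mitochondrial genetic codes, and divergence-rate ratios.
* **A clade-structured simulator.** Kingman coalescent genealogies grafted
  onto a clade backbone, K80 sequence evolution matched to the K2P
  estimator, country labels nested in clades — every pipeline stage is
  testable offline with known truth.

## Worked example

```r
library(cladedelim)

ds  <- simulate_clade_dataset(sim_scenario(seed = 1))
dm  <- k2p_matrix(ds$alignment)
res <- resl(dm)

print(dm)
#> k2p_dist: 100 sequences, max distance 12.1%
print(res)
#> partition (resl): 100 sequences in 5 OTUs
adjusted_rand_index(res, ds$truth)
#> [1] 1

group_summary(dm, res)
#>    group  n   max_intra nn_group nn_distance
#> 1 OTU_01 20 0.013820196   OTU_02  0.02948654
#> 2 OTU_02 20 0.003046466   OTU_01  0.02948654
#> 3 OTU_03 20 0.003048790   OTU_01  0.06887543
#> 4 OTU_04 20 0.004574937   OTU_01  0.07715462
#> 5 OTU_05 20 0.006104580   OTU_01  0.09828453

dist_histogram(dm)$empty_intervals
#>      lo    hi
#> 1 0.015 0.025
#> 2 0.040 0.065

diversity(ds$alignment)
#>     n sites   S    k     pi  h    Hd tajima_D fu_li_D fu_li_Dstar
#> 1 100   658 138 44.5 0.0676 23 0.932     2.22      NA        2.08
```

Reading it: the simulated dataset carries five clades; the refined
single-linkage clusterer recovers exactly five OTUs in perfect agreement
with the generating truth (adjusted Rand index 1). Within-OTU distances
top out at 1.4% while nearest neighbours sit at ≥2.9%, and the distance
histogram is bimodal with an empty interval between the two modes — the
barcode gap the delimitation relies on. The pooled diversity row shows the
signature of pooling divergent clades: high haplotype diversity and a
strongly positive Tajima's D.

`run_pipeline()` executes the whole chain (QC → distances → delimitation →
tree → diversity → AMOVA → network) and writes a TSV/Newick/JSON report
bundle whose contents are byte-identical across reruns with the same seed.

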