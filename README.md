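# arowana

Simulation-based demographic inference for two-basin SNP data, built around
the silver arowana (*Osteoglossum bicirrhosum*) study system: 13 diploids
(11 Tocantins-Araguaia/TAb, 2 Amazon/AMb) genotyped at 1661 biallelic DArT
SNPs, and the question of how the two basin populations arose — persistent
panmixia, vicariance, or a directed founder-effect colonization.

The package is aimed at population geneticists who want a tested, reusable
version of this workflow:

1. **Coalescent simulation** (`simulate_dataset()`, `simulate_batch()`) of
   four two-deme scenarios under uniform priors — panmixia; vicariance; TAb
   colonized from AMb with a founder bottleneck (size ratio θrF-A) and
   exponential recovery (ratio θrC-A); and the mirror colonization. Scaled
   parameters follow θ = 4·Ne·μ·G per site and CT = DT/(4·Ne·G), with
   Ne ~ U(10⁴, 10⁶), DT ~ U(0, 2·10⁶) yr, G ~ U(1, 2) yr,
   μ = 1.25·10⁻⁹ /site/yr, θrF-A ~ U(0.01, 0.1), θrC-A ~ U(0.1, 1).
   Datasets are `ms`-style 0/1 haplotype blocks with a fixed number of
   segregating sites; by default every SNP draws its own genealogy
   (`linkage = "unlinked"`, matching scattered reduced-representation
   markers), with the classical single-genealogy layout available.
2. **Image encoding** (`matrix_to_image()`): rows sorted within deme blocks,
   site columns sorted into a joint-frequency-spectrum-like canonical order,
   fixed shape with padding/subsampling, unphased genotypes as {0, ½, 1}.
3. **Convolutional inference** (`train_classifier()`, `select_model()`,
   `train_regressor()`, `estimate_params()`): a compact CNN (two
   batch-normalized 3×3 conv + max-pool blocks, a dense layer with dropout,
   softmax or linear head, Adam, mini-batch 250) for 4-way scenario
   classification and 4-parameter regression (Ne, DT, θrF-A, θrC-A on
   normalized scales), scored by RMSE and Spearman's ρ on held-out
   simulations. The network is implemented in compiled code inside the
   package; no external deep-learning framework is required.
4. **SNP statistics** (`diversity()`, `pairwise_fst()`, `pcoa()`):
   observed/unbiased expected heterozygosity, G_IS, Weir–Cockerham pairwise
   F_ST, and principal coordinates on 1 − IBS distances, with readers and
   writers for VCF, DArT two-row CSV and plain 0/1/2 matrices.
5. **Synthetic data** (`generate_dataset()`, `generate_pseudo_empirical()`):
   a hierarchical Balding–Nichols generator emulating the empirical datasets
   (sample sizes, locus counts, missingness, between/within-basin F_ST), plus
   a coalescent-backed pseudo-empirical path for self-consistency tests.

`run_pipeline()` chains everything (simulate → encode → train → select →
estimate → report) from a single seeded `run_config()`; `run_stats()` covers
the statistics-only route.

## Worked example

A reduced but complete run (a few minutes on one CPU core): simulate
training data, select the demographic scenario for a pseudo-empirical
dataset generated under the TAb-colonization scenario at the point estimates
Ne = 468,195, DT = 1,049,955 yr, θrF-A = 0.0551, θrC-A = 0.547, then
estimate its parameters.

```r
library(arowana)

cfg <- run_config("desk", seed = 1,
                  n_per_model = 500L, train_n = 1600L, test_n = 400L,
                  estimation_n = 4000L, estimation_test_n = 400L,
                  epochs = 10L, n_sites = 200L)
scenario <- tibble::tibble(model_id = 3L, ne = 468195, dt = 1049955, g = 1.5,
                           theta = 4 * 468195 * 1.25e-9 * 1.5,
                           ct = 1049955 / (4 * 468195 * 1.5),
                           founder_ratio = 0.0551, growth_ratio = 0.547)
pseudo <- generate_pseudo_empirical(scenario, dataset_shape(11, 2, 200),
                                    missing_rate = 0.0095, rng_seed = 7)
report <- run_pipeline(cfg, empirical = pseudo)
report
```

```
== demographic inference report ==
empirical data: user
held-out classification accuracy: 0.885
selected scenario: model 3 (posterior 0.873)
parameter recovery (held-out simulations):
     parameter      rmse spearman_rho
            ne 0.1755068    0.4622841
            dt 0.2496267    0.5486807
 founder_ratio 0.2960093    0.2650785
  growth_ratio 0.2143677    0.7160503
parameter estimates (median and 95% bootstrap interval):
     parameter        point       median        lower        upper
            ne 8.659054e+05 3.267525e+05 7.873877e+04 1.411539e+06
            dt 1.334647e+06 1.143976e+06 4.916293e+05 1.717551e+06
 founder_ratio 5.859255e-02 4.886238e-02 3.164626e-02 7.791394e-02
  growth_ratio 7.517086e-01 4.925301e-01 2.181150e-01 8.389997e-01
```

Reading the output: the classifier, trained on 1,600 simulated datasets at
this reduced scale, separates the four scenarios with 88.5% held-out
accuracy and assigns the pseudo-empirical dataset to the correct
TAb-colonization scenario with posterior 0.87; the regression head recovers
divergence time and growth ratio best at this scale (Spearman's ρ 0.55 and
0.72 on held-out simulations), and the bootstrap intervals in the final
block cover the generating Ne and DT. The `data_stats` slot additionally
holds the diversity table (A, H_O, H_E, G_IS per population) and pairwise
Weir–Cockerham F_ST of the input matrix. At the full workstation scale
(`run_config("desk")`: 2,000 simulations per scenario at 400 sites,
20,000 estimation simulations) held-out accuracy reaches the mid-90s and
ρ(DT) ≈ 0.60 — see the acceptance script below.

Diversity statistics of any genotype file:

```r
gm <- generate_dataset(synth_preset("bicirrhosum", rng_seed = 1))
diversity(gm)
tidy(pairwise_fst(gm))
autoplot(pcoa(gm))
```

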