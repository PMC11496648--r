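# edmweb

Empirical dynamic modelling (EDM) of species interaction webs from
**replicated short time series** — the data regime of mesocosm
experiments, where each experimental unit yields only ~10 censuses but
many units (tanks × years) share similar dynamics.

`edmweb` is for community ecologists and ecotoxicologists who want to go
from a long-format density panel (tank × treatment × year × census ×
functional group) to:

1. a **causal interaction network** (convergent cross mapping with a
   three-criterion acceptance cascade),
2. **time-varying per-capita interaction effects** for every accepted
   link (regularized multivariate S-map), and
3. a test of how interaction variability mediates **population
   sensitivity to press disturbances** such as annual pesticide
   application (mixed-model regression with Type III likelihood-ratio
   tests).

## The methods at the core

All series are ln(x+1)-transformed (identity for coverage proportions)
and z-standardized as a 24-fragment *composite*; delay embeddings never
cross a fragment boundary. Per taxon, the embedding dimension E ∈ 2..6 is
chosen by leave-one-out simplex projection skill (RMSE).

**CCM cascade.** A link donor → recipient is accepted iff, cross-mapping
the donor from the recipient's manifold:
(1) skill gain Δρ = ρ(L_max) − ρ(L_min) > 0.1 with L_min = E+1,
L_max = 24(10−(E−1)), over 1000 library draws;
(2) ρ(L_max) beats 1000 *seasonal surrogates* of the donor (cyclic
10-census mean preserved exactly, anomalies permuted; add-one permutation
p < 0.05, marginal links 0.05 ≤ p < 0.1 flagged); and
(3) lagged CCM over offsets −2..+2 places the optimal lag ≤ 0 (best skill
in the future vetoes the pair as a false positive).

**Regularized S-map.** For each recipient, a mixed embedding
{R_t, R_{t−1}, …, D1_t, D2_t, …} of dimension max(E, 1+n_donors) predicts
the per-capita growth ln((N_{t+1}+1)/(N_t+1)) by locally weighted ridge
regression — weights exp(−θ d_i/d̄), penalty λ‖b‖² (intercept
unpenalized), (θ, λ) tuned by LOOCV RMSE on fixed grids. The coefficient
of donor column d at time t estimates the per-capita interaction effect
∂(1/N_r · dN_r/dt)/∂N_d — one value per link, tank, year, census.

**Interaction properties → stability.** Each link yields an IDD slope
(coefficients regressed on recipient standardized density; sign =
direction, negative is potentially stabilizing), temporal variability and
mean strength (|SD| and |mean| of control coefficients per year ×
replicate, averaged). Population sensitivity is |ln((T+0.1)/(C+0.1))| on
raw mean densities per taxon × year × contrast. The headline LMM regresses
ln(1+sensitivity) on the three properties, IDD direction, their
interaction and recipient function, with random intercepts for link and
year, tested by Type III likelihood-ratio χ².

A **synthetic community generator** with known density-dependent
interaction Jacobians (J = ā + b·z_recipient + noise over a Gompertz
community model with seasonal forcing and selective insecticide/herbicide
presses) makes every stage verifiable without field data.

## Worked example

```r
library(edmweb)

sim <- simulate_community(synthetic_config(), seed = 1)  # known ground truth
cs  <- preprocess(sim$panel)                             # 240-point composites
E   <- select_embeddings(cs)
E[c("phytoplankton", "rotifers", "molluscs")]
#> phytoplankton      rotifers      molluscs
#>             6             5             5

links <- sim$truth$web[, c("donor", "recipient")]        # true links
its <- interaction_timeseries(links, cs, E)
its
#> <interaction_series: 8 links, 1248 coefficient records>
head(its$models, 3)                                      # tuned S-map per recipient
#>       recipient theta lambda       rmse       rho
#> 1      rotifers   8.0   0.01 0.11461352 0.8488158
#> 2 phytoplankton   2.5   2.00 0.08108936 0.5882996
#> 3   crust_zoopl   4.0   0.01 0.10426850 0.7925069

pr <- link_properties(its, cs)
pr[1:2, c("donor", "recipient", "idd_slope", "idd_direction",
          "mean_strength", "temporal_variability")]
#>               donor recipient    idd_slope idd_direction mean_strength temporal_variability
#> 1     phytoplankton  rotifers -0.012845985      negative    0.04719010           0.06785947
#> 2 phytophilous_pred  rotifers  0.007160039      positive    0.03333379           0.06156066

st  <- sensitivity_table(sim$panel)                      # |LRR| per taxon/year/contrast
dat <- assemble_sensitivity_data(pr, st, "IH")           # insecticide + herbicide
sensitivity_regression(dat)
#> Type III likelihood-ratio tests (sensitivity ~ interaction properties)
#>                  term       chi2 df           p
#>         mean_strength  0.5471153  1 0.459498791
#>  temporal_variability  5.8589594  1 0.015497954
#>                   idd 10.6225105  1 0.001117193
#>         idd_direction 11.0478000  1 0.000887925
#>         idd:direction 10.5135630  1 0.001185015
#>    recipient_function  2.8276488  1 0.092653919
```

Read: on this simulated community the per-recipient S-map models fit with
ρ ≈ 0.6–0.85; the mean interaction strength carries no signal for
sensitivity (χ² = 0.55, p = 0.46) while interaction variability and
density-dependence terms do — the kind of pattern the pipeline is built
to detect. `detect_links(cs, E, seed = ...)` runs the full 90-pair CCM
scan instead of using the true links, and
`run_pipeline(pipeline_config(...))` orchestrates all stages with one
master seed and writes every table plus a JSON manifest.

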