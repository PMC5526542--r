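# ancdim

Antenatal care (ANC) has two distinct dimensions. One is independent of
the health-care delivery system: how often, and how early, a pregnant
woman attends. The other depends on it: which services she actually
receives — tetanus vaccination, weight, height and blood-pressure
measurement, urine and blood samples, breastfeeding counselling,
information on complication signs. `ancdim` estimates the effect of each
dimension on the probability of institutional delivery (facility birth
vs home birth), for researchers working with DHS-style maternal-health
microdata.

The difficulty is endogeneity: unobservables (health knowledge,
autonomy, risk aversion) drive both ANC uptake and the choice of
delivery place, so a single-equation probit confounds the structural
effect with selection. `ancdim` therefore fits, for each dimension
*D* ∈ {d1 = 1{visits ≥ 3}, d2 = 1{top PCA care level}}:

* the **naive probit**
  `O = 1{δ·D + x'β + ε > 0}`, ε ~ N(0, 1);
* the **recursive bivariate probit**

  ```
  D = 1{γ·Z + x'β' + ε' > 0}
  O = 1{δ·D + x'β  + ε  > 0},   (ε, ε') ~ BVN(0, 0, 1, 1, ρ)
  ```

  identified by the instrument Z = first ANC visit in the first
  trimester (excluded from the outcome equation), together with the Wald
  test of exogeneity on atanh ρ. Effects are reported as counterfactual
  average predicted probabilities p̄(d) = meanᵢ Φ(xᵢ'β̂ + d·δ̂).

The care dimension is built by `compute_care_score()`: first principal
component of the eight binary service items (the DHS wealth-index
convention), sign-oriented so more care scores higher, cut into
equal-probability levels; `cronbach_alpha()` reports scale reliability.

Because DHS microdata are registered-access, the package ships a
synthetic generator (`generate_dataset()`) that draws microdata from the
exact structural model above with known δ, γ, ρ and covariate effects,
plus a Monte Carlo driver (`simulation_study()`) for bias, test-size and
coverage experiments. A small generated example dataset (n = 500, seed
20170725) ships at `inst/extdata/anc_synthetic_n500.csv`.

## Worked example

```r
library(ancdim)
cfg <- sim_config(n = 5000, seed = 1)   # delta = 1, rho = -0.4, gamma = 1
sim <- generate_dataset(cfg)
report <- run_analysis(sim$data)
print(report)
```

```
Probit vs biprobit comparison (n = 5000, L = 3, alpha = 0.758)
 dimension probit_coef probit_stars probit_p0 probit_p1 biprobit_coef
        d1       0.524          ***     0.276     0.462          1.14
        d2       0.173          ***     0.357     0.419          1.04
 biprobit_stars biprobit_p0 biprobit_p1    rho rho_behaviour
            ***       0.182       0.577 -0.457         rho<0
            ***       0.265       0.647 -0.594         rho<0
```

Reading the d1 row: the naive probit puts the visits effect at 0.524,
but the generator's truth is δ = 1 with ρ = −0.4 — unobservables that
raise ANC uptake lower facility delivery, so the naive estimate is badly
attenuated. The biprobit recovers 1.14 (n = 5000; at n = 50,000 it
converges to 0.99), estimates ρ̂ = −0.46, and the Wald test labels the
dimension endogenous (`rho<0`). The probability pairs say: setting
everyone to <3 visits vs 3+ visits moves the average institutional
delivery probability from 0.18 to 0.58 under the corrected model,
against an understated 0.28 → 0.46 under the naive one. `alpha = 0.758`
is the Cronbach reliability of the eight-item care scale, and
`report$crosstab` prints the descriptive table (here 37.8% institutional
delivery, 53.7% with 3+ visits).

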