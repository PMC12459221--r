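# premap

Paramagnetic relaxation enhancement (PRE) profiling of flexible protein
loops from methyl-detected NMR spectra, for structural biologists who
need to trace where a disordered loop goes when crystallography cannot
see it.

A nitroxide spin label placed in a mobile loop broadens the NMR peaks of
every methyl group it approaches within ~25 Å, with an r⁻⁶ distance
dependence that makes even transient excursions detectable. `premap`
implements the full quantitative chain around this observable for a
homodimeric allosteric enzyme:

* **PRE intensity ratios** with concentration correction and first-order
  error propagation:
  *I*ratio = *I*dia / (*I*para · *c*),
  σ_R = R·√((σ_dia/I_dia)² + (σ_para/I_para)²),
  with bleached peaks (signal lost to strong PRE) kept as lower bounds;
* **two-time-point PRE rates**
  Γ₂ = ln[(I_dia(T_b)·I_para(T_a)) / (I_dia(T_a)·I_para(T_b))] / (T_b − T_a),
  the exact inverse of two-point exponential decay, with noise-floor
  lower bounds;
* **effector-difference profiles** ΔI between bound states, with
  sign-only records where one side is bleached;
* **solvent-PRE effective net charge** from oppositely charged
  cosolutes, ϕ = I⁻ratio − I⁺ratio (ϕ > 0 ⇒ net positive patch),
  σ_ϕ in quadrature, plus the multi-step significance filter on
  ΔΔϕ = |Δϕ_mut − Δϕ_wt| (threshold 0.4, all four samples with
  σ_ϕ ≤ 20 % of |ϕ|);
* **methyl chemical-shift perturbations**
  √(Δδ_H² + (0.133·Δδ_C)²);
* **an inter-/intra-protomer distance census** over homodimer
  simulation snapshots (multi-model PDB or TSV), counting 5–15 Å close
  approaches per chain pairing and exact class minima;
* **a synthetic forward model** (ensemble ⟨r⁻⁶⟩ PRE attenuation,
  charge-coupled cosolute broadening, dimer snapshots with planted
  close-approach fractions) so every stage is verifiable by parameter
  recovery.

See the methods vignette (`vignettes/pre-profiling.Rmd`) for the models,
defaults, and design rationale.

## Worked example

Forward-simulate a spin-labelled loop that sits at a "home" position 92 %
of the time and makes 8 % excursions toward the active site, then
recover the profile:

```r
library(premap)

probes <- list(I225 = c(8, 0, 0),    # proximal to the label home position
               V197 = c(40, 10, 0),  # near the transient excursion site
               L12  = c(20, 30, 0))  # remote from both
model <- loop_ensemble_model(
  members  = rbind(c(0, 0, 0),      # label "home" position
                   c(40, 0, 0)),    # transient excursion toward the active site
  weights  = c(0.92, 0.08),
  probe_sites = probes, noise_sigma = 500)

tabs <- generate_pre_tables(model, seed = 7)
profile <- annotate_groups(build_pre_profile(tabs$dia, tabs$para))
profile[, c("residue_index", "methyl_id", "i_ratio", "sigma_ratio",
            "bleached", "group")]
#>   residue_index methyl_id i_ratio sigma_ratio bleached           group
#> 1            12    L12-d1    1.01     0.00717    FALSE   distal_group2
#> 2           197   V197-g1    2.68     0.03856    FALSE   distal_group2
#> 3           225   I225-d1   67.43          NA     TRUE proximal_group1
```

Reading the output: the remote residue L12 shows no PRE (ratio ≈ 1);
I225, next to the label's home position, is fully bleached — its "ratio"
is a lower bound at the 3σ detection limit with no finite error; and
V197, 10 Å from the excursion site, shows a clear ratio of 2.7 even
though the loop spends only 8 % of its time there — the r⁻⁶ average at
work.

The same 8 % excursion physics in coordinate space, analysed by the
distance census:

```r
gen <- generate_snapshots(n_frames = 600, f_close_inter = 0.08, seed = 7)
census <- distance_series(gen$snapshots)
close_fraction(census, "inter")   # 0.0733  (planted 0.08, 1200 records)
min_class_distance(census, "intra")  # 25.01 A: never PRE-detectable
```

So 7.3 % of inter-protomer loop-to-active-site distances fall in the
5–15 Å window (the planted 8 % within the binomial sampling bound),
while intra-protomer distances never drop below 25 Å — the pattern that
distinguishes across-dimer from within-chain loop contacts.

`run_pipeline()` ties the stages together from a YAML/JSON config with a
sample manifest, writes one TSV per stage plus a JSON run log (every
effective parameter, seed, content hashes), and skips unchanged stages
on rerun.

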