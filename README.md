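# mitoflex

Kinetic modelling of skeletal-muscle mitochondrial beta-oxidation,
metabolic control analysis, OGTT-derived insulin-sensitivity indices and
lipidomics/proteomics statistics — the computational toolchain for
studying how ageing and dietary lipid overload jointly drive
intramuscular lipid accumulation and insulin resistance in a 2x2
age-by-diet mouse design.

**Who it is for.** Researchers in muscle metabolism and systems biology
who want to (a) turn targeted-proteomics tables into per-animal kinetic
models of fatty-acid beta-oxidation, (b) ask *which enzyme controls the
flux* under different substrate and malonyl-CoA regimes, and (c) relate
tissue lipid remodelling to whole-body insulin sensitivity, all on plain
delimited-text inputs.

## The models at the core

**Beta-oxidation.** Palmitoyl-CoA enters via CPT1B (competitively
inhibited by malonyl-CoA, product-inhibited by acylcarnitine), is
imported as C16-acylcarnitine (lumped CACT/CPT2) and chain-shortened by
acyl-CoA dehydrogenases (VLCAD/LCAD/MCAD/SCAD), a lumped hydratase/HAD
step and two thiolases (MTP, MCKAT), each with shared competitive
denominators over its chain-length range. CoA and carnitine moieties are
conserved. The steady-state CPT1B rate *J* (umol min⁻¹ per mg total
protein) is the pathway flux readout; one C16 yields 8 acetyl-CoA, so at
steady state 8·J equals the acetyl-CoA sink rate.

**Metabolic control analysis.** The flux-control coefficient of enzyme
*i* is

    FCC_i = (dJ/J) / (dVmax_i/Vmax_i)  ~=  (ΔJ/ΔVmax_i) · (Vmax_i/J),

estimated with a forward perturbation ΔVmax = Vmax·1e-6 on
machine-accurate steady states; the summation theorem
(Σ FCC = 1 over all rate-scaling steps) is checked everywhere.

**Insulin sensitivity.** Glucose and insulin OGTT traces are fitted to

    C(t) = C_b + C_1 (e^(-k_e1 t) - e^(-k_a t)) + C_2 e^(-k_e2 t)

and MISI = max post-peak (−dC/dt) / mean insulin; HOMA-IR =
glucose[mM] · insulin[mU/L] / 14.1 (mouse-adjusted).

**Omics statistics.** Class-internal-standard normalization; per-age
differential abundance (log2, mean-centring, Student's t, BH or
two-stage FDR at Q = 5%, fold-change gate 1.5/0.66); diet-response
scatter normalization; Pearson correlation of lipid species with MISI;
two-way (Type II) factorial screens. A fully seeded synthetic cohort
generator exercises every stage without external data.

## Worked example

```r
library(mitoflex)

ps <- bx_parameter_set()                 # documented default model
steady_state(ps, S_cyt = 1, M = 0)
#> <bx_steady_result> S_cyt = 1 uM, malonyl-CoA = 0 uM
#>   flux J = 0.000114583 umol/min/mg | C16-acylcarnitine = 0.392288 uM
#>   converged: TRUE | residual: 1.14e-13
steady_state(ps, S_cyt = 1, M = 0.2)$flux   # malonyl-CoA throttles entry
#> [1] 3.047e-05

fcc_profile(ps, enzymes = c("CPT1B", "MCKAT"), grid = substrate_grid(5))
#>  S_cyt_uM malonylCoA_uM         flux enzyme          fcc
#>       0.1             0 1.531005e-05  CPT1B 9.764249e-01
#>       0.1             0 1.531005e-05  MCKAT 5.081737e-06
#>       1.0             0 1.145834e-04  CPT1B 8.707382e-01
#>       1.0             0 1.145834e-04  MCKAT 3.751060e-04
#>      10.0             0 4.025917e-04  CPT1B 4.676358e-01
#>      10.0             0 4.025917e-04  MCKAT 1.786340e-01
```

At 0.1 uM palmitoyl-CoA, CPT1B is essentially the sole rate-limiting
step (FCC ~ 0.98); under a 10 uM substrate load almost half the control
has moved downstream, mostly to the medium-chain thiolase MCKAT — the
control-shift signature of lipid overload. With 0.2 uM malonyl-CoA the
flux drops ~4-fold and CPT1B keeps control over the whole range.

```r
cohort <- generate_cohort(cohort_config(seed = 1))
s <- cohort$ogtt$Y_LFD_1
fit <- fit_ogtt(s, "glucose")
misi(fit, s)$misi                        # mM/min per mU/L
#> [1] 0.0091
homa_ir(s$glucose[1], insulin_to_mUL(s$insulin[1], "ng/mL"))
#> [1] 3.10
```

(The fitted curve is robust; the individual rate constants are only
weakly identified from 8 points — see the identifiability discussion in
`vignettes/mitoflex-methods.Rmd` before interpreting `k_e1`.)

The umbrella pipeline (synthetic cohort → per-animal parameter sets →
flux/FCC scans → OGTT indices → lipid differential tables → manifest):

```r
run_pipeline(pipeline_config(out_dir = "out", seed = 1))
```

or from the shell, subcommand by subcommand:

```sh
Rscript inst/cli/mitoflex.R run --seed 1 --out out
Rscript inst/cli/mitoflex.R simulate --params out/params/Y_LFD_1.params \
    --malonyl 0.2 --points 25 --out scan.tsv
```

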