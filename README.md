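# valvecea

Decision-analytic cost-effectiveness model comparing **transcatheter
aortic valve implantation (TAVI)** with **surgical aortic valve
replacement (SAVR)** for elderly, high-surgical-risk aortic-stenosis
patients, from a healthcare-payer perspective with 2020 Iranian-Rial
costs. It is written for health economists who want the full analysis —
base case, probabilistic sensitivity analysis (PSA),
cost-effectiveness acceptability curve (CEAC) and tornado one-way
analysis — as tested, configurable code rather than a spreadsheet.

## The model

A 30-day decision-tree stage merged with first-year trial outcomes sets
each strategy's entry distribution over NYHA classes I–IV and death, and
its acute cost (procedure, hospitalization, device, plus adverse-event
management weighted by event probabilities). A lifetime Markov cohort
model then tracks nine states — NYHA I–IV, the same four classes after a
major stroke, and death — in one-year cycles, with an identical all-cause
death probability from every alive state, stroke applied to survivors
(multiplicative competing risks), a 0.39 stroke disutility deferred one
cycle for rehabilitation, and 6.5% annual discounting of both costs and
effects:

```
V(arm) = C_acute + Σ_t ⟨π_{t-1}, r_t⟩ / (1 + r)^t
ICER   = (C_TAVI − C_SAVR) / (E_TAVI − E_SAVR)
NMB(λ) = λ·ΔE − ΔC
```

Parameter uncertainty propagates through moment-matched Beta (utilities)
and Gamma (costs) distributions; a patient-level microsimulation of the
identical state process serves as an independent validation oracle for
the cohort engine. All parameters live in a strict YAML configuration
(`inst/extdata/model_default.yaml`); every under-specified modelling
choice is an explicit knob. See the vignette
`vignettes/cost-effectiveness-model.Rmd` for the full account.

## Worked example

```r
library(valvecea)

cfg <- default_config()          # bundled published parameter set
res <- run_model(cfg)
res$TAVI
#> TAVI: cost 551,892,734 IRR, 1.579 QALYs per patient
res$SAVR
#> SAVR: cost 107,952,075 IRR, 1.468 QALYs per patient

# incremental comparison from the published per-arm base-case values
inc <- incremental(arm_result("TAVI", 720257876, 1.27),
                   arm_result("SAVR", 352077775, 0.90))
inc
#> Incremental cost-effectiveness (intervention vs comparator)
#>   delta cost : 368,180,101 IRR (US$ 1,473)
#>   delta QALYs: 0.37
#>   ICER       : 995,081,354 IRR/QALY (US$ 3,980)

nmb(inc, 551400000)    # 1x GDP per capita -> -164,162,101 IRR
nmb(inc, 1654200000)   # 3x GDP per capita -> +243,873,899 IRR
threshold_ratio(inc$icer, 551400000)   # 1.8
```

Reading: TAVI buys 0.37 extra QALYs per patient at 368M IRR extra cost —
995M IRR (US$ 3,980) per QALY, about **1.8×** the 1×-GDP willingness-to-pay
threshold. The negative net monetary benefit at 1× GDP and positive at 3×
GDP say TAVI is not cost-effective at the lower threshold but becomes so
at the upper one.

Under the package's own default knobs the full model reproduces the
orderings (TAVI more effective and costlier) but not the published
levels, because post-year-1 mortality and the valve-cost assignment are
under-specified in the source evidence;
`inst/extdata/model_calibrated.yaml` documents the knob settings that
bring every arm-level output within 15% of the published table (vignette,
"Calibration").

Uncertainty analyses:

```r
psa <- run_psa(cfg, n = 10000, seed = 1)
psa_summary(psa)$icer_ratio_of_means
ceac(psa)                                   # (wtp, probability) table
tornado(lapply(owsa_default_parameters(), function(p) owsa(cfg, p)))
```

`run_base_case()` / `run_uncertainty()` write the same results as CSV +
JSON reports with a run manifest; `inst/cli/valvecea` is a thin
command-line wrapper over them (`run-base`, `run-psa`, `run-owsa`,
`ceac`, `simulate`, `validate-config`).

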