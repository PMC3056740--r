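# flowInherit

Transfer-function analysis of mitotic partitioning from flow-cytometry
dye dilution.

## What problem this solves

How evenly does a dividing cell split its labelled material — endosomes,
organelles, aggregates, delivered nanoparticles — between its two
daughters? Time-lapse microscopy sees too few divisions to answer at the
population level. flowInherit answers it from two bulk fluorescence
measurements: label the material with a stable dye (e.g. endocytosed
quantum dots, so cell fluorescence is proportional to labelled-vesicle
count), record the per-cell intensity histogram, culture for one division
round, record it again. The package is for experimentalists and modellers
who have such paired measurements (or want to design them) and need the
division asymmetry quantified with statistical power of >10⁴ cells.

## The model

A daughter inherits a fraction *x* of the parent's label, its sibling
1 − *x*, with

&nbsp;&nbsp;*P(x) ∝ ½ N(x; α, Δα²) + ½ N(x; 1 − α, Δα²)*, truncated to [0, 1],

where α is the mean splitting ratio (α = 0.5 is symmetric division) and
Δα its spread. The later histogram is the earlier one pushed through the
transfer operator

&nbsp;&nbsp;*N_f(I) = ∫ N_i(I′) T(I, I′, t) dI′*,&nbsp;&nbsp;
*T(I, I′, t) = f_t (1/I′) P(I/I′) + (1 − f_t) δ(I − I′)*,

with *f_t* the fraction of cells that divided during the interval *t*.
Fitting the operator to the measured pair (seeded differential evolution)
recovers (α, Δα, f_t); independently, the moment identity
*f_t = 2(1 − ⟨I_t⟩/⟨I_0⟩)* estimates the dividing fraction from the two
means alone. A Monte-Carlo single-cell simulator generates synthetic
experiments and serves as the event-level oracle for every model
component. See the vignette (`vignettes/transfer-function-method.Rmd`)
for assumptions, discretization and numerical choices.

## Worked example

Simulate a 10⁴-cell experiment at α = 0.71, Δα = 0.11, f_t = 0.98 (19 h
interval), bin both time points to 256 shared linear bins, and fit:

```r
library(flowInherit)

cfg <- SimConfig(nCells = 10000, seed = 7)      # defaults = the above
hp  <- sampleToHistograms(simulatePair(cfg), nBins = 256)
fit <- fitTransfer(hp$t0, hp$t, FitOptions(seed = 7))
fit
#> FitResult (sse): alpha = 0.7076, deltaAlpha = 0.1095, ft = 0.9751
#>   objective = 7.31151e-05, correlation = 0.9981, p = 0.8344, ft (moment) = 0.9798
#>   9150 evaluations, converged = TRUE, restart spread = 0.000319
```

Reading the output: the fitted mean splitting ratio 0.708 says one
daughter typically inherits ~71 % of the label (asymmetric division);
0.110 is the population spread of that ratio; 97.5 % of cells divided in
the interval, agreeing with the fit-free moment estimate 0.980 computed
from the two mean intensities — the cross-check that the fit is not
leaning on the optimizer. Correlation ~0.998 and the per-bin p ~0.83 are
descriptive fit-quality indices. All three parameters land within ±0.01
of the generating truth.

The same pipeline runs from the shell over CSV files:

```sh
exec/flowinherit simulate --config sim.yaml --out run
exec/flowinherit fit --h0 run_t0.csv --ht run_t.csv --out fit.json
exec/flowinherit estimate-ft --h0 run_t0.csv --ht run_t.csv
```

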