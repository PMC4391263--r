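# polgkin

Pre-steady-state kinetic analysis of the human mitochondrial DNA polymerase
gamma (Pol-γ) and its disease mutants.  The package is for enzymologists who
characterize polymerase variants by rapid-quench-flow kinetics: it simulates
explicit mass-action mechanisms, fits them globally to titration time
courses, derives the kinetic parameters the field reports, and quantifies
their uncertainty by χ²-threshold confidence contours.  A seeded
synthetic-data generator emulates every experiment class, so the entire
pipeline is validated by parameter-recovery simulation without instrument
data.

## The model

Single-nucleotide incorporation is described by the minimal mechanism

    E + D25  <=>[k1/k-1]  E·D25
    E·D25 + N  <=>[k2/k-2]  E·D25·N  -->[k3]  E·D26
    E + D26  <=>[k1/k-1]  E·D26

with the observable being total extended product (E·D26 + D26), the
quantity a quantified gel reports.  The standard derived parameters are

| quantity | definition | units |
|---|---|---|
| K_d,app | k-2 / k2 | μM |
| K_d,DNA | k-1 / k1 | nM |
| specificity constant (k_cat/K_m) | k_pol / K_d,app, k_pol = k3 | μM⁻¹s⁻¹ |
| processivity | k_pol / k_off, k_off = k-1 | nt |

Multiple-turnover bursts follow A(1−e^(−k_obs·t)) + k_ss·t with
k_off = k_ss/A; mismatch excision follows A0·e^(−k_exo·t) + C; processive
polymerization is a sequential ladder ED25 → ED26 → … at per-position rates
kpol_i with every EDn exchanging with free enzyme through K_d,DNA.
Simulation uses a stiff ODE solver (deSolve) over a compiled mass-action
derivative; fitting is multi-start Levenberg–Marquardt in log parameter
space with a Nelder–Mead polish; confidence limits are read where χ²
exceeds 1.1 × χ²_min with all other parameters re-optimized at every grid
node.  See the vignette (`vignettes/polgamma-kinetics.Rmd`) for the full
account.

## Worked example

Derived parameters of the S305R mutant against wild type, from the
published rate constants:

```r
library(polgkin)
derived_parameters(polg_rates("S305R"), reference = polg_rates("WT"))
#> K_d,app       = 1.2 uM
#> K_d,DNA       = 100 nM
#> k_pol/K_d,app = 10.3 uM^-1 s^-1
#> processivity  = 10.3 nt
#> fold changes vs reference: k_off 60, K_d,DNA 10.1
```

The S305R mutation leaves the enzyme holding its DNA ten-fold more weakly
(K_d,DNA 100 vs 9.9 nM), dissociating 60-fold faster, and therefore
processive for only ~10 nucleotides per binding event instead of
thousands.

Generate a synthetic nucleotide titration at the S305R truth values (six
dATP concentrations, 5% gel noise) and refit it:

```r
set <- gen_single_turnover(design_single_turnover("S305R", seed = 1))
fit_global(set, free = c("k_minus2", "k3"),
           fixed = list(k2 = 0.5, k1 = 0.012, k_minus1 = 1.2),
           n_starts = 2, seed = 1)
#> Global fit (scheme1): chi-square = 706.328 over 72 points
#>   k_minus2   = 629.019
#>   k3         = 13.4287
#> fixed: k2 = 0.5, k1 = 0.012, k_minus1 = 1.2
#> derived:
#> K_d,app       = 1.26 uM
#> K_d,DNA       = 100 nM
#> k_pol/K_d,app = 10.7 uM^-1 s^-1
#> processivity  = 11.2 nt
```

One noisy replicate recovers the chemistry rate k_pol = 13.4 s⁻¹ (truth
12.4) and K_d,app = 1.26 μM (truth 1.2); replicate means converge on the
truth values, which is what the recovery studies below check.

## The analysis workflow

Numbered drivers under `analysis/` run the full study and write their
tables under `results/`:

1. `01_simulate.R` — synthetic datasets for every experiment class at the
   published concentration designs;
2. `02_fit_incorporation.R` — global incorporation fits and the
   kinetic-parameter table (K_d,DNA, k_pol, K_d,app, k_pol/K_d,app, k_exo);
3. `03_burst_excision.R` — burst fit (k_off = k_ss/A, 60-fold change) and
   excision rates;
4. `04_processive.R` — processive-ladder fits (5-step and 10-step);
5. `05_contours.R` — confidence contours and 10%-threshold limits for the
   four rate constants;
6. `06_recovery.R` — 20-replicate recovery summaries (truth, mean, bias,
   RMSE) per experiment class.

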