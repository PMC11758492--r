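# hdxcalib

Structure-to-reactivity calibration for in-droplet hydrogen/deuterium
exchange mass spectrometry (HDX-MS) of peptides.

## The problem

Fast in-droplet HDX labels a peptide's labile hydrogens during the
microseconds a charged droplet lives between a spray emitter and a mass
spectrometer inlet. The centroid shift of the isotopic envelope counts the
deuteriums taken up — but that total mixes side-chain, terminal and backbone
amide exchange, and only the backbone amides report on conformation.
Separating them, and then explaining the backbone signal with the peptide's
conformational ensemble from molecular dynamics (MD), is what this package
does. Its users are mass spectrometrists and computational biophysicists who
want a reactivity measurement (a single percent-backbone-exchange number per
peptide) to carry structural-flexibility information, e.g. for screening
intrinsically disordered regions.

## The models

**Experimental arm.** Per-ion uptake is the intensity-weighted centroid mass
difference of the envelopes before and after D₂O exposure. Analyte uptake is
referenced to a co-sprayed internal standard (free lysine) by regressing
uptake on the standard's percent exchange across exposures and evaluating the
line at a fixed 75 % reference level. Side-chain/terminal contributions are
modelled per site class (amine, guanidino, hydroxyl, ...) with propensities
*p*ᵢ ∈ [0, 1] solved from free-amino-acid standards by nonnegative least
squares (cross-checked against the analytic ordinary-least-squares solution).
The backbone signal is

    %BB = 100 · (D_total − Σᵢ nᵢ pᵢ) / n_bb

where *n_bb* counts backbone amide hydrogens (prolines and a free N-terminal
residue excluded).

**Theoretical arm.** Each backbone amide in each MD frame is classified open
(exchange-competent, *c*ₒ) or closed (*c*c) under two criteria:

- *M*_inter: open ⇔ SASA(NH) ≥ 8.3 Å² **and** ≥ 2 waters within 3.3 Å of the
  amide hydrogen at an N–H···O angle within 30° of linear;
- *M*_intra: closed ⇔ SASA(NH) < 8.3 Å² **or** the amide hydrogen donates an
  intramolecular hydrogen bond; open otherwise.

State populations give the protection factor PF = f_c / f_o per residue.
The *digital* rule counts a residue as exchanged when ln PF < 0; the
*combined* kinetic model folds in the sequence-dependent intrinsic rate
k_int (poly-DL-alanine reference rates with neighbour and temperature
corrections):

    HDX_i = 1 − exp(−k_int,i · t / PF_i)

with the reaction time *t* arbitrary for calibration purposes. Theoretical
%BB (mean contribution × 100) is then regressed against experimental %BB;
slope, intercept, R², residual sum of squares and average percent error rank
the models.

## Worked example

```r
library(hdxcalib)

## 1. sites: bradykinin has 5 backbone amides (3 prolines + residue 1 drop out)
enumerate_sites(peptide("RPPGFSPFR"))
#> site_inventory: backbone = 5  side/terminal = 12  total = 17
#>    guanidino=8, hydroxyl=1, n_terminal_amine=2, c_terminal_acid=1

## 2. uptake of a lysine internal standard envelope at 86 % incorporation
env <- make_envelope(n_sites = 6, p = 0.86, seed = 1)
uptake(env$before, env$after, n_sites = 6)
#> deuterium_uptake: 5.1924 Da (+/- 0.2885) = 86.00% of 6 sites [z=1]

## 3. a synthetic trajectory through states -> protection -> exchange
toy   <- make_toy_trajectory("AAAAAA", n_frames = 500,
                             f_open = c(0.9, 0.7, 0.4, 0.2, 0.05), seed = 7)
traj  <- read_trajectory(toy$pdb)
pf    <- protection_factors(classify_states(traj, model = "inter"))
round(pf[, c("resno", "f_open", "pf", "ln_pf")], 3)
#>   resno f_open     pf  ln_pf
#> 1     2   0.90  0.111 -2.197
#> 2     3   0.70  0.429 -0.847
#> 3     4   0.40  1.500  0.405
#> 4     5   0.20  4.000  1.386
#> 5     6   0.05 19.000  2.944
digital_exchange(pf)
#> theoretical_exchange (digital_inter): 40.00% BB over 5 amides
cmb_exchange(pf, kint_profile(peptide("AAAAAA"), pH = 7, temperature = 300))
#> theoretical_exchange (cmb_inter): 79.99% BB over 5 amides

## 4. calibration: backbone-site counts alone do not predict %BB exchange
exper <- c(PA = 1.5, Nt17 = 6.1, BK = 17.6, KDD = 10.8, PS = 31.0)
sites <- c(PA = 20, Nt17 = 16, BK = 5, KDD = 12, PS = 20)
fit_line(sites, exper, model_id = "M_BB")
#> regression_fit [M_BB]: m = -0.08166 (1.1), b = 14.59 (16), R^2 = 0.002, SS_res = 528, n = 5
```

The two amides with f_open > 0.5 give ln PF < 0, hence 2/5 = 40 % digital
exchange; the combined model instead weights each residue by how fast its
intrinsic chemistry outruns its protection. The near-zero R² in step 4 is
the motivation for ensemble-based predictors: the number of amides carries
essentially no information about how many of them exchange.

A command-line wrapper is installed as `exec/hdxcalib` (subcommands `sites`,
`kint`, `uptake`, `scale`, `backbone`, `calibrate`); run it with `--help`.

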