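# ssindex

Site-specific prediction of coronary plaque deposition risk from the
**stenosis susceptibility index (SSI)**, computed by the virtual stenosis
method on a patient-specific coronary segment tree.

## The problem and the index

Coronary plaque tends to accumulate where wall shear stress (WSS) stays
low. At a candidate site in a coronary artery, imagine plaque growing from
0% to 25% to 50% diameter stenosis: fractional flow reserve (FFR) distal
to the site falls while the maximum wall shear stress at the throat
(WSSmax) rises. Plotting WSSmax (y) against FFR (x) across these virtual
severities gives a nearly linear relationship whose slope magnitude is the
site's SSI:

    SSI = (WSSmax,sten − WSSmax,ref) / (FFR,ref − FFR,sten)

or, normalizing the reference state to WSSmax = 0 and FFR = 1,
`SSI = WSSmax / (1 − FFR)`. A **large** SSI means a small amount of plaque
already drives WSS to the vasodilation-triggering level that inhibits
further deposition; a **small** SSI marks a site where severe stenosis can
develop before that protective response — the site most susceptible to
plaque deposition, and empirically the most likely future PCI target.

`ssindex` implements the whole pipeline:

- **coronary tree model** — a JSON segment-graph format (lengths,
  tapering diameters, RCA RV/LV perfusion-territory tags), validation,
  summed qualifying vessel lengths;
- **lumped-parameter outlet boundaries** — vessel-length-based resistance
  allocation `R_LAD = k/l_LAD`, `R_LCX = k/l_LCX`,
  `R_RCA = αk/l_RV + k/l_LV` with
  `k = (ΔP/Q)[l_LAD + l_LCX + l_RV·l_LV/(l_RV + α·l_LV)]` (α = 3.45 by
  default), recursive length-proportional distribution to terminal
  outlets, optional on–off collateral switching;
- **reduced-order hemodynamic solver** — a 0D resistive network with a
  Young-type quadratic stenosis loss, damped-Newton solution of the
  junction mass-balance equations, steady or quasi-static pulsatile inlet;
- **virtual stenosis sweeps and SSI analysis** — severity sweeps at
  candidate sites, OLS slope fits, per-artery and global minimum-SSI
  ranking, and a clinical concordance reporter with a built-in encoded
  seven-patient pilot observation table;
- **synthetic fixtures** — a seeded synthetic coronary tree generator and
  a parametric arterial pressure waveform builder, so everything runs
  without any external data.

The solver is deliberately reduced-order (a documented design choice, not
a limitation of the format): per-site SSI magnitudes from 3D CFD are not
reproduced, but every ranking, reporting and concordance computation, and
every qualitative property of the index (FFR monotonically falling,
WSSmax rising with severity, near-linear WSSmax–FFR response) is.

## Worked example

```r
library(ssindex)

tree <- generate_tree(42)       # synthetic 3-artery tree, seed-reproducible
tree
#> coronary_tree: patient 'synthetic-42', 15 segment(s)
#>   RCA: 5 segment(s), total length 179.3 mm
#>   LAD: 5 segment(s), total length 194.0 mm
#>   LCX: 5 segment(s), total length 176.4 mm

res <- run_ssi(tree)            # calibrate outlets, sweep 0/25/50%, fit SSI
res
#> ssi_result: 9 site(s)
#>  site_id artery      ssi r_squared
#>  RCA_p25    RCA 3809.140 0.9943759
#>  RCA_p50    RCA 3448.676 0.9943463
#>  RCA_p75    RCA 2823.325 0.9958835
#>  LAD_p25    LAD 1238.775 0.9838370
#>  LAD_p50    LAD 1443.978 0.9861772
#>  LAD_p75    LAD 1541.887 0.9806252
#>  LCX_p25    LCX 1274.644 0.9847497
#>  LCX_p50    LCX 1645.837 0.9881068
#>  LCX_p75    LCX 1456.711 0.9854112
#> ssi_ranking: per-artery minimum SSI
#>  artery site_id      ssi
#>     RCA RCA_p75 2823.325
#>     LAD LAD_p25 1238.775
#>     LCX LCX_p25 1274.644
#> global minimum: LAD (SSI = 1239)
```

SSI values are in dyn/cm² per unit FFR. Nine default candidate sites sit
at 25/50/75% of each artery's main-trunk length; the proximal LAD site has
the smallest slope here, so it is the predicted most plaque-susceptible
location. The `r_squared` column confirms the near-linear WSSmax–FFR
response that makes a single slope a meaningful summary.

The concordance reporter scores minimum-SSI predictions against observed
PCI sites. On the packaged seven-patient pilot observation table:

```r
concordance_report(table1_fixture()$observations)
#> concordance_report
#>   per-patient: 5/7 matched, rate 71.4%
#>   per-vessel:  7/9 matched, rate 77.8%
#>   MI observed in 4 of 7 patient(s)
```

A command-line interface is installed as `exec/ssi`
(`ssi run|report|table1|synth`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","ssi",package="ssindex"))')" \
    synth --seed 42 --out tree.json
```

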