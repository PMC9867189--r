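# idpcg

Coarse-grained simulation and sequence-patterning analysis of
intrinsically disordered proteins (IDPs).

Intrinsically disordered proteins — and in particular the FG nucleoporins
that fill the nuclear pore complex — sample broad conformational
ensembles whose dimensions (end-to-end distance $R_e$, radius of gyration
$R_g$, hydrodynamic radius $R_h$) and reconfiguration dynamics depend on
the composition and the *patterning* of cohesive, neutral and charged
residues along the chain. `idpcg` implements a minimal four-letter
(`P`/`H`/`+`/`-`) bead-spring heteropolymer for studying these effects:

- **Engine** — overdamped Brownian dynamics (Ermak–McCammon),
  $\Delta X = MF\Delta T + H\Delta W$, with FENE bonds, a soft 8–6
  repulsive core, an 8–6 cohesive tail of strength $\epsilon/k_BT$
  between `H` beads, screened-Coulomb electrostatics between charges,
  and optional Rotne–Prager–Yamakawa hydrodynamic coupling with a
  Cholesky noise factor. The hot loop is compiled (Rcpp/RcppArmadillo)
  with a Verlet neighbour list.
- **Sequence analytics** — repeat-notation parser (`"(HP)30"`,
  `"PP(HHHHPPPP)7HH"`), FASTA reduction maps, composition fractions,
  sequence charge decoration
  $\mathrm{SCD} = N^{-1}\sum_{i>j} q_i q_j\sqrt{i-j}$ and the blob-based
  charge-patterning parameter $\kappa$.
- **Static observables** — $R_e$, gyration tensor, asphericity
  $\delta$, Kirkwood hydrodynamic radius
  $R_k = [N^{-2}\sum_{i\neq j}\langle 1/r_{ij}\rangle]^{-1}$, MSD-based
  $R_h$, conditional distributions $p(R_e|R_g)$ and the
  two-points-in-a-sphere reference density.
- **Dynamics** — end-to-end vector ("rotation") and distance
  ("reconfiguration") autocorrelation functions via an FFT correlator,
  integrated correlation times truncated at $3\tau_e$, Zimm-scaling
  checks, and multimodality diagnostics of $p(R_e)$.
- **Calibration** — mapping heterogeneous sequences onto an equivalent
  homopolymer cohesiveness via isotonized reference curves, the
  $(e^{a\epsilon}-1)/b$ fit, and monotone (isotonic) regressions of
  dimension ratios on SCD.

Analysis functions take and return tibbles, fitted objects have
`tidy()`/`glance()` methods, and result types have `autoplot()`/`plot_*`
helpers. See the methods vignette (`vignettes/idpcg-methods.Rmd`) for the
model, units, parameter meanings and numerical choices.

## Worked example

```r
library(idpcg)

sequence_metrics(tibble::tibble(spec = c(
  "(HP)30", "(PHHP)15", "(PHHHPP)10", "PP(HHHHPPPP)7HH", "(PPHHHHHPPP)6")))
#> # A tibble: 5 x 7
#>   name                n   f_H f_plus f_minus    scd kappa
#>   <chr>           <int> <dbl>  <dbl>   <dbl>  <dbl> <dbl>
#> 1 (HP)30             60   0.5      0       0 -0.410    NA
#> 2 (PHHP)15           60   0.5      0       0 -0.537    NA
#> 3 (PHHHPP)10         60   0.5      0       0 -0.778    NA
#> 4 PP(HHHHPPPP)7HH    60   0.5      0       0 -1.00     NA
#> 5 (PPHHHHHPPP)6      60   0.5      0       0 -1.32     NA
```

All five 60-mers share the same composition ($f_H = 1/2$); only the size
of the cohesive patches differs, and |SCD| grows with patch size — the
patterning axis along which chain dimensions shrink at intermediate
cohesiveness.

```r
cfg <- simulation_config(n_steps = 2e6, n_equil = 4e5, n_runs = 2, seed = 1,
                         forcefield = forcefield(eps = 0))
traj <- run_simulation("(H)50", cfg)
ensemble_summary(traj)[, c("mean_rg2", "ratio_re2_rg2", "mean_delta")]
#> # A tibble: 1 x 3
#>   mean_rg2 ratio_re2_rg2 mean_delta
#>      <dbl>         <dbl>      <dbl>
#> 1     44.7          6.81      0.458
```

A zero-cohesiveness 50-mer behaves as a swollen coil:
$\langle R_e^2\rangle/\langle R_g^2\rangle$ is above the ideal-chain
value 6 and the mean asphericity is far from spherical. Increasing
`eps` in `forcefield()` drives the coil–globule transition; the ratio
crosses 6 near $\epsilon \approx 0.7\,k_BT$ and approaches the
uniform-sphere value 2 deep in the globule.

A thin CLI wraps the same functions, e.g.
`inst/cli/idpcg scd "(HP)30"` or
`inst/cli/idpcg simulate --seq "(HP)50" --eps 3.2 --steps 1e7 --seed 7`.

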