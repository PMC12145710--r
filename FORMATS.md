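# File dialects

All text files are UTF-8 with '.' as decimal separator. SI units (Pa, s, m,
K) everywhere except concentrations in mg/mL and cell areas in µm²/px².

## Mechanical curve CSV

One file per constant-strain-rate test.

```
time_s,strain,stress_Pa
0,0,0
1.2121,0.012121,46.93
...
```

* `time_s` strictly increasing, starting at 0; `strain(0) = stress(0) = 0`.
* `strain` may be omitted; the reader reconstructs it as
  `strain_rate * time_s` when given `--strain-rate` / `strain_rate=` and
  flags the curve (`strain_reconstructed` attribute).

## Calibration table CSV

Header `agarose_mg_ml,dextran_mg_ml` plus either lumped parameters

```
agarose_mg_ml,dextran_mg_ml,E0_Pa,E1_Pa,eta1_Pa_s,eta2_Pa_s,phi
```

or descriptors (optionally with `E_app_Pa`)

```
agarose_mg_ml,dextran_mg_ml,E_eq_Pa,E_inst_Pa,tau_rel_s,E_app_Pa
```

`(agarose_mg_ml, dextran_mg_ml)` keys must be unique. Descriptors are
derived from parameters on read when absent.

## Cell measurement table CSV

Region-level segmentation export, one row per cell:

```
condition,A,P,A_N,GI_nuc,GI_cyt
```

`A`/`P` cytosolic area and perimeter, `A_N` nuclear area (same units as
`A`), `GI_*` mean gray intensities.

## Simulation traces CSV

```
time_s,total_mass_mg,D_app_m2s,xi_m
```

`xi_m` is NA for runs with an externally supplied diffusion schedule.

## Run configuration YAML

Sections (all optional per subcommand; unknown sections/keys rejected):

```yaml
asls:      {E0, E1, eta1, eta2, phi}          # Pa, Pa, Pa.s, Pa.s, -
protocol:  {strain_rate, t_end, n_samples, strain_limit}
transport: {r_h, kappa, mu, T, p, alpha, k_r, c0}
grid:      {extents, nodes, boundary, bc_value}   # 'nodes', not 'n':
                                                  # YAML 1.1 reads bare n as a boolean
fit:       {initial_guess, lower, upper, tol, max_iter, n_starts, seed}
design:    {E_low, E_high, label, tau_b, tau_L_min, tau_L_max,
            metric, mode, band, target_regime}
noise:     {kind, level, seed}
```

## JSON reports

`fit` writes `{params, eta_eff, descriptors, rss, r2, eta_unidentifiable}`;
`design` writes the full `design_report()` structure (`target`, `window`,
`agarose_selection`, `dextran_selection`, `formulations` with `De_point`,
`De_range`, `regime` per formulation). Written with `jsonlite`
(`auto_unbox = TRUE`, full precision).
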