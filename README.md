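# quadcal

Thermodynamic analysis of DNA G-quadruplex unfolding from calorimetric and
spectroscopic traces.

G-rich sequences such as the human telomeric repeat d[AGGG(TTAGGG)₃] fold
into G-quadruplexes whose stability is routinely characterised by
differential scanning calorimetry (DSC), osmotic-stress melting and
pressure-perturbation calorimetry (PPC). `quadcal` implements the full
analysis chain for unimolecular quadruplex unfolding:

- **DSC deconvolution.** An excess heat capacity trace is modelled as a sum
  of independent two-state van't Hoff transitions (the "non-2-state" model).
  Each transition contributes

      Cp_i(T) = ΔH_cal,i · (ΔH_vH,i / R T²) · K_i / (1 + K_i)²,
      K_i(T)  = exp[ −(ΔH_vH,i / R) (1/T − 1/T_m,i) ],

  and `fit_non2state()` estimates (ΔH_vH, T_m, optionally ΔH_cal) per
  transition by bounded Levenberg–Marquardt after cubic instrument-baseline
  removal (`fit_baseline()`). The model-free totals — the curve integral
  ΔH_tot and the area-median melting temperature T_m(tot) — come from
  `total_enthalpy()` and `tm_total()`.

- **Osmotic-stress water counting.** Melting a quadruplex at increasing
  glycerol concentrations shifts T_m; converting each melt to an apparent
  ln K at a common reference temperature and regressing on ln[H₂O] gives

      Δn_w = d ln K / d ln[H₂O],

  the change in the number of bound waters per strand on unfolding
  (`delta_nw()`; positive slope = water uptake).

- **PPC volumetrics.** Pulse heats from the four chained scans
  (water/water, buffer/water, buffer/buffer, sample/buffer) are converted to
  the solute thermal expansion coefficient

      α_s = α_o − ΔQ / (T ΔP m_s V_s),

  and the transition peak is integrated over a progress-weighted baseline
  to the unfolding volume change ΔV (`ppc_baseline_chain()`,
  `alpha_solute()`, `delta_volume()`).

- **CD topology.** `classify_quadruplex_topology()` reads the band structure
  of a circular dichroism spectrum (dual positive 270/290 nm bands → hybrid;
  positive ~265 with negative ~240 → parallel; positive ~295 with negative
  ~260 → antiparallel).

- **Synthetic traces.** Raw instrument scans for such experiments are rarely
  deposited, so every stage has a seeded generator with known ground truth
  (`gen_dsc_thermogram()`, `gen_osmolyte_series()`, `gen_ppc_trace()`,
  `gen_cd_spectrum()`); composing a noiseless generator with its analysis
  recovers the injected value, which is how the package validates itself.

## Worked example

Deconvolve a noisy two-transition thermogram with the published h-Tel22
per-peak parameters as ground truth, then count waters and measure the
unfolding volume change on matching synthetic series:

```r
library(quadcal)

trs <- list(transition(57.4, celsius_Tm = 53.5),
            transition(98.9, celsius_Tm = 67.2))
cur <- gen_dsc_thermogram(trs, noise_sd = 0.03, seed = 11)
summary(fit_non2state(cur, n_transitions = 2))
#> non-2-state DSC fit: 2 transition(s), residual rms 0.0298 kJ/(mol K)
#> two-state transition: dH_vH = 57.4 kJ/mol, Tm = 326.63 K (53.48 degC)
#> two-state transition: dH_vH = 99.0 kJ/mol, Tm = 340.34 K (67.19 degC)
#> curve integral dH_tot = 150.5 kJ/mol, area-median Tm_tot = 63.26 degC
#> sum of fitted amplitudes = 156.4 kJ/mol
```

Both injected transitions are recovered to a fraction of a percent at an
instrument-scale noise level. Note the two totals: the sum of fitted
amplitudes estimates the full transition enthalpy (57.4 + 98.9 = 156.3),
while the windowed curve integral is slightly lower because the broad
low-temperature transition still carries heat outside the 5–110 °C scan.

```r
ser <- gen_osmolyte_series(61.1, dH = 154.5, Tm0 = 340.35, pcts = 0:5,
                           tm_noise_sd = 0.2, seed = 3)
delta_nw(ser)
#> osmotic-stress water count: delta_nw = 61.5 +/- 0.4 waters/strand (R^2 = 0.9998, n = 6)

quartet <- gen_ppc_trace(-0.106, Tm = 340.35)
ac <- alpha_solute(ppc_baseline_chain(quartet))
delta_volume(ac, window = c(315.35, 365.35), molar_volume = 6966 * 0.55)
#> unfolding volume change: delta_V = -0.1057 mL/mol over 42.2-92.2 degC

sp <- gen_cd_spectrum(data.frame(center = c(270, 290),
                                 amplitude = c(5.2, 4.1), width = 6),
                      noise_sd = 0.1, seed = 2)
classify_quadruplex_topology(sp)
#> quadruplex topology: hybrid (confidence 0.88)
#> bands:
#>  center amplitude
#>   270.0     5.321
#>   290.5     4.107
```

The injected water count (61.1) and volume change (−0.106 mL/mol) are
recovered within their noise, and the dual 270/290 nm signature is called
hybrid — the mixed parallel/antiparallel fold expected for the human
telomeric sequence in potassium.

File-based workflows use the CSV dialects in `read_curve_csv()` /
`write_curve_csv()` (temperatures in °C on disk, kelvin in memory) and
`read_strands_fasta()` with `strand_concentration()` for Beer–Lambert
concentration checks; a small FASTA of the three telomeric strands ships in
`inst/extdata/`.

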