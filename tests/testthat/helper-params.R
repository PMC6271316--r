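# Published thermodynamic parameters of the human telomeric core quadruplex
# (h-Tel22) and its 5'-T / 5'-TT extensions, used as ground truth for
# parameter-recovery tests. Enthalpies kJ/mol, temperatures degC, water
# counts per strand, volume changes mL/mol.
htel <- list(
  mer22 = list(dH_tot = 154.5, Tm_tot = 67.2,
               dH1 = 57.4, Tm1 = 53.5, dH2 = 98.9, Tm2 = 67.2,
               dnw = 61.1, dV = -0.106, eps = 228500,
               seq = "AGGGTTAGGGTTAGGGTTAGGG"),
  mer23 = list(dH_tot = 189.2, Tm_tot = 62.4,
               dH1 = 72.3, Tm1 = 52.3, dH2 = 98.5, Tm2 = 66.5,
               dnw = 73.2, dV = -0.059, eps = 236500,
               seq = "TAGGGTTAGGGTTAGGGTTAGGG"),
  mer24 = list(dH_tot = 229.7, Tm_tot = 61.3,
               dH1 = 60.0, Tm1 = 46.2, dH2 = 174.3, Tm2 = 62.4,
               dnw = 59.2, dV = -0.109, eps = 244600,
               seq = "TTAGGGTTAGGGTTAGGGTTAGGG"))

# two-peak transitions for one parameter set, van't Hoff enthalpies as
# printed and calorimetric amplitudes scaled so they sum to dH_tot
htel_transitions <- function(p, scale_amplitudes = FALSE) {
  s <- if (scale_amplitudes) p$dH_tot / (p$dH1 + p$dH2) else 1
  list(transition(p$dH1, celsius_Tm = p$Tm1, dH_cal = p$dH1 * s),
       transition(p$dH2, celsius_Tm = p$Tm2, dH_cal = p$dH2 * s))
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)
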