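# gdamage

Quantification of DNA damage G-values from the thin-film plasmid
relaxation assay — for radiation chemists and radiobiologists who measure
strand breaks, crosslinks and enzyme-revealed base lesions on agarose gels
and need yields per unit of deposited energy.

## The problem

Low-energy electrons (LEEs, 0–30 eV) are the most abundant species produced
by ionizing radiation, and their contribution to DNA damage can be isolated
with a substrate-subtraction experiment: thin plasmid films (pGEM-3Zf(-),
3197 bp) on tantalum and on glass are exposed to 1.5 keV X-rays under a
controlled atmosphere and hydration level Γ. Photons traversing the film
eject photoelectrons from Ta (η_e = 0.057 ± 0.005 per photon, mean energy
Ē = 5.33 eV); glass emits none worth counting, so

    Y_LEE = Y_Ta − Y_glass

for every lesion. Gel electrophoresis resolves supercoiled, circular (SSB),
linear (DSB) and crosslinked (CL) forms; digesting portions of each sample
with Nth and Fpg converts damaged pyrimidines and purines into strand
breaks, extending the taxonomy to isolated base damages, non-DSB clustered
damages (NDCDs), BD-related crosslinks and total base damage, with a heated
arm revealing heat-labile sites.

`gdamage` implements the full chain:

1. **band_io** — band intensities → per-lane conformation fractions
   (undoing the 1.12 supercoiled staining bias);
2. **dose_response** — linear exposure–response fits; effective yield =
   slope / initial supercoiled fraction; uncertainty = scatter of six
   replicate slopes;
3. **decomposition** — the nine-lesion taxonomy from the four treatment
   arms, and the Ta − glass subtraction;
4. **gvalue** — yields → G-values (damages/100 eV):

       G_X   = Y_glass · N_DNA · 100 · CF_X   / (1486 eV · X_Abs)
       G_LEE = Y_LEE   · N_DNA · 100 · CF_LEE / (η_e · X_Trans · Ē)

   with CF_X = 1.094, CF_LEE = 1.05, and re-weighting of G-values over
   arbitrary 0–30 eV electron spectra;
5. **report** — hydration enhancement ratios, oxygen enhancement ratios
   (OER), G_LEE/G_X, direct/indirect decomposition, rendered tables;
6. **synthetic_data** — a forward model of the whole campaign
   (single-event Poisson band partition, staining bias, Gaussian band
   noise) so every stage is testable by parameter recovery.

The modelling surface is one fitting function, `plasmid_damage_fit()`,
returning a classed object with `print`, `summary`, `coef`, `predict`,
`plot`, `residuals`, `fitted` and `simulate` methods.

## Worked example

Simulate a noise-free campaign with the built-in reference G-value table as
truth, then recover it:

```r
library(gdamage)
truth  <- reference_gvalues()
bands  <- simulate_experiment(truth, experiment_design(slope_replicates = 2),
                              noise_sd = 0, seed = 1)
fit    <- plasmid_damage_fit(bands)
fit
#> Plasmid film damage fit
#>   1152 lanes, 8 conditions (gas x gamma x substrate), 256 slope fits
#>   gases: O2; gamma: 2.5, 10, 20, 33; substrates: glass, Ta
#>   enzyme baseline: heated
#>   G-values: use coef(), summary() or render_report()
#>   enzyme baseline: heated

subset(as.data.frame(coef(fit)), gamma == 33 & lesion %in% c("SSB", "DSB"))
#>    gas gamma source lesion      G     sd
#> 32  O2    33      X    SSB  3.895 0.0000
#> 33  O2    33      X    DSB  0.200 0.0000
#> 72  O2    33    LEE    SSB 16.648 1.4604
#> 73  O2    33    LEE    DSB  2.000 0.1754
```

The generating values (G_X(SSB) = 3.9, G_X(DSB) = 0.20, G_LEE(SSB) = 16.7,
G_LEE(DSB) = 2.0 at Γ = 33) are recovered to better than 1%; the LEE sds
carry the 9% relative uncertainty of η_e. Ratio statistics of the reference
table itself:

```r
round_half_up(enhancement_ratio(truth, "LEE", "SSB")$value, 1)
#> [1] 2.1        # G_LEE(SSB) grows 2.1-fold from dry film to full hydration

direct_indirect(truth, "total", 33)
#>   direct_pct indirect_pct
#>     50.35294     49.64706   # at Γ = 33, half the LEE damage is indirect

r <- lee_over_x(truth)
subset(r, statistic == "LEE_over_X_max" & lesion %in% c("DSB", "NDCD"))
#>         statistic source lesion gamma value     sd
#>    LEE_over_X_max  LEE/X    DSB    33 10.00 0.7071
#>    LEE_over_X_max  LEE/X   NDCD    20 15.45 1.6734
```

i.e. per unit of deposited energy, LEEs are up to 10× (DSBs) and 15×
(NDCDs) more effective than 1.5 keV X-rays at producing potentially lethal
cluster lesions. `render_report()` turns any G table into a deterministic
plain-text/CSV report with enhancement-ratio rows.

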