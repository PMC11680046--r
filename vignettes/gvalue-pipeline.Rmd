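---
title: "From gel bands to G-values: methods and design of gdamage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gel bands to G-values: methods and design of gdamage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdamage)
```

## The measurement problem

Most of the energy that ionizing radiation deposits in biological matter ends
up in secondary electrons below 30 eV (low-energy electrons, LEEs). Their
contribution to DNA damage can be isolated with a thin-film plasmid assay:
five-monolayer (15 nm) films of supercoiled plasmid DNA (pGEM-3Zf(-),
3197 bp, 320 ng per film) are deposited on tantalum and on glass, and exposed
to 1.5 keV X-rays under a controlled atmosphere and hydration level
$\Gamma$ (water molecules per nucleotide, 2.5–33). Photons traversing the
film eject photoelectrons from the Ta surface (mean energy
$\bar E = 5.33$ eV, $\eta_e = 0.057 \pm 0.005$ electrons per incident
photon); glass emits a negligible electron current. Damage measured on glass
is therefore photon damage, and the Ta-minus-glass difference is LEE damage.

Damage is read out by agarose gel electrophoresis: supercoiled (undamaged),
circular (single-strand break, SSB), linear (double-strand break, DSB) and
inter-duplex crosslinked (CL) plasmid forms migrate as distinct bands.
Splitting each irradiated sample into four portions — untreated, heated
(37 °C, 1 h), and digested with the base-excision enzymes Nth or Fpg —
extends the readout to base damage (BD): the enzymes excise damaged
pyrimidines (Nth) and purines (Fpg) and convert them into strand breaks, so
the *additional* SSB, DSB, CL and loss-of-supercoiled yields of the enzyme
arms measure isolated BDs, non-DSB clustered damages (NDCDs), BD-related
crosslinks (BD-CLs) and total BDs respectively. Heating alone reveals
heat-labile sites.

`gdamage` implements the full quantification chain from quantified band
intensities to G-values (damages per 100 eV of deposited energy), and a
forward simulator of the experiment so that the chain can be validated by
parameter recovery.

## The model

### Single-event kinetics

In the fluence range used, every lesion is induced by a single event, so the
number of lesions of class $k$ on a plasmid after fluence $\phi$
(photons cm$^{-2}$) is Poisson with mean $m_k = r_k\,\phi$, where $r_k$ is
the per-plasmid damage rate. An initially supercoiled molecule is classified
by the highest-priority lesion it carries — a DSB linearises it regardless of
other damage, a crosslink dominates a nick — giving the band partition

$$
\begin{aligned}
P(\text{linear}) &= 1 - e^{-m_\mathrm{DSB}},\\
P(\text{crosslinked}) &= e^{-m_\mathrm{DSB}}\left(1 - e^{-m_\mathrm{CL}}\right),\\
P(\text{circular}) &= e^{-m_\mathrm{DSB}-m_\mathrm{CL}}\left(1 - e^{-m_\mathrm{SSB}}\right),
\end{aligned}
$$

with the remainder supercoiled, and pre-existing circular / crosslinked /
concatemeric material carried through inertly. The priority rule is a
modelling choice (electrophoretic mobility class is set by the dominant
conformational change); the assay itself does not dictate a competition
rule. Under enzyme treatment the effective means grow by the revealed
shares: Nth adds the pyrimidine share $p$ of each BD-class rate, Fpg the
purine share $1-p$, and every 37 °C-incubated arm (heated, Nth, Fpg)
additionally converts heat-labile sites into SSBs. The analysis sums the two
enzymes' additional yields, so recovered BD classes are independent of $p$
(property-tested at $p \in \{0, 0.3, 0.5, 1\}$); the simulator's default is
$p = 0.5$, as the split is not quantified experimentally.

### Yield extraction

For fluences small enough that $m_k \ll 1$, each band fraction is linear in
$\phi$. `fit_exposure_response()` fits ordinary least squares of fraction
against fluence (replicate lanes as separate points), and
`effective_yield()` divides the slope by the initial supercoiled fraction
$f_{SC,0}$ of the unirradiated sample, giving the effective yield in
lesions per plasmid per photon cm$^{-2}$. Loss of supercoiled is fitted on
the supercoiled band directly (its negative slope, reported as a positive
magnitude) rather than inferred as the sum of product forms — the two can
differ in real data, and the measured band is authoritative. Intercepts
absorb the initial composition plus manipulation damage and never enter the
yields.

Each condition is measured as six independent slope replicates; the
reported uncertainty is the *scatter* of those six slopes
(`replicate_mean()`), not the propagated per-fit residual error, which is
retained only as a diagnostic.

### Lesion taxonomy and substrate subtraction

Per condition, `prompt_lesions()`, `heat_labile()` and `enzyme_lesions()`
map the per-treatment yields onto the nine-lesion taxonomy. The enzyme
differences are taken against the **heated** arm by default: the enzyme
incubations include the same 37 °C hour, so heat-labile breaks appear in
both and cancel, cleanly separating heat-labile from enzyme-revealed yields.
(`enzyme_baseline = "untreated"` is available; it folds the heat-labile
yield into every BD class.) Negative differences — pure noise around a small
true yield — are carried unclipped so that downstream subtractions stay
unbiased; clipping happens only at report rendering. Total BD is measured on
the supercoiled band and is *not* forced to equal
isolatedBD + NDCD + BD-CL.

`lee_yields()` forms the LEE row as Ta − glass for every lesion, combining
standard deviations in quadrature (the replicates on the two substrates are
independent).

### G-values

With $N_\mathrm{DNA}$ plasmids per film, the damage count per unit fluence
is $D = Y \times N_\mathrm{DNA}$. G-values divide this by the energy
deposited per unit fluence in each channel and correct for the finite film
thickness:

$$
G_X = \frac{Y_\mathrm{glass}\, N_\mathrm{DNA}\; 100\; CF_X}
           {1486\,\mathrm{eV} \times X_\mathrm{Abs}},
\qquad
G_\mathrm{LEE} = \frac{Y_\mathrm{LEE}\, N_\mathrm{DNA}\; 100\; CF_\mathrm{LEE}}
                      {\eta_e\, X_\mathrm{Trans}\, \bar E},
$$

with $CF_X = 1.094$ and $CF_\mathrm{LEE} = 1.05$. As printed, these
relations are dimensionally underspecified ("photons absorbed" against a
per-area fluence); `gdamage` resolves this by representing
$X_\mathrm{Abs}$ and $X_\mathrm{Trans}$ as *effective areas* (cm²): film
area times the fraction of photons absorbed in, or transmitted through, the
film. Fluence × effective area is then a pure photon count and both
equations balance. The defaults use the film geometry (radius 2 mm) and an
absorbed fraction of 0.003, consistent with the attenuation of a 15 nm,
1.7 g cm$^{-3}$ DNA film at 1.5 keV; their exact values cancel in any
simulate→analyse round trip, which is also property-tested. The relative
uncertainty of $\eta_e$ (0.005/0.057 ≈ 9%) is propagated into every LEE
G-value in quadrature.

$N_\mathrm{DNA}$ is derived from the deposited mass at 650 Da per base pair
(≈ 9.3 × 10¹⁰ plasmids per 320 ng film) unless overridden.

### Spectrum re-weighting

A G-value is tied to the energy distribution $Z(E)$ of the electrons that
produced it. Given the lesion's yield function $Y(E)$ on 0–30 eV,
`spectral_g()` re-expresses a reference G-value under another distribution
by the energy-deposition-weighted yield ratio

$$
G(Z_t) = G_\mathrm{ref}\,\frac{W(Z_t)}{W(Z_\mathrm{ref})},
\qquad
W(Z) = \frac{\int Z(E)\,Y(E)\,dE}{\int Z(E)\,E\,dE},
$$

computed by trapezoidal integration with linear interpolation onto the
union grid (tabulated inputs arrive on unknown native grids). This formula
is a **reconstruction**: the original transfer procedure is described only
as requiring $Y(E)$, and the chosen weighting is the one that satisfies the
two limits that procedure must have — the identity transform
($Z_t = Z_\mathrm{ref}$ returns $G_\mathrm{ref}$) and the monochromatic
limit ($W \propto Y(E_0)/E_0$ for a delta-like spectrum). It is invariant
to rescaling $Y$ or either spectrum. Published re-weighted values for
specific high-energy-radiation spectra are not reproduced here because the
required $Z(E)$ and $Y(E)$ tabulations are external inputs; the transform
is validated on its closed-form limits and a two-point hand integral.

## Uncertainty conventions

All uncertainty arithmetic is first-order (quadrature) propagation
(`udiff`, `usum`, `uratio`), matching the convention that ratio error bars
are "the standard deviations obtained from the division". Correlations are
ignored because each combined term comes from independent replicates. The
test suite compares the propagation against a 10⁵-draw Monte-Carlo oracle;
the oracle's spread is measured as the half-width of the central 68.27%
interval because a ratio of Gaussians is heavy-tailed (its moments diverge
as the denominator approaches zero), which makes the sample standard
deviation an unstable and biased comparator at 10–20% relative input sds.
Agreement is required within 3 points of relative sd across inputs up to
20% relative sd.

## The synthetic generator: what it does and does not emulate

`simulate_experiment()` produces band tables with the statistical structure
of the real campaign: the exposure schedule (0, 5, 10, 20, 30, 40 minutes at
constant flux), 3 lanes per exposure, 6 independent slope replicates per
condition, the initial composition of the plasmid stock (96.0% supercoiled,
0.73% crosslinked, 0.72% circular, 2.54% concatemeric — renormalised to sum
to one), the supercoiled staining bias (the SC band is *divided* by 1.12 so
the analysis must undo it), and additive Gaussian band noise (default sd
0.003 on the intensity scale), clipped at zero. Intensities, not fractions,
are emitted; renormalisation is the analysis's job.

It does **not** emulate: gel-image artifacts (background, smears, lane
distortion — quantified band tables are the entry point), dose-rate or
saturation effects, concatemer damage (carried as inert), electron-track
structure or radical diffusion, or correlated noise between bands of one
lane. Parameter-recovery tests therefore validate the *quantification
chain*, not the instrument: passing them shows the analysis inverts the
assay's statistical model, not that the model captures every feature of
real gels.

### The linear regime and the default flux

Ordinary least squares on the exponential single-event response has a
curvature bias of roughly half the largest Poisson mean over the fitted
range (measured on this design; e.g. ≈5% bias at a maximum mean of 0.1).
The absolute photon flux of the apparatus is a free constant; the default,
2.5 × 10⁸ photons cm⁻² min⁻¹, keeps the largest per-plasmid mean near 0.01
for G-values of realistic magnitude, so every recovered quantity is within
about 0.5% of truth in the noise-free limit. Real campaigns are typically
run at higher doses where the linear fit incurs a visible few-percent
curvature bias; users simulating such conditions should expect slope
attenuation of order half the maximum Poisson mean.

A consequence of staying in this strictly linear regime with a fixed
absolute band noise is that the *stochastic* uncertainties of small-signal
cells — especially LEE cells, which are differences of two slopes — are
large relative to their values. Recovery tests are therefore posed in
standardised units (within 3 recovered sds, which holds with margin since
each reported value is a mean of six replicate slopes), while accuracy is
pinned down by the noise-free rerun.

## Worked example

```{r example, eval = FALSE}
truth <- reference_gvalues()                  # published reference table
design <- experiment_design()                 # the full campaign
bands <- simulate_experiment(truth, design, noise_sd = 0.003, seed = 1)
fit <- plasmid_damage_fit(bands)
summary(fit)                                  # G table with ER rows
lee_over_x(coef(fit))                         # LEE/X ratios and maxima
direct_indirect(coef(fit), "total", 33)       # direct/indirect split
```

Ratio statistics of the reference table itself (no simulation):

```{r ratios}
g <- reference_gvalues()
round_half_up(enhancement_ratio(g, "LEE", "SSB")$value, 1)   # 2.1
round_half_up(direct_indirect(g, "total", 33)["direct_pct"], 0)  # 50
```

## Numerical choices and edge cases

* **Rounding for display** is half-up at the configured decimals
  (`round_half_up()`); this choice reproduces the published one-decimal
  ratio cells from the published G-values wherever the two are mutually
  consistent. (A few published ratio cells were evidently computed from
  unrounded G-values and cannot be reproduced from the printed ones; they
  are neither "corrected" nor used in tests.)
* **Negative estimates** survive the whole chain and are clipped only in
  `render_report()`, with a footnote.
* **Zero-fluence lanes** define the initial composition per condition; the
  fit refuses to guess `f_sc0` without them.
* **Degenerate fits** (exact lines, constant fractions) get sd 0 from the
  residual-variance formula rather than NaN.
* **OER omissions**: cells whose anoxic (N₂) reference sits near background
  are dropped only when explicitly listed, never by an automatic threshold.
* The **N₂ reference table** for OER is an external input; tests use
  synthetic N₂ tables with known generating ratios.

## Problem sizes

The test suite simulates the full campaign (4 hydration levels × 2
substrates × 4 treatments × 6 series × 6 fluences × 3 lanes ≈ 3,456 lanes)
once with noise and once noise-free with 2 series, plus many single-condition
campaigns; the whole suite runs in under a minute on one core. The
acceptance script repeats the two full-campaign analyses at a user-supplied
seed. These sizes are the package's validation choices and can be scaled
up freely through `experiment_design()`.

## Known limitations

* The linear-fit contract means the pipeline is quantitative only in the
  single-event regime; no saturation model is provided.
* The spectral transform is a documented reconstruction (see above), and
  re-weighted G-values inherit its assumptions.
* G-value uncertainties include replicate scatter and $\eta_e$; film-area
  and humidity uncertainties are carried in the configuration but not
  propagated by default.
* The heated-baseline convention for enzyme differences is a modelling
  decision; both baselines are implemented and differ exactly by the
  heat-labile yield per enzyme arm.
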