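---
title: "Growth resilience to drought and later mortality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth resilience to drought and later mortality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the design

Severe droughts kill some trees and spare their neighbours. If mortality is
not random, trees that eventually die during a drought may already have
responded differently to *earlier, non-lethal* droughts — and tree rings let
us look back at those responses at annual resolution. The design this
package implements is a matched-pairs case–control study: at each site both
now-dead and surviving conspecifics were cored, so status contrasts are
estimated within site and species, and site/species/genus enter the models
only as random intercepts.

The per-tree quantities are the Lloret indices around one extreme drought
event per site, computed on raw growth (ring width TRW, mm, and basal area
increment BAI, mm²):

- resistance `Rt = Dr / PreDr` — capacity to keep growing during the event;
- recovery `Rc = PostDr / Dr` — capacity to return to pre-event growth;
- resilience `Rs = PostDr / PreDr = Rt × Rc` — capacity to regain the
  pre-event growth level.

`PreDr` and `PostDr` are arithmetic means over the `window_m` years before
and after the event (default 4, configurable 1–8), both excluding the event
year itself; `Dr` is the event-year growth. The exclusion follows the usual
Lloret convention: "the preceding period" does not contain the drought year,
and including it would mechanically pull all three ratios toward 1.

## Pipeline stages and the choices inside them

### Standardisation and site chronologies

Low-frequency variance in raw ring series reflects tree age/size and stand
history, not climate. Each series is divided by a stiff cubic smoothing
spline whose frequency response is 0.50 at a wavelength of 67% of the series
length. The smoother is implemented as the second-difference penalised
least-squares filter; its interior transfer function is
`H(ω) = 1 / (1 + 16 λ sin⁴(ω/2))`, so the stiffness λ is set analytically
from the 50%-at-wavelength condition rather than tuned. One consequence
worth knowing: with only ~1.5 cycles of the design wavelength inside a
series, boundary regions are smoothed less than the interior, so the
*apparent* attenuation of a windowed low-frequency sine is above 0.5; the
filter property itself is verified on a long series where edges are
negligible (measured response 0.52 at 15 cycles, vs 0.62 when 1.5 cycles
fill the whole window). Series shorter than 15 years are skipped; a
non-positive fitted value (possible under extreme suppression) falls back to
horizontal-mean detrending with a warning.

The ratio indices are then prewhitened with an AR(p) model — maximum
likelihood, order selected by AIC among 0..min(10, N/4) — keeping residuals
re-centred on the series mean, and scaled to mean exactly one. Both now-dead
and surviving trees enter the site chronology: the standardisation treats
every series identically, and excluding dead trees would bias the growth
signal the event detector relies on. Per-year averaging uses Tukey's
biweight robust mean with tuning constant c = 9 (the dendro convention:
support of median ± 9·MAD), iterated to |Δ| < 1e−10 with at most 50
iterations and a median fallback when the MAD is zero.

### SPEI

The drought index is the standardised k-month climatic water balance. For
scale k and a target month, the monthly differences P − PET are summed over
the k months ending in the target month (sums, not means — standardisation
makes the two equivalent, but the choice is stated for bit-reproducibility);
years lacking a full k-month history are absent, not zero. A 3-parameter
log-logistic distribution is fitted to the calibration values by unbiased
probability-weighted moments — the classic parameter formulas expect the
(1−F)-weighted moments, and left-skewed balance series land on the
mirrored-skew branch of the same generalized-logistic family (negative
shape, origin above the data), which is fully supported — and every value is
mapped through the fitted CDF and the standard normal quantile function.
Probabilities are clamped to [1e−8, 1−1e−8] so SPEI stays finite (|SPEI| ≤
5.6); if the moment fit degenerates (|shape| ≤ 1 or inconsistent signs) the
standardisation falls back to Gringorten empirical quantiles with a warning,
which preserves the ordering. The calibration span defaults to the full
record, mirroring how public SPEI products are fitted; it is configurable.

The grid covers 5 target months × 24 scales = 120 entries per site. Northern
sites use June–October. The southern-hemisphere convention spans December of
the previous calendar year to May; since the design uses exactly five target
months per hemisphere, we take the five obtained by a six-month phase shift
of the northern set — December (previous year) through April — and windows
that cross the calendar year are assigned to the ring year containing the
later month. The aridity index is mean annual precipitation over mean annual
reference evapotranspiration for a 1970–2000 reference span (higher =
wetter).

### Window selection and event detection

For each of the 120 candidates the site chronology is regressed on SPEI by
ordinary least squares over the common period (default 1931–1980; Gaussian
errors, identity link), requiring at least 20 overlapping years per
candidate; the minimum-AIC candidate wins, with ties broken toward the
smaller scale and then the earlier target month. Selection is invariant to
affine rescaling of the chronology.

The single event per site is searched between 10 and 40 years before the
first retained death (deaths more than 50 years before the site's last death
are excluded as exceptional long mortality). A year qualifies when (1) SPEI
at the selected window is below the site's 10th percentile — computed over
the full SPEI record with linearly interpolated order statistics (R type 7),
documented so results are reproducible — and (2) site-mean raw TRW,
averaging all trees of both statuses with data, is reduced by more than 5%
relative to the mean of the 4 preceding years, in the same year or the year
after (either lag suffices). Among qualifying years the most negative SPEI
is chosen; the tie-break is a design decision, since selecting "a single
drought event" does not itself fix the rule. Sites with no qualifying year
are discarded from status models but logged.

### Indices, covariates and trajectories

BAI is reconstructed outside-in from DBH at sampling: `r(last) = DBH·10/2`
mm, `r(t−1) = r(t) − trw(t)`, `BAI(t) = π(r(t)² − r(t−1)²)`; bark thickness
is ignored because DBH at sampling is the only anchor available. Locally
absent rings (zero values in Tucson files, decoded as NA) are bridged by
linear interpolation for the radius accumulation only and never enter the
ratio indices, whose numerators and denominators must be positive. Trees
whose reconstructed inner radius would go negative are truncated with a
warning. `DBH_i`, tree size in the event year, removes the diameter grown
after the event.

Trees lacking `window_m` complete years on either side of the event are
skipped with a recorded reason rather than evaluated on shortened windows —
shortened windows would make indices incomparable across trees, and the
sensitivity analysis at `window_m = 1..8` covers the question of window
length. `Δtime = last_year − event_year` for every tree: death year for
now-dead trees, sampling year for surviving ones. SPEI covariates are
`SPEI_i` (event year), `PreSPEI`/`PostSPEI` (means over the m years
before/after) and the differences `SPEIdiff_resist = SPEI_i − PreSPEI`,
`SPEIdiff_recov = PostSPEI − SPEI_i`, `SPEIdiff_resil = PostSPEI − PreSPEI`.

The growth-trajectory figure is per-tree `log(TRW(t)/PreDr)` over relative
years −4..+8, with stratum means (taxonomic group × status) and percentile
95% confidence bands from resampling trees with replacement (default 1000
draws, seeded); strata with fewer than 5 trees are skipped.

### Mixed models

Responses are log-transformed indices (log makes the multiplicative identity
additive and the residuals approximately Gaussian). The full fixed structure
is status, taxonomic group, `DBH_i`, `SPEI_i`, `Δtime`, aridity, soil PC1
and all status interactions; the resilience model additionally carries
`SPEIdiff_resil`, while the resistance and recovery models carry `SPEI_i`
only — their own SPEI differences are nearly collinear with `SPEI_i` and
would destabilise the fits. Status is coded with now-dead as the reference
level. Continuous predictors are standardised to zero mean and unit variance
so slopes are standardised coefficients; the response and the intercept stay
on the (log) response scale. The random part is intercepts for genus,
species within genus, and site within species — kept even when genera are
few; singular fits are reported with a warning, never silently simplified.

Fits use REML for coefficient reporting and a maximum-likelihood refit for
every AIC comparison (fixed structures differ between compared models).
p-values use the normal approximation to the Wald statistic — a deliberate
choice in the absence of a Satterthwaite implementation among the package's
dependencies; at the within-site replication this design provides, the
approximation is accurate, and the type-I simulation in the acceptance suite
confirms uniform null p-values. Backward reduction drops the least
significant droppable term whenever that lowers the ML AIC, where a main
effect is droppable only after every interaction containing it is gone; the
trail of drops is recorded, and ΔAIC against the same model without any
status term summarises the evidence that status matters. R²m/R²c follow the
variance decomposition var_fixed / (var_fixed + var_random + var_resid),
with the random variance added to the numerator for R²c. Adjusted means are
fixed-effect predictions on a reference grid (factors crossed, standardised
covariates at zero, equal weights over non-focal factor levels),
exponentiated back to the ratio scale, with pairwise surviving − now-dead
contrasts; means are split by taxonomic group exactly when a status × group
term survived reduction. At desk-scale site numbers the full interaction
structure can exceed the site-level degrees of freedom; `build_design`
refuses rank-deficient designs by default and offers an explicit
`on_alias = "drop"` mode (used by the pipeline) that sheds aliased
interaction terms with warnings.

## The synthetic world

The generator produces what the analysis assumes, with known truth:

- **Climate.** Monthly precipitation: winter-wet seasonal cycle with a
  site-level lognormal wetness multiplier (sd 0.2) and lognormal monthly
  noise (sd 0.35); PET: summer-peaked cycle with milder noise. In the event
  year the k months ending at the site's true window are driven into deficit
  and the deficit is deepened deterministically until the event year is the
  strict site minimum of the aggregated balance at the true window — the
  planted event is a guarantee of the stated world, not a tuned parameter.
- **Growth.** log TRW = log(negative-exponential size trend: 0.8 + 1.5
  e^(−0.04·age) mm) + 0.15 · SPEI(true window) + AR(1) noise (lag-1 0.3,
  innovation sd 0.2). The SPEI regressor is computed by the package's own
  SPEI module for internal consistency. The multiplicative lognormal form
  guarantees positive widths and makes the log indices normally distributed
  by construction; the negative-exponential trend is the classic
  standardisation target and is removable by the spline.
- **The event and the deficits.** All trees lose 20% of event-year growth.
  Now-dead trees are additionally multiplied by the taxon's resistance
  deficit in the event year and by resistance × recovery deficit in the four
  post-event years, so the *expected dead/surviving index ratios equal the
  configured deficits* (defaults: angiosperms 0.7 resistance / 1.0 recovery,
  gymnosperms 0.9 / 0.7 — the two taxa fail differently, as the study design
  expects). Death years are uniform in [event + 10, event + 40], which makes
  the event-window search rule satisfiable by construction.
- **Structure.** Sites alternate taxa and nest in species and genera; DBH is
  the accumulated diameter plus a 1 cm pith/bark allowance, so the BAI
  reconstruction is consistent. The soil table draws ten characteristics
  from a latent fertility factor loading positively on total nitrogen,
  organic carbon and available water capacity; clay/silt/sand are
  renormalised to sum to 100%.
- **Determinism.** Every stage derives its own RNG stream from the master
  seed (per stage and site), so identical configurations are byte-identical
  on disk and independently re-runnable.

What the generator does **not** emulate: competition and stand structure,
biotic mortality agents, missing rings, dating error, species-specific
climate responses beyond the single true window, or the heterogeneity of a
real pancontinental database. A green test therefore establishes that the
pipeline recovers planted structure under its own assumptions — it does not
certify effect sizes on real data, and the published coefficient values are
not reproducible at desk scale by design.

Where neither the analysis nor the generator dictated a value (growth
autocorrelation 0.3, noise sd 0.2, climate noise 0.35, SPEI slope 0.15), the
defaults were chosen once as values a dendroecologist would call plausible
for temperate conifer/broadleaf sites, with recoverability of the planted
structure — not realism — as the stated aim.

## Numerical choices and degenerate inputs

- Spline stiffness from the closed-form 50%-cutoff relation; sparse banded
  solve; constants are reproduced exactly.
- Biweight: iterate from the median; tolerance 1e−10; cap 50 iterations;
  median returned when MAD = 0; single values returned as-is.
- SPEI: probability clamping at 1e−8; empirical-quantile fallback warns;
  constant aggregated series are an error (no silent zero-SPEI).
- Ties in window selection: smaller scale, then earlier target month —
  stated so reruns are bit-identical.
- rwl dialects: 0.01 mm files terminate series with 999, 0.001 mm files with
  −9999; automatic detection keys on the terminator and refuses ambiguous
  files; zero ring values decode as missing.
- Rank-deficient model designs: error by default, explicit drop mode in the
  pipeline (see above).

## Known limitations

- p-values use Wald z; with very few genera the genus-level terms' uncertainty
  is understated (the nested random intercepts are retained regardless, and
  singular fits are flagged).
- The spline's boundary behaviour under-smooths series ends, as for any
  natural-boundary smoother; chronologies inherit slightly inflated variance
  in their first and last years.
- Cross-dating is assumed correct; partial final rings of dying trees are
  treated as complete.
- The event detector returns at most one event per site; multi-event
  histories are out of scope.
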