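---
title: "Chromatogram processing with fplcplot: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatogram processing with fplcplot: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fplcplot)
```

`fplcplot` processes UV chromatograms from preparative liquid chromatography
(FPLC): it reads the text exports of Äkta/Unicorn™ instruments and a generic
template, fits and subtracts baselines, annotates fractions and
elution-volume ranges, integrates peak areas, and renders annotated figures.
This vignette explains the models and the design decisions, in particular
where a choice was genuinely open.

## The data model

A **curve** is one detector trace: paired vectors of elution volume (ml) and
signal (mAU for UV channels), with unit labels from the source file and an
optional detection wavelength parsed from the curve name (`"UV 1_280"` →
280 nm; 260/280/230 are also recognized as embedded tokens). Construction
rejects non-finite values, mismatched lengths and decreasing volumes;
duplicated volumes are kept with a warning — plotting tolerates them, and
the baseline fit does not require strict monotonicity.

A **chromatogram** is a parsed run: one or more uniquely named curves plus
the event marks the instrument records — fraction starts (strictly
increasing volumes, unique labels), injections, and logbook entries — and
metadata (source file, dialect, chromatogram id).

The fraction collector records only where each fraction *starts*. Intervals
are reconstructed by the tiling rule: fraction *i* spans from its start to
the next fraction's start, and the final fraction is closed at the maximum
elution volume of the primary UV curve. The instrument does not state where
the last fraction ends; ending it at the end of the trace matches the
furthest point a filled area can visually extend and keeps the intervals an
exact tiling (widths sum to the covered span, no gaps or overlaps). The
**primary curve** — the one fraction and volume highlights are drawn under —
is the 280 nm channel when present (the protein-sensitive trace), otherwise
the first curve.

## Reading vendor exports

Unicorn exports use a paired-column layout: header row 1 names each
(volume, value) column pair, row 2 gives units, and columns are ragged
(curves of different lengths are padded with trailing empty cells). Event
pairs are recognized by unit-row tokens (`"(Fractions)"`, `"Injection"`,
`"Logbook"`; case-insensitive substring match). Different Unicorn versions
and site locales vary in encoding and number formatting, so the dialect is a
*descriptor object* — encoding, delimiter, decimal mark, header depth —
rather than code to edit per version, and `detect_dialect()` infers it:

- encoding from the byte-order mark (UTF-16 LE/BE, UTF-8), from a byte-level
  heuristic for BOM-less UTF-16 (the zero-byte pattern), or by UTF-8
  validation with latin-1 fallback. Pure-ASCII latin-1 files are
  byte-identical to UTF-8 and are reported as such — they parse identically.
- delimiter by frequency in the header row (tab, semicolon, comma);
- decimal mark by sampling numeric-looking data cells (only relevant for
  tab/semicolon files; a comma delimiter forces dot decimals, since
  delimiter and decimal mark must differ).

Parsing rules worth stating: trailing empty cells end a column's series, but
an *internal* empty cell is ambiguous and rejected; a text-valued pair with
no recognized event token is kept as logbook-like events with a warning
rather than silently dropped (no named column disappears without notice);
non-monotonic fraction volumes are an error naming the offending rows.
Exports holding several chromatograms (`Chrom.1_…`, `Chrom.2_…` prefixes)
are supported by keeping the first and warning about the rest — whether the
app-style workflow ever sees such files is undocumented, so the conservative
behaviour is to parse one run deterministically.

The writers emit the same layouts with numbers at 10 significant digits,
enough that a write→parse round trip reproduces every field at print
precision; this is also how all fixtures are made. The generic template (for
non-Äkta instruments) differs in sharing a single volume column across
curves, with an optional trailing fraction pair.

## The baseline model

The baseline is fitted by asymmetric least squares (ALS): a Whittaker
smoother with iteratively reweighted asymmetry. Given signal $y$, the
baseline $z$ minimizes

$$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2,$$

with $w_i = p$ where $y_i > z_i$ and $w_i = 1-p$ otherwise, recomputed each
iteration until the relative change of $z$ drops below `tol` (default
`1e-6`) or `max_iter` (default 20) is reached; convergence is reported on
the model object. Small $p$ (default 0.01) makes points above the line —
peaks — nearly irrelevant, so the line hugs the slowly varying component.
The second differences are index-spaced (slight x non-uniformity is
ignored), keeping the system pentadiagonal; it is solved with a sparse
Cholesky factorization, and the suite verifies the solution against a dense
reference implementation to 1e-8. The fit has no randomness.

**Choosing $\lambda$.** With index-spaced differences the smoother's
half-width is approximately $\lambda^{1/4}$ *samples*, so the meaning of
$\lambda$ couples to sampling density. Vendor exports sample at ~0.002 ml;
a useful baseline must be stiff on the scale of the narrowest peaks
(SEC peaks have $\sigma \gtrsim 0.2$ ml), which requires
$\lambda \gtrsim (4\sigma_{min}/\Delta x)^4 \approx 2\times 10^{11}$.
The default is $\lambda = 10^{11}$ (~1 ml half-width at 0.002 ml sampling).
A much smaller $\lambda$ (e.g. $10^6$, a common default in the spectroscopy
literature where traces have ~1000 points) corresponds at this sampling
density to a half-width of 0.06 ml — the "baseline" then climbs into the
peaks themselves and baseline-corrected areas collapse. Users with coarser
data should scale $\lambda$ by $(\Delta x_{ref}/\Delta x)^4$.

**Behaviour under noise.** On peak-free stretches with noise sd $\sigma_n$,
the asymmetric equilibrium places the line near the lower noise quantile,
about $1.7\sigma_n$ below the true drift at $p = 0.01$ — visually correct
(the line underlines the trace) and small against real peaks. Tall peaks
additionally pull a stiff line slightly upward through their residual weight
$p$; at $p = 0.01$ this can raise the line above the local noise floor near
a dominant peak (about 10% of samples end up below the line on the default
synthetic run), while at $p = 0.001$ the line stays essentially under the
whole envelope (<2%). Both regimes are exercised in the tests.

Baseline subtraction returns a new curve (name suffixed
"(baseline-corrected)"); areas of corrected curves may legitimately be
negative where the signal dips below the fitted line.

## Normalization

Instrument channels sit on arbitrary offsets. The default normalization,
`shift_min_zero`, subtracts each curve's minimum — it keeps mAU readable on
the axis, which is why it is also the default for plotting. `minmax_01`
rescales to [0, 1] for overlaying channels of very different magnitude (it
is an error on a constant curve). Whether channels should be normalized
jointly or independently is not dictated by anything in the data; each curve
is normalized *independently*, since the usual question ("where does each
channel elute?") is per-channel, and a shared scale would make the weaker
260 nm channel hard to read. Both methods are idempotent, preserve x
exactly, and preserve the argmax of y.

## Intervals, areas, zoom

`restrict_to_range()` clips a curve to a volume window and inserts exact
linearly interpolated samples at the window edges, so that filled areas and
integrals start and stop exactly at the requested volumes. `integrate_auc()`
is the trapezoid rule on that clipped piecewise-linear trace — chosen over
higher-order rules because vendor exports are unevenly sampled, and the
trace *is* piecewise linear once drawn. Areas are exactly additive over
adjacent intervals (shared edges are interpolated identically).

`apply_zoom()` clips every rendered view — curves, baselines, fraction
intervals (truncated at the window edge, dropped when fully outside) and the
volume highlight — to the zoom window. Because clipping only inserts
collinear boundary points, the area of any sub-interval inside the window is
unchanged by zooming (to ~1e-12 relative; floating-point interpolation at
window edges is the only perturbation).

## Rendering

A figure is assembled as a decision tree over the style and selection flags,
each contributing a fixed set of layers in a fixed order: filled areas under
each curve (off by default — the area under the curve is transparent unless
a fill color is chosen); the curves (260 nm red, 280 nm blue by default,
colors overridable per wavelength or per curve name); fitted baselines in
the same color as their curve (dashed); highlighted areas under the primary
curve for each selected fraction (purple by default) and for the volume
range, drawn with partial alpha so overlaps composite visibly; and a
tick-and-label strip under the plot for fraction labels. The layer roles of
a figure are introspectable via `layer_inventory()`, which is also how the
decision tree's completeness is tested (all 2⁵ flag combinations map to
exactly their documented inventories). Rendering is deterministic: the same
inputs give byte-identical exports (after stripping the embedded device
timestamps from PDF/EPS headers).

The label strip places a tick at each interval start with the label beneath,
alternating between two rows when a deterministic width heuristic predicts
collision — preventing overlaps rather than leaving them for an image
editor. When both UV channels are drawn they share a single y axis.
Axis labels default to "Elution volume (ml)" / "mAU" and follow the file's
unit rows only through the style, which owns all axis text.

Export supports PDF and EPS (vector, sized in inches) and TIFF/PNG rasters
whose pixel dimensions are exactly `round(size_inches × dpi)` (default
300 dpi). Writes are atomic — a failed export leaves no partial file.

## Styles persist; selections do not

`plot_style()` holds everything about *appearance* (colors, alphas, flags,
axis labels, normalization method); `chrom_selection()` holds the per-file
choices (fraction labels, volume range, zoom). Only styles are persisted by
`save_style()`/`load_style()` — a flat JSON config, serialized at full
double precision so round-trips are exact. Fractions are defined anew for
every file, so a config containing selection-like keys (`fractions`,
`volume_range`, `zoom`, …) is rejected with an explanation, and unknown keys
are an error listing them rather than being ignored. This split is what
makes the batch workflow safe: one saved style applied to many runs yields
figures with identical style layers and differing data.

## The synthetic generator

`synth_spec()`/`synth_chromatogram()` simulate a run as Gaussian elution
peaks on a linear drift with additive Gaussian detector noise, per channel,
plus a regular fraction scheme; the exact drift values and closed-form peak
areas ($scale \cdot height \cdot \sigma\sqrt{2\pi}$) are returned as ground
truth. The default recipe emulates a ~24 ml analytical SEC column
(Superdex-200-class): x ∈ [0, 24] ml at 0.002 ml steps, one dominant
monomer peak at 14 ml (60 mAU, σ = 0.35 ml), a 280 nm channel and a 260 nm
channel at 0.55 relative height (a typical A260/A280 for pure protein),
drift 2 + 0.15·x mAU, noise sd 0.5 mAU, and 24 fractions of 0.5 ml from
8 ml. The RNG is seeded per recipe and the caller's RNG state is restored.

What it does *not* emulate — and what passing tests therefore cannot show
about real data: asymmetric/tailing peak shapes, detector saturation,
conductivity or pH gradients, injection disturbances, air spikes, and
non-linear buffer baselines. The generator validates the pipeline's
*mechanics* (parsing, geometry, integration, recovery under Gaussian noise),
not chromatographic realism.

## Numerical choices and degenerate inputs

- Numbers are written at 10 significant digits; round-trip tests compare at
  that print precision (1e-8 relative).
- The ALS linear system's conditioning grows with $\lambda$; at
  $\lambda = 10^{11}$ solutions are accurate to ~1e-5 relative, which is
  far below detector noise. The sparse-vs-dense equivalence check runs at
  $\lambda \le 10^6$ on short curves where both solvers are accurate to
  1e-8.
- Curves shorter than 3 points cannot be baseline-fitted (second differences
  undefined); constant curves are their own baseline fixed point but cannot
  be min-max normalized; a zoom or range excluding all data is an
  empty-selection error rather than an empty result.
- Fraction intervals with a zero-width final fraction (`x_end` at or before
  the last start) are a boundary error.
- Test problem sizes: round-trip properties run on ~100 randomized fixtures
  of 500–3000 points; baseline recovery and end-to-end area recovery run on
  the full default 12001-point grid; solver-equivalence curves are ≤200
  points so the dense oracle stays exact.

## Known limitations

Only ALS baselines are provided (no rolling-ball/SNIP/polynomial variants,
no automatic $\lambda$ selection); region-restricted baseline fitting is not
supported (the fit is always for the whole curve). Binary Unicorn result
archives (.res/.zip) are out of scope — export to text first. Peak
*detection* is deliberately absent: fractions and volume ranges are the
units of annotation. Non-UV channels parse as generic curves with their
file units; no conductivity/pH-specific semantics are applied.
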