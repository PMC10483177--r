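# fplcplot

Parse, annotate and plot preparative liquid-chromatography (FPLC) profiles.

Äkta instruments running Unicorn™ software record UV absorbance (mAU at 280,
260 and often 230 nm) against elution volume during protein purification, and
can export those traces as tab-separated or CSV text files. The instrument
plots themselves are hard to annotate and unsuitable for publication.
`fplcplot` is a scriptable toolkit for everything downstream of the export:

- **Reading vendor exports** in their paired-column layout — one
  (volume, value) column pair per curve plus fraction/injection/logbook event
  pairs — tolerating the dialect differences between Unicorn versions and
  site locales (UTF-16 encodings, tab/semicolon/comma delimiters,
  comma-decimal numbers), plus a simple generic template for data from
  non-Äkta instruments.
- **Baseline fitting** by asymmetric least squares, **normalization**,
  **fraction-interval annotation**, **trapezoidal peak-area (AUC)
  integration** and **zooming**.
- **Publication-quality figures** (ggplot2) with filled areas, highlighted
  fractions and elution-volume ranges, fraction labels under the plot, and
  export to PDF, EPS, TIFF or PNG.
- A **command-line interface** and a persisted **plot-style config** for
  batch-plotting many similar runs with one consistent look.
- A **synthetic chromatogram generator** with exact ground truth, so the
  whole pipeline is testable without instrument data.

It is aimed at biochemistry and structural-biology labs that purify proteins
routinely and want reproducible, scriptable chromatogram figures instead of
instrument screenshots.

## The model at the core

The baseline is an Eilers-style Whittaker smoother with asymmetric weights
(ALS), the standard chromatography choice. It minimizes

```
sum_i w_i (y_i - z_i)^2  +  lambda * sum_i (Delta^2 z_i)^2
```

iterating `w_i = p` where `y_i > z_i` (peaks count little) and
`w_i = 1 - p` otherwise, until the relative change of `z` falls below `tol`.
The system is pentadiagonal and solved sparsely; a dense reference solver in
the test suite checks the solution to 1e-8. Defaults: `p = 0.01`,
`max_iter = 20`, `tol = 1e-6`, and `lambda = 1e11` — the second differences
are index-spaced, so the smoother's half-width is about `lambda^(1/4)`
samples; at the 0.002 ml sampling of typical vendor exports that is ~1 ml,
stiff on the scale of SEC peaks so the baseline tracks drift, not peaks. For
coarser data scale `lambda` by `(dx_ref / dx)^4`.

Peak areas are trapezoidal integrals of the piecewise-linear trace over an
interval, with exact linear interpolation at interval boundaries, optionally
after baseline subtraction. Fraction intervals are reconstructed from the
collector's start marks: each fraction ends where the next begins, the last
at the end of the primary UV curve.

## Worked example

```r
library(fplcplot)

# a synthetic Superdex-200-like run (ground truth known), written and read
# back through the Unicorn dialect as a stand-in for a real export
run <- synth_chromatogram(synth_spec(seed = 42))
f <- file.path(tempdir(), "run15.txt")
write_unicorn_txt(run$chromatogram, f, unicorn_dialect("utf-16-le", "\t", "."))

chrom <- read_unicorn_txt(f)      # dialect auto-detected
detect_dialect(f)
#> <unicorn_dialect> utf-16-le, tab-delimited, decimal '.', 2 header row(s)
chrom$curves[["UV 1_280"]]
#> <fplc_curve> UV 1_280 [280 nm]: 12001 points, 0-24 ml, mAU

uv280 <- normalize_curve(chrom$curves[["UV 1_280"]])   # min -> 0 mAU
bl <- fit_baseline_als(uv280)
bl
#> <baseline_model> 'UV 1_280': 12001 points, lambda=1e+11, p=0.01, converged after 8 iteration(s)

# baseline-corrected area of each fraction under the main peak
iv <- fraction_intervals(chrom)
peak_fracs <- iv[iv$start_ml >= 12.5 & iv$end_ml <= 15.5, ]
aucs <- vapply(seq_len(nrow(peak_fracs)),
               function(i) integrate_auc(uv280, peak_fracs[i, ], baseline = bl),
               numeric(1))
data.frame(fraction = peak_fracs$label, auc_ml_mAU = round(aucs, 2))
#>   fraction auc_ml_mAU
#> 1       10       0.12
#> 2       11       3.84
#> 3       12      22.22
#> 4       13      22.21
#> 5       14       3.85
#> 6       15       0.11
sum(aucs)   # 52.3 ml*mAU; the generator's true peak area is 52.6
```

The fractions' areas quantify how much protein each collected tube holds —
here fractions 12 and 13 carry the peak. An annotated figure of the same
run:

```r
fig <- render_chromatogram(
  chrom,
  plot_style(show_baseline = TRUE, show_fraction_labels = TRUE),
  chrom_selection(fractions = c("11", "12", "13"), volume_range = c(12, 16)))
layer_inventory(fig)
#> [1] "curve" "curve" "baseline" "fraction_highlight" "fraction_highlight"
#> [6] "fraction_highlight" "range_highlight" "fraction_ticks" "fraction_labels"
export_figure(fig, "run15.pdf")                      # vector
export_figure(fig, "run15.tiff", dpi = 300)          # 1800 x 1200 px raster
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fplcplot", package = "fplcplot"))')
$CLI synth --out demo.txt --seed 7        # fixture + demo.txt.truth.json
$CLI info demo.txt                        # curves, units, extent, fractions
$CLI plot demo.txt --out demo.pdf --fractions 11,12,13 --baseline "UV 1_280" \
     --range 12:16 --save-style style.json
$CLI plot other.txt --out other.pdf --style style.json   # same look, new run
$CLI template --out blank.txt             # generic non-Äkta template
```

The style config (`style.json`) persists only *how* plots look (colors,
alphas, flags, axis labels, normalization). Per-file selections — which
fractions, which volume range, which zoom window — are deliberately never
saved and must be restated for each file; a config containing them is
rejected.

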