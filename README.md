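# imic — immunofluorescence multichannel image cytometry

`imic` turns multiplexed immunofluorescence images of tissue sections into
per-cell, per-marker quantitative data. It is written for the four-channel
setting used in upper-airway mucosa research — a DAPI nuclear counterstain
plus three direct-conjugated cytoplasmic markers (AF488 = pancytokeratin
for epithelial cells, eFluor 570 = vimentin for connective-tissue cells,
AF594 = CD45/CD18 for leukocytes) — and for anyone who needs flow-
cytometry-style population percentages from FFPE sections rather than from
cell suspensions.

The pipeline:

1. **Nuclear segmentation** in the DAPI master channel (Gaussian
   smoothing, Otsu or fixed threshold, distance-transform watershed),
   followed by the *remove labels* area gate that keeps only biologically
   plausible nuclei with area in the closed interval [40, 100] µm²,
   rejecting fragments of cut nuclei and nuclear conglomerates.
2. **Cell-mask growing** per channel from the nuclear margin, outward and
   inward, in 0.5 µm growing steps until a sudden intensity step, a
   neighbouring cell, the nucleus centre, or the per-channel step limit
   (2.0 for AF488/AF594, 4.0 for eFluor 570 — elongated connective-tissue
   cells need the deeper search).
3. **Positivity gating** by the cell/background ratio *r = m/b*, where *m*
   is the cell's mask mean and *b* the median intensity of the nucleus-free
   background. The per-channel threshold τ is the upper bound of the 95%
   distribution-free CI of the median ratio over a 30% random cell sample;
   a cell is positive iff *r* > τ (strictly).
4. **Population tabulation** of the 8 marker combinations
   (cytokeratin-single … triple negative) with per-stratum percentages in
   epithelium and lamina propria, plus Wilcoxon signed-rank region
   contrasts and Bonferroni-corrected pairwise proportion tests between
   diagnosis groups.
5. **Quality controls**: isotype-control ROC (Mann–Whitney AUC) per
   channel and channel-spillover quantification from single-stain runs.

Because no public images accompany the original protocol, the package
ships a synthetic **tissue-phantom generator** (`generate_phantom()`) with
complete ground truth — pseudostratified epithelium over lamina propria,
3486 cells/mm², lognormal nucleus areas with median 64 µm², glands,
sub-1% channel spillover, isotype and single-stain control slides — so
every stage is testable end to end. See `vignettes/imic-methods.Rmd` for
the models, parameter meanings and design decisions.

## Worked example

```r
library(imic)

# half-millimetre square of synthetic mucosa at the default composition
cfg <- phantom_config(width_px = 1970L, height_px = 1970L, seed = 1L)
run <- run_pipeline(phantom = cfg, seed = 2L)
run
#> <imic_run> 1970 x 1970 px; 851 nuclei identified, 2 removed by gate, 849 cells
#> thresholds:
#>     channel      tau ci_lower n_sample n_domain_excluded       ci_method
#> 1     af488 5.243206 1.057425      254                 0 order_statistic
#> 2 efluor570 5.925816 1.570779      254                 0 order_statistic
#> 3     af594 6.297556 3.912239      254                 0 order_statistic

head(as.data.frame(run$populations), 8)
#>       region      population count total percentage
#> 1 epithelium       ck_single    77   115 66.9565217
#> 2 epithelium      vim_single     0   115  0.0000000
#> 3 epithelium       cd_single     1   115  0.8695652
#> 4 epithelium   vim_cd_double     0   115  0.0000000
#> 5 epithelium   ck_vim_double     3   115  2.6086957
#> 6 epithelium    ck_cd_double    22   115 19.1304348
#> 7 epithelium triple_positive     7   115  6.0869565
#> 8 epithelium triple_negative     5   115  4.3478261
```

Reading the output: 851 nuclei passed segmentation, of which 2 fell
outside the 40–100 µm² plausibility gate. The thresholds are the realized
cell/background ratios above which a cell counts as positive in each
channel (the quotient scale, so τ = 5.24 means 5.24× background). The
population table gives counts and percentages per tissue stratum — here
the epithelial band is, as built, dominated by cytokeratin-single-positive
cells (67%). `run$cells` holds the full classified cell table;
`write_run(run, "out/")` writes everything as TSV plus a JSON report.

Users with their own segmentation can enter at the table level:
`classify_cell_table(cells, background)` takes any per-cell intensity
table with `mean_af488 / mean_efluor570 / mean_af594` columns. A thin
command-line interface with `simulate`, `run`, `classify` and `qc`
subcommands lives at `inst/cli/imic.R`.

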