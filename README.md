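# cloneBow

Multicolor (Brainbow/zebrabow-style) clonal analysis of neural progenitor
lineages in R.

## The problem

In multicolor lineage tracing, Cre recombination switches each labelled
founder cell to one of several spectrally distinct fluorophores, so clonally
related cells share a color. Quantifying such experiments — for example in
the embryonic zebrafish hindbrain, where boundary progenitors switch from
symmetric proliferative to neurogenic divisions — requires a chain of
operations that are easy to get subtly wrong: binning noisy RGB measurements
into discrete color identities, grouping cells into clones by color plus
spatial contact, deciding which clones are traceable, calling
progenitor/neuron fates from position and apical contact, classifying
division modes, and comparing experimental groups with the appropriate
statistics. cloneBow implements this pipeline as tested, reusable functions
for anyone analyzing annotated cell tables from multicolor imaging.

## The model

* **Color identities.** Measured channel means `(R, G, B)` are normalized to
  the 2-simplex, `r = R/(R+G+B)` etc., and the simplex is partitioned into a
  triangular grid with each edge split into 5 equal intervals: 15 upward plus
  10 downward unit triangles, i.e. **25 color identities**. A point with
  floors `i = ⌊5r⌋, j = ⌊5g⌋, k = ⌊5b⌋` lies in a downward triangle iff
  `i+j+k = 3`; half-open intervals and an upward-triangle rule for lattice
  points make the assignment total and unique. Identities above 10% of cells
  are *frequent*, below 2.5% *rare*.
* **Clones.** Cells in the same color identity and within a contact distance
  `d_contact` (default 12 µm) are clonally related: clones are connected
  components of that graph, numbered by mediolateral then dorsoventral
  position. Traceable clones have 1–3 cells in the progenitor domain; clones
  with frequent colors are followed only when isolated.
* **Fates and division modes.** A cell is a progenitor (P) when apically
  attached or near the ventricle, a neuron (N) when in the mantle zone
  without apical contact. A division is PN when the daughters separate across
  the ventricular/mantle boundary, PP or NN when they stay in contact at the
  same dorsoventral level with matching fates; daughters tracked less than
  3 h are not fated. Without tracks, modes are inferred from endpoint clone
  composition (each PP adds a progenitor, each PN a neuron; NN only in
  even-neuron clones, one per mutually-nearest contacting neuron pair).
* **Statistics.** Two-group comparisons are normality-gated (Shapiro–Wilk,
  then Welch's t or Mann–Whitney); multi-group designs use one-way ANOVA with
  Dunnett contrasts. A summary-statistic Welch mode verifies printed
  mean ± s.d./n legends.
* **Synthetic data.** A generator simulates recombination outcomes
  (copy-number-weighted fluorophore mixtures), stochastic lineages (per-frame
  division probability, PP/PN/NN mode probabilities, truncated-normal
  sister-division delays), spatial rendering with channel noise, and full
  ground truth — so every stage is testable without imaging data.

## Worked example

```r
library(cloneBow)

## clone calling on the bundled synthetic example table
cells <- readCellTable(system.file("extdata", "synthetic_cells.tsv",
                                   package = "cloneBow"))
callClones(cells[cells$time_hpf == 32, ])
#> CloneSet: 6 clones over 12 cells (0 unassigned), dContact = 12 um

## a full time-lapse workflow on a simulated cohort
cfg <- simulationConfig(nFounders = 200, seed = 7)
res <- runWorkflow(simulateDataset(cfg), "timelapse")

round(res$mode_shares, 1)
#>   PP   PN   NN
#> 37.1 60.0  2.9
round(100 * res$proliferation$dividing_fraction, 1)
#> [1] 48.9
res$growth$summary
#>    time_hpf  mean        sd   n
#> 32       32 2.005 0.4755055 200
#> 45       45 3.435 1.7921591 200
round(res$sisters$delay_mean, 2)
#> [1] 2.57
```

The mode shares are the percentages of symmetric proliferative (PP),
asymmetric (PN) and symmetric neurogenic (NN) divisions recovered by
track-based classification; the cohort was simulated at 40/58/2, so the
recovered values show the sampling spread at this cohort size. Clones start
at about two cells and grow to about three over the 13 h window, and sister
cells divide about 2.6 h apart.

Verifying a printed legend from group summaries alone:

```r
round(unlist(welchFromSummary(5.3, 4, 6, 13.5, 5.7, 9)), 4)
#> statistic        df   p_value
#>   -3.2730   12.9117    0.0061
```

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "clonebow.R", package = "cloneBow"))') \
  run-all --workflow timelapse --seed 7 --out out/
```

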