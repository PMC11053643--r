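---
title: "Methods: blood-concentration screening ratios for PFAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood-concentration screening ratios for PFAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcbcr)
```

## The screening model

For chemicals with long biological half-lives, blood concentrations are
approximately stationary, so a single biomonitoring summary statistic is a
meaningful exposure surrogate. The package compares such measurements with
in vitro bioactivity through

$$\mathrm{BCBCR} = \frac{\mathrm{POD_{chemical}}\ \mathrm{(ng/mL)}}
                        {c_\mathrm{plasma}\ \mathrm{(ng/mL)}},$$

one ratio per chemical × population × reported metric. The statistic is a
margin-of-exposure analogue on the internal-concentration scale: no
dose-response modelling, no interspecies extrapolation, and no
tissue-partitioning corrections (deliberately — partitioning predictions
for the fluorinated backbone are too uncertain to improve on the nominal
ratio). Values below 1 indicate measured blood levels within the bioactive
range; because screening uncertainties plausibly span two orders of
magnitude, bands at 1, 100, 1000 and 10,000 are reported rather than a
single bright line. All band comparisons are strict (`< 1`, `< 100`, ...),
so a ratio exactly at a boundary falls in the band above.

Key assumptions, each surfaced in the outputs rather than silently applied:

* **Stationarity.** The ratio is only interpretable for chemicals with
  half-lives of months or more. Half-life class is carried as a flag
  (`halflife_applicable`), not a filter: short-half-life chemicals remain
  in the ranking but are marked.
* **Total concentration.** Measured plasma values are total (bound plus
  free), and in vitro PODs are nominal test concentrations; the ratio
  inherits both conventions.
* **Censoring is not potency.** A chemical inactive in every assay set up
  to the top tested concentration gets the sentinel POD; ratios built on it
  are flagged `censored` so they read as "no observed bioactivity up to the
  tested range", not as evidence of safety.

## Harmonizing biomonitoring records

Records arrive as population summary statistics (percentiles 5–99, minimum,
maximum, mean, median), one per row, in ng/mL (µg/L accepted as identical,
µg/mL scaled ×1000). All mean flavours — arithmetic, geometric, "average" —
are designated means, and means, medians and 50th percentiles share the
central stratum of the five metric groups (High / 75th / 50th / 25th /
Low) used in presentation.

Matrix conversion to plasma equivalents uses the steady-state
blood-to-plasma concentration ratio $R_{b2p}$:
$c_\mathrm{plasma} = c_\mathrm{blood} / R_{b2p}$ for whole blood, cord
blood and blood spots; serum, plasma and their cord variants are taken as
plasma directly. Measured in vivo ratios take precedence over in
vitro-derived predictions when a roster distinguishes them; chemicals with
no ratio fall back to a default of 0.5, the typical value in the measured
PFAS range (most observed ratios fall between 0.5 and 0.6, i.e. roughly
half the body's blood volume is plasma and PFAS partition mostly into it).
The conversion factor and its provenance are recorded on every record.

Values at or below the detection or quantitation limit are kept as
reported — no LOD/√2 substitution — and records whose value is only the
string "<LOD" are rejected at ingest rather than imputed. Duplicate
records are retained by design: sources overlap (several data sets
re-summarize the same national surveys) and deduplication across summary
statistics is not well defined. Every plasma value above 100 ng/mL is
returned by `qc_flag()` for manual review; high values drive the minima of
a ratio whose numerator rarely moves, so transcription errors there are the
ones that matter.

## POD aggregation

Endpoint-level results (AC50s, benchmark concentrations, lowest effect
levels, with hitcalls) aggregate in two stages:

1. **Set level.** Within one chemical and assay set, the POD is the lower
   5th percentile of active potencies — except for technologies whose POD
   is defined as the lowest endpoint value: the two-endpoint estrogen
   impedance assay (ACEA), phenotypic profiling (HTPP, per cell type) and
   the zebrafish embryotoxicity battery. Transcriptomics and phenotypic
   profiling cell types, and each of the 12 primary-cell systems (BSK),
   are separate assay sets; within a primary-cell system the default 5th
   percentile applies (the within-system rule is not otherwise specified;
   it is exposed in the policy object). An all-inactive set receives the
   1000 µM sentinel (configurable) and is marked censored.
2. **Chemical level.** The minimum over set-level PODs, ties broken by
   lexicographic assay-set name so the driving set is deterministic. The
   ng/mL value is `pod_um × MW`; a missing molecular weight leaves the
   ng/mL value `NA` with a warning rather than failing the µM result.

The percentile uses linear interpolation between order statistics
(`stats::quantile` type 7), the default convention of most scientific
software; the convention is a policy option since aggregated potency
distributions are small and the choice is visible at n < 20.

Developmental neurotoxicity (DNT) curves pass a confidence filter before
aggregation; a hit is demoted to inactive (potency cleared) when any of
three criteria is met: ≥ 3 caution flags; a positive curve with model top
≤ 1.2 × cutoff whose potency falls below the tested concentration range
(a shallow extrapolated fit); or an undetermined hitcall from a series
with fewer than four concentrations. The filter is idempotent and its
effect is recorded per row.

## Chain length

For structure–occurrence analyses, chain length is the maximum contiguous
number of fully fluorinated carbons: a carbon qualifies when it carries at
least one fluorine and no hydrogens, so the CF2 carbon bonded to a
sulfonate group counts while the fluorine-free carboxyl carbon does not
(perfluorooctane sulfonic acid → 8, perfluorooctanoic acid → 7).
Contiguity is the longest simple path in the carbon–carbon adjacency graph
restricted to qualifying carbons, which handles branched structures
deterministically; the subgraphs are tiny, so the exhaustive search is
exact. Ether carbons qualify under this rule when H-free and F-bearing
(the ether PFAS GenX scores 3, its perfluoropropyl arm, because the carbon
graph is severed at the ether oxygen). The alternative of disqualifying
any heteroatom-bonded carbon was rejected: it would undercount every
sulfonate and sulfonamide. Chemicals without structures return `NA`, never
0, so they are excluded from — not misplaced in — chain-length analyses.
SMILES parsing is delegated to OpenBabel (via ChemmineR); the
qualification rule and path search operate on the resulting atom/bond
tables, with implicit hydrogens detected from the bond-order deficit at
each carbon.

Molecular weights are summed from 2021 IUPAC standard atomic weights
embedded as constants; 1 µM of a chemical of molecular weight MW g/mol is
exactly MW ng/mL, and the conversion round-trips to floating precision.

## In vivo anchor

The packaged 28-day oral rat study table provides, per chemical and sex,
lowest effect levels (mg/kg-day) for nine phenotypes and the measured
plasma concentration at the lowest LEL. The in vivo POD is the row
minimum over non-missing phenotypes (all attaining phenotypes are listed).
In vitro set-level PODs, converted to ng/mL, are compared against the
closed interval spanned by the male and female plasma-at-lowest-LEL
values; a POD exactly at an endpoint counts as in range (the interval is a
two-point empirical range, not a confidence bound, so the boundary
convention is inclusive by choice). Plasma values at the lowest LEL are
consumed as reported, not recomputed from dose.

## The synthetic generator

Population plasma concentrations are modelled log-normal — the standard
working model for biomonitoring concentrations of slowly cleared
chemicals — with geometric mean `gm` (ng/mL) and geometric standard
deviation `gsd`; exposed cohorts are the same model with a multiplicative
shift. For blood-like reporting matrices the individual values are moved
to the blood scale with a known true $R_{b2p}$ *before* summarizing, so
the pipeline's conversion can be checked for exact recovery (quantiles and
means commute with positive scaling). Defaults — `gm = 5` ng/mL,
`gsd = 2`, 500 subjects, LOD 0.05 ng/mL — sit in the range typical of
general-population PFAS serum surveys; tests that probe asymptotics raise
`n_subjects` to 10,000.

Assay endpoints are i.i.d. log-normal around a true POD, with the location
calibrated to the aggregation rule: under the percentile rule the
population 5th percentile equals the truth; under the minimum rule the
location is set so the *median* of the sample minimum equals the truth
(the minimum of $n$ i.i.d. draws has its median at quantile
$1 - 0.5^{1/n}$). At zero noise every draw equals the truth exactly. For
DNT sets, three lure curves are injected — one per filter criterion, each
with a potency far below the truth — so an unfiltered pipeline visibly
corrupts the POD and the filter's effect is testable. Determinism: one
global seed fans out per spec through a stable string hash (chemical,
study, population class — not the reporting matrix, so the same cohort
reported in two matrices shares its individuals), so adding a spec never
perturbs existing ones.

What the generator does **not** emulate: toxicokinetic time-courses,
between-study analytical bias, correlated mixtures of co-occurring PFAS,
non-log-normal heavy tails from point-source exposures, and
reporting-level censoring of individual draws. Passing tests therefore
demonstrate that the pipeline's arithmetic and bookkeeping are correct
under the stated model — not that the model captures every feature of
field biomonitoring data.

## Numerical and design choices

* Quantile convention: type 7 everywhere (generator and aggregator), so
  recovery tests are exact rather than convention-limited.
* Strict inequalities for QC (`> 100` ng/mL) and all bands.
* Zero plasma values make the ratio undefined: skipped with a warning,
  never dropped silently or imputed.
* Ranking keeps censored-POD chemicals, flagged, because a sentinel-based
  ratio is a statement about tested range, not potency; removing them
  would hide the chemicals most in need of more assays.
* The pipeline is a pure function of (inputs, configuration): reruns
  produce byte-identical tables. Figures are presentation aids (log10
  axes, exposed = orange / general = blue) and carry no information absent
  from the tables.
* Problem sizes in the test suite: 1000-instance property checks for
  aggregation oracles, 20 × 10,000-subject end-to-end recoveries (observed
  error well under the 5% bound), 50-seed Monte-Carlo calibration of noisy
  POD recovery (15% bound on the median).

## Limitations

The ratio is only as good as its inputs: endpoint potencies are consumed
as fitted (no curve refitting), partition ratios as supplied (no
physiology-based prediction), and half-life classes as annotated.
Reproducing published full-data rankings requires the corresponding
biomonitoring and POD tables in the documented schemas; the package ships
only the two in-paper tables (the 31-chemical roster and the rat-study
LELs) plus the generator. Ether-PFAS chain lengths depend on the
qualification rule documented above; comparisons against sources using a
different convention should recompute rather than mix.
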