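---
title: "Methods: quantifying and testing cysteine-thiol oxidation with cysredox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and testing cysteine-thiol oxidation with cysredox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysredox)
```

## The measurement model

Sequential iodoTMT labelling produces, for every peptide and biological
replicate, two reporter-ion intensities: the **SH** channel (first label,
originally free thiols) and the **Sox** channel (second label, reversibly
oxidized thiols reduced in vitro with TCEP). Assuming both labels report the
same underlying peptide pool, the reversibly oxidized fraction of that pool
is estimated per replicate as

$$\mathrm{OX\%} = 100 \cdot \frac{\mathrm{Sox}}{\mathrm{SH} + \mathrm{Sox}}.$$

Two asymmetric missing-value rules follow from the MS dropout mechanism:

* **SH missing, Sox present**: the free-thiol signal fell below the
  detection limit while oxidized signal was measured. SH is imputed as 0
  and OX% becomes 100. This is an upper-bound estimate, appropriate because
  reporter dropout is intensity-driven (a low SH signal means a mostly
  oxidized pool).
* **Sox missing**: without the oxidized channel the ratio is undefined;
  OX% is `NA`. No imputation is attempted, because a missing Sox can mean
  either low oxidation or overall low abundance.

Rows in which *no* channel carries a value are removed during filtering;
rows that retain SH signal but never a Sox value in any replicate of either
condition yield all-`NA` oxidation and are dropped from the profile (they
are identified but not quantifiable; the count is recorded on the profile
object and in the run log).

## Filtering

Four removal rules are applied in a fixed order, each with an audited
count: potential contaminants, reverse (decoy) hits, peptides identified
only by site, and peptides whose sequence contains no cysteine; finally the
no-quantitative-information rule above. Reporter intensities written as
exactly 0 are treated as missing on input: MaxQuant writes 0 for
unquantified reporter channels, and the SH imputation rule only makes sense
for absent, not measured-zero, signals.

## Normalization

Channels are normalized in log2 space by **median of medians within
(condition x thiol state) groups**: in a two-condition design the four
groups are (A, SH), (A, Sox), (B, SH), (B, Sox). Each channel is shifted
additively so its median over present values equals the median of its
group's channel medians. Grouping SH with SH and Sox with Sox is essential:
normalizing SH and Sox channels to a *common* target would force the
median oxidation toward 50 % and systematically distort the ratio. Because
the shift is additive in log2 (multiplicative in intensity) and shared by
all peptides of a channel, it removes exactly the per-channel loading and
labelling-yield differences while leaving within-channel structure intact.
The operation is idempotent, and the per-channel medians, targets and
shifts are written to a normalization audit table.

The oxidation ratio is computed on back-transformed (linear) intensities,
not on log2 values: the normalized log2 data are exponentiated, summed per
replicate pair, and only then converted to a percentage. Summation is per
replicate pair — the only reading consistent with requiring "at least two
valid oxidation values per group" for testing, which presupposes
replicate-level oxidation values.

## Differential oxidation

Peptides with at least `min_valid = 2` valid oxidation values in each
condition are tested with a two-sided Student's t-test with pooled
variance (the common default of proteomics packages for this design;
Welch's correction is a deliberate non-default because three replicates
give too little information to estimate separate variances). The ranking
statistic for FDR estimation is SAM-style,

$$d_i = \frac{\bar{x}_{A,i} - \bar{x}_{B,i}}{s_i + s_0},$$

with $s_i$ the pooled-t standard error and fudge factor $s_0 = 0$ by
default (configurable; a positive $s_0$ damps large $d$ from
small-variance peptides).

**Permutation-based FDR.** Replicate labels are reassigned across the two
conditions, the same reassignment applied to all peptides, and the null
statistics pooled over all peptides. For each peptide,

$$q_i =
  \frac{\frac{1}{P}\sum_{p=1}^{P} \#\{|d^{(p)}| \ge |d_i|\}}
       {\#\{|d_{\mathrm{obs}}| \ge |d_i|\}},$$

clipped to $[0, 1]$. Following the usual q-value convention, each peptide
then takes the minimum of this estimate over all thresholds at or below
its own $|d|$ (any more lenient threshold still calls the peptide), which
makes $q$ non-increasing in $|d|$. For a 3 vs 3 design the assignment
space is enumerated exhaustively. Two numerical choices matter:

* **The observed grouping is excluded from the null ensemble.** Of the 20
  distinct assignments of six replicates into two groups of three, the
  identity and its mirror reproduce the observed statistics, not null
  ones. With only 20 assignments their inclusion would contribute
  $2/20 = 0.1$ to every q-value — a hard floor above the conventional
  $\alpha = 0.05$, under which no peptide could ever be called
  significant in a triplicate design. The 18 informative assignments are
  used; q-values of 0.015 or 0.004, as this design produces in practice,
  are only possible under this convention.
* **Zero-variance guard.** When the pooled variance is exactly zero, a
  mean difference at or below `delta_eps` ($10^{-9}$ percentage points,
  configurable) is treated as no difference ($d = 0$, $p = 1$); a larger
  difference follows the $t = \pm\infty$, $p = 0$ convention. Without the
  guard, replicate values that differ by one floating-point ulp — common
  after normalization of low-noise data — produce infinite null
  statistics that destroy the q-value ranking.

Significance is strict: `q < alpha` (a peptide at exactly 0.05 is not
called). Direction follows the sign of `delta_ox = mean(A) - mean(B)`; the
reported `log2_ratio = log2(meanA/meanB)` matches volcano-plot convention.

**Condition-specific oxidation.** A peptide with valid Sox in all
`only_in_required` replicates (default: all three) of one condition and
none in the other is called oxidized only in that condition. These
peptides are untestable by the t-test (no valid values in one group), so
the 3:0 rule complements rather than overlaps the q-value calls.

**Oxidation classes.** Per-condition mean oxidation is binned into
`low` (< 20 %), `mid` (20-80 %, bounds inclusive) and `high` (> 80 %).
The bounds are written `<20 %` and `>80 %` for the outer classes, so 20
and 80 themselves fall in `mid`.

## Site mapping and annotation

Peptides are located as substrings of their leading protein (razor-protein
semantics beyond the leading accession are out of scope). A peptide that
matches at several positions is flagged ambiguous and contributes no
coordinates — inventing one of several possible sites would fabricate
data; it stays in the peptide-level results. Each cysteine at peptide
offset $k$ of a peptide starting at protein position $s$ maps to residue
$s + k - 1$, which is asserted to be a cysteine. Unique sites aggregate
their supporting peptides' condition means by the median (robust to one
outlying missed-cleavage variant; configurable to the mean). Annotation
labels (disulphide, S-nitrosylation, ...) attach exactly to sites; a
peptide inherits a label when **at least one** of its mapped cysteines
carries it — the standard convention for multi-cysteine peptides, since
the peptide-level measurement cannot resolve which cysteine is modified.
Multi-cysteine peptides carry one oxidation value applied to all their
sites; site-level disambiguation from peptide-level reporter data is not
possible and not attempted.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without
raw MS data. It emulates:

* a proteome of random sequences (uniform residue background; cysteines at
  `cys_rate`, default 3 %, about the mammalian proteome frequency; K+R
  jointly ~10 % so tryptic peptides have realistic lengths);
* trypsin/P digestion (cleavage after K/R including before proline, the
  defining difference from plain trypsin), peptide length 6-40 residues;
* per-site true oxidation fractions drawn from condition-specific beta
  mixtures: a bulk component with mode 12 % in condition A and 4 % in
  condition B (the observed fetal 9-16 % vs adult <9 % pattern) plus a
  high-oxidation component (mode 90 %) with more weight in condition B
  (heavier >70 % tail in the adult-like condition);
* injected differential effects: labels are assigned **per peptide** (all
  of a peptide's sites shifted together by exactly `effect_size`), because
  the measured quantity is the peptide-level mean over sites — injecting
  a single site of a multi-cysteine peptide would dilute the peptide-level
  effect below the nominal size. `frac_differential` counts sites;
  peptides are accumulated until that site budget is covered;
* condition-exclusive oxidation: a fraction of peptides has true fraction
  0 in condition B, so their Sox signal is structurally absent there;
* reporter intensities: per-(peptide, condition) abundance (lognormal,
  log2 mean 20, sd 2) times a per-replicate loading factor shared by the
  SH and Sox channels of that replicate (log2 sd 0.5). The separable
  structure is what median-of-medians normalization is designed to
  remove; with it, the full pipeline recovers true fractions exactly at
  zero noise, which is the generator's strongest self-check;
* multiplicative lognormal measurement noise on each reporter intensity
  (`noise_sigma`, log2 scale; default 0.3 ~ 23 % CV);
* missingness: intensities of exactly zero are absent, and dropout occurs
  with logistic probability rising as log2 intensity falls below
  `missing_threshold` (default 12) — missing-not-at-random, the mechanism
  presupposed by the SH imputation rule;
* decoy rows: REV__/CON__ accessions and only-by-site flags in MaxQuant
  conventions, for exercising the filter stage.

`shared_baseline = TRUE` switches non-differential sites to a single
baseline fraction shared by both conditions. This mode exists because the
condition-specific default makes essentially *every* site truly different
(a global distribution shift), which is realistic but unsuitable for
calibration studies: type-I error must be measured under a global null,
and sensitivity/FDR for injected effects must not count the background
shift as false positives.

What the generator does **not** model — and hence what passing tests do
not show about real data: between-replicate biological variability of the
true oxidation fractions (replicates differ only by technical noise, so
differential calls are more abundant at desk scale than in real
experiments), isotopic impurity and ratio compression, retention-time or
spectrum-level effects, and shared peptides between proteins.

## Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha` | 0.05 | q-value | conventional FDR threshold |
| `min_valid` | 2 | replicates | minimum per group for a t-test |
| `only_in_required` | replicates (3) | replicates | the 3:0 rule |
| `class_bounds` | 20, 80 | % oxidation | low/mid/high class limits |
| `s0` | 0 | % oxidation | plain t ranking |
| `delta_eps` | 1e-9 | % oxidation | zero-variance guard (numerical) |
| `n_permutations` | exhaustive | — | exact at 3 vs 3 (18 informative) |
| `cys_rate` | 0.03 | per residue | proteome cysteine frequency |
| `noise_sigma` | 0.3 | log2 | ~23 % reporter CV |
| `missing_threshold` | 12 | log2 intensity | dropout onset |
| `effect_size` | 0.4 | fraction | 40-point injected difference |

## Problem sizes and numerical checks

The test suite and the acceptance script run simulations at desk scale:
60-280 proteins, giving roughly 200-1100 cysteine peptides in a 2x3x2
channel design — large enough for stable medians and error-rate estimates,
small enough to run in seconds. The digestion and permutation-FDR
implementations are verified exactly against independent brute-force
oracles (200 random sequences up to length 50; all label assignments on
tables of up to 8 rows). Noise-free end-to-end recovery is required to be
exact to 1e-9 percentage points; normalization must hit each group target
to 1e-9 in log2 units. Degenerate inputs that are handled explicitly:
empty proteomes (schema-valid empty outputs), channels with no present
values (a data error), non-positive intensities after reading (a data
error naming the cell), peptides mapping to zero or multiple protein
positions (unmapped/ambiguous, never fabricated coordinates), and tied
|d| values in the FDR ranking (shared counts give equal q).

## Known limitations

Peptide-level oxidation cannot resolve individual cysteines of multi-Cys
peptides; condition summaries use valid values only and can rest on as few
as two replicates; the permutation null at 3 vs 3 has 18 informative
assignments, so q-values have a resolution floor of roughly 1/18 per
pooled-null count unit at the top of the ranking (mitigated by pooling
across peptides); and the generator's realism limits are listed above.
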