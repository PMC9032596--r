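---
title: "Mapping deep-sowing tolerance loci: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping deep-sowing tolerance loci: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoqtl)
```

## The problem

When maize is sown well below the usual 3–5 cm (15–20 cm in dry regions,
to reach soil moisture), the seedling only emerges if its mesocotyl — the
stem segment between seed and coleoptile node — elongates enough to push
the shoot to the surface. Mesocotyl length (MES) is therefore the central
deep-sowing tolerance trait. `mesoqtl` implements the computational chain
used to dissect its genetics in a biparental cross: a tolerant and an
intolerant inbred are crossed, the F2 is genotyped, F2:3 families are
phenotyped across sowing depths, and three complementary mapping routes
are combined — a composite-interval-mapping (CIM) QTL scan, bulked-segregant
sequencing (BSA) of extreme phenotype pools, and intersection of the
resulting intervals with differential-expression evidence.

## Phenotype genetics

For a balanced trial of $g$ families $\times$ $n$ environments $\times$
$r$ replicates, `estimate_variance_components()` applies the
expected-mean-squares method of the two-way ANOVA:
$\hat\sigma^2_\epsilon = MS_{err}$,
$\hat\sigma^2_{ge} = (MS_{GE} - MS_{err})/r$,
$\hat\sigma^2_g = (MS_G - MS_{GE})/(nr)$, with negative estimates
truncated to zero (the raw values are retained). Heritabilities follow as

$$H_B^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_{ge}^2/n +
\sigma_\epsilon^2/(nr)}, \qquad
H_{GE}^2 = \frac{\sigma_{ge}^2/n}{\sigma_g^2 + \sigma_{ge}^2/n +
\sigma_\epsilon^2/(nr)}.$$

Two orientation choices deserve a note because published formula sheets
are not always internally consistent:

* The $H_{GE}^2$ numerator is the *interaction* component
  $\sigma_{ge}^2/n$. The variant with $\sigma_g^2/n$ in the numerator
  (which forces $H_{GE}^2 = H_B^2/n$) is available behind
  `as_printed = TRUE` purely for auditing.
* The depth rate-of-change is
  $RC = (\bar T_{deep}/\bar T_{normal} - 1)\times 100$, i.e. a mesocotyl
  growing from 3.82 cm at 3 cm depth to 12.70 cm at 20 cm depth has
  $RC = 232.46\%$. The alternative printed form
  $(1 - \bar T_{normal}/\bar T_{deep})\times 100$ is again available via
  `as_printed = TRUE`.

Heterosis indices (`heterosis()`) use the standard definitions from
generation means; the identity $HI = MH + 100$ holds algebraically and is
tested. Distribution descriptors use moment skewness and *excess*
kurtosis (normal = 0); the segregation-analysis rule of thumb flags a
trait as approximately normal when both are below 1 in absolute value.
The kurtosis convention matters for that rule and is stated here because
formula sheets rarely say which one they use.

## The CIM scan

Genotype probabilities on a 1 cM grid are computed per individual by
conditioning on the nearest flanking typed markers under the Haldane map
function (`genotype_probabilities()`); missing genotypes are bridged by
the nearest non-missing flanks and the 1:2:1 prior beyond terminal
markers. The scan (`cim_scan()`) is Haley–Knott regression: the family
mean is regressed on the expected additive dosage and heterozygote
probability at the test position plus the background cofactors, giving
$LOD = (n/2)\log_{10}(RSS_{null}/RSS_{full})$. This is a deliberate
divergence from full EM interval mapping: at this marker density
(mean interval 5.6 cM) the LOD difference is negligible, the fit is
deterministic, and a permutation scan of the whole genome costs two
matrix products per permutation.

Cofactors are selected by forward–backward stepwise regression with 2-df
marker tests at entry/exit p = 0.05, then capped to the 5 strongest by
marginal F statistic. The cap mirrors the long-standing CIM convention of
a small fixed number of background parameters; in our simulations an
uncapped p &lt; 0.05 selection admits 12–15 cofactors and visibly degrades
peak localisation, while the capped scan matches plain interval mapping
where no background signal exists. Cofactors within 10 cM of the test
position are excluded from its fit (the scan window). Permutation
thresholds (`permutation_threshold()`) re-scan permuted family means with
the *fixed* cofactor set — re-running stepwise selection inside each
permutation is not done; this is the common practical choice and keeps
1000-permutation runs cheap. Peaks are called per contiguous
supra-threshold segment; effects are reported with the convention that
positive additive values mean the second (intolerant) parent's allele
increases the trait, dominance is rescaled to the F2 scale (the fitted
heterozygote coefficient estimates $d/2$ for F2:3 family means, because
one selfing generation halves the heterozygote dominance deviation), and
gene action is classed by Stuber's $|d/a|$ intervals with right-closed
boundaries ($[0,0.20]$ A, $(0.20,0.80]$ PD, $(0.80,1.20]$ D, $>1.20$ OD) —
closing the right end resolves the gap left by the conventional
"0.00–0.20 / 0.21–0.80" notation.

## Bulked-segregant index mapping

The 30 + 30 extreme bulks are chosen on family means in the deepest
environment with deterministic id-based tie-breaking. Sites informative
for mapping have opposite homozygous parents and at least 10 reads in
each offspring pool. The SNP/InDel index of a pool is the fraction of its
reads carrying the tolerant parent's allele (sites with zero depth are
masked, never reported as 0), and $\Delta$ = index(LM) − index(SM), so
selection for long mesocotyls appears as $\Delta > 0$ at linked loci.

The null confidence band is simulated: each replicate draws two bulks of
30 F2 plants (equivalently 60 alleles at frequency 1/2), binomial read
counts at a given depth, and the resulting $\Delta$; the central 99%
interval is tabulated on a depth grid (5–200×, step 5) and interpolated
linearly at each site's mean pool depth — per-site simulation would be
needlessly slow and the band varies smoothly in depth. Sliding windows
(default 1 Mb, 200 kb step, at least 10 sites; all configurable) average
the per-site values, windows outside the (window-averaged) band are
significant two-sided by default, and significant windows merge into
linked regions whose ends are clipped to the outermost supporting sites.
The window defaults are choices, not reconstructions: source studies of
this design report linked regions of roughly 2–9 Mb, which these defaults
resolve.

## cQTL integration

QTL peaks are placed on the physical axis by their flanking markers;
linked BSA regions arrive with physical endpoints. Evidence intervals on
one chromosome whose gaps are at most 2 Mb cluster by single linkage
(`merge_evidence()`), and a cluster containing both QTL- and BSA-derived
members forms a constitutive QTL whose envelope runs from the smallest
member start to the largest member end. The 2 Mb default is the smallest
round value that unifies the published chromosome-4 BSA regions (largest
internal gap ≈ 1.45 Mb) into the single reported constitutive locus; it
is exposed as an argument. Coordinates are 1-based inclusive throughout
(the convention of printed QTL tables); BED export converts to 0-based
half-open. Candidate genes are the genes overlapping the envelope that
pass the strict differential-expression filter FDR &lt; 0.001 and
|log2FC| &gt; 1.

## The study simulator

`scenario_study()` generates the whole design under one seed: 346 F2
plants from two gametes each (Markov walks along 10 chromosomes,
1410.6 cM, 260 evenly spaced markers, Haldane recombination, no
interference), F2:3 family values in three depth environments with 10
replicates, extreme bulks of 30, and pooled reads at 45× mean Poisson
coverage with a symmetric 0.001 allele-flip error. True QTL effects
default to the published 16-entry effect table; the F2:3 family value of
a heterozygous F2 parent is $d/2$. Markers, variant sites, and the true
QTL are simulated as one linked process, so marker–trait and site–trait
correlations are internally consistent. Physical positions use a linear
1 cM = 1 Mb scaling per chromosome — needed because QTL results live in
cM but BSA regions in bp; it is configurable and makes no claim about
real maize recombination-rate variation.

What the simulator deliberately omits: genotyping error beyond the allele
flip, segregation distortion, crossover interference, real gene density,
linkage disequilibrium structure of real inbreds, and any transcriptome
simulation (DEG tables are plain inputs). Passing tests therefore show
the *methods* are correct and calibrated under the stated statistical
model, not that real data meet that model.

## Numerical choices and problem sizes

* Quantiles are type-7 throughout (permutation thresholds, simulated
  bands).
* Region lengths in Mb round half-up to 2 decimals, matching printed
  tables; `round()`'s round-half-even would differ on exact boundaries.
* Degenerate scan positions (no dosage variance, collinear dominance
  column) fall back to the additive-only fit or LOD 0 rather than
  erroring.
* Negative variance components truncate to zero after estimation.
* Test and validation runs use: Mendelian segregation at n = 10,000;
  confidence-band calibration on 20,000 null sites at 45×; CIM recovery
  over 200 simulated studies (n = 346, one 14%-PVE locus, 200-permutation
  thresholds); heritability recovery over 100 balanced trials of 200
  families. These sizes give Monte-Carlo errors comfortably below the
  tolerances they are tested against.

## Known limitations

* The scan fits one QTL at a time (plus cofactors); no multiple-QTL or
  epistasis models.
* The permutation threshold conditions on the observed cofactor set, so
  it is slightly anti-conservative in principle; the null calibration
  test bounds the effect.
* The unbalanced-design path of the variance-component estimator is a
  hard error, not a plug-in approximation.
* Only the F2 population type is implemented for the BSA null band.
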