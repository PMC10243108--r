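---
title: "Decoy-amino-acid FLR estimation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoy-amino-acid FLR estimation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoyFLR)
```

## The problem

Phosphoproteomics pipelines report, for every peptide-spectrum match (PSM),
a localization probability for each candidate modified residue. These scores
are local: a 0.95 from one pipeline or dataset is not the same evidence as a
0.95 from another, and a score threshold says nothing about the global
fraction of misplaced sites in the reported list. Searching with a decoy
amino acid — alanine, which cannot carry a phosphate — makes localization
errors directly observable: every pAla match is known to be wrong, and the
rate of pAla matches estimates the rate of silent errors on the genuine
target residues S, T and Y.

decoyFLR implements the post-processing around that idea: score adjustment
by observation frequency, global FLR estimation, redundancy collapsing, and
cross-study aggregation. The input contract is a table of PSM-site rows that
already passed PSM-level FDR control (typically 1%); PSM-level filtering,
raw-file processing and the search engines themselves are out of scope.

## Combined score

Each PSM-site carries `final_score = peptide_prob * site_prob`, the product
of the PSM identification probability (an iProphet probability, or 1 - PEP
for Percolator-style pipelines) and the site localization probability. Both
factors live in [0, 1]; the product is the confidence that the peptide is
right *and* the site is right.

## Binomial adjustment

Random matches recur less often than genuine sites. For each protein
position we count `s`, the number of PSMs observing it phosphorylated, and
`n`, the number of PSMs whose peptide covers the position at all. With `p`
the per-spectrum chance of a decoy match (unique pAla PSM-site matches /
unique spectra), the penalty is the binomial upper tail

$$P_s = \Pr(X \ge s), \qquad X \sim \mathrm{Binomial}(n, p),$$

and each record's score is multiplied by $(1 - P_s)$. A site seen once in
fifty covering PSMs is heavily penalised; a site phosphorylated in most of
its coverage is left nearly untouched.

Two choices deserve comment:

- **Tail versus point mass.** We use the upper tail $\Pr(X \ge s)$ — "at
  least this many chance successes" — because it is the quantity with the
  described behaviour (monotone in `s`, penalising rarely observed sites
  more). A `mode = "pmf"` switch exposes the point-mass variant for
  sensitivity analysis. Numerically the tail is computed with
  `pbinom(s - 1, n, p, lower.tail = FALSE)`, the survival form, which does
  not cancel catastrophically for large `n`.
- **Coverage scope.** Ideally `n` counts all PSMs passing FDR control,
  phosphorylated or not, via an explicit coverage table (`coverage`
  argument). When only phospho-enriched PSM-site rows are available, `n` is
  inferred from the peptide spans of those rows — an approximation that
  undercounts coverage by never-phosphorylated peptides, and is documented
  as such.

## Decoy-based FLR

Sites are ranked by score, descending. Ties are broken alphabetically by
peptide sequence and then by site position — never by the modified residue,
because any residue-aware tie order would systematically place decoys above
or below their target-residue peers and bias the estimate.

With `T` and `A` the total counts of target and decoy residues in the
counting scope and `D_n` the cumulative decoy count at rank `n`,

$$\mathrm{FLR}(n) = \frac{D_n \cdot T/A}{\,n - D_n\,}.$$

The `T/A` factor scales decoy counts to the target scale (errors land on a
residue roughly in proportion to its abundance); the subtraction in the
denominator reflects that decoy rows are removed from reported output, and
no factor of two is applied. `D_n` is counted **conservatively**: every site
of a PSM containing a decoy match counts toward the decoy tally, on the
logic that a decoy match discredits the whole PSM. Reported output always
drops rows whose own residue is the decoy; the conservative flag governs
only the estimate.

The running FLR is noisy and non-monotone where decoy counts are small, so
thresholding uses `q_flr`, the running minimum taken from the bottom of the
list upward (the q-value construction). Both columns are reported: the raw
running FLR for curve inspection, `q_flr` for thresholding. Degenerate
cases are pinned down explicitly: `FLR = 0` while no decoy has been seen,
`FLR = 1` on an all-decoy prefix, and values are clipped to [0, 1].

The scope of `T` and `A` is an explicit argument: counted over the observed
unique peptides (default), over a FASTA database, or supplied as a fixed
ratio. For a meta-analysis the fixed-ratio route keeps all datasets on one
normalisation.

### Known bias of the conservative count

On simulated data where the truth is known, the conservative count makes
the estimate sit a few percent *above* the real FLR whenever PSMs carry
more than one phosphosite: the sibling sites of a decoy-bearing PSM enter
`D_n` and are then scaled by `T/A` again, double-counting part of the error
mass of multi-site PSMs. With realistic multi-site rates this is a
systematic overestimate of roughly 5-10% relative, visible in
`evaluate_recovery()` as `est_flr` slightly above `real_flr`. We keep the
conservative definition — erring high is the intended direction for a
reported error rate — and document the bias rather than hiding it.

## Collapsing redundancy

Abundant peptidoforms are sampled by many spectra. Four strategies reduce
each (peptidoform, site) group to one score:

| method | score | assumption |
|---|---|---|
| `max` | best member score | PSM-site scores independent |
| `mean` | average member score | scores centred on the truth |
| `mm` | mean of each PSM's site scores, best PSM wins | the PSM, not the site, is the experimental unit |
| `product` | $1 - \prod (1 - s_i)$ | every observation is independent evidence |

In `mm`, all sites of a peptidoform receive the representative PSM's mean
by default (`mm_assign = "psm_mean"`); keeping each site's own score from
that PSM is available behind `mm_assign = "site_score"`, since the source
procedure does not pin this down. `product` is retained although it
over-accumulates (correlated observations violate its independence
assumption and its FLR curve is visibly worse) — reproducing that failure
is part of the package's purpose. Its grouping is peptidoform-site by
default with a protein-site option, another point the source description
leaves ambiguous.

Conservative decoy flags and support counts propagate through collapsing
by set union and group size; protein-site uniquification takes the maximum
over peptidoform sites.

## Meta-analysis

Scores are never compared across datasets — the score distributions of
independent studies differ too much for that to be meaningful. Only the
per-dataset FLR status crosses the dataset boundary. Sites are classed:

- **Gold** — passes the strict threshold (default 1%) in at least
  `gold_min = 2` datasets;
- **Silver** — passes the strict threshold in at least one but fewer than
  `gold_min`;
- **Bronze** — any other site passing the loose threshold (default 5%)
  somewhere.

Decoy-residue sites are carried through the catalogue and classed by the
same rules, so each class gets an empirical FLR:
`FLR(class) = decoys * ratio / targets`. Redundancy removal keeps the best
per-dataset q-value as provenance; deduplication across datasets is
expected to raise class FLRs slightly (correct sites recur across studies
more than random ones), which is why the class FLR is computed on the
deduplicated catalogue rather than assumed from the input thresholds.

## What the generator simulates — and what it does not

`simulate_psm_dataset()` works at the score-table level the post-processing
consumes; no spectra, masses or fragment ions are simulated. The moving
parts, with defaults:

- a proteome of 300 proteins x 350 residues with average amino-acid
  composition, digested tryptically (cleave after K/R, up to one missed
  cleavage, lengths 7-35);
- planted phosphosites on 15% of S/T/Y positions, with lognormal abundance
  (`sdlog = 1`) so that genuine sites recur across PSMs while errors
  scatter — the frequency signal the binomial adjustment exploits;
- 20,000 PSMs; each picks a planted site by abundance, and with probability
  `1 - true_localization_rate` (default error rate 10%) the **whole PSM**
  mislocalizes: every site lands on another S/T/Y/A position of the
  peptide. Treating mislocalization as a PSM-level event encodes the
  premise behind conservative decoy flagging (a decoy match discredits its
  whole PSM). The error residue class is drawn by the peptide's full
  S/T/Y/A composition, making the decoy a fair, frequency-proportional
  sample of the error process — the core assumption of decoy-based FLR —
  so `T/A` normalisation is exact by construction;
- per-PSM score bases from two Beta distributions (correct: Beta(3.5, 0.9);
  incorrect: Beta(0.8, 2.2), whose small right tail supplies the
  occasional high-scoring random match that frequency adjustment exists to
  demote), with per-site scores concentrated around their PSM's base
  (concentration 400). The tight within-PSM coupling mirrors the near-unit
  rank correlation between the `max` and `mm` collapses observed for
  probabilistic pipelines;
- a second planted site in the same peptide joins the PSM with probability
  0.2, giving a realistic minority of multi-phosphosite PSMs;
- the `"overlapping"` preset (error rate 0.35, nearly coincident score
  distributions) emulates low-specificity studies in which few sites
  survive stringent FLR thresholds.

Passing tests on these simulations shows the estimator and bookkeeping are
correct *under the generator's assumptions*. Real data differ in ways the
generator does not attempt: localization errors are not purely PSM-level,
score distributions are not Beta, peptide identification errors introduce
wrong sequences (not merely wrong positions), abundances correlate with
sequence properties, and chimeric spectra violate the one-PSM-per-spectrum
contract. Synthetic calibration is therefore evidence of internal
consistency, not of performance on any particular real dataset.

## Numerical and procedural choices

- Positions are 1-based and inclusive throughout; protein coordinates come
  from the input table (an exact-substring FASTA mapper is provided as an
  optional helper). Peptides listing several accessions take the
  lexicographically smallest — a deterministic convention, not a biological
  claim.
- All orderings use radix sorting with explicit tie keys, so results are
  independent of input row order and locale.
- Round-tripping: numeric columns are written with 17 significant digits,
  so `read(write(x))` reproduces scores exactly.
- Problem sizes in the shipped tests and the acceptance script (a 20,000
  PSM single-dataset study; four 5,000 PSM datasets for the meta stage;
  twenty 2,500 PSM replicates for calibration) were chosen so that decoy
  counts at the interesting thresholds are in the tens to hundreds — large
  enough for the binomial sampling error to be a meaningful yardstick,
  small enough to run comfortably on a laptop.

## Limitations

- FLR estimates inherit the decoy assumption: errors must hit the decoy
  residue in proportion to its abundance. Enrichment chemistry or motif
  biases that break this proportionality bias the estimate.
- The conservative decoy count overestimates mildly on multi-phosphosite
  data (quantified above).
- Scores outside [0, 1] are not supported; pipelines emitting unbounded
  scores need a calibration step first.
- Open modification searches are explicitly out of scope.
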