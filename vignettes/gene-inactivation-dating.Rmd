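---
title: "Detecting and dating gene inactivation from codon alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating gene inactivation from codon alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudochron)
```

## The scientific problem

When a phenotype is lost in a lineage — teeth in baleen whales, tooth enamel
in aardvarks, armadillos and pangolins — the genes serving only that
phenotype are released from purifying selection. They accumulate
open-reading-frame-disrupting mutations ("lesions"), drift toward a neutral
substitution pattern, and become pseudogenes. Two questions follow:

1. **Is the gene dead in a given lineage?** Evidence comes from two
   independent directions: physical lesions in the sequence (frameshifts,
   premature stops, splice-site mutations, deleted exons, a lost start
   codon) and a statistical signature — the nonsynonymous/synonymous rate
   ratio $\omega = dN/dS$ rising from the small values typical of conserved
   proteins toward 1, the neutral expectation.
2. **When did it die?** A branch of duration $T$ on which the gene was
   functional for $T_s$ and neutral for $T_n = T - T_s$ shows an *average*
   $\omega$ intermediate between the functional value and 1. Inverting that
   mixture gives the time of inactivation, which can then be compared with
   the fossil record of the phenotype: gene loss predating the oldest
   fossil is consistent with gene loss causing (or accompanying) the
   phenotype's loss; postdating it, with gene loss as a consequence.

`pseudochron` implements both analyses and a simulator that generates data
with known answers so every stage can be validated end to end.

## The lesion scanner

`detect_lesions()` / `scan_alignment()` compare each query row of a
codon-aware alignment against an intact reference whose ungapped sequence
defines the CDS coordinate system. Seven lesion classes are called
(`LESION_TYPES`):

- **initiation_codon_mutation** — the codon aligned to reference positions
  1–3 is fully resolved and is not ATG.
- **frameshift_deletion / frameshift_insertion** — a maximal run of query
  gaps over reference positions (deletion) or of query bases in
  reference-gap columns (insertion) whose length is not a multiple of 3.
- **exon_deletion** — a deletion run covering an entire annotated exon;
  reported per exon, with only the residual length counting toward a
  frameshift call.
- **premature_stop_codon** — TAA/TAG/TGA read in the *query's local
  reading frame*: the query's ungapped sequence is translated from its
  first base, so the frame starts in the reference frame and shifts at
  every indel. This is the biologically meaningful frame downstream of a
  frameshift; a stop only visible post-shift is still a genuine lesion.
  Stops at or after the reference's terminal stop are not premature.
- **splice_donor_mutation / splice_acceptor_mutation** — per-taxon intron
  dinucleotides from the gene-structure table differing from the canonical
  GT (donor) / AG (acceptor).

Codons or dinucleotides containing any missing symbol (`N`, `?`) or gap are
never called: low-coverage data must not manufacture lesions.

`map_shared_lesions()` places identical lesions (same type, position,
length, detail) on the species tree under Dollo parsimony: carried by
exactly the leaf set of a clade → single origin on that clade's stem
branch; one carrier → terminal branch; otherwise flagged homoplastic. This
is how, e.g., single-base deletions shared by all baleen whales are
assigned to the baleen-whale stem.

## The codon substitution model

Selection is quantified with a Goldman–Yang-style codon model over the 61
sense codons. Off-diagonal rates between codons $i \to j$ differing at one
position are

$$q_{ij} = \pi_j \times \begin{cases}
1 & \text{synonymous transversion}\\
\kappa & \text{synonymous transition}\\
\omega & \text{nonsynonymous transversion}\\
\omega\kappa & \text{nonsynonymous transition}
\end{cases}$$

with $q_{ij} = 0$ for multi-nucleotide changes, and the generator scaled to
one expected substitution per codon per unit time, so branch lengths are in
substitutions/codon. Equilibrium frequencies $\pi$ come from the alignment
via `F1x4` (pooled nucleotide frequencies, 3 free parameters), `F3x4`
(position-specific, 9) or `F61` (codon counts, 60), selectable by AIC
(`select_frequency_scheme()`).

`fit_codon_model()` fits one of four branch models, with branches
partitioned into *background* and *foreground* categories by tags on the
Newick tree (`tag_branches()`, or `#label` suffixes parsed by
`read_branch_tree()`):

| model | background | foreground | use |
|-------|-----------|------------|-----|
| A | one shared free $\omega$ | (same) | overall selection |
| B | $\omega \equiv 1$ | (same) | neutral null |
| C | $\omega_1$ free | $\omega_2$ free | two-ratio test |
| D | $\omega_1$ free | $\omega_2 \equiv 1$ | neutral foreground |

B ⊂ A ⊂ C and D ⊂ C, so `fit_model_ladder()` runs three likelihood-ratio
tests (each df = 1): **A vs B** (any selection signal at all), **C vs A**
(foreground differs from background) and **C vs D** (foreground differs
from neutral). *Complete relaxation* is declared when C-vs-A is significant
and C-vs-D is not: the foreground $\omega$ has left the background value
and is indistinguishable from 1.

Premature stop codons are recoded to missing data before fitting
(`recode_premature_stops()`), since stops are outside the model's state
space; the terminal stop columns are removed.

## Dating the inactivation

With $K$ the fitted foreground $\omega_2$ of a mixed branch, $K_s$ the
functional-period ratio (taken from the same fit's background $\omega_1$)
and $K_n = 1$ by definition of neutrality, the branch average obeys

$$K = K_s \frac{T_s}{T} + K_n \frac{T_n}{T}
\quad\Longleftrightarrow\quad
T_n = T\,\frac{K - K_s}{1 - K_s}.$$

`neutral_time()` applies the inversion to the lower and upper bounds of the
divergence-time interval for the branch, yielding an interval of neutral
time and hence an inactivation-date interval (`branch_end_age` $+ T_n$, in
Ma before present). Outside the mixture's domain the estimate is clamped
with a flag: $K < K_s$ gives $T_n = 0$ (no neutral signal) and $K > 1$
gives $T_n = T$ (whole branch neutral) — the only monotone choice, since
the formula's domain ends at $K = 1$. $K_s \ge 1$ is an explicit error, not
a silent clamp. `consistency_check()` then performs the cause-vs-consequence
interval comparison against a fossil age.

```{r dating}
est <- neutral_time(K = 0.414, Ks = 0.116, T_lower = 70, T_upper = 84)
est
consistency_check(est, fossil_age = 19)$relation
```

One documented subtlety: applying the equation to a whole *clade* (rather
than a single branch) with $T$ measured from the clade's split from its
sister lineage mixes stem and crown histories; the dating operation here is
the generic single-branch inversion, and clade-level use should be
interpreted with that caveat. The `branch_end_age` argument exists so a
stem-branch estimate maps to absolute dates (crown age $+ T_n$).

## The simulator and its realism

`simulate_alignment()` evolves codons along a time-calibrated tree (Ma)
and is the package's source of ground truth. Design choices:

- **Background $\omega_1 = 0.116$** — a typical value for a conserved
  enamel-matrix protein gene under purifying selection, and the value used
  throughout the validation harnesses.
- **$\kappa = 2$** — a representative mammalian transition/transversion
  ratio.
- **Clock rate 0.005 substitutions/codon/Ma** — mammalian neutral rates
  are of order $2\times10^{-9}$ substitutions/site/year; over three sites
  per codon that is $\sim 6\times10^{-9}$ per codon per year, i.e.
  0.006/codon/Ma, rounded to a conservative 0.005. The clock is the
  *neutral* rate: with synonymous flux $B$ and nonsynonymous flux $A$
  (at $\omega = 1$), a segment under selection strength $\omega$ evolves at
  the reduced total rate $\mathrm{clock}\times(B + \omega A)/(B + A)$, so
  the synonymous rate is identical on functional and neutral segments —
  purifying selection removes nonsynonymous changes only. This is what
  makes a mixed branch's average dN/dS the *time-linear* mixture of its
  segment $\omega$s, the premise of the dating equation above; scaling the
  mean-1 generator uniformly instead would bias the branch average toward
  the neutral value.
- **427 codons, 11 exons** — the size of a typical short secreted-protein
  gene; the default gene structure splits the CDS into equal exons with
  canonical GT/AG splice sites.
- **Switches to neutrality** — each switch names a tip set and an age: the
  stem branch of their MRCA becomes neutral at that age and all
  descendants inherit neutrality, giving known $(T_s, T_n)$ per switched
  branch for end-to-end dating validation.
- **Planted lesions** — `inject_lesions()` edits the finished alignment
  with any of the seven lesion classes, applied identically across taxa
  for shared lesions so Dollo mapping can recover the clade.

Truth accounting has one subtlety worth stating: a planted frameshift
shifts the local reading frame and typically *creates* downstream stop
codons that were never planted. These are genuine lesions of the emitted
sequence, so the truth table records every premature stop present in the
final local frame, flagging the non-planted ones `induced = TRUE`. This is
what makes exact recall/precision bookkeeping possible.

Known limitations: the simulator draws codons independently (no rate
variation among sites, no indel evolution beyond planted lesions, no CpG
effects), trees must be ultrametric for the time-calibrated generator, and
forced ATG/stop anchoring of the first and last codons slightly reduces
variance at the termini. Substitution-driven stop codons cannot arise
(the state space is the 61 sense codons), so all premature stops in
simulated data are planted or frameshift-induced — convenient for truth
accounting, but a mild departure from real pseudogene evolution.

## Numerical choices

- The generator is reversible, so $\Pi^{1/2} Q \Pi^{-1/2}$ is symmetric;
  transition matrices come from one symmetric eigendecomposition per
  $(\kappa,\omega)$, reused across branch lengths. Tiny negative entries
  from roundoff are clipped to 0.
- The likelihood uses Felsenstein pruning over compressed site patterns,
  with per-pattern rescaling to avoid underflow and all-ones partial
  vectors for missing codons.
- Optimisation is bounded quasi-Newton (L-BFGS-B) on log-transformed rate
  parameters ($\kappa \in [0.01, 100]$, $\omega \in [10^{-4}, 50]$, branch
  lengths $\in [0, 20]$), with an *analytic* gradient: edge-length
  derivatives from a two-pass (postorder/preorder) algorithm and
  $\kappa$/$\omega$ derivatives via the Fréchet derivative of the matrix
  exponential in the eigenbasis, differentiated through the mean-rate
  normalisation. Convergence targets $\sim 10^{-8}$ on the log-likelihood,
  with 3 $\omega$ multi-starts.
- The ladder fits warm-start B → A → C, D, which both accelerates
  convergence and guarantees the nesting inequalities
  $\ell_C \ge \ell_A \ge \ell_B$, $\ell_C \ge \ell_D$ at the optimum.
- Pipeline stages are memoised by a content hash of their inputs, so
  re-running an analysis with one changed foreground only recomputes the
  dependent fits.

These choices keep the validation harnesses at interactive speed: a
14-taxon, 500-codon four-model ladder fits in seconds, and the 200-replicate
type-I calibration (9 taxa × 300 codons, three fits each) runs in minutes
on one CPU. Those problem sizes — and the 116-taxon, 427-codon
`paper_scale` fixture bundle — are the scales the package is designed for.

## A complete analysis

```{r pipeline, eval = FALSE}
bundle <- simulate_alignment(sim_config(
  whale_like_tree(), n_codons = 300, seed = 21, reference = "Outgroup1",
  switches = list(list(taxa = "Mysticete3", age = 14, omega = 1)),
  lesions = list(list(type = "premature_stop_codon",
                      taxa = "Mysticete3", codon = 40))))

report <- run_full_analysis(
  alignment = bundle$alignment,
  tree = bundle$truth$tree_subs,
  gene_structure = bundle$gene_structure,
  foregrounds = list(
    mysticete3 = list(taxa = "Mysticete3", T_lower = 14, T_upper = 14,
                      fossil_age = 25)),
  freq = "F3x4", seed = 99)
report
render_report(report, "report/")
```

The same pipeline is scriptable from the shell via
`inst/scripts/pseudochron-cli.R` (subcommands `scan`, `fit`, `date`,
`simulate`, `run`).
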