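---
title: "Methods: a taxonomy-aware census of RNA family distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a taxonomy-aware census of RNA family distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnacensus)
```

## The problem and the model

Curated RNA family databases group homologous non-coding RNA sequences into
families (and families of shared ancestry into clans), each with a curated
seed alignment and a bitscore gathering cutoff. Every annotation carries a
source taxon, so a family's *phyletic pattern* — the set of taxa, divisions
and domains it occupies — can be computed directly. `rnacensus` turns that
into a reproducible pipeline with five analytical stages:

1. **Taxon resolution.** Each taxon id is walked up the taxonomic hierarchy.
   Its *domain* is the configured top-level node (Archaea, Bacteria,
   Eukaryota, or the fourth non-cellular set, Viruses) found on the chain.
   Its *major division* is domain-dependent: for Archaea and Bacteria, the
   child of the domain node on the chain (the database's top-level
   classification, typically a phylum); for eukaryotes, the first supergroup
   anchor met walking upward, under a user-overridable map following the
   six-supergroup scheme of Adl and colleagues; for viruses, the single
   division "Viruses". Reclassified taxa are handled by a merge map applied
   both to the queried id and to the resolved division node, so e.g.
   annotations filed under Thaumarchaeota can be counted with Crenarchaeota,
   matching how the underlying database classified those sequences at the
   time such censuses were taken. Unknown or retired ids degrade to
   `UNASSIGNED` rather than aborting a multi-million-row run; unassigned
   counts are reported so nothing is silently dropped.

2. **Vetting.** Multi-domain patterns are exactly the interesting ones, and
   exactly the ones most sensitive to annotation noise, so families whose
   annotations span more than one domain (viruses included) get a two-step
   filter. First, records flagged `MISANNOTATED` — the outcome of an
   external taxonomic re-confirmation such as reciprocal BLAST, which this
   package deliberately abstracts into an evidence column — are removed.
   Second, records with bitscore in the *marginal window*
   `[cutoff, cutoff + margin)` are removed unless a curator marked them
   `CONFIRMED`. The margin defaults to 10 bits. The window is half-open: a
   score exactly at `cutoff + margin` is confident. Scores below the cutoff
   itself (which should not occur in curated exports) fall in the same
   window rather than being special-cased. Single-domain families pass
   through untouched; `vet_all` extends the filter globally for sensitivity
   analysis. Vetting is at family level only: a clan whose *members* are
   each single-domain is not re-vetted merely because the clan spans
   domains.

3. **The census.** `build_presence()` bins vetted annotations into a boolean
   unit × column matrix with a parallel support-count matrix (`present` is
   defined as `support > 0`). Columns are either the four top-level sets or
   the divisions of one domain. At clan level a clan replaces its member
   families and its presence is the OR of theirs, so headline counts mix
   families and clans without double counting. `venn_partition()` assigns
   every unit with non-empty presence to exactly one of the 15 regions of
   the four-set Venn diagram; units whose annotations all resolved to
   `UNASSIGNED` are excluded and counted separately. A unit is *interdomain*
   when present in ≥ 2 of the three domains of life — viruses are a fourth
   set in the Venn analysis, not a domain, so domain+virus sharing is listed
   separately. A unit is *broadly distributed* in a domain when present in
   at least 50% of the domain's major divisions; the threshold is inclusive
   ("at least"), and the denominator is every division the taxonomy supplies
   for that domain, not only divisions with data, because the comparison is
   against the domain's known diversity (an `occupied_only` switch exists
   for sensitivity checks). Percentages are rounded half-up to one decimal,
   the convention of the printed rates this computation reproduces (13/69 =
   18.8%, 15/223 = 6.7%, 20/826 = 2.4%). Normalised taxonomic abundance
   divides the distinct annotated taxa of a unit in a group by an *explicit
   roster* of sampled taxa for that group; requiring the roster keeps the
   normalisation auditable and stops annotation density from being mistaken
   for taxonomic spread.

4. **Dollo mapping.** Families are homology groups, so a family's presence
   pattern on a rooted species tree is modelled with a single gain and any
   number of independent losses (Dollo parsimony) — not Fitch parsimony,
   which would allow repeated origins; a Fitch score is available for
   comparison via `fitch_changes()` but never used for nomination. Under
   Dollo the optimal gain is the most recent common ancestor of the presence
   tips, and the minimal loss count is the number of maximal subtrees below
   the gain containing no presence tip. Polytomies are allowed; each absent
   child of a polytomy is one loss. `nominate_candidates()` flags units
   whose gain sits at the domain root, or whose gain clade fully contains at
   least `clade_coverage` (default 0.5) of the root's presence-bearing
   immediate child clades. The coverage clause is this package's reading of
   a tree-guided broad-distribution rule: the underlying studies do not
   state a precise criterion for their tree-derived candidates, so we mirror
   the division-level 50% rule on the tree and expose the knob. An optional
   `max_losses` cap filters patterns that would demand implausibly many
   independent losses. Unrooted input trees are rejected unless an outgroup
   is given — rooting moves every MRCA and is never guessed.

5. **Discovery curves.** A family's discovery date is the minimum of its
   literature-reference dates and its sequence-record dates. Curves
   cumulate per year (year–month input accepted, binned by year) within
   domain-distribution classes 1-/2-/3-domain, counting domains of life
   only: viral presence does not change a family's class.

## The simulator: what it emulates and what it does not

`simulate_census_data()` generates the full input bundle — taxonomy tables,
a rooted species tree, annotation and family metadata tables — from an
explicit evolutionary model with recorded ground truth, so every pipeline
stage is testable without any external download and classification accuracy
is measurable.

Default study conditions, chosen once: three cellular domains plus a viral
set; 6 divisions per domain (the eukaryote supergroup scheme recognises six
top groups, and the prokaryote divisions are kept symmetric); 8 taxa per
division (a modest, GEBA-scale spread per division); 200 families; class
mix 0.90 domain-specific / 0.05 LUCA-vertical / 0.05 HGT, echoing the
strong domain restriction seen in curated data while leaving enough
multi-domain families to exercise the interesting code paths; per-branch
loss probability 0.05; one expected transfer per HGT family; 0.1 expected
false positives per family. The home domain of each family is drawn with
weights proportional to the published per-domain family totals (69
archaeal, 223 bacterial, 826 eukaryotic, plus a small viral share), so the
simulated census has the right qualitative skew. Per-family gathering
cutoffs are uniform on 20–50 bits. True hits score
`cutoff + margin + Exponential(mean 15)` — always confident; false hits
score uniformly inside the marginal window `[cutoff, cutoff + margin)`
(floored to one decimal so rounding cannot lift them out of it) and are
flagged `UNTESTED` or, with probability 0.25, `MISANNOTATED`. The margin
filter is therefore perfectly separating at default noise by construction;
harder mixtures are opt-in via the bitscore parameters.

The species tree is built per division as a caterpillar (pectinate) clade
of its taxa; divisions are chained within each domain and the three domain
clades join as ((Archaea, Bacteria), Eukaryota) under a labelled root. The
caterpillar shape gives non-trivial nested Dollo cases; internal labels
(`DIV_*`, `DOM_*`, `PROK`, `ROOT`) make gain nodes stable and readable.
Viruses are an annotation source only, with no tree placement, matching
their role as a fourth Venn set.

Gains: LUCA-vertical families gain at the root; others gain at the domain
root with probability `root_gain_prob` (default 0.15) or at a uniformly
chosen node inside the domain clade — most families therefore have narrow
distributions, as observed in real repertoires. Losses prune each branch
below the gain independently with `loss_prob`; a loss pattern that would
erase the family entirely is redrawn (and, if 50 redraws fail, the family
keeps its full clade). HGT families receive `1 + Poisson(hgt_rate − 1)`
transfer events, each grafting the tip set of a random node in a random
other cellular domain. Sampling bias thins *detection*: division weights
are Dirichlet-distributed with concentration `1/sampling_bias`, and an
annotation in a division is observed with probability
`min(1, n_divisions × weight)`; bias 0 means every true presence is
observed.

One degenerate corner is resolved by design: with `hgt_rate = 0` an
HGT-class family would receive zero transfers and be observationally
identical to a domain-specific family, making "perfect recovery" logically
unattainable. The simulator therefore folds the HGT share of the class mix
into the domain-specific class when `hgt_rate = 0`, and recovery scoring
reports accuracy for the classes actually present in the truth.

What passing tests on simulated data do **not** show about real data: the
simulator draws clean taxonomies (no retired ids, no above-division
placements), bitscore distributions that make the margin filter exactly
separating, losses that are independent across branches, and transfers that
graft whole clades. Real annotation noise is messier on every axis, so
simulated recovery rates are upper bounds, not estimates, of performance on
a live database export.

## Numerical and degenerate-input choices

- Percentage rounding is half-up (away from zero), not R's default
  round-to-even, to match the printed-rate convention; implemented in
  `round_half_up()`.
- The marginal window is half-open at the top; equality with
  `cutoff + margin` is confident. The boundary had to be fixed somewhere;
  "within +10 bits" is read as bounding the marginal zone, and both
  branches are pinned by an exhaustive sweep test.
- The broad-distribution threshold is inclusive at exactly 50%.
- Empty presence sets are usage errors in `dollo_reconstruct()` (a gain
  cannot be placed); units with empty presence are excluded from Venn
  regions and reported via `n_empty`.
- Unknown taxon ids never raise during assignment; structural defects of
  the taxonomy itself (duplicate ids, missing root, broken parent chains)
  always do.
- Annotations mapping above division level (e.g. an "uncultured bacterium"
  attached directly to the domain node) resolve to division `UNASSIGNED`,
  occupy no division column, and are thereby excluded from
  division-occupancy numerators; the denominator is the configured division
  roster either way.
- Ties in gain placement cannot occur: among nodes whose clade contains all
  presence tips, the one with the smallest clade is the unique MRCA.

## Problem sizes used in the shipped checks

The test suite enumerates all 945 labelled rooted shapes on six tips (and
everything smaller) against a brute-force loss-minimisation oracle over all
gain placements, plus 100 random shapes each for 7–10 tips with every
non-empty presence subset; Venn conservation is checked on 1000 random
matrices; noise-free recovery on 20 seeded replicates at the default
generator conditions; the remaining checks use 60–200-family simulations.
These sizes keep a full run to about a minute while covering the space the
algorithms actually branch on.

## Known limitations

- Vetting operates on the evidence column; the package does not run any
  homology search itself, so the quality of `MISANNOTATED`/`CONFIRMED`
  flags is the caller's responsibility.
- Clan-level vetting (a clan spanning domains through single-domain member
  families) is deliberately not performed.
- The Dollo model ignores branch lengths; no likelihood model of gain/loss
  is provided, and none is needed for the parsimony census.
- Discovery dates arrive pre-extracted in the tables; no live database or
  alignment-file parsing is attempted.
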