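---
title: "Consensus and conflict cards: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus and conflict cards: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c2cards)
library(dplyr)
```

## The problem

Several curated pathway databases describe the metabolic network of the same
organism, yet agree on surprisingly few reactions. Part of the disagreement
is real biology (a gene product is or is not linked to a reaction); much of
it is representational — protonation conventions at different pH values,
one-step versus multi-step descriptions of the same conversion, generic
versus specific metabolites, and inconsistent identifier coverage. Before
networks can be reconciled, a curator needs to see, entity by entity, where
the databases agree and where they conflict, and whether a conflict is
biological or representational.

`c2cards` implements that comparison as *consensus-and-conflict cards*: a
card is centered at a gene, an EC number, or a reaction, and lists one row
per (reaction, pathway, database) with the EC numbers, the Boolean gene
association, and the pathway each source database attaches to the
chemistry, together with explicit reaction-similarity annotations. The
three perspectives are complementary: a representational difference (say,
ornithine described with or without its stereo-descriptor) breaks
reaction-level matching but not the gene or EC perspective, so switching
perspective is how such differences are side-stepped.

## Matching model

Records never share a universal key, so identity is built from evidence
cascades, then closed transitively (matches between databases A–B and B–C
imply A–C; classes are connected components of the match graph, with the
lexicographically smallest member key as the deterministic class id).

**Genes** match on Entrez Gene id and/or Ensembl Gene id. Records not
linked to the same genome database can still be bridged by a shared HGNC
symbol; the bridge applies only when the two records share *no* id
namespace, so it never overrides an explicit id disagreement. We evaluate
"shared namespace" over Entrez and Ensembl: UniProt ids are carried for
display but take no part in matching, because they identify proteins
rather than genes and would make an id disagreement ambiguous.

**Metabolites** match by a three-step cascade:

1. If both records carry a KEGG Compound id, that comparison is final —
   agreement matches, disagreement vetoes everything else. Requiring *both*
   ids prevents mere absence from vetoing a match.
2. Otherwise any of KEGG Glycan, ChEBI, PubChem Compound, or CAS present in
   both and equal is a match. An unequal shared id at this step does not
   veto step 3: these namespaces are patchier than KEGG Compound and a
   single stale ChEBI link should not overrule a clean name match.
3. Otherwise names are compared (any primary name or synonym of one record
   against any of the other — the permissive cross-product reading, since
   synonym lists exist precisely to catch naming variation),
   case-insensitively, ignoring spaces and punctuation (every
   non-alphanumeric character). A name match counts only if both records
   carry a parseable chemical formula and the formulas agree on every
   element *except hydrogen* — protonation conventions differ by database,
   so H counts are uninformative.

PubChem Substance ids are depositor-specific and never used as evidence;
`convert_substance_ids()` promotes them to Compound ids when a mapping is
supplied. Identifiers flagged obsolete by `apply_id_updates()` drop out of
every step. InChI and SMILES are carried as display information only.

**EC numbers** are compared literally; the missing component marker `-` is
not a wildcard, because an incomplete number may mean either "not further
classifiable" or "not yet classified" and wildcard matching would
manufacture spurious consensus. A deliberate, user-visible exception is the
EC-card option to ignore the fourth component, which distinguishes
substrate specificities rather than enzyme subclasses.

## The overlap statistic

Each reaction is reduced to a *signature*: the pair of per-side sets of
metabolite equivalence classes, with duplicates collapsed (no
stoichiometry), compartments ignored, and the currency classes (e⁻, H⁺,
H₂O) removed — reactions are inconsistently balanced for those species.
The similarity of two reactions is

$$\mathrm{overlap} = \frac{\#\text{matching metabolites}}
{\max(|R_1|, |R_2|)} \times 100\%$$

computed side-respecting but direction-ignoring: matches are counted in
the parallel (left–left + right–right) and antiparallel (left–right +
right–left) orientations and the better one is used, so two databases
writing the same reversible reaction in opposite directions still score
100. Using the *larger* reaction in the denominator makes the statistic
penalize unmatched participants on either side.

Numerical conventions, fixed once:

* Displayed percentages are floored to integers (a 2-of-3 match displays
  as 66, matching the convention of the original application); internal
  values stay rational. The behaviour at exact halves is unobservable from
  integer output; flooring is the documented choice.
* Two empty signatures (a reaction of only currency species) score 0%,
  not 100% — degenerate reactions must not cluster.
* Exact-match reaction classes are the transitive closure over pairs at
  exactly 100%; partial overlaps are reported but never merged.
* A mismatch-tolerant query ranks reactions by descending percent, then
  (database, reaction id) for a deterministic tie-break; the mismatch
  count is `max(size1, size2) − matches`.

Because matching is compartment-blind, a cytosolic and a mitochondrial
copy of the same chemistry in one database form a single exact-match
class. Each stays a distinct record and a distinct card row (compartments
are displayed); only the similarity layer identifies them.

## Cards

A card's rows cover every database containing the focal entity via its
equivalence class — listing class-wide, not just records sharing the
queried symbol, since the purpose is cross-database comparison. A reaction
in *k* pathways yields *k* rows; missing elements render as "—". Rows are
ordered by database, reaction id, then pathway name. Gene associations
render in the convention `or` = isozymes, parenthesized `and` = complex,
comma = source database without Boolean syntax (unknown semantics). Genes
display as HGNC symbols (multiple symbols joined by `__`), falling back to
Entrez, Ensembl, then the internal id, in that order. Similarity is an
all-pairs table on the gene and EC perspectives and a per-row percentage
against the focus on the reaction perspective. Ambiguous focal-gene
queries (a symbol hitting several classes) are an error listing the
candidates — resolution is explicit, never silent.

## Corpus tools

`dead_end_metabolites()` reports classes that one database only produces
or only consumes. Reversible and unknown-direction reactions count as both
producing and consuming every participant: absence of direction evidence
should not create spurious dead-ends. The currency exclusion applies by
default (water is not an interesting dead-end) and can be switched off;
both modes are provided because either convention is defensible.
`corpus_stats()`, `presence_overview()`, `pathway_membership_tables()` and
`metabolite_fate()` give the per-database content statistics, cross-database
presence matrices, enrichment-ready membership tables, and per-metabolite
reaction lists.

## Interchange format

The package reads one directory per source database of TSV tables
(metabolites, genes, reactions, participants, gene associations, EC links,
pathway links, pathways) rather than the databases' native dumps, which
are versioned, heterogeneous, and partly behind licenses; converting a
native export into the documented TSV schema is the user's (scripted)
responsibility. Identifier status flags (`current` / `transferred` /
`obsolete`) are serialized as optional `*_status` columns. Records are
written in a canonical sort order so exports are byte-stable; update
tables must be pre-flattened (chains are an input error) which makes
`apply_id_updates()` a deterministic, idempotent single pass.

## The synthetic generator

`generate_corpus()` replicates a base network — a linear chain with
cofactor branches and occasional water participants, enough structure to
create fates and dead-ends — across databases and perturbs it with the
conflict classes observed between real databases: granularity splits,
generic-vs-specific and protonation metabolite variants, alternative
substrates, missing genes, isozyme/complex operator divergence, identifier
sparsity, and synonym-only identity. All randomness flows from one seed;
the same configuration is byte-identical across runs. Ground truth
(metabolite, gene, and exact-reaction classes, plus per-perturbation
labels) is emitted alongside, so tests can assert parameter recovery: with
no identity-destroying perturbations the identity and overlap machinery
recovers the truth exactly, and with protonation/granularity perturbations
only, gene-perspective cards still co-locate all variants of a perturbed
reaction.

What the generator does *not* emulate: genome-scale topology, realistic
name/synonym noise beyond the modeled classes, curation lag between
database versions, or licensing-driven content gaps. Passing recovery
tests therefore demonstrates the correctness of the matching and overlap
machinery under controlled conflicts, not real-database accuracy: the
genome-scale content statistics of the historical database releases
cannot be reproduced without those exact downloads.

Default problem sizes used by the test suite — five databases of 30 base
reactions for recovery runs, two databases of five or six reactions for
the randomized oracle sweeps, 10⁴ random signature pairs and 100 random
match graphs for the property suites — were chosen to exercise every code
path with comfortable margins on a single CPU.

## A worked example

```{r}
corpus <- paper_fixtures("arginase")
card <- reaction_card(corpus, "l-arginine + H2O -> ornithine + urea",
                      allowed_mismatches = 1)
tidy(card)[, c("source_db", "reaction", "overlap", "ec", "genes")]
```

The two databases describe ornithine at different levels of detail with
disjoint identifiers, so the query matches one database at 100 and the
other at 66 (2 matching metabolites of 3, after water exclusion, floored)
— and the agreeing EC number and genes on the same card are exactly the
evidence a curator needs to call this a representational, not biological,
difference.

## Known limitations

* Within-database duplicate reactions differing only by compartment merge
  into one exact-match class by design; a compartment-aware mode is out of
  scope.
* Name matching cannot rescue records with unparseable formulas (polymers,
  R-groups); those match only by identifier.
* The ambiguity of a term resolving to several metabolite classes in a
  textual reaction query is resolved by using all of them, which can
  slightly inflate the query signature; assign identifiers in queries for
  exactness.
* Reaction mass-balance checking, compartment-aware matching, fuzzy string
  similarity, and structure-based (InChI/SMILES) matching are deliberately
  not implemented.
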