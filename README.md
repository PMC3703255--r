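# c2cards

Consensus-and-conflict cards for metabolic pathway databases.

The metabolic network of an organism such as *H. sapiens* is described by
several independently curated pathway databases that agree on far fewer
reactions than one would hope. `c2cards` harmonizes such descriptions,
quantifies reaction-level agreement, and assembles concise per-entity
overviews of what the databases do and do not agree on — the working
material of anyone curating or reconciling metabolic reconstructions.

Its core pieces:

* **Cross-database identity.** Genes match on Entrez and/or Ensembl ids
  with an HGNC-symbol bridge when no id namespace is shared; metabolites
  match by a cascade — KEGG Compound id (decisive when both records carry
  one), then KEGG Glycan / ChEBI / PubChem Compound / CAS, then
  normalized-name plus hydrogen-insensitive chemical-formula agreement.
  Pairwise matches are closed transitively into equivalence classes.
  EC numbers compare literally (`-` is never a wildcard).
* **Reaction similarity.** Each reaction becomes a signature: per-side sets
  of metabolite classes with e⁻, H⁺ and H₂O excluded. Two reactions R₁, R₂
  score

  overlap = matching metabolites / max(|R₁|, |R₂|) × 100 %

  side-respecting but direction-ignoring (the better of the parallel and
  antiparallel orientations), displayed floored to an integer.
* **Cards.** `gene_card()`, `ec_card()` and `reaction_card()` build one row
  per (reaction, pathway, database) with EC numbers, Boolean gene
  associations (`or` = isozymes, parenthesized `and` = complex, comma =
  unknown semantics) and pathway context, plus a similarity table —
  all-pairs for the gene/EC perspectives, per-row percent versus the focus
  for the reaction perspective, with mismatch-tolerant queries.
* **Corpus tools.** Dead-end metabolite detection, metabolite fate,
  pathway membership tables, per-database content statistics, and
  cross-database presence overviews; everything exports as TSV/JSON.
* **Generators.** Deterministic synthetic multi-database corpora with
  ground truth covering the classic conflict classes (granularity splits,
  protonation variants, alternative substrates, missing genes, identifier
  sparsity), and six hand-coded mini-corpora of well-known conflict
  scenarios.

## A worked example

```r
library(c2cards)

corpus <- paper_fixtures("arginase")   # two databases, ornithine described
                                       # at different levels of detail
card <- reaction_card(corpus, "l-arginine + H2O -> ornithine + urea",
                      allowed_mismatches = 1)
cat(render_card(card, "tsv"))
```

```
Database	Reaction	Overlap(%)	EC number	Gene(s)	Pathway
Reactome	l-arginine[c] + H2O[c] → l-ornithine[c] + urea[c]	66	3.5.3.1	ARG1	Urea Cycle
Reactome	l-arginine[m] + H2O[m] → l-ornithine[m] + urea[m]	66	3.5.3.1	ARG2	Urea Cycle
Recon1	l-arginine[c] + H2O[c] → ornithine[c] + urea[c]	100	3.5.3.1	ARG1	Urea cycle / amino group metabolism
Recon1	l-arginine[m] + H2O[m] → ornithine[m] + urea[m]	100	3.5.3.1	ARG2	Urea cycle / amino group metabolism
```

One database matches the query exactly (100). The other describes
ornithine as *l-ornithine* under a different identifier, so only 2 of 3
non-currency metabolites match: 2/3 × 100 = 66.67, displayed as 66. The
agreeing EC number (3.5.3.1) and genes (ARG1 cytosolic, ARG2
mitochondrial) on the same card tell the curator this is a
representational difference, not a biological disagreement.

More: `gene_card(paper_fixtures("ctps"), "CTPS")` shows a five-database
gene perspective with a protonation conflict;
`ec_card(paper_fixtures("succinate_coa_ligase"), "6.2.1.4")` shows a
consensus reaction beside a two-database alternative-substrate variant;
`tidy()`, `glance()` and `autoplot()` work on every card. A command-line
interface (`ingest`, `card`, `tools`, `fixtures`) is available via

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "c2cards.R", package = "c2cards"))')" --help
```

See `vignettes/consensus-conflict-cards.Rmd` for the matching model,
numerical conventions, and design rationale.

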