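# coralkey

An R engine for **polytomous taxonomic identification keys** — the
numbered couplet-and-lead tables by which systematists identify
organisms — shipping, fully encoded and machine-validated, a complete
genus-level key to the Recent **azooxanthellate Scleractinia** (the
deep- and cold-water stony corals): 120 genera and 7 additional
subgenera keyed across 111 couplets and 246 leads.

It is written for two audiences. Coral workers get a computable,
checkable version of the comprehensive published key: interactive and
scripted identification, per-taxon path reconstruction, region and
bibliography lookups, and a derived multi-access (polyclave) filter.
Biodiversity informaticians get a general key engine: a typed decision
graph with a JSON document format and published schema, a validator
that reports structural faults as coded findings, exhaustive path
enumeration, DOT/CSV exports, and a seeded random-key generator with
defect injection for property testing.

## The model in brief

A key is a rooted directed graph. Couplet $c$ offers leads
$\ell_{c,a}, \ell_{c,b}, \dots$ ($2 \le k \le 26$; the coral key is
dichotomous at 101 of 111 couplets and polychotomous up to 7 leads);
each lead carries a verbatim character statement and targets either
another couplet or a taxon terminal. An identification is a root-to-
terminal path; its length is counted in decisions. Taxon identity is
the pair (genus, subgenus-or-null), so a variable taxon keyed "(in
part)" at several terminals is one taxon with several paths. The
multi-access view classifies each taxon × (couplet, lead) cell as
**R**equired (every path of the taxon takes that lead), e**X**cluded
(every path passes the couplet via another lead) or **·** inapplicable,
and order-free filtering keeps a taxon while *any* of its variant paths
is compatible with every asserted lead — which makes filtering monotone.
Bracketed geographic ranges are carried as metadata and are never
diagnostic, following the source key's own usage note.

## Worked example

```r
library(coralkey)
key <- load_builtin_key()
key_census(key)
#> <taxon_census>
#>   distinct genera:       120
#>   subgenus pairs:       13 (7 additional subgenera)
#>   distinct taxa:         127
#>   terminal leads:        136
#>   multiply keyed:
#>     Anthemiphyllia x2
#>     Caryophyllia (Caryophyllia) x3
#>     ...
```

The census says the encoded key covers 120 genera, that its 13 named
genus–subgenus pairs amount to 7 subgenera beyond each genus's first,
and that eight variable taxa are keyed at more than one terminal —
*Caryophyllia (Caryophyllia)* at three. A scripted identification of a
solitary, free-living, cylindrical corallum:

```r
run_session(key, c("b", "b", "a", "f"))
#> <key_session> complete in 4 decisions: 1b -> 43b -> 67a -> 68f
#> Stenocyathus
#>   regions: Atl. + IWP + Ant.
#>   figure:  F13
```

Why is *Caryophyllia (Caryophyllia)* keyed three times? Because
corallum attachment and thecal ornament vary within the subgenus, it is
reachable as an attached corallum (couplet 51), as a free conical one
(84), and via the transverse-division route (111):

```r
for (p in paths_to_taxon(key, "Caryophyllia", "Caryophyllia")) print(p)
#> 1b -> 43a -> 44a -> 45b -> 51a -> Caryophyllia (Caryophyllia) (in part)
#> 1b -> 43b -> 67a -> 68a -> 69c -> 83a -> 84b -> Caryophyllia (Caryophyllia) (in part)
#> 1b -> 43b -> 67b -> 102e -> 111a -> Caryophyllia (Caryophyllia) (in part)
```

Multi-access filtering answers "solitary, free, conical — what could it
be?" without forcing the key's question order (24 candidate taxa):

```r
head(filter_taxa(key, c("1" = "b", "43" = "b", "67" = "a", "68" = "a")), 3)
#>                           taxon         genus       subgenus n_compatible_paths
#> 1                   Aulocyathus   Aulocyathus           <NA>                  1
#> 2     Balanophyllia (Eupsammia) Balanophyllia      Eupsammia                  1
#> 3 Caryophyllia (Acanthocyathus)  Caryophyllia Acanthocyathus                  1
```

And the bibliography of previously published species-level keys is
searchable:

```r
species_key_lookup("Deltocyathus")[, c("subject", "scope")]
#>                      subject         scope
#> 8      Deltocyathus, species comprehensive
#> 37 Deltocyathus, W. Atlantic     faunistic
#> 38  Deltocyathus, W. Pacific     faunistic
```

A command-line front end wraps the same functions
(`inst/cli/coralkey`): `validate`, `identify`, `path`, `stats`,
`filter`, `matrix`, `regions`, `bib`, `gen`, `break`, `export`, with
exit codes 0 (success), 1 (validation/data problem), 2 (usage).

```sh
Rscript inst/cli/coralkey path Turbinolia
Rscript inst/cli/coralkey filter --assert 1=b --assert 44=a
```

## Data files

* `inst/extdata/scleractinia_key.json` — the encoded key (single source
  of truth; statements verbatim, metadata structured).
* `inst/extdata/key-document.schema.json` — the document schema.
* `inst/extdata/table1_bibliography.csv` — previously published
  species-level keys (comprehensive and faunistic; tabular keys
  flagged).
* `inst/extdata/regions.csv` — controlled vocabulary of range tokens
  with printed variants.

See the vignette (`vignettes/coralkey-methods.Rmd`) for the full
account of the model, validation codes, path semantics, generator
design and encoding decisions.
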