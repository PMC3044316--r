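# pathwaylint

Rule-based quality control and simulation-readiness complementation for
manually curated biological pathway models.

## The problem

Curated pathway databases are built by hand: curators read a publication and
draw the signalling or metabolic events as a bipartite graph in the
place/transition style — **entities** (proteins, DNA, mRNA, small molecules,
complexes) and **processes** (biological events such as phosphorylation,
binding, translocation), joined by role-typed **connectors** (substrate,
inhibitor, activator, product). Schema-level validation cannot catch the
errors that actually occur during curation: an activator drawn as a second
substrate, a binding event labelled as a dimerization, a transcription
product typed `Protein` instead of `mRNA`, a modified protein without its
feature annotation, or a species with no synthesis or degradation process —
which makes the model unusable for token/ODE simulation even when it is
syntactically valid.

`pathwaylint` implements a registry of **40 event-condition-action rules**
over this data model, organized in three criteria:

1. **Structural correctness** (1 rule). At most one connector may join a
   given process/entity pair — an entity participates in a process with
   exactly one role. Formally, for a process \(x_1\) and entity \(x_2\) the
   condition \(\neg\,[\exists^{\le 1} x_3\,
   \mathrm{CONNECTOR}(x_1,x_3)\wedge \mathrm{ENTITY}(x_3,x_2)]\) raises an
   `INVALID_CONNECTION` warning listing the candidate connectors; the fix
   needs a human.
2. **Biological correctness** (36 rules, one per covered biological event,
   in five groups). Each rule is a declarative constraint with four clause
   kinds, evaluated in order: **cardinality** (e.g. dimerization has exactly
   one substrate), **type** (DNA binding needs a `Dna` substrate and a
   `Complex` product), **property** (the dimerization substrate carries
   stoichiometric coefficient 2, oligomerization 3–20, polymerization ≥ 21;
   a transcription product sits in the nucleoplasm; a phosphorylation
   product carries `FT_Phosphorylated`), and **property relationship**
   (substrate and product of a modification reference the same molecule via
   unification xrefs; a translocation's source and target compartments must
   differ). Violations are reported in a 15-category warning taxonomy.
3. **Systematic correctness** (3 rules, mutating). Species never produced
   by any process gain an unknown-production process (complexes: a binding
   process over their recorded components); every protein, complex, mRNA
   and small molecule without a degradation process gains an
   unknown-degradation process. After this *complementation* the model has
   a source and sink for every species and is ready for simulation.

Events with no distinguishing characteristics (e.g. `ME_Cleavage`,
`ME_UnknownInteraction`) deliberately have no rule; they are accounted
separately, not warned about.

## Worked example

The shipped example model reconstructs a classic curation mistake: in a
Ras → Raf1 activation, activated Ras was drawn as a second *substrate* of
the unknown-activation process rather than as its *activator*.

```r
library(pathwaylint)

m <- read_pathway_model(system.file("extdata", "example_model.json",
                                    package = "pathwaylint"))
report <- validate_pathway(m, criteria = c(1, 2, 3))
report
#> <validation_report> case1_original (criteria 1,2,3)
#>   processes: 1, entities: 3
#>   warnings: 1
#>    - WRONG_CARDINALITY_INPUTPROCESS: 1
#>   complementation (criterion 3) would add:
#>    - C3_STARTING_ENTITY: 2
#>    - C3_STARTING_COMPLEX: 0
#>    - C3_DEGRADING_ENTITY: 3

tidy(report)$message
#> [1] "ME_UnknownActivation requires exactly 1 inputprocess entity but 2 are connected."
```

The one warning is the misassignment: unknown activation takes a single
substrate, and the curator should re-wire Ras through an activator
connector (`make_case_models()$case1_fixed` validates cleanly). The
criterion-3 block says what a complementation pass would add — the two
never-produced proteins need production processes and all three proteins
need degradation processes:

```r
res <- complement_model(m)
glance(res$delta)
#> # A tibble: 1 × 5
#>   n_processes n_connectors n_production n_binding n_degradation
#> 1           5            5            2         0             3
```

`validate_pathway()` never mutates; `complement_model()` returns the
rewritten model together with a replayable delta. Reports have
`tidy()`/`glance()`/`autoplot()` methods, JSON and per-event TSV writers,
and models export to GraphML for visual inspection. A command-line wrapper
lives at `system.file("cli", "pathwaylint", package = "pathwaylint")` with
`validate`, `complement`, `rules` and `fixtures` subcommands (exit codes:
0 clean, 1 warnings, 2 load error).

Synthetic fixtures are first-class: `make_clean_model()` builds models
that provably satisfy every constraint, `inject_violations()` plants an
exact, post-hoc-verified number of violations of chosen categories, and
`make_case_models()` reconstructs two worked correction examples.

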