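# guideqc

Internal-interaction screening and activity quantification for
CRISPR-Cas9 guide RNAs.

A single-guide RNA (sgRNA) is a 20-nt target-specific **spacer** joined to
an invariant **scaffold** that binds Cas9. Guides fail in predictable ways
when the spacer base-pairs with something it shouldn't:

* **internal hairpins** — the spacer folds on itself and sequesters the
  region that must pair with target DNA;
* **backbone interactions** — the spacer pairs with scaffold bases and
  disrupts the stem-loops Cas9 requires.

Both defects are visible from sequence alone using simple base-pairing
rules (canonical G:C and A:U plus the weaker G:U wobble; A:G is a
mismatch), and guides carrying strong predicted stems show sharply reduced
cleavage activity. `guideqc` provides, in tidyverse-native form:

* a **duplex screen** (`screen_guides()`, `classify_guide()`) that
  enumerates maximal intra-spacer and spacer–scaffold stems (default:
  stems of ≥ 4 pairs flag a guide; stems containing a G:U wobble need one
  extra pair) and reports 1-based coordinates, pair composition, and an
  additive stability score (G:C = 3, A:U = 2, G:U = 1);
* a **maximum-pairing fold** (`max_pair_fold()`) — a Nussinov dynamic
  programme with deterministic traceback, verified against exhaustive
  structure enumeration;
* **activity quantification** (`fit_ec50()`, `fraction_cleaved()`,
  `mutagenesis_rate()`) — Hill-sigmoid fits with the exponent fixed at 2
  on two-fold titration series from 600 nM, per-replicate fits summarised
  as mean ± s.e.m., and censoring of estimates above 1,000 nM;
* a **substitution-minimizing PSSM scan** (`scan_pssm()`,
  `pssm_from_consensus()`, `read_pfm()`) over FASTA genomes, both strands,
  with BED export;
* **deterministic synthetic fixtures** (`make_hairpin_spacer()`,
  `make_backbone_spacer()`, `make_clean_spacer()`,
  `simulate_cleavage_curve()`, `plant_genome()`) that attach ground-truth
  manifests, so every module is testable without external data;
* `tidy()` / `glance()` / `augment()` and `autoplot()` methods, and a
  command-line tool (`inst/exec/guideqc`) with `screen`, `fold`,
  `fit-ec50`, `mut-rate`, `scan` and `simulate` subcommands.

No real scaffold sequence ships with the package: the bundled scaffolds
are synthetic stand-ins with the canonical repeat:anti-repeat plus three
stem-loop architecture. Point `read_scaffold()` at your actual backbone
for production use.

## Worked example

```r
library(guideqc)

toy <- read_scaffold(system.file("extdata", "scaffold_toy_synthetic.txt",
                                 package = "guideqc"))
guides <- tibble::tibble(
  id     = c("hp", "bb", "ok"),
  spacer = c(make_hairpin_spacer(seed = 7, scaffold = toy)$spacer,
             make_backbone_spacer(scaffold = toy, seed = 7)$spacer,
             make_clean_spacer(seed = 7, scaffold = toy)$spacer)
)

screen_guides(guides, scaffold = toy)
#> # A tibble: 3 × 8
#>   id    spacer     gg_applied internal_hairpin backbone_interaction clean n_hits
#>   <chr> <chr>      <lgl>      <lgl>            <lgl>                <lgl>  <int>
#> 1 hp    UUGUACUCG… FALSE      TRUE             FALSE                FALSE      1
#> 2 bb    GUGCUUUUG… FALSE      FALSE            TRUE                 FALSE      6
#> 3 ok    CGGUCGGGA… FALSE      FALSE            FALSE                TRUE       0
#> # ℹ 1 more variable: hits <list>
```

The flagged hairpin is a single 4-pair stem at spacer positions 5–8
pairing 14–17 (pairs A:U|G:C|A:U|G:C, stability 10), and the full fold
agrees:

```r
f <- max_pair_fold(guides$spacer[1])
cat(f$sequence, f$dot_bracket, f$score, sep = "\n")
#> UUGUACUCGAAGAGAGUUAU
#> ..((((((.....))).)))
#> 13
```

Quantify activity from a simulated two-replicate titration:

```r
curve <- simulate_cleavage_curve(ec50 = 150, f_max = 0.9, noise_sd = 0.05,
                                 replicates = 2, seed = 42)
tidy(fit_ec50(curve))
#> # A tibble: 1 × 8
#>   guide_id  ec50   sem f_max  hill censored ec50_label n_replicates
#>   <chr>    <dbl> <dbl> <dbl> <dbl> <lgl>    <chr>             <int>
#> 1 sim       142.  9.91 0.917     2 FALSE    141.7                 2
```

The same screen from the shell (the `-gg` flag substitutes the first two
spacer bases with G before screening; `-bb` screens against the extended
backbone):

```sh
$ guideqc screen -f guides.txt --scaffold scaffold_toy_synthetic.txt
hp	UUGUACUCGAAGAGAGUUAU	internal_hairpin
bb	GUGCUUUUGCGCCUUGUUCG	backbone_interaction
```

Clean guides are omitted from the list report; `--out tsv` emits every
hit with coordinates, pairs, and stability instead.

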