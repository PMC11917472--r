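---
title: "Designing pop-in/pop-out genome-editing plasmids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing pop-in/pop-out genome-editing plasmids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipodesign)
```

## The editing strategy

Pop-in/pop-out (PIPO) is the classic two-step, marker-recycling route to
scarless genome editing in *Saccharomyces cerevisiae*. A plasmid carrying a
counterselectable marker (typically *URA3*) is linearized inside a region of
genomic homology and integrates at the target locus by single crossover
(pop-in, selected on media lacking uracil). The integration duplicates the
homologous sequences, leaving two direct repeats flanking the plasmid body.
Spontaneous recombination between either repeat pair excises the plasmid
(pop-out, counterselected on 5-FOA): recombination through one repeat pair
restores the wild-type locus, through the other it leaves the intended edit.

Designing the plasmid insert by hand is tedious because several constraints
interact:

* enough homology on *each side* of the linearization cut for efficient
  integration;
* a controlled **ratio** of "good" (pop-out) to "bad" (pop-in) homology,
  because the longer repeat wins the excision competition more often;
* a linearization site that is *unique* on the final plasmid;
* subcloning sites in the vector's multiple cloning site (MCS) that cut
  neither the insert nor the backbone elsewhere;
* for tagging, in-frame flanking sites around the linker and tag gene that do
  not introduce stop codons; and
* the smallest possible synthesized insert, since synthesis cost scales with
  length.

`pipodesign` automates this design space for three edit geometries: ORF
deletion (`delete`), N-terminal tagging (`tag_n`) and C-terminal tagging
(`tag_c`), and verifies every design by simulating both recombination steps.

## Inputs and the locus convention

The gene of interest is supplied as a single FASTA record laid out as
`flank_len` bp of 5' flanking region (5'FR), the ORF, then `flank_len` bp of
3' flanking region (3'FR); 1,000 bp flanks are the default and match the
per-gene download layout of yeastgenome.org. `parse_goi()` partitions the
sequence positionally; `validate_locus()` then warns (never aborts) if the
ORF does not start with ATG, does not end in a stop codon, has a length that
is not a multiple of 3, or if a user-supplied interval of an overlapping ORF
intersects either flank. Overlaps are taken as explicit intervals rather than
detected by sequence similarity: annotation quality varies, and the user
usually knows the overlapping feature precisely.

All user-facing coordinates in the package are 0-based and half-open
(coordinate 0 is the first base of the 5'FR); this keeps arm-length
arithmetic free of off-by-one ambiguity.

## The design procedure

For each task, two locus regions participate and both role assignments are
enumerated: the region hosting the linearization cut supplies the **pop-in
homology** and the other supplies the **pop-out homology**. For deletion the
pair is {3'FR, 5'FR} (and the reverse); for C-tagging {3'FR, ORF}; for
N-tagging {5'FR, ORF}.

1. **Cut-site search.** Every enzyme in the user's preference-ordered list is
   scanned against the usable interval of each pop-in region, on both strands
   with IUPAC degeneracy expanded. A hit becomes a candidate only if the
   whole recognition site lies inside the region; a candidate is flagged
   inadmissible (with a coded reason) if the enzyme is not unique within the
   region, or if the cut is closer than `min_homology` to either region end.
   For the ORF under C-tagging the usable interval ends at the stop-codon
   boundary, because the native stop is removed from the insert and sequence
   beyond it cannot contribute homology.
2. **Pop-in arm.** The arm runs from the insert junction through the cut plus
   exactly `min_homology` bp beyond it, so both sides of the cut carry at
   least `min_homology` of genomic identity. Its length is therefore
   `d_junction + min_homology`.
3. **Pop-out arm.** The target length is
   `round(r_homo * pop_in_len)` (half away from zero), taken flush against
   the junction of the pop-out region and extending away from it — flush
   placement is what makes the post-integration direct repeats contiguous.
   If the region holds fewer bases, the whole usable region is taken and the
   design is flagged `POP_OUT_TRUNCATED` (a warning, not a rejection).
4. **Insert assembly.** In genomic 5'→3' order:
   * `delete`: 5'FR part + 3'FR part;
   * `tag_c`: ORF part (native stop removed) + site1 + linker + site2 + tag
     gene (terminal stop ensured) + site3 + 3'FR part;
   * `tag_n`: 5'FR part + site1 + tag gene (ATG ensured, terminal stop
     stripped) + site2 + linker + site3 + ORF part from the native ATG.
   Each 6 bp site contributes two codons and the linker and tag gene are
   required to be multiples of 3, so the fusion reading frame is preserved.
   Site 1 in `tag_n` sits 5' of the fusion start (untranslated) and site 3 in
   `tag_c` sits 3' of the fusion stop; both are exempt from the stop-codon
   check, the other sites are checked in their exact frame with flanking
   context.
5. **Tag-flank enzymes** are assigned greedily in file order from the 6 bp
   unambiguous subset of the enzyme list: a site must pass the stop-codon
   check where translated, be absent from the backbone and the draft insert,
   and differ from the linearization enzyme. Because concatenation junctions
   can coincidentally recreate an assigned site, the assembled insert is
   re-scanned and the selection retried without the offender when that
   happens.
6. **MCS pair.** The first pair (file order) of distinct enzymes that each
   cut the backbone exactly once, inside the MCS, never cut the insert, and
   differ from the linearization enzyme is chosen; the pair is oriented so
   the pop-out arm sits next to the lower-coordinate MCS cut (an arbitrary
   but fixed convention for reproducibility). The assembled circular plasmid
   must carry the linearization site and every tag site exactly once; pairs
   violating this are passed over, and if all fail the candidate is rejected
   with the first blocking constraint as its reason.
7. **Optimum.** Among valid candidates the design with the minimal insert
   length (everything that must be synthesized) is flagged optimal; ties
   break by larger achieved homology ratio, then smaller junction distance,
   then enzyme file order. Rejected candidates keep machine-readable reasons
   so a failed gene can be diagnosed from the report alone.

Uniqueness checks on circular molecules (backbone, assembled plasmid) use
circular topology — a site spanning the ligation origin is still a site —
while insert-only checks are linear. The cut coordinate used in all arm
arithmetic is the top-strand cut; for a site found on the minus strand the
mirrored coordinate `start + (site_length - cut_offset)` is used, which is
the physically correct top-strand position for a reverse-oriented
recognition site. Overhang geometry is deliberately ignored: homologous
recombination responds to sequence length around the cut, not to ligation
chemistry.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_homology` | 70 bp | minimum homology on each side of the linearization cut; 70 bp is comfortably above the lower limit of efficient homologous recombination in yeast |
| `r_homo` | 2 | target pop-out/pop-in homology length ratio; ratios ≥ 2 empirically bias the excision step toward the intended edit |
| `flank_len` | 1,000 bp | flank length in the locus input |
| `linker` | (Gly-Gly-Ser)×2, 18 bp | in-frame linker between ORF and tag |
| `min_repeat` | 25 bp | safety-scan threshold in the pop-out simulation; spontaneous recombination below this length is negligible |

`r_homo` trades insert length against pop-out efficiency: doubling it roughly
triples the synthesized arm material for a given cut. The engine accepts any
positive value (0.5–4 is the practically explored range).

## The in-silico verifier

Wet-lab pop-out efficiencies are an empirical quantity that no string
algorithm can predict; what *can* be checked computationally is that every
design is geometrically correct. `linearize_plasmid()` opens the assembled
plasmid at its cut; `simulate_pop_in()` finds the unique genomic position
where both plasmid ends map adjacently and integrates the molecule there,
annotating the two direct-repeat pairs (each maximally extended, so
coincidental boundary matches are part of the repeat); `enumerate_pop_out()`
excises the loop between each repeat pair and classifies every product by
exact string equality against the wild-type locus and the computed intended
edit. A k-mer safety scan additionally reports any *other* direct repeat of
at least `min_repeat` bp flanking the integrated backbone. The round-trip
requirement — exactly one wild-type reversion, exactly one intended edit,
nothing else — is the package's primary acceptance property. Recombination is
modeled as exact-match repeat excision: no mismatch tolerance, no gene
conversion, no outcome probabilities.

## What the synthetic fixtures emulate

`make_fixture_case()` builds a complete study condition: a locus with one
planted linearization site per region (BamHI in the 5'FR, XhoI in the ORF,
EcoRI in the 3'FR) at seeded-random admissible distances, on a background
drawn at GC ≈ 0.40 (yeast-like intergenic composition) with every other
enzyme site scrubbed away; ORFs and the synthetic tag gene are drawn
codon-wise from the 61 sense codons so reading frames are stop-free by
construction; the backbone is a 3 kb scrubbed circle with a three-enzyme MCS
(SacI/KpnI/SalI) and an inert placeholder marker block — marker identity
never enters the design arithmetic. Default fixture ORFs are 300 bp, which
deliberately exercises the pop-out truncation path whenever the ORF supplies
the pop-out homology.

These fixtures give planted, fully controlled geometry; they do **not**
reproduce real genomic repeat structure, biased codon usage, overlapping
features, or the site-density statistics of natural sequence. Passing tests
therefore demonstrate algorithmic correctness of the design rules and the
recombination geometry, not genome-wide designability rates, which depend on
the real sequence inputs.

## Numerical and degenerate-input choices

* `round(r_homo * pop_in_len)` rounds half away from zero to a whole base.
* Achieved ratio is reported as `pop_out_len / pop_in_len`; when not
  truncated it is within `1/pop_in_len` of `r_homo` by construction.
* `min_homology` is met with ≥ (the boundary case is admissible), covered by
  tests on both sides of the boundary.
* Degenerate (IUPAC) recognition patterns are supported throughout the
  scanner; the tag-flank list is restricted to unambiguous 6 bp patterns
  because those sites are written into the synthesized sequence.
* An ORF that does not end in a stop codon is used whole (no trimming) after
  drawing a validation warning; an empty candidate set yields an empty-valid
  design object whose report tallies every rejection reason.
* Problem sizes in the test suite and acceptance script — 60–100 fixture
  loci, 300 bp ORFs, 1,000 bp flanks, a 3 kb backbone — were chosen as the
  smallest sizes that exercise every geometric path (both role assignments,
  truncation, both tagging frames) while keeping the battery comfortably
  fast.

## Known limitations

* No synonymous-codon rewriting of user tag sequences to remove duplicate
  restriction sites: a tag gene that cannot coexist with the constraints is
  the user's to recode.
* No primer design, no Gibson/Golden-Gate planning, no methylation
  sensitivity, and no modeling of Type IIS offset-cutting geometry beyond
  the single top-strand cut coordinate.
* The verifier checks geometry, not efficiency; relative pop-out outcome
  frequencies are outside its scope.
* The batch driver consumes per-gene FASTA files; it does not parse genome
  annotation (GFF) to build loci itself.

## A worked example

```{r example}
case <- make_fixture_case(seed = 1)
design <- pipo_design(case$locus, "tag_c", case$backbone, case$params)
glance(design)
tidy(design)[, c("enzyme", "pop_in_region", "d_junction", "pop_in_len",
                 "pop_out_len", "achieved_ratio", "truncated", "insert_len",
                 "status", "optimal")]
verify_design(design)
```

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(design)
```
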