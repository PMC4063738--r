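# introsig

Population-genetic signatures of recent interspecific introgression, as an
R package plus a reproducible analysis workflow.

## The problem

Hyperpolymorphic loci such as the MHC are usually explained by ancient
balancing selection, with divergent alleles persisting across speciation
events (trans-species polymorphism). An alternative is recent
introgression: a haplotype crosses a species barrier by hybridization and
backcrossing, then rises in frequency. The two hypotheses leave opposite
footprints in the chromosomal neighborhood of the locus. The motivating
case is the MHC *DRB* gene of Alpine ibex (*Capra ibex ibex*), where one of
only two exon-2 alleles is identical to a domestic-goat allele and the
surrounding region shows every hallmark of a recent transfer from goats.

`introsig` implements the full signature battery a population geneticist
would run on such a case:

- **Sequence evidence** — raw p-distance (no substitution model), percent
  identity, amino-acid divergence, cross-species allele sharing on a
  trimmed fragment, and the pairwise homoplasy (Phi) recombination test
  with a site-permutation null.
- **Linkage disequilibrium** — pairwise r² from phased haplotypes
  (counting) or unphased genotypes (EM), LD strength classes and
  strong-LD spans, VIF pruning, and the Hill expected-r² decay fit
  E[r²](C), C = ρ·d, ρ = 4Nₑr.
- **Haplotype structure** — extended haplotype homozygosity (EHH),
  integrated iHH, and bifurcation diagrams around a core SNP, on physical
  distance.
- **Windows** — sliding expected heterozygosity (2p(1−p)) and SNP density
  stratified by carrier class at a diagnostic marker.
- **Trees and networks** — neighbor joining and NeighborNet circular split
  networks (non-negative least-squares split weights) with a quantitative
  carrier-haplotype cluster-cohesion score.
- **Synthetic data** — seeded generators for an introgression scenario
  (multi-deme, single donor haplotype, exponential block erosion around a
  focal SNP) and for structured sequence panels, with full truth objects,
  so every stage is testable end to end without external data.

## Worked example

The `analysis/` directory holds the numbered workflow. Script
`analysis/02_sequence_panel.R` runs the sequence-level analyses on a
synthetic panel with the structure of the sequenced *DRB* study set and
prints:

```
donor goat vs carrier haplotype: 99.8% identity (5/2253 sites differ)
ibex haplotype divergence: 5.1% (116 sites)
ibex panel: 116 informative sites, Phi p = 1
goats panel: 64 informative sites, Phi p = 9.999e-05
```

Read: the goat-type ibex haplotype is nearly identical to a donor-goat
haplotype across 2253 bp of mostly non-coding sequence (5 differences),
while the two ibex haplotypes are 5.1% diverged — far too much for recent
common ancestry within ibex. The ibex panel shows no evidence of
recombination between the two haplotypes (Phi p = 1: they have not
coexisted long), while the goat panel is clearly recombinant
(p < 0.0001), as expected for haplotypes that have recombined freely
within the donor species.

`analysis/03_ld_analysis.R` to `06_networks.R` run the chromosome-scale
battery on the default synthetic scenario (four demes, donor-haplotype
frequencies 0.31/0.20/0.20/0.02, 750 kb expected donor block at 3 Mb on a
6 Mb chromosome):

```
deme1: 18145 pairs | strong/moderate/weak = 102/241/486 | strong span 286 kb | rho = 2.43e-05 /bp
deme4:  9316 pairs | strong/moderate/weak = 0/0/32      | strong span 0 kb   | rho = 7.61e+04 /bp
introgressed allele (37 carriers): iHH left/right/total = 216087/169908/385995 bp
native allele (163 carriers):      iHH left/right/total = 58799/151744/210543 bp
mean He inside the donor-block region: carrier 0.320 vs native 0.119
section 2 (2.2-4.3 Mb) [contains diagnostic SNP]: cohesion = 0.581 (p = 0.005)
section 1 (0.0-2.2 Mb): cohesion = 0.042 (p = 0.035)
```

Every signature points the same way: the high-frequency deme shows a
strong-LD block and slow decay (small ρ) where the low-frequency deme
shows none; the introgressed allele carries the longer conserved
haplotype (higher iHH); carriers are nearly twice as heterozygous as
natives inside the block and indistinguishable outside; and carrier
haplotypes cluster tightly only in the chromosome section containing the
diagnostic SNP.

A single call chains the whole battery on any dataset:

```r
library(introsig)
sim <- generate_introgression_dataset(introgression_scenario(seed = 1))
report <- run_full_analysis(list(genotypes = sim$genotypes,
                                 haplotypes = sim$haplotypes,
                                 diagnostic_marker = "snp_diag",
                                 seed = 1),
                            out_dir = "results/report")
```

which writes per-stage TSV/NEXUS/JSON artifacts plus a machine-readable
`summary.json` with seeds, parameters and a config hash.

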