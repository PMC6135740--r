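# lineageseq

Analysis workflow for single-cell RNA-seq of mouse preimplantation embryos in
which the two blastomeres of the 2-cell embryo are heritably labelled by
stochastic Brainbow recombination (GFP/CFP/RFP/YFP), founding two traceable
cell-division lineages (A and B). The package asks whether those two lineages
are transcriptionally equivalent, and whether unannotated transcript isoforms
carrying transposable-element sequence distinguish them.

It is written for developmental and computational biologists who want the
statistical machinery of this design — not the upstream microscopy,
alignment or assembly — as tested, reusable R functions, exercisable end to
end on a bundled synthetic-data generator with planted ground truth.

## What it computes

**Lineage assignment** (`call_marker`, `assign_lineages_all`, `qc_filter`).
Each blastomere's expressed marker is called from reads mapped to the four
Brainbow marker genes (≥ 10 reads and five-fold dominance); embryos showing
exactly two markers are partitioned into lineages A/B. Cells with fewer than
3 million uniquely mapped read pairs are dropped; genes count as expressed at
FPKM > 1.

**Blastocyst balance** (`balance_classify`, `summarize_balance`). From imaging
counts of marker±cells in the embryonic/abembryonic poles, each embryo's
2×2 table per marker gives an odds ratio

    OR = (pos_emb × neg_abem) / (neg_emb × pos_abem)

(0.5 added to all cells when any is zero). An embryo is *balanced* iff
1/3 < OR < 3 strictly, under three counting methods: one-third inclusion,
one-half inclusion, and a pole-ratio variant that includes every embryo.

**Transcriptome-wide lineage divergence** (`variance_partition_matrix`,
`empirical_R`, `compare_to_beta`). For every gene g, a Gaussian linear model
with embryo as a factor and lineage nested within embryo is decomposed by
sequential sums of squares, and

    r_g = SS_lineage / (SS_lineage + SS_embryo)

Under a balanced Gaussian null with E embryos, r_g ~ Beta(E/2, (E−1)/2). The
empirical distribution R across genes is compared against reference Beta
distributions (KS distance, upper tails P(R ≥ 1−δ), Q-Q points): excess mass
near 1 means some genes vary more between lineages than between embryos.

**Per-gene lineage tests with a shuffled background** (`lineage_tests`,
`shuffle_background`, `compare_distributions`). F = (SS_lineage/d1) /
(SS_res/d_res) per gene, BH q-values, and a permutation background built by
reshuffling lineage labels within each embryo; real and background q
ensembles are compared by a two-sample Kolmogorov–Smirnov test.

**Transposon-related novel isoforms (TRENIs)** (`find_novel`, `call_treni`,
`classify_placement`, `junction_ratio`, `family_enrichment`). Novel isoforms
are transcripts whose intron chain is absent from the reference; a TRENI
carries ≥ 10 bp of exonic RepeatMasker repeat overlap. Each repeat is placed
5′-UTR versus downstream of the host start codon (strand-aware), supported by
its junction ratio (fraction of repeat-overlapping reads spliced into the
nearest reference exon), and summarized by per-family enrichment odds ratios
with Woolf 95% CIs, suppressed below 20 in-TRENI copies.

## Worked example

The analysis is organised as numbered drivers over the package functions:

```sh
Rscript analysis/01_simulate.R 1          # seed 1
Rscript analysis/02_assign_lineages.R
Rscript analysis/03_embryo_balance.R
Rscript analysis/04_variance_partition.R
Rscript analysis/05_lineage_difftest.R 1
Rscript analysis/06_treni.R 1
```

At seed 1 this prints, among other lines:

```
    method n_included n_unbalanced percent_unbalanced
       all         18           12                 66
four_cell: 2000 expressed genes with defined r; mean r = 0.282
  vs Beta(1,3): KS = 0.152; P(R >= 0.9) empirical 0.0090 vs analytic 0.0010
four_cell: 2000 genes tested; real vs shuffled KS = 0.938 (p = 2.2e-16)
  193 real vs 0 shuffled q-values below 0.01
  191/193 q<0.01 hits are planted genes
novel isoforms: 30 called, 30 true, 30 agree
  Alu    a=8   OR=4.57 [1.59, 13.10] p=0.0022
```

Reading: two thirds of simulated blastocysts are pole-biased and the
classifier recovers every generated label; the planted 10% of lineage-shifted
genes lift the upper tail of R above every reference Beta and dominate the
q < 0.01 calls while the within-embryo shuffled background yields none; and
the repeat family the generator enriches (Alu) tops the odds-ratio ranking.
Tables land under `results/`.

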