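# crispacer

CRISPRi guide library design for Cas12a in AT-rich bacterial genomes, plus
scoring of the pooled fitness screens built from such libraries.

Gut commensals such as *Bacteroides* have AT-rich genomes (and even more
AT-rich small-RNA genes, ~35% GC), which starves SpCas9 of its `NGG` PAM but
leaves the Cas12a `TTV` PAM abundant. `crispacer` implements the complete
rule-based design path for dCas12a CRISPRi against a predefined gene set —
typically intergenic small regulatory RNAs (sRNAs), whose short length makes
them invisible to transposon mutagenesis — and the count-based analysis of a
two-condition pooled knockdown screen:

1. **PAM census** — occurrences of the common Cas PAMs (`NGG`, `NNAGAA`,
   `TTV`, `NNNNGATT`, `TTTV`, `NGRR`) per gene and genome-wide, the analysis
   used to choose a nuclease for a given gene set.
2. **Spacer design** — for each gene, candidate protospacers with a `TTV`
   PAM immediately 5′, either strand within the promoter (50 nt upstream of
   the TSS) or the coding strand within the gene body (so the gRNA anneals
   to the template strand); ranked by GC content in [0.35, 0.75], region
   (promoter > 5′ gene half > 3′ half), extended `TTTV` PAM, and TSS
   proximity; three gRNAs per gene by default.
3. **Off-target filter** — discards any spacer with a second genomic site at
   Hamming distance ≤ 2 (i.e. fewer than three mismatches) preceded by a
   `TTV` PAM, on either strand of any replicon, circular origins included.
4. **CRISPR arrays** — three further non-overlapping spacers assembled into
   a single repeat–spacer array transcript; every direct-repeat copy must
   still fold its 3′-terminal processing hairpin in at least one
   near-minimum-free-energy structure (ViennaRNA `RNAsubopt` behind a
   narrow adapter), otherwise spacer triples/orderings are retried.
5. **Cloning output** — gRNA spacers flanked by Gibson homology arms; arrays
   as six oligos (both strands of each repeat–spacer unit) with orthogonal
   4-nt Golden-Gate overhangs, verified by an in-silico reassembly oracle.
6. **Screen scoring** — spacer extraction from amplicon FASTQ between
   constant flanks, exact member counting, per-replicate
   `log2((stress+pc)/(control+pc))` on counts-per-million, per-gene
   averaging over members, a one-sample location test with
   Benjamini–Hochberg FDR, and hit calls at `|mean log2FC| > 0.5` and
   `FDR < 0.05`.
7. **Synthetic fixtures** — deterministic generators for 35%-GC genomes with
   planted sRNA genes and PAM deserts, off-target decoys at chosen Hamming
   distances, and negative-binomial screen counts (variance `μ + φμ²`) with
   planted per-gene effects, so the whole pipeline is testable offline.

## Worked example

```r
library(crispacer)

fx  <- make_genome(n_genes = 8, genome_length = 30000, gc = 0.35, seed = 3)
lib <- design_library(fx$genome, fx$genes)
lib
#> <crispacer_library> 8 genes: 24 gRNAs, 4 arrays, 4 design notes

head(lib$spacer_table[, c("gene_id", "spacer_sequence", "strand",
                          "pam_sequence", "region_kind", "annealing")], 3)
#>   gene_id      spacer_sequence strand pam_sequence region_kind    annealing
#> 1 srna001 AATCGCCATGAAGCAACTCC      -          TTA    promoter promoter_fwd
#> 8 srna001 CGCTACACGGAATACCGTTA      -          TTA transcribed     template
#> 9 srna001 TACCCAGATACGAGAATCTA      -          TTC transcribed     template
```

Every spacer sits 3′ of a `TTA`/`TTC`/`TTG` PAM on its protospacer strand;
gene-body spacers all carry `annealing = "template"`. The four genes without
arrays record why (`insufficient spacers for array`) in `lib$failures`.
Simulating a bile-stress-style screen over this library and scoring it:

```r
sim  <- simulate_screen(lib$manifest, effects = c(srna001 = 1.5), seed = 5)
srna <- aggregate_srna(guide_log2fc(sim$counts), lib$manifest)
srna[order(srna$fdr)[1], c("gene_id", "mean_log2fc", "fdr", "hit")]
#>   gene_id mean_log2fc         fdr  hit
#> 1 srna001    1.080439 0.004403031 TRUE
```

The planted gene is the only hit: mean log2 fold change above the 0.5
cutoff with FDR < 0.05 (positive = members enriched under stress).

A command-line wrapper is installed as `exec/crispacer` with subcommands
`simulate`, `census`, `design`, `count` and `score`; configuration is a YAML
file mirroring `design_config()`, with unknown keys rejected.

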