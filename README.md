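# tfconcord

Screening transcription factors by the rank concordance between their
predicted promoter targets and genome-wide differential expression.

## The problem

After a perturbation experiment (treatment vs control RNA-seq), which
transcription factors are *driving* the observed expression changes? A
factor that represses its targets should leave a signature: the genes
carrying its strongest promoter binding sites should sit low in the
expression ranking, and vice versa for an activator. `tfconcord` turns
that intuition into a calibrated test, for people who have (1) a
differential-expression table, (2) promoter sequences (or a genome plus
GFF3 annotation), and (3) motif models (JASPAR-style position frequency
matrices).

## The method in brief

1. **Scan.** Every promoter (550 bp upstream of the TSS by default) is
   scored on both strands against each motif. A window's **Jindex** is its
   log10 likelihood ratio under motif vs background,
   `J = Σ_p log10(P_motif(b_p|p) / P_bg(b_p))`; sites with `J ≥ 1.0`
   (10× more likely under the motif) are kept. A gene with ≥ 1 site joins
   the factor's target set, ranked `S_i` by its best site.
2. **Rank.** Each gene's differential expression collapses to the signed
   **RDE** score, `RDE = −sgn(log2FC) · 2^|log2FC| · log10(FDR)`; the whole
   transcriptome is ranked `L_i` by descending RDE (no significance
   filter).
3. **Test.** On the shared genes, with `R_i` the list rank paired with set
   rank `i` and pair weights `v_i` from the mixed density of the pooled
   ranks, the weighted Kendall's tau

   `τ_w = 2 / [(Σ v_i)² − Σ v_i²] · Σ_{i>j} v_i v_j sgn(i−j) sgn(R_i−R_j)`

   is standardized by its exact permutation-null standard deviation and
   compared with N(0,1) (two-sided); permutation p-values are available as
   a cross-check. Benjamini–Hochberg adjusts across factors. `τ_w < 0`
   with the factor itself upregulated is the repressor signature.
4. **Profile.** For any hit, a sliding window of `⌈0.02·n⌉` genes along
   the RDE or weighted-rank ordering shows where the factor's Jindex and
   RDE mass sit (`Saverage` / `Laverage` weighted means per window).

A self-contained generator (`simulate_dataset()`) builds motifs, promoters
with planted graded binding sites, and DE tables with a known planted
regulator, so the whole pipeline is testable offline.

## Worked example

The `analysis/` scripts run the full workflow on the default synthetic
design (2,000 genes, 550-bp promoters, one planted repressor "FOCAL" among
24 decoy motifs):

```sh
Rscript analysis/01_simulate.R       # writes results/data/{motifs.pfm,promoters.fa,de_table.tsv}
Rscript analysis/02_scan.R           # Jindex scan -> hits + gene sets
Rscript analysis/03_rank.R           # RDE-ranked gene list
Rscript analysis/04_concordance.R    # the weighted-tau screen
Rscript analysis/05_window_profile.R # sliding-window profile of the top hit
```

Step 2 reports, for this seed (42):

```
426162 binding sites at Jindex >= 1.0 across 25 motifs; 49537 TF-target pairs in 25 gene sets
focal set: 1986 target genes, top Jindex 5.03
```

and step 4 recovers the planted repressor as the only significant factor,
negative τ_w, with the asymptotic and permutation p-values agreeing:

```
25 TFs tested; 1 significant after BH at 0.05
top of the screen:
  tf_id n_overlap   tau_w     ld    p_asym p_perm   q_value direction
1 FOCAL      1986 -0.6212 -21.86 5.70e-106 0.0005 1.42e-104  negative
2  TF12      2000  0.0457   1.85  6.39e-02 0.0640  6.42e-01  positive
...
```

The FOCAL row is what the planted effect size 1.0 at noise SD 1.0
produces; decoys land near τ_w ≈ 0 with p-values matching their
permutation estimates. Step 5 then shows the repressor geometry along the
weighted-rank ordering — the window-median Jindex and RDE are
anticorrelated (Spearman −0.304 across the 1,947 windows): high-Jindex
windows are depleted of upregulated genes.

The same machinery runs on real inputs via `run_pipeline()`:

```r
library(tfconcord)
cfg <- run_config(pfm_file = "motifs.pfm",
                  genome_fasta = "genome.fa", annotation_gff = "genes.gff3",
                  de_table = "limma_results.tsv",   # logFC / adj.P.Val work
                  n_perm = 2000, seed = 1, out_dir = "out")
res <- run_pipeline(cfg)
head(res$results)
```

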