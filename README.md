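# scDuet

Cross-modal contrastive integration of paired single-cell RNA and ATAC
profiles, with transformer-based gene-peak regulatory link inference and
chromatin-potential analysis.

## The problem

Matched multiome assays profile the transcriptome and chromatin
accessibility in the same cell. That pairing is a supervision signal: the
RNA view and the ATAC view of cell *i* should land on the same point of a
shared embedding space. scDuet exploits it three ways:

1. **Integration.** Two asymmetric teacher-student encoder pairs (an
   attention-based teacher over sparse feature tokens, a dense student)
   embed both modalities on a common hypersphere, trained with a
   cross-modal NT-Xent loss. For a mini-batch of N paired cells and
   temperature τ, with `s(u, v) = u·v / (τ‖u‖‖v‖)`,

   ```
   ℓ(m, m⁺) = −log  exp(s_{m,m⁺}) / Σ_{k≠m} [exp(s_{k,m}) + exp(s_{k,m⁺})]
   L = (1/2N) Σ_m [ℓ(m, m⁺) + ℓ(m⁺, m)]
   ```

   where the sum runs over the 2N in-batch points (both modalities)
   excluding only the anchor.

2. **Regulatory links.** A transformer decoder is fine-tuned on top of the
   pretrained token embeddings: gene-token self-attention, then
   cross-attention between genes and peaks with an additive mask that
   closes every gene-peak pair farther apart than 1.2 Mb (or on different
   chromosomes). The per-cell CLS attention rows of the two cross passes,
   contracted over cells, give a G×P global attention matrix that ranks
   candidate gene-peak interactions; ranking quality is evaluated against
   promoter-capture Hi-C style truth sets by AUROC.

3. **Chromatin potential.** An MLP head predicts expression from the ATAC
   student embedding; the residual (predicted − measured) is the
   footprint of chromatin opening ahead of transcription. Residual trends
   along pseudotime are smoothed with a GAM, and fuzzy c-means soft
   clustering of pseudo-bulk accessibility plus matched-background
   co-occurrence tests link temporal peak modules to their genes.

A full integration metric suite is included: FOSCTTM, mean average
precision, cell-type/batch silhouette scores, neighbor consistency,
Seurat alignment score, graph connectivity, and the composite scores
`bio = mean(MAP, ctASW, NC)`, `omics = mean(SAS, bASW, GC)`,
`overall = 0.6·bio + 0.4·omics`.

Everything runs on a compact reverse-mode autodifferentiation engine
written in base R (gradients verified against finite differences in the
test suite), so no deep-learning framework is required.

## Worked example

Desk-scale profile (600 cells, 300 genes, 600 peaks, 3 cell types;
roughly six minutes on one CPU):

```r
library(scDuet)

sim  <- generate_multiome(seed = 7)          # planted links, lag, types
proc <- preprocess_multiome(sim$dataset)     # filter, normalize, HVG, encode

fit  <- train_pretrain(proc, contrastive_config(seed = 7))  # 20 epochs
emb  <- compute_embeddings(proc, fit$params)
print(metric_report(emb, proc$cells$cell_type, proc = proc))
#> metric_report
#>   map                    0.9162
#>   cell_type_asw          0.5984
#>   batch_asw              0.9584
#>   nc                     0.2075
#>   sas                    0.6380
#>   gc                     1.0000
#>   foscttm                0.1361
#>   alignment              0.6561
#>   uniformity             -2.0446
#>   biology_conservation   0.5740
#>   omics_mixing           0.8655
#>   overall                0.6906

mask <- build_attention_mask(proc$genes, proc$peaks)         # 1.2 Mb window
dec  <- train_decoder(fit$params, proc, mask, decoder_config(seed = 7))
att  <- decoder_attention(dec$dparams, dec$enc_params, proc, mask)
tab  <- global_attention_table(att$global, mask)
truth <- paste(sim$truth$planted_links$gene_id, sim$truth$planted_links$peak_id)
lab  <- as.integer(paste(tab$gene_id, tab$peak_id) %in% truth)
cat(sprintf("planted-link AUROC over %d candidate pairs: %.3f\n",
            nrow(tab), auroc(tab$weight, lab)))
#> planted-link AUROC over 600 candidate pairs: 0.814
```

Reading the numbers: FOSCTTM 0.136 means that for a typical cell only
~14% of other-modality cells sit closer than its true cross-modal match
(0.5 would be random; a random-initialization baseline on this data
scores ≈0.48). MAP 0.92 says embedding neighborhoods are nearly pure in
cell type; batch ASW 0.96 and graph connectivity 1.0 say the two
modalities are thoroughly mixed within each type. The AUROC measures how
well the decoder's global attention separates the planted gene-peak
links from same-window decoy pairs.

The single-cell pipeline can also be driven as one call:

```r
state <- run_pipeline(run_config(seed = 7),
                      stages = c("simulate", "preprocess", "pretrain",
                                 "embed", "interact", "predict",
                                 "evaluate", "potential"),
                      out_dir = "scduet_out")
```

which writes the joint embedding, the global attention table, the metric
report and a manifest (configuration hash + seed). A thin command-line
wrapper with `simulate` / `pipeline` / `evaluate` subcommands is installed
at `inst/cli/scduet`.

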