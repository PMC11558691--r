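# phenoGRN

Phenotype-relevant gene regulatory network (GRN) inference from three
channels of summary statistics.

## The problem

Most GRN inference methods ask "which transcription factors (TFs) regulate
which genes?". In many studies — for example human embryonic stem cells
(hESC) differentiating into definitive endoderm (dEN) — the sharper
question is which TF→gene interactions are *relevant to the phenotype*:
TF *i* regulates gene *j*, **and** gene *j*'s expression tracks the
phenotype label. phenoGRN answers this by integrating, for each candidate
pair:

* `P_j` — the gene–phenotype p-value from differential-expression analysis
  (raw, edgeR-style input table);
* `p_ij` — an expression-based TF–gene pseudo p-value (Elastic Net
  selection over the TF panel, then OLS t-tests);
* `q_ij` — a ChIP-seq-based TF–gene pseudo p-value (T-Gene-style
  peak-to-gene distance p-values, consolidated by the minimum over peaks
  and conditions).

A probabilistic graphical model ties them together through latent edge
indicators `T_ij ~ Bernoulli(gamma)` with
`gamma ~ TruncNormal(2/22, 1/22; 0, 4/22)`:

```
P_j  | T_.j    ~  Uniform(0,1)                          if all T_ij = 0
                  Beta(alpha', 1)                       otherwise
p_ij | T_ij=1  ~  Beta(a_H1, 1)
p_ij | T_ij=0  ~  r Beta(a_H1, 1) + (1-r) Beta(a_H0, 1)
```

(and identically for `q_ij` with its own latents;
`r ~ U(0,1)`, `a_H1 ~ U(0,0.5)`, `a_H0 ~ U(0.5,1)` per gene). Posteriors
come from an MCMC sampler written in C++ (Gibbs on indicators, slice
sampling on the bounded latents). Per-gene negative controls
(`ref_PIE`, `ref_Q`, `ref_PIE_Q` — artificial edges with one or both
channels at the null value 1) plus min-max normalization, an elbow rule,
a control filter and a `mu = 2/22` threshold refine the posterior into a
final network with confidence scores in [0, 1]. An AUPRC-ratio harness
(area under the precision–recall curve divided by the random-predictor
baseline) evaluates rankings against ground-truth edge lists, and a
synthetic-evidence generator with planted networks makes the whole
pipeline testable offline.

See `vignettes/phenotype-grn-methods.Rmd` for the model, its assumptions
and every design decision.

## Worked example

```r
library(phenoGRN)

cfg  <- sim_config(seed = 11)              # 22 TFs, 200 genes
net  <- generate_planted_network(cfg)
ev   <- generate_summary_evidence(net, cfg)
fit  <- fit_alpha_prime(ev$genes$p_pheno)
hp   <- model_hyperparams(alpha_prime = fit$alpha_prime)
post <- sample_posterior(add_controls(ev), hp, sampler_config(seed = 5))
grn  <- assemble_grn(post)
res  <- auprc(post[!post$is_control, c("tf", "gene", "score")],
              list(positives = net$edges,
                   universe  = ev$candidates[, c("tf", "gene")]))
c(ratio = res$auprc_ratio, auprc = res$auprc, edges = nrow(grn$edges))
#>   ratio     auprc     edges
#>    5.62     0.629       204
```

The printed numbers (one run at the seeds shown, default sampler) mean:
the posterior ranking of candidate pairs achieves 5.6× the
precision–recall area of a random predictor against the planted edges,
and 204 edges survive the three filters. The ablated variants
(`variant = "RnP"` — expression only; `"CnP"` — ChIP only) reached 4.42
and 4.00 on the same data: integrating both channels wins, mirroring the
published ablation ordering.

The same pipeline runs from the command line:

```sh
Rscript -e 'quit(status = phenoGRN::main())' run-all --out_dir run1 --seed 7
```

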