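# ssnplm

Sequence similarity networks and a lightweight protein language model for
exploring the sequence–function space of enzyme families.

Carbohydrate-active enzyme families such as the GH29 α-L-fucosidases
contain thousands of sequences but only a few dozen functionally
characterised members. A standard way to organise such a family is the
**sequence similarity network (SSN)**: reduce redundancy at 80% identity,
connect representative sequences that share ≥ 40% pairwise alignment
identity, and read the connected components as putative isofunctional
clusters. The catch is that an SSN only speaks about the sequences it was
built from. `ssnplm` closes that gap the way recent family studies do:
it treats SSN cluster membership as a supervised label space and trains a
small BERT-style protein language model — masked-language-model (MLM)
pre-training on the unlabelled corpus, then an attention classification
head over the top-K clusters — so that *any* new sequence can be assigned
to a cluster, with calibrated confidence.

The package is aimed at computational biologists who want this workflow as
composable, testable R functions at desk scale. It provides:

* FASTA I/O with strict normalisation to the 21-letter alphabet
  (`read_fasta()`, `write_fasta()`);
* pairwise alignment identity (BLOSUM62, affine gaps 11/1, global or
  local) and CD-HIT-style greedy redundancy reduction
  (`align_identity()`, `reduce_redundancy()`);
* SSN construction, cluster analysis with convergence ratios, top-K label
  extraction, and Cytoscape-ready GraphML/TSV export (`build_ssn()`,
  `find_clusters()`, `top_k_labels()`, `export_graph()`);
* a transformer encoder with MLM pre-training, an attention + dense
  classification head, one-hot baseline, embeddings and a deterministic
  2-D projection (`pretrain_mlm()`, `build_classifier()`,
  `train_classifier()`, `predict_clusters()`, `one_hot_baseline()`,
  `embed_sequences()`, `project_2d()`);
* evaluation by accuracy and **exponential cross-entropy (ECE)
  perplexity**, `exp(mean(-log p_i(y_i)))`, which runs from 1
  (deterministic correct) to K (uniform over K clusters)
  (`accuracy()`, `ece_perplexity()`);
* a synthetic family-structured corpus generator with closed-form identity
  expectations, so every stage is testable without external databases
  (`generate_families()`);
* a seeded end-to-end pipeline (`run_semisupervised()`) and a thin CLI
  (`inst/cli/ssnplm.R`) with `simulate`, `reduce`, `ssn`, `labels`,
  `pretrain`, `train`, `predict`, `evaluate` and `run-all` subcommands.

Results come back as tibbles; fitted objects have `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

Five synthetic families stand in for a family-level sequence extract; the
pipeline reduces redundancy, builds the network, labels the top clusters,
pre-trains the encoder and trains the classification head:

```r
library(ssnplm)

corpus <- generate_families(n_families = 5, members_per_family = 30,
                            length = 100, p_sub = 0.15, seed = 42)
red <- reduce_redundancy(corpus, threshold = 0.80)
#> Redundancy reduction at identity >= 0.8
#>   150 sequences -> 136 representatives

net <- build_ssn(red$representatives, identity_threshold = 0.40)
#> Sequence similarity network: 136 nodes, 1785 edges (identity >= 0.4 )
part <- find_clusters(net)
#> SSN partition: 5 main clusters, 0 singletons
#>   cluster_id  size n_edges convergence_ratio
#> 1          1    29     406                 1
#> 2          2    28     378                 1
#> ...

labels <- top_k_labels(part, k = 5)
labelled <- red$representatives[red$representatives$id %in% labels$id, ]

enc <- pretrain_mlm(corpus,
  encoder_config(n_blocks = 2, d_model = 64, n_heads = 4,
                 d_feedforward = 256, max_length = 128),
  epochs = 20, seed = 42)

head <- build_classifier(
  classifier_config(n_classes = 5, d_head = 64, n_heads = 4,
                    hidden_dims = c(128, 64)), d_model = 64, seed = 42)
fit <- train_classifier(enc, head, labelled, labels,
                        epochs = 60, lr = 2e-3, seed = 42)
glance(fit)
#>       n accuracy   ece
#> 1    30    0.967  1.23

predict(fit, corpus[1:3, ])[, c("id", "predicted_cluster", "max_probability")]
#>   id           predicted_cluster max_probability
#> 1 fam01_seq001                 4           0.999
#> 2 fam01_seq002                 4           1.000
#> 3 fam01_seq003                 4           1.000
```

Reading the numbers: all five families are recovered as fully connected
clusters (convergence ratio 1, the isofunctional signature); the held-out
accuracy of 0.967 with ECE 1.23 says the head assigns 29 of 30 test
representatives to the right cluster and does so confidently (ECE 1 would
be deterministic correct; uniform guessing over 5 clusters would be 5).
The three query sequences of family `fam01` are confidently placed in
cluster 4 — cluster *ranks* are size-ordered, so family indices and
cluster ids need not coincide.

The convergence ratio, cluster sizes and projections are plottable:

```r
autoplot(part)
plot_projection(project_2d(embed_sequences(enc, red$representatives)), labels)
```

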