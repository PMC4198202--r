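# emocorr

Emotion assortativity in microblog interaction networks.

People connected by social ties tend to share affective states. `emocorr`
is an R package for quantifying that tendency — separately for **anger,
joy, sadness and disgust** — in Twitter/Weibo-style microblog data. It is
aimed at computational social scientists who have (or want to simulate) a
stream of posts with retweet/mention metadata and want to know how strongly
each emotion correlates across social ties, and how that correlation
depends on social distance, tie strength, degree and local clustering.

## What it computes

1. **Distant supervision + classifier.** Tweets carrying emoticons that map
   to exactly one emotion become training labels (no manual annotation).
   A four-class multinomial naive Bayes classifier with Laplace smoothing
   labels everything else:
   `P(w|c) = (n(w,c) + 1) / (N_c + |V|)`, classification is the log-space
   argmax of `log P(c) + Σ log P(w_i|c)`, and incremental count updates are
   exact (`train(A)` then `update(B)` ≡ `train(A ∪ B)`).
2. **Interaction network.** Each retweet or mention is one interaction
   event; users posting more than one tweet every two days are kept, and an
   undirected edge with weight `w(u,v)` = total events survives iff
   `w(u,v) ≥ n`, the tie-strength threshold.
3. **Emotion correlation.** Per-user emotion vectors (class fractions of
   tweets) are compared over all ordered user pairs at shortest-path
   distance `h`: Pearson's `r` or Spearman's `ρ = 1 − 6Σd²/(N(N²−1))` on
   the source/target sequences, with bootstrap mean ± sd (resampling index
   sequences with replacement), a shuffle null, and stratifications by
   degree, clustering-coefficient bin and threshold `n`.
4. **Synthetic corpora with known ground truth.** A generator produces
   Weibo-like corpora (small-world / preferential-attachment / random
   graphs; Dirichlet emotion mixtures assortatively smoothed with a single
   knob `ρ`; emotion-specific vocabularies; 5% emoticon coverage;
   per-edge interaction counts) so the whole pipeline is testable against
   truth.

## Worked example

```r
library(emocorr)

cfg <- generator_config(n_users = 300, seed = 42)   # rho = 0.6 by default
run <- run_pipeline(tempfile(), generator = cfg, n = 3, hops = 1:3,
                    B = 500, seed = 42)

run$manifest[c("n_tweets", "n_labeled", "n_graph_nodes", "n_graph_edges")]
#> $n_tweets        59857
#> $n_labeled        2982
#> $n_graph_nodes     297
#> $n_graph_edges     606

subset(run$estimates, emotion == "anger")
#>  stratum_type stratum_value emotion  method     r_mean      r_std n_pairs
#>           hop             1   anger pearson 0.58011707 0.01984177    1212
#>           hop             2   anger pearson 0.27371495 0.01709852    2860
#>           hop             3   anger pearson 0.09920742 0.01259432    6278
```

Reading this: 59,857 synthetic tweets were generated for 300 users; 2,982
(~5%) carried a usable emoticon and trained the classifier; 297 users
survived the activity and tie-strength (`n = 3`) filters, forming 606
edges. The anger fraction of directly connected users (hop 1, 1,212 ordered
pairs) correlates at `r ≈ 0.58 ± 0.02`; the correlation decays to ~0.27 at
two hops and ~0.10 at three — the generator was configured with
assortativity `ρ = 0.6`, and the pipeline recovers a strong, distance-
decaying signal. On a `ρ = 0` corpus the same estimate fluctuates around 0.

The run directory contains `edge_list.tsv`, per-user `vectors.tsv`,
`correlations.csv` and a `manifest.json` with stage counts; rerunning with
the same seed reproduces every file byte for byte.

## Documentation

The methods vignette (`vignettes/emotion-assortativity.Rmd`) describes the
model, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and known limitations.
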