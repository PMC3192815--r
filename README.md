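# rabclass

Identification and subfamily classification of Rab GTPases.

Rab proteins are small GTPases that regulate vesicular trafficking. Their
subfamily identity is conserved across distant organisms, so annotating a
protein as, say, Rab5 predicts its cell-biological role — but the annotation
problem is genuinely hard: generic GTPase signal makes Rabs look like Ras,
Rho, Ran or Arf proteins, and the subfamilies are mutually very similar.
rabclass is for anyone who needs Rab repertoires at proteome scale — cell
biologists profiling trafficking machinery across genomes, and curators who
want a reproducible first pass before manual refinement.

## Method

The classifier runs in two phases.

**Phase 1 (family):** a sequence is a Rab only if it (1) passes a pooled
G-domain profile filter whose threshold is calibrated to admit every curated
reference GTPase, (2) has its best local-alignment hit (Smith–Waterman,
BLOSUM62, affine gaps 11/1, Karlin–Altschul E ≤ 1e-10 with
E = K·m·n·e^(−λS), λ = 0.267, K = 0.041) among the reference *Rabs* rather
than any non-Rab GTPase, and (3) carries at least one of the five diagnostic
RabF motifs (consensus seeds `igvdf`, `klqiw`, `rfxxxt`, `yyrga`, `lvydit`)
at an exact position p-value ≤ 0.0005. Accepted Rabs get a confidence

    confidence = e_bh · (0.5 + 0.5·min(1, distinct_motifs/2)),
    e_bh = s_rab / (s_rab + s_nonrab)   (bit scores)

— a documented reconstruction of the original (unpublished) evidence fusion.

**Phase 2 (subfamily):** if the identity to the best hit is below 40% the Rab
is called **RabX** (no known subfamily); otherwise each subfamily k is scored
by `0.5·(b_k/Σb + r_k/Σr)` where `b_k` is the best pairwise bit score against
members of k and `r_k` the bit score against the subfamily's
position-specific scoring matrix (E ≤ 1e-5). Scores sum to 1; the argmax is
the call and its score the call confidence. High-confidence mode demotes
calls below a 0.4 cutoff (chosen by ROC analysis; `roc_auc()` reproduces it)
to RabX.

RabX sequences can then be grouped into *hypothetical subfamilies*:
within-genome identity graphs (≥ 70%) partitioned by Markov clustering
(inflation 2.0), merged across genomes by single linkage at > 70%, and
categorized by taxonomic breadth. A seeded generator
(`simulate_benchmark()`) builds complete synthetic reference/query/decoy
fixtures so every stage is testable without downloads.

## Worked example

```r
library(rabclass)
cfg <- pipeline_config()
bench <- simulate_benchmark(n_subfamilies = 4, members_per_subfamily = 3,
                            query_identity_band = c(0.6, 0.8),
                            n_decoys = 8, n_queries = 12, seed = 3)
bench$db
#> Rab reference database
#>   entries:   24 (12 Rab / 12 non-Rab)
#>   subfamilies: 4
#>   G-domain calibration: 53.30 bits

calls <- rabify_batch(bench$queries, bench$db, cfg)
attr(calls, "funnel")
#>   input gdomain  bh_rab     rab   named
#>      20      18      16      12      12

head(calls[, c("query_id", "is_rab", "rejected_stage", "family_confidence",
               "call", "call_confidence", "gate_identity")], 5)
#>   query_id is_rab rejected_stage family_confidence call call_confidence gate_identity
#> 1 query001   TRUE              0                 1 Rab1       0.8312622     0.7783784
#> 2 query002   TRUE              0                 1 Rab1       0.9233226     0.7204301
#> 3 query003   TRUE              0                 1 Rab1       0.7456016     0.7934783
#> 4 query004   TRUE              0                 1 Rab2       0.6972180     0.7967914
#> 5 query005   TRUE              0                 1 Rab2       0.8236041     0.6363636

report <- accuracy_report(calls, bench$truth)
report$family$overall_fraction     # 1  (20/20 family decisions correct)
report$subfamily$overall_fraction  # 1  (12/12 subfamily calls correct)
```

Reading the funnel: of 20 inputs, 18 pass the G-domain filter, 16 survive
best-hit triage, 12 carry a RabF motif and are accepted as Rabs — the 8
decoys were rejected at the stage they were engineered to fail — and all 12
Rabs receive a named subfamily call at the 40% gate.

The same workflow is available from a shell via the bundled CLI
(`inst/scripts/rabclass`): `simulate`, `build-db`, `classify`,
`cluster-rabx`, `evaluate`.

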