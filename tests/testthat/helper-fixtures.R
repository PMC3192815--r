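# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small benchmark used across unit tests: 4 subfamilies x 3 members.
tiny_bench <- function() memo("tiny_bench", function()
  simulate_benchmark(n_subfamilies = 4, members_per_subfamily = 3,
                     query_identity_band = c(0.6, 0.8),
                     n_decoys = 8, n_queries = 12, seed = 3))

# Full study-scale benchmark (acceptance tests): 12 x 8, band 0.55-0.85,
# 80 decoys, 120 queries, seed 7 — plus its normal-mode classification.
bench7 <- function() memo("bench7", function() simulate_benchmark(seed = 7L))

bench7_calls <- function() memo("bench7_calls", function()
  rabify_batch(bench7()$queries, bench7()$db, pipeline_config()))

fasta_file <- function(text) {
  f <- tempfile(fileext = ".faa")
  writeLines(text, f)
  f
}

# A minimal FamilyDecision accepted as Rab, carrying a given best-hit
# identity; used to probe the phase-2 gate in isolation.
accepted_decision <- function(query_id, bh_identity) {
  structure(list(query_id = query_id, is_rab = TRUE, rejected_stage = 0L,
                 evidence = list(gdomain_bits = 50,
                                 bh = data.frame(subject_id = "ref",
                                                 family_label = "Rab",
                                                 subfamily = "Rab1",
                                                 bit_score = 100,
                                                 identity = bh_identity),
                                 best_nonrab_bits = 0,
                                 distinct_motifs = 5L),
                 confidence = 0.95),
            class = "rab_family_decision")
}
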