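test_that("sequence evolution hits its identity target deterministically", {
  cfg <- pipeline_config()
  set.seed(97)
  parent <- seq_records("p", random_peptide(300))
  # target 1: identical copy
  same <- evolve_sequence(parent[1, , drop = FALSE], 1.0, seed = 5, cfg = cfg)
  expect_equal(same$residues, parent$residues)
  # target 0.7 on a 300-mer: realized identity inside the +/- 0.03 band
  ev <- evolve_sequence(parent[1, , drop = FALSE], 0.7, seed = 5, cfg = cfg)
  realized <- local_align(ev, parent[1, , drop = FALSE], cfg)$identity
  expect_gte(realized, 0.67)
  expect_lte(realized, 0.73)
  expect_equal(realized, attr(ev, "realized_identity"))
  # same seed twice: identical output
  ev2 <- evolve_sequence(parent[1, , drop = FALSE], 0.7, seed = 5, cfg = cfg)
  expect_identical(ev$residues, ev2$residues)
  expect_error(evolve_sequence(parent[1, , drop = FALSE], 0, cfg = cfg))
})

test_that("motif protection is honoured and can make targets unreachable", {
  cfg <- pipeline_config()
  set.seed(107)
  parent <- seq_records("p", random_peptide(60))
  prot <- cbind(start = c(1L, 31L), end = c(20L, 50L))  # 40 of 60 protected
  ev <- evolve_sequence(parent[1, , drop = FALSE], 0.8,
                        preserve_motifs = TRUE, protect = prot,
                        seed = 9, cfg = cfg)
  for (k in 1:2) {
    ix <- prot[k, 1]:prot[k, 2]
    expect_identical(substring(ev$residues, prot[k, 1], prot[k, 2]),
                     substring(parent$residues, prot[k, 1], prot[k, 2]))
  }
  expect_error(evolve_sequence(parent[1, , drop = FALSE], 0.2,
                               preserve_motifs = TRUE, protect = prot,
                               seed = 9, cfg = cfg), "unreachable")
})

test_that("benchmark bookkeeping is complete and self-consistent", {
  b <- tiny_bench()
  p <- b$params
  entries <- b$db$entries
  expect_equal(sum(entries$family_label == "Rab"),
               p$n_subfamilies * p$members_per_subfamily)
  expect_equal(length(b$db$subfamily_profiles), p$n_subfamilies)
  expect_length(b$db$rabf_models, 5L)
  expect_equal(nrow(b$queries), p$n_queries + p$n_decoys)
  # truth covers every query; decoys are negatives
  expect_setequal(b$truth$query_id, b$queries$id)
  expect_equal(sum(!b$truth$is_rab), p$n_decoys)
  expect_true(all(b$truth$subfamily[b$truth$is_rab] %in%
                    names(b$db$subfamily_profiles)))
})

test_that("generated queries respect the advertised identity band", {
  b <- tiny_bench()
  band <- b$params$query_identity_band
  qt <- b$truth[b$truth$is_rab, ]
  expect_true(all(qt$realized_identity >= band[1] - 0.03))
  expect_true(all(qt$realized_identity <= band[2] + 0.03))
})

test_that("subfamily ancestors sit below the 40% cross-identity ceiling", {
  b <- tiny_bench()
  cfg <- pipeline_config()
  anc <- b$ancestors
  for (i in seq_len(nrow(anc) - 1)) for (j in (i + 1):nrow(anc)) {
    idy <- local_align(list(id = "i", residues = anc$residues[i]),
                       list(id = "j", residues = anc$residues[j]),
                       cfg)$identity
    expect_lt(ifelse(is.na(idy), 0, idy), 0.40)
  }
})

test_that("stage-3 decoys carry no detectable RabF motif", {
  b <- tiny_bench()
  cfg <- pipeline_config()
  d3 <- b$queries[grepl("^decoy3", b$queries$id), , drop = FALSE]
  expect_gt(nrow(d3), 0L)
  for (i in seq_len(nrow(d3)))
    expect_equal(attr(scan_motifs(d3[i, , drop = FALSE], b$db$rabf_models,
                                  cfg), "distinct_motifs"), 0L)
})

test_that("regeneration with identical parameters is byte-identical", {
  b1 <- simulate_benchmark(n_subfamilies = 2, members_per_subfamily = 2,
                           query_identity_band = c(0.65, 0.8),
                           n_decoys = 2, n_queries = 4, seed = 19)
  b2 <- simulate_benchmark(n_subfamilies = 2, members_per_subfamily = 2,
                           query_identity_band = c(0.65, 0.8),
                           n_decoys = 2, n_queries = 4, seed = 19)
  expect_identical(b1$db$entries, b2$db$entries)
  expect_identical(b1$queries, b2$queries)
  expect_identical(b1$truth, b2$truth)
  d1 <- file.path(tempdir(), "benchA"); d2 <- file.path(tempdir(), "benchB")
  write_benchmark(b1, d1); write_benchmark(b2, d2)
  for (fl in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, fl))),
                     unname(tools::md5sum(file.path(d2, fl))), label = fl)
})
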