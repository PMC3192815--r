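test_that("an exact reference Rab copy is accepted with high confidence", {
  b <- tiny_bench()
  cfg <- pipeline_config()
  q <- b$db$entries[b$db$entries$id == "Rab1_m1", , drop = FALSE]
  dec <- identify_family(q, b$db, cfg)
  expect_true(dec$is_rab)
  expect_equal(dec$rejected_stage, 0L)
  expect_gte(dec$evidence$distinct_motifs, 2L)
  expect_gte(dec$confidence, 0.9)
  sc <- subfamily_scores(q, b$db, cfg)
  expect_equal(sum(sc), 1, tolerance = 1e-9)
  call <- classify_subfamily(q, dec, sc, cfg)
  expect_equal(call$call, "Rab1")
  expect_equal(call$call_confidence, unname(sc["Rab1"]))
})

test_that("a sequence most similar to a non-Rab GTPase is rejected at stage 2", {
  b <- tiny_bench()
  cfg <- pipeline_config()
  q <- b$db$entries[b$db$entries$id == "Ras_m1", , drop = FALSE]
  dec <- identify_family(q, b$db, cfg)
  expect_false(dec$is_rab)
  expect_equal(dec$rejected_stage, 2L)
  expect_equal(dec$evidence$bh$family_label, "nonRab:Ras")
  expect_error(classify_subfamily(q, dec, numeric(0), cfg), "accepted")
})

test_that("a Rab-like sequence without motifs is rejected at stage 3", {
  b <- tiny_bench()
  cfg <- pipeline_config()
  # stage-3 decoys are Rab-derived scaffolds audited to scan motif-free
  d3 <- b$queries[grepl("^decoy3", b$queries$id), , drop = FALSE]
  expect_gt(nrow(d3), 0L)
  seen_stage3 <- FALSE
  for (i in seq_len(nrow(d3))) {
    dec <- identify_family(d3[i, , drop = FALSE], b$db, cfg)
    expect_false(dec$is_rab)
    expect_equal(dec$evidence$distinct_motifs, 0L)
    if (dec$rejected_stage == 3L) {
      seen_stage3 <- TRUE
      expect_equal(dec$evidence$bh$family_label, "Rab")
    }
  }
  expect_true(seen_stage3)
})

test_that("family confidence increases with motifs and Rab/non-Rab margin", {
  # direct probes of the fusion formula's monotonicity via crafted evidence
  fuse <- function(s_rab, s_non, dm) {
    e_bh <- if (s_non > 0) s_rab / (s_rab + s_non) else 1
    e_bh * (0.5 + 0.5 * min(1, dm / 2))
  }
  expect_equal(fuse(100, 0, 2), 1)
  expect_true(fuse(100, 50, 2) < fuse(100, 25, 2))
  expect_true(fuse(100, 50, 1) < fuse(100, 50, 2))
  expect_true(all(vapply(0:5, function(d) fuse(80, 40, d), 1) >= 0))
  expect_true(all(diff(vapply(0:5, function(d) fuse(80, 40, d), 1)) >= 0))
})

test_that("subfamily scores are a normalized, symmetric likelihood vector", {
  b <- tiny_bench()
  cfg <- pipeline_config()
  # symmetric twin database: same member sequences under two subfamily names
  rabs <- b$db$entries[b$db$entries$subfamily %in% "Rab1", , drop = FALSE]
  twin <- rbind(rabs, rabs)
  twin$id <- c(paste0(rabs$id, "_A"), paste0(rabs$id, "_B"))
  twin$subfamily <- rep(c("RabA", "RabB"), each = nrow(rabs))
  class(twin) <- c("rab_reference_entries", "data.frame")
  db2 <- build_reference_db(twin, cfg, dedupe = FALSE)
  q <- seq_records("q", rabs$residues[1])
  sc <- subfamily_scores(q[1, , drop = FALSE], db2, cfg)
  expect_equal(sum(sc), 1, tolerance = 1e-9)
  expect_equal(unname(sc["RabA"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(sc["RabB"]), 0.5, tolerance = 1e-9)
  # random query with no evidence in either channel: empty map
  set.seed(23)
  rq <- seq_records("rq", random_peptide(200))
  expect_length(subfamily_scores(rq[1, , drop = FALSE], b$db, cfg), 0L)
})

test_that("the 40% identity gate and tie-breaking control the call", {
  b <- tiny_bench()
  cfg <- pipeline_config()
  q <- seq_records("q", b$db$entries$residues[1])
  sc <- c(Rab1 = 0.6, Rab2 = 0.3, Rab3 = 0.1)
  # below the gate: RabX regardless of scores
  low <- classify_subfamily(q[1, , drop = FALSE],
                            accepted_decision("q", 0.35), sc, cfg)
  expect_equal(low$call, "RabX")
  # above the gate: named call
  high <- classify_subfamily(q[1, , drop = FALSE],
                             accepted_decision("q", 0.45), sc, cfg)
  expect_equal(high$call, "Rab1")
  # empty scores: RabX even above the gate
  none <- classify_subfamily(q[1, , drop = FALSE],
                             accepted_decision("q", 0.9),
                             setNames(numeric(0), character(0)), cfg)
  expect_equal(none$call, "RabX")
  # exact two-way tie: lexicographically smallest name, flagged ambiguous
  tie <- classify_subfamily(q[1, , drop = FALSE],
                            accepted_decision("q", 0.9),
                            c(Rab2 = 0.5, Rab1 = 0.5), cfg)
  expect_equal(tie$call, "Rab1")
  expect_true(tie$ambiguous)
})

test_that("high-confidence mode only demotes named calls to RabX", {
  cfg <- pipeline_config()
  q <- seq_records("q", "MKACDEFGHIKLMNPQRSTVWY")
  dec <- accepted_decision("q", 0.8)
  sc <- c(Rab1 = 0.35, Rab2 = 0.33, Rab3 = 0.32)
  normal <- classify_subfamily(q[1, , drop = FALSE], dec, sc, cfg, "normal")
  hc <- classify_subfamily(q[1, , drop = FALSE], dec, sc, cfg,
                           "high_confidence")
  expect_equal(normal$call, "Rab1")
  expect_equal(hc$call, "RabX")              # 0.35 < 0.4 cutoff
  expect_equal(hc$scores, sc)                # scores retained
  sc2 <- c(Rab1 = 0.55, Rab2 = 0.45)
  hc2 <- classify_subfamily(q[1, , drop = FALSE], dec, sc2, cfg,
                            "high_confidence")
  expect_equal(hc2$call, "Rab1")             # above the cutoff: kept
})

test_that("batch classification reports the stage funnel and is reproducible", {
  b <- tiny_bench()
  cfg <- pipeline_config()
  calls <- rabify_batch(b$queries, b$db, cfg)
  expect_equal(nrow(calls), nrow(b$queries))
  funnel <- attr(calls, "funnel")
  expect_equal(unname(funnel["input"]), nrow(b$queries))
  expect_true(all(diff(unname(funnel[c("input", "gdomain", "bh_rab",
                                       "rab")])) <= 0))
  stage <- calls$rejected_stage
  expect_equal(unname(funnel["gdomain"]), sum(stage != 1L))
  expect_equal(unname(funnel["rab"]), sum(stage == 0L))
  calls2 <- rabify_batch(b$queries, b$db, cfg)
  expect_identical(calls, calls2)
  # empty batch
  empty <- rabify_batch(b$queries[0, , drop = FALSE], b$db, cfg)
  expect_equal(nrow(empty), 0L)
})
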