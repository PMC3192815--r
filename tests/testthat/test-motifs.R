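test_that("PWM construction counts, pseudocounts and validates", {
  inst <- rep("IGVDF", 5)
  pwm <- build_pwm(inst, "RabF1", pseudocount = 0)
  expect_equal(pwm$width, 5L)
  for (i in 1:5) {
    expect_equal(sum(pwm$matrix[i, ]), 1, tolerance = 1e-9)
    expect_equal(unname(pwm$matrix[i, substr("IGVDF", i, i)]), 1)
  }
  # letter never seen at a column has probability 0 at pseudocount 0
  pwm2 <- build_pwm(c("IGVDF", "LGVDF"), "RabF1", pseudocount = 0)
  expect_equal(unname(pwm2$matrix[1, "A"]), 0)
  # increasing pseudocount moves cells monotonically toward background
  bg <- rep(1 / 20, 20)
  p_small <- build_pwm(inst, "RabF1", pseudocount = 1)$matrix[1, "I"]
  p_large <- build_pwm(inst, "RabF1", pseudocount = 100)$matrix[1, "I"]
  expect_true(p_small > p_large && p_large > 1 / 20)
  expect_error(build_pwm(c("IGVD"), "RabF1"), "length")
  expect_error(build_pwm(inst, "RabF1", pseudocount = -1), ">= 0")
})

test_that("position p-value matches enumeration oracles exactly", {
  # single-column model: +1 bit only for the top letter, uniform background
  m <- matrix(0.9 / 19, nrow = 1, ncol = 20, dimnames = list(NULL, AA))
  m[1, "I"] <- 0.1                      # log2(0.1 / 0.05) = exactly 1 bit
  pwm <- structure(list(motif_id = "one", seed = "i", width = 1L, matrix = m,
                        background = setNames(rep(1 / 20, 20), AA)),
                   class = "rab_pwm")
  expect_equal(position_pvalue(pwm, 1), 1 / 20)
  # threshold at/below the minimum attainable score gives p = 1
  expect_equal(position_pvalue(pwm, -10), 1)

  # width-2 models vs exhaustive enumeration over all 400 dimers,
  # under a background concentrated on a 4-letter sub-alphabet
  bg4 <- setNames(rep(1e-4, 20), AA)
  bg4[c("A", "C", "D", "E")] <- (1 - 16e-4) / 4
  set.seed(21)
  for (rep_i in 1:3) {
    counts <- matrix(stats::rgamma(40, 1), nrow = 2)
    mm <- counts / rowSums(counts)
    colnames(mm) <- AA
    pwm2 <- structure(list(motif_id = "two", seed = "xx", width = 2L,
                           matrix = mm, background = bg4),
                      class = "rab_pwm")
    for (thr in c(-2, 0, 1, 3))
      expect_equal(position_pvalue(pwm2, thr), enumerate_pvalue(pwm2, thr),
                   tolerance = 1e-12)
  }
})

test_that("position p-value is monotone non-increasing in the threshold", {
  db <- tiny_bench()$db
  pwm <- db$rabf_models[[1]]
  thr <- seq(-5, 15, by = 0.5)
  pv <- vapply(thr, function(t) position_pvalue(pwm, t), numeric(1))
  expect_true(all(diff(pv) <= 1e-15))
  expect_true(all(pv >= 0 & pv <= 1))
})

test_that("scanning finds implanted consensus motifs and is deterministic", {
  db <- tiny_bench()$db
  cfg <- pipeline_config()
  set.seed(9)
  seqres <- paste0(random_peptide(60), "IGVDF", random_peptide(60))
  s <- seq_records("probe", seqres)
  hits <- scan_motifs(s[1, , drop = FALSE], db$rabf_models, cfg)
  f1 <- hits[hits$motif_id == "RabF1", ]
  expect_gte(nrow(f1), 1L)
  expect_true(61 %in% f1$position)
  expect_true(all(f1$position_pvalue <= cfg$motif_pvalue))
  hits2 <- scan_motifs(s[1, , drop = FALSE], db$rabf_models, cfg)
  expect_identical(hits, hits2)
  # empty model list -> empty hit table
  expect_equal(nrow(scan_motifs(s[1, , drop = FALSE], list(), cfg)), 0L)
})

test_that("null window calls stay within the p-value calibration bound", {
  # an exact position p-value gate at p calls at most a fraction p of
  # background windows per motif in expectation (union bound over 5 motifs)
  db <- tiny_bench()$db
  cfg <- pipeline_config()
  set.seed(31)
  n_sim <- 100
  calls <- 0
  windows <- 0
  for (i in seq_len(n_sim)) {
    s <- seq_records("null", random_peptide(500))
    h <- scan_motifs(s[1, , drop = FALSE], db$rabf_models, cfg)
    calls <- calls + nrow(h)
    windows <- windows + sum(vapply(db$rabf_models, function(m)
      500 - m$width + 1, numeric(1)))
  }
  rate <- calls / windows
  # per-window call rate at or below the gate (3x slack for MC noise)
  expect_lte(rate, cfg$motif_pvalue * 3)
  # expected calls per 500-mer bounded by p * windows * 5 (union bound)
  expect_lte(calls / n_sim, cfg$motif_pvalue * 496 * 5)
})

test_that("MEME minimal export round-trips the motif models", {
  db <- tiny_bench()$db
  f <- tempfile(fileext = ".meme")
  write_meme_minimal(db$rabf_models, f)
  lines <- readLines(f)
  expect_equal(lines[1], "MEME version 4")
  expect_equal(sum(grepl("^MOTIF ", lines)), 5L)
  back <- rabclass:::read_meme_minimal(f)
  expect_equal(names(back), names(rabf_seeds))
  expect_equal(back$RabF3$width, 6L)
  expect_equal(back$RabF1$matrix, db$rabf_models$RabF1$matrix,
               tolerance = 1e-9)
})
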