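#' Phase 1: is the sequence a Rab?
#'
#' Three short-circuiting stages, strictly in order: (1) the G-domain profile
#' filter; (2) best-hit triage against the curated reference set — the
#' sequence is discarded if it has no reference hit at the family E-value gate
#' or if its best hit is a non-Rab GTPase; (3) the RabF motif scan — with no
#' detectable motif the sequence cannot be a Rab. Survivors get a family
#' confidence in `[0, 1]`:
#' `confidence = e_bh * (0.5 + 0.5 * min(1, distinct_motifs / 2))` with
#' `e_bh = s_rab / (s_rab + s_nonrab)` on bit scores (`e_bh = 1` when no
#' non-Rab hit passes the gate). This fusion is a documented reconstruction,
#' bounded, monotone in each evidence channel; it is not the original
#' (unpublished) combination formula.
#'
#' @param query single-row `rab_seqs` record.
#' @param db `rab_reference_db` from [build_reference_db()].
#' @param cfg [pipeline_config()].
#' @return list of class `rab_family_decision`: query_id, is_rab,
#'   rejected_stage (0 accepted, 1 no G-domain, 2 best hit non-Rab, 3 no RabF
#'   motif), evidence (gdomain_bits, bh, best_nonrab_bits, distinct_motifs,
#'   hits), confidence (NA unless accepted).
#' @export
identify_family <- function(query, db, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (!inherits(db, "rab_reference_db") || is.null(db$gdomain_profile))
    stop("db must be a complete rab_reference_db")
  gd <- gdomain_pass(query, db$gdomain_profile, cfg)
  evid <- list(gdomain_bits = gd$bits, bh = NULL, best_nonrab_bits = 0,
               distinct_motifs = 0L, hits = NULL)
  out <- list(query_id = query$id, is_rab = FALSE, rejected_stage = 1L,
              evidence = evid, confidence = NA_real_)
  class(out) <- "rab_family_decision"
  if (!gd$passes) return(out)

  hits <- best_hits(query, db, cfg)
  out$evidence$hits <- hits
  out$rejected_stage <- 2L
  if (nrow(hits) == 0L) return(out)   # no BH => cannot be most similar to a Rab
  bh <- hits[1, ]
  out$evidence$bh <- bh
  nonrab <- hits[hits$family_label != "Rab", , drop = FALSE]
  out$evidence$best_nonrab_bits <-
    if (nrow(nonrab)) max(nonrab$bit_score) else 0
  if (bh$family_label != "Rab") return(out)

  mh <- scan_motifs(query, db$rabf_models, cfg)
  dm <- attr(mh, "distinct_motifs")
  out$evidence$distinct_motifs <- dm
  out$evidence$motif_hits <- mh
  out$rejected_stage <- 3L
  if (dm == 0L) return(out)

  s_rab <- bh$bit_score
  s_non <- out$evidence$best_nonrab_bits
  e_bh <- if (s_non > 0) s_rab / (s_rab + s_non) else 1
  out$is_rab <- TRUE
  out$rejected_stage <- 0L
  out$confidence <- e_bh * (0.5 + 0.5 * min(1, dm / 2))
  out
}

#' Phase 2: likelihood scores over subfamilies
#'
#' For each subfamily `k`: `b_k` is the best pairwise bit score against
#' members of `k` among hits passing the family E-value gate (0 if none), and
#' `r_k` the profile bit score against the subfamily PSSM (0 if gated at the
#' profile E-value). The score is `0.5 * (b_k / sum(b) + r_k / sum(r))`; if
#' exactly one channel is all-zero its weight shifts entirely to the other;
#' with both channels empty the result is an empty vector. Non-empty score
#' vectors sum to 1.
#'
#' @param query single-row `rab_seqs` record.
#' @param db `rab_reference_db`.
#' @param cfg [pipeline_config()].
#' @param hits optional precomputed [best_hits()] table for this query.
#' @return named numeric vector over subfamilies (possibly empty).
#' @export
subfamily_scores <- function(query, db, cfg = pipeline_config(), hits = NULL) {
  cfg <- as_config(cfg)
  if (is.null(hits)) hits <- best_hits(query, db, cfg)
  subs <- names(db$subfamily_profiles)
  b <- setNames(numeric(length(subs)), subs)
  rab_hits <- hits[hits$family_label == "Rab", , drop = FALSE]
  if (nrow(rab_hits)) {
    agg <- tapply(rab_hits$bit_score, rab_hits$subfamily, max)
    b[names(agg)] <- agg
  }
  r <- vapply(subs, function(k)
    pssm_score(query, db$subfamily_profiles[[k]], cfg)$bit_score, numeric(1))
  sb <- sum(b); sr <- sum(r)
  if (sb == 0 && sr == 0) return(setNames(numeric(0), character(0)))
  if (sb == 0) sc <- r / sr
  else if (sr == 0) sc <- b / sb
  else sc <- 0.5 * (b / sb + r / sr)
  sc
}

#' Phase 2: the subfamily call
#'
#' If the best-hit identity is below the 40% gate, or the score vector is
#' empty, the Rab is assigned to the undetermined subfamily RabX. Otherwise
#' the highest-scoring subfamily is called (exact ties break to the
#' lexicographically smallest name and set the ambiguity flag) with the
#' winning normalized score as call confidence. In high-confidence mode a
#' named call whose confidence falls below `cfg$confidence_cutoff` is demoted
#' to RabX (scores retained) — the mode can only demote, never add, named
#' calls.
#'
#' @param query single-row `rab_seqs` record.
#' @param decision `rab_family_decision` with `is_rab = TRUE`.
#' @param scores vector from [subfamily_scores()].
#' @param cfg [pipeline_config()].
#' @param mode `"normal"` or `"high_confidence"`.
#' @return list of class `rab_subfamily_call`: query_id, scores, call,
#'   call_confidence, mode, gate_identity, ambiguous.
#' @export
classify_subfamily <- function(query, decision, scores,
                               cfg = pipeline_config(),
                               mode = c("normal", "high_confidence")) {
  cfg <- as_config(cfg)
  mode <- match.arg(mode)
  if (!isTRUE(decision$is_rab))
    stop("classify_subfamily requires a sequence accepted as a Rab")
  gate_identity <- if (!is.null(decision$evidence$bh))
    decision$evidence$bh$identity else NA_real_
  out <- list(query_id = query$id, scores = scores, call = "RabX",
              call_confidence = NA_real_, mode = mode,
              gate_identity = gate_identity, ambiguous = FALSE)
  class(out) <- "rab_subfamily_call"
  if (length(scores) == 0L || is.na(gate_identity) ||
      gate_identity < cfg$identity_subfamily_gate)
    return(out)
  top <- max(scores)
  winners <- sort(names(scores)[scores == top])
  out$call <- winners[1]
  out$ambiguous <- length(winners) > 1L
  out$call_confidence <- unname(scores[winners[1]])
  if (mode == "high_confidence" && out$call_confidence < cfg$confidence_cutoff)
    out$call <- "RabX"              # demotion keeps scores and confidence
  out
}

#' Run the full pipeline on a batch of sequences
#'
#' Applies [identify_family()] and, for accepted Rabs, [subfamily_scores()]
#' and [classify_subfamily()] to every query; per-query failures are logged
#' and the batch continues. The per-stage funnel (input, G-domain survivors,
#' best-hit-Rab survivors, motif survivors = Rabs, named subfamily calls) is
#' attached as attribute `funnel`.
#'
#' @param queries `rab_seqs` data frame.
#' @param db `rab_reference_db`.
#' @param cfg [pipeline_config()].
#' @param mode `"normal"` or `"high_confidence"`.
#' @return data.frame (one row per query): query_id, is_rab, rejected_stage,
#'   family_confidence, call, call_confidence, gate_identity, distinct_motifs,
#'   scores_json, mode.
#' @export
rabify_batch <- function(queries, db, cfg = pipeline_config(),
                         mode = c("normal", "high_confidence")) {
  cfg <- as_config(cfg)
  mode <- match.arg(mode)
  rows <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, , drop = FALSE]
    rows[[i]] <- tryCatch({
      dec <- identify_family(q, db, cfg)
      if (dec$is_rab) {
        sc <- subfamily_scores(q, db, cfg, hits = dec$evidence$hits)
        call <- classify_subfamily(q, dec, sc, cfg, mode)
        data.frame(query_id = q$id, is_rab = TRUE, rejected_stage = 0L,
                   family_confidence = dec$confidence,
                   call = call$call,
                   call_confidence = if (is.na(call$call_confidence))
                     NA_real_ else call$call_confidence,
                   gate_identity = call$gate_identity,
                   distinct_motifs = dec$evidence$distinct_motifs,
                   scores_json = as.character(jsonlite::toJSON(
                     as.list(round(sc, 6)), auto_unbox = TRUE)),
                   mode = mode, stringsAsFactors = FALSE)
      } else {
        data.frame(query_id = q$id, is_rab = FALSE,
                   rejected_stage = dec$rejected_stage,
                   family_confidence = NA_real_, call = NA_character_,
                   call_confidence = NA_real_, gate_identity = NA_real_,
                   distinct_motifs = dec$evidence$distinct_motifs,
                   scores_json = "{}", mode = mode, stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      message("query ", q$id, " failed: ", conditionMessage(e))
      data.frame(query_id = q$id, is_rab = NA, rejected_stage = NA_integer_,
                 family_confidence = NA_real_, call = NA_character_,
                 call_confidence = NA_real_, gate_identity = NA_real_,
                 distinct_motifs = NA_integer_, scores_json = "{}",
                 mode = mode, stringsAsFactors = FALSE)
    })
  }
  if (length(rows) == 0L) {
    out <- data.frame(query_id = character(), is_rab = logical(),
                      rejected_stage = integer(),
                      family_confidence = numeric(), call = character(),
                      call_confidence = numeric(), gate_identity = numeric(),
                      distinct_motifs = integer(), scores_json = character(),
                      mode = character(), stringsAsFactors = FALSE)
    attr(out, "funnel") <- c(input = 0L, gdomain = 0L, bh_rab = 0L,
                             rab = 0L, named = 0L)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stage <- out$rejected_stage
  attr(out, "funnel") <- c(
    input = nrow(out),
    gdomain = sum(!is.na(stage) & stage != 1L),
    bh_rab = sum(!is.na(stage) & !stage %in% c(1L, 2L)),
    rab = sum(!is.na(stage) & stage == 0L),
    named = sum(!is.na(out$call) & out$call != "RabX"))
  out
}

#' Write classifier calls as TSV
#' @param calls data.frame from [rabify_batch()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  write_tsv(calls, path)
  invisible(path)
}

read_calls_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
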