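# Seeded synthetic benchmark generator. Emulates the structure of the
# validation problem: a curated reference set of Rab subfamilies plus non-Rab
# GTPase classes, queries at controlled divergence from the reference Rabs,
# and decoys engineered to fail specific pipeline stages. All sequences share
# a G-domain-like core (so the pooled profile filter is meaningful); Rab
# sequences additionally carry the five RabF motifs implanted as noisy
# consensus instances; subfamilies are forced below 40% cross-identity by
# rejection sampling.

sample_background <- function(n, bg) {
  paste(sample(AA20, n, replace = TRUE, prob = bg), collapse = "")
}

# substitution-matrix-conditioned proposal: replace residue a by b != a with
# probability proportional to background[b] * exp(lambda * S(a, b))
substitute_residue <- function(a, cfg) {
  if (!a %in% AA20) return(sample(AA20, 1L))
  s <- blosum62()[a, AA20]
  p <- cfg$background * exp(cfg$ka_lambda * s)
  p[a] <- 0
  sample(AA20, 1L, prob = p / sum(p))
}

mutate_positions <- function(chars, pos, cfg) {
  for (i in pos) chars[i] <- substitute_residue(chars[i], cfg)
  chars
}

protect_mask <- function(L, ranges) {
  m <- logical(L)
  if (!is.null(ranges) && nrow(ranges))
    for (k in seq_len(nrow(ranges))) m[ranges[k, 1]:ranges[k, 2]] <- TRUE
  m
}

#' Evolve a sequence to a target identity
#'
#' Applies point substitutions (drawn from a substitution-matrix-conditioned
#' proposal) until the realized identity to the parent — measured as
#' aligned-column identity of the best local alignment — falls within
#' `target_identity +/- 0.03`. With `preserve_motifs`, the protected ranges
#' (`attr(parent, "motif_ranges")` or the `protect` argument) are never
#' mutated; an unreachable target under that protection is an error.
#'
#' @param parent single-row `rab_seqs` record.
#' @param target_identity fraction in (0, 1].
#' @param preserve_motifs protect motif windows from mutation.
#' @param seed integer seed (same seed, same output); NULL uses the current
#'   RNG stream.
#' @param cfg [pipeline_config()].
#' @param protect optional 2-column matrix of 1-based inclusive ranges.
#' @param new_id id of the evolved record (default `<parent>_ev`).
#' @return single-row `rab_seqs` record; realized identity in attribute
#'   `realized_identity`, protected ranges carried over in `motif_ranges`.
#' @export
evolve_sequence <- function(parent, target_identity, preserve_motifs = FALSE,
                            seed = NULL, cfg = pipeline_config(),
                            protect = NULL, new_id = NULL) {
  cfg <- as_config(cfg)
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must be in (0, 1]")
  run <- function() {
    chars0 <- strsplit(parent$residues, "")[[1]]
    L <- length(chars0)
    if (preserve_motifs && is.null(protect))
      protect <- attr(parent, "motif_ranges")
    mask <- if (preserve_motifs) protect_mask(L, protect) else logical(L)
    mutable <- which(!mask)
    n_mut <- round((1 - target_identity) * L)
    if (n_mut > length(mutable))
      stop("target identity ", target_identity,
           " unreachable: protected motifs cover too much of the sequence")
    chars <- chars0
    mutated <- sample(mutable, n_mut)
    chars <- mutate_positions(chars, mutated, cfg)
    if (target_identity == 1 || n_mut == 0L) {
      out <- parent
      out$id <- if (is.null(new_id)) paste0(parent$id, "_ev") else new_id
      attr(out, "realized_identity") <- 1
      attr(out, "motif_ranges") <- attr(parent, "motif_ranges")
      return(out)
    }
    measure <- function(chars) {
      local_align(list(id = "child", residues = paste(chars, collapse = "")),
                  list(id = "parent", residues = parent$residues),
                  cfg)$identity
    }
    realized <- measure(chars)
    for (iter in seq_len(50L)) {
      if (!is.na(realized) && abs(realized - target_identity) <= 0.03) break
      if (is.na(realized) || realized < target_identity - 0.03) {
        k <- max(1L, ceiling((target_identity -
                                ifelse(is.na(realized), 0, realized)) * L / 2))
        if (length(mutated) == 0L)
          stop("cannot raise identity further toward ", target_identity)
        rev_ix <- sample(mutated, min(k, length(mutated)))
        chars[rev_ix] <- chars0[rev_ix]
        mutated <- setdiff(mutated, rev_ix)
      } else {
        k <- max(1L, ceiling((realized - target_identity) * L / 2))
        fresh <- setdiff(mutable, mutated)
        if (length(fresh) == 0L)
          stop("target identity ", target_identity,
               " unreachable under motif protection")
        new_ix <- sample(fresh, min(k, length(fresh)))
        chars <- mutate_positions(chars, new_ix, cfg)
        mutated <- c(mutated, new_ix)
      }
      realized <- measure(chars)
    }
    if (is.na(realized) || abs(realized - target_identity) > 0.03)
      stop("failed to reach target identity ", target_identity,
           " (realized ", signif(realized, 3), ")")
    out <- parent
    out$id <- if (is.null(new_id)) paste0(parent$id, "_ev") else new_id
    out$residues <- paste(chars, collapse = "")
    attr(out, "realized_identity") <- realized
    attr(out, "motif_ranges") <- attr(parent, "motif_ranges")
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Scaffold layout shared by every generated sequence (lengths in residues).
scaffold_layout <- function() {
  widths <- unname(nchar(rabf_seeds))             # 5 5 6 5 6
  segs <- c(flank1 = 25L, coreA = 40L,
            m1 = widths[1], sp1 = 10L, m2 = widths[2], sp2 = 10L,
            m3 = widths[3], sp3 = 10L, m4 = widths[4], sp4 = 10L,
            m5 = widths[5], coreB = 40L, flank2 = 15L)
  ends <- cumsum(segs)
  starts <- ends - segs + 1L
  motif_ranges <- cbind(start = starts[c("m1", "m2", "m3", "m4", "m5")],
                        end = ends[c("m1", "m2", "m3", "m4", "m5")])
  rownames(motif_ranges) <- names(rabf_seeds)
  list(segs = segs, starts = starts, ends = ends,
       motif_ranges = motif_ranges, length = sum(segs))
}

# Noisy consensus instance of one RabF motif: consensus letters kept with
# probability 1 - noise, otherwise substituted; wildcard positions random.
noisy_motif_instance <- function(seed_str, cfg, noise = 0.15) {
  chars <- toupper(strsplit(seed_str, "")[[1]])
  for (i in seq_along(chars)) {
    if (chars[i] == "X" || runif(1) < noise)
      chars[i] <- if (chars[i] == "X")
        sample(AA20, 1L, prob = cfg$background)
      else substitute_residue(chars[i], cfg)
  }
  paste(chars, collapse = "")
}

build_scaffold <- function(lay, core_a, core_b, cfg, with_motifs,
                           core_identity = 0.5) {
  drift <- function(core) {
    chars <- strsplit(core, "")[[1]]
    n <- round((1 - core_identity) * length(chars))
    paste(mutate_positions(chars, sample(length(chars), n), cfg),
          collapse = "")
  }
  parts <- character(length(lay$segs))
  names(parts) <- names(lay$segs)
  parts["flank1"] <- sample_background(lay$segs["flank1"], cfg$background)
  parts["flank2"] <- sample_background(lay$segs["flank2"], cfg$background)
  for (sp in c("sp1", "sp2", "sp3", "sp4"))
    parts[sp] <- sample_background(lay$segs[sp], cfg$background)
  parts["coreA"] <- drift(core_a)
  parts["coreB"] <- drift(core_b)
  for (i in seq_along(rabf_seeds)) {
    slot <- paste0("m", i)
    parts[slot] <- if (with_motifs)
      noisy_motif_instance(rabf_seeds[[i]], cfg)
    else sample_background(lay$segs[slot], cfg$background)
  }
  paste(parts, collapse = "")
}

extract_ranges <- function(residues, ranges) {
  vapply(seq_len(nrow(ranges)), function(k)
    substr(residues, ranges[k, 1], ranges[k, 2]), character(1))
}

#' Generate a complete synthetic benchmark
#'
#' Builds a reference database of `n_subfamilies` Rab subfamilies (one random
#' ancestor each, all five RabF motifs implanted, cross-subfamily identity
#' forced below 40% by rejection sampling) plus four non-Rab GTPase classes,
#' evolves `members_per_subfamily` members per subfamily, trains the database,
#' and emits query and decoy sets with a complete truth table. Queries are
#' evolved from reference Rab members inside `query_identity_band` with
#' motifs preserved; decoys are split between stage-3 decoys (Rab-derived
#' scaffolds with motif windows randomized, audited to scan to zero motifs)
#' and stage-2 decoys (evolved from non-Rab members). Regeneration with the
#' same parameters is byte-identical.
#'
#' @param n_subfamilies number of Rab subfamilies (>= 2).
#' @param members_per_subfamily reference members per subfamily.
#' @param query_identity_band length-2 numeric, identity band for queries.
#' @param n_decoys total decoys (split evenly between stage-2 and stage-3).
#' @param n_queries number of Rab-derived queries.
#' @param seed integer master seed.
#' @param cfg [pipeline_config()].
#' @return list of class `rab_benchmark`: db, queries (`rab_seqs`, queries
#'   then decoys), truth (query_id, is_rab, subfamily), params, audit
#'   (regeneration counts).
#' @export
simulate_benchmark <- function(n_subfamilies = 12L,
                               members_per_subfamily = 8L,
                               query_identity_band = c(0.55, 0.85),
                               n_decoys = 80L,
                               n_queries = 120L,
                               seed = 7L,
                               cfg = pipeline_config(seed = seed)) {
  cfg <- as_config(cfg)
  if (n_subfamilies < 2L) stop("need at least 2 subfamilies")
  band <- sort(query_identity_band)
  if (band[1] <= 0 || band[2] > 1) stop("invalid query identity band")
  lay <- scaffold_layout()
  audit <- c(ancestor_retries = 0L, member_retries = 0L, decoy_retries = 0L)

  res <- with_seed(seed, {
    core_a <- sample_background(lay$segs["coreA"], cfg$background)
    core_b <- sample_background(lay$segs["coreB"], cfg$background)

    # --- Rab ancestors, rejected until all pairs sit below the 40% gate
    ancestors <- character(0)
    for (k in seq_len(n_subfamilies)) {
      repeat {
        cand <- build_scaffold(lay, core_a, core_b, cfg, with_motifs = TRUE)
        ok <- TRUE
        for (prev in ancestors) {
          idy <- local_align(list(id = "a", residues = cand),
                             list(id = "b", residues = prev), cfg)$identity
          if (!is.na(idy) && idy >= 0.40) { ok <- FALSE; break }
        }
        if (ok) { ancestors <- c(ancestors, cand); break }
        audit["ancestor_retries"] <- audit["ancestor_retries"] + 1L
        if (audit["ancestor_retries"] > 200L)
          stop("could not place ancestors below the 40% cross-identity ceiling")
      }
    }

    # --- non-Rab ancestors (same core, no motifs)
    nonrab_classes <- c("Ras", "Rho", "Ran", "Arf")
    nonrab_anc <- vapply(nonrab_classes, function(cl)
      build_scaffold(lay, core_a, core_b, cfg, with_motifs = FALSE),
      character(1))

    genomes <- paste0("g", 1:4)
    taxa <- c(g1 = "TaxonA", g2 = "TaxonA", g3 = "TaxonB", g4 = "TaxonB")

    # --- reference members
    make_member <- function(parent_res, id, target, motifs = TRUE) {
      parent <- seq_records(paste0(id, "_anc"), parent_res)[1, , drop = FALSE]
      attr(parent, "motif_ranges") <- if (motifs) lay$motif_ranges else NULL
      evolve_sequence(parent, target, preserve_motifs = motifs,
                      cfg = cfg, new_id = id)
    }
    rab_rows <- list(); inst_rows <- list()
    for (k in seq_len(n_subfamilies)) {
      sf <- sprintf("Rab%d", k)
      for (j in seq_len(members_per_subfamily)) {
        id <- sprintf("%s_m%d", sf, j)
        target <- runif(1, 0.85, 0.95)
        mem <- make_member(ancestors[k], id, target)
        g <- genomes[(j - 1L) %% 4L + 1L]
        rab_rows[[length(rab_rows) + 1L]] <- data.frame(
          id = id, residues = mem$residues, genome = g, taxon = taxa[[g]],
          family_label = "Rab", subfamily = sf, stringsAsFactors = FALSE)
        inst_rows[[length(inst_rows) + 1L]] <- data.frame(
          motif_id = names(rabf_seeds),
          instance = extract_ranges(mem$residues, lay$motif_ranges),
          stringsAsFactors = FALSE)
      }
    }
    nonrab_rows <- list()
    for (cl in nonrab_classes) {
      for (j in 1:3) {
        id <- sprintf("%s_m%d", cl, j)
        mem <- make_member(nonrab_anc[[cl]], id, runif(1, 0.85, 0.95),
                           motifs = FALSE)
        g <- genomes[(j - 1L) %% 4L + 1L]
        nonrab_rows[[length(nonrab_rows) + 1L]] <- data.frame(
          id = id, residues = mem$residues, genome = g, taxon = taxa[[g]],
          family_label = paste0("nonRab:", cl), subfamily = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    entries <- do.call(rbind, c(rab_rows, nonrab_rows))
    class(entries) <- c("rab_reference_entries", "data.frame")
    instances <- do.call(rbind, inst_rows)

    db <- build_reference_db(entries, cfg, motif_instances = instances,
                             dedupe = FALSE)

    # --- queries: evolved from reference Rab members inside the band
    rab_ids <- entries$id[entries$family_label == "Rab"]
    queries <- list(); truth <- list()
    for (i in seq_len(n_queries)) {
      src_id <- rab_ids[(i - 1L) %% length(rab_ids) + 1L]
      src <- entries[entries$id == src_id, , drop = FALSE]
      parent <- seq_records(src$id, src$residues)[1, , drop = FALSE]
      attr(parent, "motif_ranges") <- lay$motif_ranges
      target <- runif(1, band[1], band[2])
      q <- evolve_sequence(parent, target, preserve_motifs = TRUE, cfg = cfg,
                           new_id = sprintf("query%03d", i))
      queries[[i]] <- data.frame(id = q$id, residues = q$residues,
                                 genome = sprintf("qg%d", (i - 1L) %% 6L + 1L),
                                 taxon = taxa[[src$genome]],
                                 stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(query_id = q$id, is_rab = TRUE,
                               subfamily = src$subfamily,
                               source = src_id, target_identity = target,
                               realized_identity = attr(q, "realized_identity"),
                               stringsAsFactors = FALSE)
    }

    # --- decoys
    n_stage3 <- n_decoys %/% 2L
    n_stage2 <- n_decoys - n_stage3
    decoys <- list(); dtruth <- list()
    for (i in seq_len(n_stage3)) {
      src_id <- rab_ids[(i * 3L - 2L) %% length(rab_ids) + 1L]
      src <- entries[entries$id == src_id, , drop = FALSE]
      parent <- seq_records(src$id, src$residues)[1, , drop = FALSE]
      repeat {
        d <- evolve_sequence(parent, runif(1, 0.8, 0.9),
                             preserve_motifs = FALSE, cfg = cfg,
                             new_id = sprintf("decoy3_%03d", i))
        chars <- strsplit(d$residues, "")[[1]]
        for (k in seq_len(nrow(lay$motif_ranges))) {
          ix <- lay$motif_ranges[k, 1]:lay$motif_ranges[k, 2]
          chars[ix] <- strsplit(sample_background(length(ix), cfg$background),
                                "")[[1]]
        }
        d$residues <- paste(chars, collapse = "")
        hits <- scan_motifs(d, db$rabf_models, cfg)
        if (attr(hits, "distinct_motifs") == 0L) break
        audit["decoy_retries"] <- audit["decoy_retries"] + 1L
        if (audit["decoy_retries"] > 200L)
          stop("could not generate motif-free stage-3 decoys")
      }
      decoys[[length(decoys) + 1L]] <- data.frame(
        id = d$id, residues = d$residues, genome = "dg1", taxon = "TaxonA",
        stringsAsFactors = FALSE)
      dtruth[[length(dtruth) + 1L]] <- data.frame(
        query_id = d$id, is_rab = FALSE, subfamily = NA_character_,
        source = src_id, target_identity = NA_real_,
        realized_identity = NA_real_, stringsAsFactors = FALSE)
    }
    nonrab_ids <- entries$id[entries$family_label != "Rab"]
    for (i in seq_len(n_stage2)) {
      src_id <- nonrab_ids[(i - 1L) %% length(nonrab_ids) + 1L]
      src <- entries[entries$id == src_id, , drop = FALSE]
      parent <- seq_records(src$id, src$residues)[1, , drop = FALSE]
      d <- evolve_sequence(parent, runif(1, 0.8, 0.9),
                           preserve_motifs = FALSE, cfg = cfg,
                           new_id = sprintf("decoy2_%03d", i))
      decoys[[length(decoys) + 1L]] <- data.frame(
        id = d$id, residues = d$residues, genome = "dg1", taxon = "TaxonA",
        stringsAsFactors = FALSE)
      dtruth[[length(dtruth) + 1L]] <- data.frame(
        query_id = d$id, is_rab = FALSE, subfamily = NA_character_,
        source = src_id, target_identity = NA_real_,
        realized_identity = NA_real_, stringsAsFactors = FALSE)
    }

    qdf <- do.call(rbind, c(queries, decoys))
    class(qdf) <- c("rab_seqs", "data.frame")
    list(db = db, queries = qdf,
         truth = do.call(rbind, c(truth, dtruth)),
         ancestors = data.frame(subfamily = sprintf("Rab%d",
                                                    seq_len(n_subfamilies)),
                                residues = ancestors,
                                stringsAsFactors = FALSE))
  })

  out <- list(db = res$db, queries = res$queries, truth = res$truth,
              ancestors = res$ancestors,
              params = list(n_subfamilies = n_subfamilies,
                            members_per_subfamily = members_per_subfamily,
                            query_identity_band = band,
                            n_decoys = n_decoys, n_queries = n_queries,
                            seed = seed),
              audit = audit)
  class(out) <- "rab_benchmark"
  out
}

#' Write a benchmark fixture to disk
#'
#' Emits `reference.faa`, `reference_manifest.tsv`, `motif_instances.tsv`
#' (regenerated from the reference members), `queries.faa` and `truth.tsv` —
#' a complete on-disk fixture consumable by the CLI.
#'
#' @param bench `rab_benchmark` from [simulate_benchmark()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bench$db$entries, file.path(dir, "reference.faa"))
  write_reference_manifest(bench$db$entries,
                           file.path(dir, "reference_manifest.tsv"))
  lay <- scaffold_layout()
  rabs <- bench$db$entries[bench$db$entries$family_label == "Rab", ]
  inst <- do.call(rbind, lapply(seq_len(nrow(rabs)), function(i)
    data.frame(motif_id = names(rabf_seeds),
               instance = extract_ranges(rabs$residues[i], lay$motif_ranges),
               stringsAsFactors = FALSE)))
  write_tsv(inst, file.path(dir, "motif_instances.tsv"))
  write_fasta(bench$queries, file.path(dir, "queries.faa"))
  tr <- bench$truth
  tr$is_rab <- ifelse(tr$is_rab, "TRUE", "FALSE")
  write_tsv(tr, file.path(dir, "truth.tsv"))
  meta <- bench$queries[, c("id", "genome", "taxon")]
  names(meta)[1] <- "query_id"
  write_tsv(meta, file.path(dir, "query_meta.tsv"))
  invisible(dir)
}
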