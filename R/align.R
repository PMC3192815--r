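#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for a raw local-alignment score `S`,
#' query length `m` and search-space residue count `n`, using the gapped
#' BLOSUM62(11,1) parameters from the configuration. Strictly decreasing in
#' `S`, linear in `m` and `n`.
#'
#' @param raw_score raw alignment score.
#' @param m query length (>= 1).
#' @param n database / subject residue count (>= 1).
#' @param cfg [pipeline_config()].
#' @return E-value (numeric).
#' @export
#' @examples
#' karlin_altschul_evalue(100, 250, 250)  # ~6.4e-9
karlin_altschul_evalue <- function(raw_score, m, n, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (any(m < 1) || any(n < 1)) stop("m and n must be >= 1")
  cfg$ka_K * m * n * exp(-cfg$ka_lambda * raw_score)
}

bit_score <- function(raw_score, cfg) {
  (cfg$ka_lambda * raw_score - log(cfg$ka_K)) / log(2)
}

aa_set <- function(x) Biostrings::AAStringSet(x)

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps (BLOSUM62; a gap of length k costs
#' `gap_open + k * gap_extend`), computed by [Biostrings::pairwiseAlignment()].
#' Identity is measured over the aligned columns of the best local alignment
#' (gap columns count in the denominator). If no positive-scoring alignment
#' exists the raw score is 0 and no alignment is reported.
#'
#' @param a,b single-row `rab_seqs` records (or lists with id/residues).
#' @param cfg [pipeline_config()].
#' @param n search-space residue count for the E-value; defaults to the
#'   subject length.
#' @return list of class `rab_alignment` with query_id, subject_id, raw_score,
#'   bit_score, evalue, identity, aligned_columns, query_span, subject_span.
#' @export
local_align <- function(a, b, cfg = pipeline_config(), n = NULL) {
  cfg <- as_config(cfg)
  if (!nzchar(a$residues) || !nzchar(b$residues))
    stop("local_align requires non-empty sequences")
  pa <- Biostrings::pairwiseAlignment(
    aa_set(a$residues), Biostrings::AAString(b$residues), type = "local",
    substitutionMatrix = blosum62(),
    gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
  raw <- Biostrings::score(pa)
  if (is.null(n)) n <- nchar(b$residues)
  if (raw <= 0) {
    out <- list(query_id = a$id, subject_id = b$id, raw_score = 0,
                bit_score = NA_real_, evalue = Inf, identity = NA_real_,
                aligned_columns = 0L, query_span = c(NA_integer_, NA_integer_),
                subject_span = c(NA_integer_, NA_integer_))
  } else {
    cols <- Biostrings::nchar(pa)
    out <- list(
      query_id = a$id, subject_id = b$id, raw_score = raw,
      bit_score = bit_score(raw, cfg),
      evalue = karlin_altschul_evalue(raw, nchar(a$residues), n, cfg),
      identity = Biostrings::nmatch(pa) / cols,
      aligned_columns = cols,
      query_span = c(BiocGenerics::start(Biostrings::pattern(pa)),
                     BiocGenerics::end(Biostrings::pattern(pa))),
      subject_span = c(BiocGenerics::start(Biostrings::subject(pa)),
                       BiocGenerics::end(Biostrings::subject(pa))))
  }
  class(out) <- "rab_alignment"
  out
}

#' Search a query against the reference set
#'
#' Aligns the query to every reference entry, keeps hits with
#' `evalue <= cfg$evalue_family` (E-values use the total residue count of the
#' reference set as search space `n`), and ranks by ascending E-value, ties by
#' descending bit score then lexicographic subject id. The first row is the
#' best hit (BH).
#'
#' @param query single-row `rab_seqs` record.
#' @param db a `rab_reference_db` (see [build_reference_db()]) or a reference
#'   entries data frame.
#' @param cfg [pipeline_config()].
#' @return data.frame of hits: subject_id, family_label, subfamily, raw_score,
#'   bit_score, evalue, identity, aligned_columns, qstart, qend, sstart, send.
#' @export
best_hits <- function(query, db, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  entries <- if (inherits(db, "rab_reference_db")) db$entries else db
  if (nrow(entries) == 0L) stop("reference set is empty")
  pa <- Biostrings::pairwiseAlignment(
    aa_set(entries$residues), Biostrings::AAString(query$residues),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
  raw <- Biostrings::score(pa)
  n_db <- sum(nchar(entries$residues))
  ev <- ifelse(raw > 0,
               karlin_altschul_evalue(raw, nchar(query$residues), n_db, cfg),
               Inf)
  cols <- Biostrings::nchar(pa)
  hits <- data.frame(
    subject_id = entries$id,
    family_label = entries$family_label,
    subfamily = entries$subfamily,
    raw_score = raw,
    bit_score = bit_score(raw, cfg),
    evalue = ev,
    identity = ifelse(cols > 0, Biostrings::nmatch(pa) / pmax(cols, 1L), NA_real_),
    aligned_columns = cols,
    qstart = BiocGenerics::start(Biostrings::subject(pa)),
    qend = BiocGenerics::end(Biostrings::subject(pa)),
    sstart = BiocGenerics::start(Biostrings::pattern(pa)),
    send = BiocGenerics::end(Biostrings::pattern(pa)),
    stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= cfg$evalue_family, , drop = FALSE]
  hits <- hits[order(hits$evalue, -hits$bit_score, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Export a hit table as TSV
#' @param hits data.frame from [best_hits()] (query column added).
#' @param query_id query identifier written into the first column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, query_id, path) {
  out <- cbind(query = rep(query_id, nrow(hits)),
               hits[, c("subject_id", "bit_score", "evalue", "identity",
                        "qstart", "qend", "sstart", "send")])
  names(out)[2] <- "subject"
  write_tsv(out, path)
  invisible(path)
}
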