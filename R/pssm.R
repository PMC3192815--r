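# Per-subfamily position-specific scoring matrices and the pooled G-domain
# profile. One transparent construction replaces the external profile tools:
# members are anchored to the first member (guide) by global pairwise
# alignment, columns with > 50% gaps are dropped, identical member sequences
# are collapsed, per-column probabilities use Henikoff position-based weights
# plus background pseudocounts, and scores are log-odds against background
# rescaled to the integer raw-score grid of the pairwise aligner
# (bits * ln2 / lambda), so that bit scores and E-values share one formula.

# Align members to the guide (first member): returns a character matrix of
# residues ("-" = deletion relative to guide), one column per guide position.
anchor_alignment <- function(members, cfg) {
  guide <- members$residues[1]
  Lg <- nchar(guide)
  rows <- matrix("-", nrow = nrow(members), ncol = Lg)
  rows[1, ] <- strsplit(guide, "")[[1]]
  if (nrow(members) > 1L) {
    pa <- Biostrings::pairwiseAlignment(
      aa_set(members$residues[-1]), Biostrings::AAString(guide),
      type = "global-local", substitutionMatrix = blosum62(),
      gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
    al_p <- as.character(Biostrings::alignedPattern(pa))
    al_s <- as.character(Biostrings::alignedSubject(pa))
    st <- BiocGenerics::start(Biostrings::subject(pa))
    for (k in seq_along(al_p)) {
      pc <- strsplit(al_p[k], "")[[1]]
      sc <- strsplit(al_s[k], "")[[1]]
      gpos <- st[k] - 1L            # guide position before current column
      for (j in seq_along(sc)) {
        if (sc[j] != "-") {
          gpos <- gpos + 1L
          if (gpos <= Lg && pc[j] != "-") rows[k + 1L, gpos] <- pc[j]
        }
        # insertions relative to the guide are dropped
      }
    }
  }
  rows
}

# Henikoff position-based sequence weights for a residue matrix ("-" ignored).
henikoff_weights <- function(rows) {
  n <- nrow(rows)
  if (n == 1L) return(1)
  w <- numeric(n)
  used <- 0L
  for (j in seq_len(ncol(rows))) {
    col <- rows[, j]
    ok <- col != "-"
    if (!any(ok)) next
    tab <- table(col[ok])
    r <- length(tab)
    if (r == 0L) next
    contrib <- ifelse(ok, 1 / (r * as.numeric(tab[col])), 0)
    w <- w + contrib
    used <- used + 1L
  }
  if (used == 0L || sum(w) == 0) return(rep(1 / n, n))
  w / sum(w)
}

#' Build a position-specific scoring matrix from member sequences
#'
#' Members are anchored to the first member by global pairwise alignment
#' (input order is the guide order; profile quality, not alignment optimality,
#' is the contract), columns with more than 50% gaps are dropped, duplicate
#' member sequences are collapsed, and per-column probabilities combine
#' Henikoff position-based weights with `pseudocount_weight` background
#' pseudocounts. Scores are log-odds versus background on the raw-score grid
#' shared with the pairwise aligner.
#'
#' @param members `rab_seqs` data frame (>= 1 row).
#' @param profile_id subfamily name, or `"GDOMAIN"` for the pooled profile.
#' @param cfg [pipeline_config()]; supplies background and gap costs.
#' @param pseudocount_weight total background pseudocount per column
#'   (default 5).
#' @return list of class `rab_pssm`: profile_id, length, scores (length x 20
#'   integer matrix), probs, source_count, calibration (NA until calibrated).
#' @export
build_pssm <- function(members, profile_id, cfg = pipeline_config(),
                       pseudocount_weight = 5) {
  cfg <- as_config(cfg)
  if (nrow(members) == 0L) stop("cannot build a profile from zero members")
  members <- members[!duplicated(members$residues), , drop = FALSE]
  rows <- anchor_alignment(members, cfg)
  gap_frac <- colMeans(rows == "-")
  rows <- rows[, gap_frac <= 0.5, drop = FALSE]
  if (ncol(rows) == 0L) stop("profile ", profile_id, ": no columns retained")
  w <- henikoff_weights(rows)
  bg <- cfg$background
  L <- ncol(rows)
  probs <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    col <- rows[, j]
    ok <- col != "-" & col != "X"
    cw <- numeric(20L); names(cw) <- AA20
    if (any(ok)) {
      agg <- tapply(w[ok], factor(col[ok], levels = AA20), sum)
      agg[is.na(agg)] <- 0
      cw <- as.numeric(agg)
    }
    tot <- sum(cw)
    p <- (cw + pseudocount_weight * bg) / (tot + pseudocount_weight)
    probs[j, ] <- p / sum(p)
  }
  # floor keeps log-odds finite even at pseudocount 0 (never-seen letters)
  lo_bits <- log2(pmax(probs, 1e-6) /
                    matrix(bg, nrow = L, ncol = 20L, byrow = TRUE))
  scores <- round(lo_bits * log(2) / cfg$ka_lambda)
  storage.mode(scores) <- "integer"
  structure(list(profile_id = profile_id, length = L,
                 scores = scores, probs = probs,
                 source_count = nrow(members), calibration = NA_real_),
            class = "rab_pssm")
}

encode_aa <- function(residues) match(strsplit(residues, "")[[1]], AA20)

#' Score a query against a subfamily profile
#'
#' Best local alignment of the query against the profile columns (affine gaps,
#' same gap costs as the pairwise search); the E-value uses the
#' Karlin-Altschul form with the profile length as `n`. Hits above
#' `cfg$evalue_profile` are gated: reported with `bit_score = 0` and
#' `passed = FALSE`.
#'
#' @param query single-row `rab_seqs` record.
#' @param profile a `rab_pssm`.
#' @param cfg [pipeline_config()].
#' @param gate apply the `evalue_profile` gate (default TRUE).
#' @return list: bit_score, evalue, raw_score, passed.
#' @export
pssm_score <- function(query, profile, cfg = pipeline_config(), gate = TRUE) {
  cfg <- as_config(cfg)
  if (!nzchar(query$residues)) stop("empty query sequence")
  raw <- .profile_sw(encode_aa(query$residues), profile$scores,
                     cfg$gap_open, cfg$gap_extend)
  bits <- if (raw > 0) bit_score(raw, cfg) else 0
  ev <- if (raw > 0)
    karlin_altschul_evalue(raw, nchar(query$residues), profile$length, cfg)
  else Inf
  passed <- ev <= cfg$evalue_profile
  if (gate && !passed) bits <- 0
  list(bit_score = bits, evalue = ev, raw_score = raw, passed = passed)
}

#' G-domain filter
#'
#' Tests whether a sequence carries the conserved GTP-binding fold, by scoring
#' it against the pooled G-domain profile and comparing to the calibrated pass
#' threshold. Calibration (done in [build_reference_db()]) sets the threshold
#' to the minimum bit score of any reference GTPase minus 1 bit of slack, so
#' that no curated GTPase is ever excluded.
#'
#' @param query single-row `rab_seqs` record.
#' @param gdomain calibrated `rab_pssm` with `profile_id = "GDOMAIN"`.
#' @param cfg [pipeline_config()].
#' @return list: passes (logical), bits.
#' @export
gdomain_pass <- function(query, gdomain, cfg = pipeline_config()) {
  if (is.na(gdomain$calibration))
    stop("G-domain profile is not calibrated")
  sc <- pssm_score(query, gdomain, cfg, gate = FALSE)
  list(passes = sc$bit_score >= gdomain$calibration, bits = sc$bit_score)
}

write_pssm_tsv <- function(pssm, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#profile_id\t%s", pssm$profile_id),
               sprintf("#length\t%d", pssm$length),
               sprintf("#source_count\t%d", pssm$source_count),
               sprintf("#calibration\t%.10g", pssm$calibration),
               paste(c("pos", AA20), collapse = "\t")), con, sep = "\n")
  for (j in seq_len(pssm$length))
    writeLines(paste(c(j, pssm$scores[j, ]), collapse = "\t"), con, sep = "\n")
  invisible(path)
}

read_pssm_tsv <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(grep("^#", lines, value = TRUE), "\t")
  kv <- setNames(vapply(meta, `[`, "", 2), sub("^#", "", vapply(meta, `[`, "", 1)))
  body <- lines[!grepl("^#", lines)][-1]
  m <- do.call(rbind, lapply(strsplit(body, "\t"), as.integer))[, -1, drop = FALSE]
  colnames(m) <- AA20
  structure(list(profile_id = kv[["profile_id"]],
                 length = as.integer(kv[["length"]]),
                 scores = m, probs = NULL,
                 source_count = as.integer(kv[["source_count"]]),
                 calibration = if (identical(kv[["calibration"]], "NA"))
                   NA_real_ else as.numeric(kv[["calibration"]])),
            class = "rab_pssm")
}
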