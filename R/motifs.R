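#' RabF motif consensus seeds
#'
#' The five diagnostic Rab-family motifs, as consensus strings; `x` marks a
#' wildcard position modelled as background.
#' @export
rabf_seeds <- c(RabF1 = "igvdf", RabF2 = "klqiw", RabF3 = "rfxxxt",
                RabF4 = "yyrga", RabF5 = "lvydit")

# Resolution of the discrete score grid used by the exact p-value DP:
# log-odds scores are rounded to centibits (1/100 bit).
PWM_GRID <- 100L

#' Build a position weight matrix from aligned motif instances
#'
#' `matrix[i, aa] = (count(i, aa) + pseudocount * background[aa]) /
#' (N + pseudocount)`; every row sums to 1. Instances must all have the seed's
#' length; wildcard (`x`) positions of the seed are modelled as ordinary
#' columns and, with no informative instances, stay at background.
#'
#' @param instances character vector of motif instances (equal length).
#' @param seed_id one of `names(rabf_seeds)` (or any label when `seed` given).
#' @param pseudocount non-negative total pseudocount weight.
#' @param background length-20 background distribution.
#' @param seed consensus string; defaults to `rabf_seeds[seed_id]`.
#' @return list of class `rab_pwm`: motif_id, seed, width, matrix
#'   (width x 20), background.
#' @export
build_pwm <- function(instances, seed_id, pseudocount = 1,
                      background = rep(1 / 20, 20),
                      seed = rabf_seeds[[seed_id]]) {
  if (length(instances) < 1L) stop("need at least one instance")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  width <- nchar(seed)
  if (any(nchar(instances) != width))
    stop("all instances must match the seed length (", width, ")")
  background <- setNames(as.numeric(background), AA20)
  inst <- toupper(instances)
  m <- matrix(0, nrow = width, ncol = 20L, dimnames = list(NULL, AA20))
  chars <- do.call(rbind, strsplit(inst, ""))
  for (i in seq_len(width)) {
    tab <- table(factor(chars[, i], levels = AA20))  # X counts nowhere
    m[i, ] <- (as.numeric(tab) + pseudocount * background) /
      (sum(tab) + pseudocount)
    m[i, ] <- m[i, ] / sum(m[i, ])
  }
  structure(list(motif_id = seed_id, seed = seed, width = width,
                 matrix = m, background = background),
            class = "rab_pwm")
}

# Integer (centibit) log-odds score matrix of a PWM; X scores 0.
pwm_int_scores <- function(pwm) {
  lo <- log2(pwm$matrix / matrix(pwm$background, nrow = pwm$width, ncol = 20L,
                                 byrow = TRUE))
  round(lo * PWM_GRID)
}

# Exact distribution of the integer window score of a random background
# width-mer: convolution of per-column score distributions.
pwm_null_distribution <- function(pwm) {
  s <- pwm_int_scores(pwm)
  # distribution as (offset, probability vector): index k -> score offset+k-1
  probs <- 1
  offset <- 0L
  for (i in seq_len(pwm$width)) {
    col_scores <- s[i, ]
    lo <- min(col_scores); hi <- max(col_scores)
    new <- numeric(length(probs) + (hi - lo))
    for (a in seq_len(20L)) {       # exact sparse convolution over 20 letters
      shift <- col_scores[a] - lo
      idx <- seq_along(probs) + shift
      new[idx] <- new[idx] + probs * pwm$background[a]
    }
    probs <- new
    offset <- offset + lo
  }
  list(offset = offset, probs = probs / sum(probs))
}

#' Exact position p-value of a PWM score threshold
#'
#' Probability that a random background window scores at least
#' `score_threshold` (log-odds, bits) against the PWM, computed exactly on a
#' 1/100-bit score grid by dynamic-programming convolution of the per-column
#' score distributions.
#'
#' @param pwm a `rab_pwm`.
#' @param score_threshold log-odds score threshold in bits.
#' @return p-value in `[0, 1]`; 1 whenever the threshold is at or below the
#'   minimum attainable score.
#' @export
position_pvalue <- function(pwm, score_threshold) {
  d <- pwm_null_distribution(pwm)
  t_int <- ceiling(score_threshold * PWM_GRID - 1e-9)
  k <- t_int - d$offset + 1L            # first index meeting the threshold
  if (k <= 1L) return(1)
  if (k > length(d$probs)) return(0)
  sum(d$probs[k:length(d$probs)])
}

# Tail p-values for every grid score (helper reused by scan_motifs):
# pval_of(s) = P(score >= s) for integer s.
pwm_tail_table <- function(pwm) {
  d <- pwm_null_distribution(pwm)
  tail <- rev(cumsum(rev(d$probs)))
  list(offset = d$offset, tail = tail)
}

#' Scan a sequence for RabF motif hits
#'
#' Every window of every motif whose exact position p-value is at most
#' `cfg$motif_pvalue` is reported, sorted by position. The count of distinct
#' motifs among the hits is attached as attribute `distinct_motifs` (this is
#' the quantity the family confidence uses).
#'
#' @param seq single-row `rab_seqs` record.
#' @param models list of `rab_pwm` objects.
#' @param cfg [pipeline_config()].
#' @return data.frame: motif_id, position (1-based start), log_odds_score
#'   (bits), position_pvalue.
#' @export
scan_motifs <- function(seq, models, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  empty <- data.frame(motif_id = character(), position = integer(),
                      log_odds_score = numeric(), position_pvalue = numeric(),
                      stringsAsFactors = FALSE)
  if (length(models) == 0L) {
    attr(empty, "distinct_motifs") <- 0L
    return(empty)
  }
  L <- nchar(seq$residues)
  if (L < min(vapply(models, `[[`, 1L, "width"))) {
    warning("sequence ", seq$id, " shorter than every motif; no scan")
    attr(empty, "distinct_motifs") <- 0L
    return(empty)
  }
  code <- match(strsplit(seq$residues, "")[[1]], AA20)  # NA for X
  out <- list()
  for (pwm in models) {
    w <- pwm$width
    if (L < w) next
    s <- pwm_int_scores(pwm)
    nwin <- L - w + 1L
    win <- integer(nwin)
    for (j in seq_len(w)) {
      aj <- code[seq_len(nwin) + j - 1L]
      sc <- ifelse(is.na(aj), 0L, s[j, ifelse(is.na(aj), 1L, aj)])
      win <- win + sc
    }
    tt <- pwm_tail_table(pwm)
    k <- win - tt$offset + 1L
    pv <- ifelse(k <= 1L, 1,
                 ifelse(k > length(tt$tail), 0, tt$tail[pmax(pmin(k, length(tt$tail)), 1L)]))
    keep <- which(pv <= cfg$motif_pvalue)
    if (length(keep))
      out[[length(out) + 1L]] <- data.frame(
        motif_id = pwm$motif_id, position = keep,
        log_odds_score = win[keep] / PWM_GRID, position_pvalue = pv[keep],
        stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  res <- res[order(res$position, res$motif_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "distinct_motifs") <- length(unique(res$motif_id))
  res
}

#' Write motif models in MEME minimal format
#'
#' Standard "MEME version 4" minimal text format (letter-probability matrices),
#' readable by the MEME suite tools.
#'
#' @param models list of `rab_pwm` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme_minimal <- function(models, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  bg <- models[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", AA20, bg), collapse = " "), ""),
             con, sep = "\n")
  for (pwm in models) {
    writeLines(c(sprintf("MOTIF %s %s", pwm$motif_id, pwm$seed),
                 sprintf("letter-probability matrix: alength= 20 w= %d nsites= 20 E= 0",
                         pwm$width)), con, sep = "\n")
    for (i in seq_len(pwm$width))
      writeLines(paste(sprintf("%.10f", pwm$matrix[i, ]), collapse = " "),
                 con, sep = "\n")
    writeLines("", con, sep = "\n")
  }
  invisible(path)
}

read_meme_minimal <- function(path) {
  lines <- readLines(path)
  bg_i <- grep("^Background letter frequencies", lines)
  bg <- rep(1 / 20, 20)
  if (length(bg_i)) {
    parts <- strsplit(trimws(lines[bg_i + 1L]), "\\s+")[[1]]
    bg <- as.numeric(parts[seq(2, length(parts), by = 2)])
  }
  starts <- grep("^MOTIF ", lines)
  models <- list()
  for (s in starts) {
    hdr <- strsplit(lines[s], "\\s+")[[1]]
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[s + 1L]))
    m <- do.call(rbind, lapply(lines[(s + 2L):(s + 1L + w)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    colnames(m) <- AA20
    models[[hdr[2]]] <- structure(
      list(motif_id = hdr[2], seed = hdr[3], width = w, matrix = m,
           background = setNames(bg, AA20)),
      class = "rab_pwm")
  }
  models
}

# Train the five RabF models. With labelled instances (a data.frame motif_id /
# instance, as emitted by the benchmark generator) training is direct counting;
# otherwise a two-pass scheme seeds each model on its consensus, takes the
# best-scoring window of every reference Rab, and retrains on those windows.
train_rabf_models <- function(rab_seqs, cfg = pipeline_config(),
                              instances = NULL, pseudocount = 1) {
  cfg <- as_config(cfg)
  bg <- cfg$background
  if (!is.null(instances)) {
    models <- lapply(names(rabf_seeds), function(mid) {
      inst <- instances$instance[instances$motif_id == mid]
      if (length(inst) == 0L) inst <- toupper(rabf_seeds[[mid]])
      build_pwm(inst, mid, pseudocount = pseudocount, background = bg)
    })
    names(models) <- names(rabf_seeds)
    return(models)
  }
  # pass 1: consensus-seeded models (70% mass on the consensus letter)
  seed_model <- function(mid) {
    seedc <- toupper(strsplit(rabf_seeds[[mid]], "")[[1]])
    m <- matrix(rep(bg, length(seedc)), nrow = length(seedc), byrow = TRUE,
                dimnames = list(NULL, AA20))
    for (i in seq_along(seedc)) {
      if (seedc[i] == "X") next
      m[i, ] <- 0.3 * bg
      m[i, seedc[i]] <- m[i, seedc[i]] + 0.7
    }
    structure(list(motif_id = mid, seed = rabf_seeds[[mid]],
                   width = length(seedc), matrix = m, background = bg),
              class = "rab_pwm")
  }
  seeds <- lapply(names(rabf_seeds), seed_model)
  names(seeds) <- names(rabf_seeds)
  # pass 2: harvest best windows, retrain
  models <- lapply(seeds, function(pwm) {
    s <- pwm_int_scores(pwm)
    wins <- vapply(seq_len(nrow(rab_seqs)), function(i) {
      res <- rab_seqs$residues[i]
      code <- match(strsplit(res, "")[[1]], AA20)
      nwin <- nchar(res) - pwm$width + 1L
      if (nwin < 1L) return(NA_character_)
      sc <- integer(nwin)
      for (j in seq_len(pwm$width)) {
        aj <- code[seq_len(nwin) + j - 1L]
        sc <- sc + ifelse(is.na(aj), 0L, s[j, ifelse(is.na(aj), 1L, aj)])
      }
      best <- which.max(sc)
      substr(res, best, best + pwm$width - 1L)
    }, character(1))
    wins <- wins[!is.na(wins)]
    if (length(wins) == 0L) return(pwm)
    build_pwm(wins, pwm$motif_id, pseudocount = pseudocount, background = bg)
  })
  models
}
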