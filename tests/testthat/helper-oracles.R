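# Independent oracles, deliberately implemented apart from the package code.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptide <- function(len, letters = AA) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Brute-force Gotoh local alignment (three explicit matrices, no recursion
# shared with the implementation). Gap of length k costs open + k * ext.
gotoh_local_score <- function(a, b, open = 11, ext = 1, mat = .blosum62) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    prev <- max(0, M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
    M[i, j] <- mat[av[i - 1], bv[j - 1]] + prev
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    best <- max(best, M[i, j])
  }
  best
}

# Mann-Whitney pairwise-concordance AUC with half-credit ties.
auc_concordance <- function(confidence, is_correct) {
  pos <- confidence[is_correct]
  neg <- confidence[!is_correct]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Exhaustive PWM tail probability: enumerate every width-mer over the full
# alphabet, score it on the same centibit grid, accumulate background mass.
enumerate_pvalue <- function(pwm, threshold_bits) {
  grid <- 100
  s <- round(log2(pwm$matrix /
                    matrix(pwm$background, nrow = pwm$width, ncol = 20,
                           byrow = TRUE)) * grid)
  t_int <- ceiling(threshold_bits * grid - 1e-9)
  combos <- expand.grid(rep(list(seq_len(20)), pwm$width))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    idx <- as.integer(combos[r, ])
    sc <- sum(s[cbind(seq_len(pwm$width), idx)])
    if (sc >= t_int) total <- total + prod(pwm$background[idx])
  }
  total
}
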