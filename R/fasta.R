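#' Sequence record tables
#'
#' Sequences travel through the pipeline as plain data frames with columns
#' `id`, `residues`, `genome`, `taxon`. `seq_records()` builds and validates
#' one; residues are uppercased and must use the 20 standard amino acids plus
#' the ambiguity code X.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of amino-acid strings.
#' @param genome,taxon optional per-sequence annotations (NA allowed).
#' @return data.frame with class `rab_seqs`.
#' @export
seq_records <- function(id, residues, genome = NA_character_,
                        taxon = NA_character_) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("id and residues must have equal length")
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(residues)))
    stop("empty sequence for id(s): ", paste(id[!nzchar(residues)], collapse = ", "))
  bad <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), residues)
  if (any(bad))
    stop("non amino-acid characters in sequence(s): ",
         paste(id[bad], collapse = ", "))
  out <- data.frame(id = id, residues = residues,
                    genome = rep_len(as.character(genome), length(id)),
                    taxon = rep_len(as.character(taxon), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("rab_seqs", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' One record per header (text up to the first whitespace becomes the id);
#' multi-line sequences are concatenated, residues uppercased, order preserved.
#' Rare ambiguity codes (B, Z, J, U, O, *) are mapped to X.
#'
#' @param path FASTA file path.
#' @return `rab_seqs` data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(aa))
  res <- toupper(as.character(aa))
  res <- gsub("[BZJUO*]", "X", res)
  seq_records(ids, res)
}

#' Write sequences to FASTA
#'
#' @param records `rab_seqs` data frame (or anything with id/residues columns).
#' @param path output path.
#' @param width line-wrap width, default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    lines <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    writeLines(c(paste0(">", records$id[i]), lines), con, sep = "\n")
  }
  invisible(path)
}
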