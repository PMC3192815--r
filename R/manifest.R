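NONRAB_CLASSES <- c("Ras", "Rho", "Ran", "Arf", "RabL2", "RabL3", "RabL5",
                    "other")

# Validate a family_label token ("Rab" or "nonRab:<class>").
check_family_label <- function(label, id) {
  if (label == "Rab") return(invisible(TRUE))
  if (grepl("^nonRab:", label)) {
    cls <- sub("^nonRab:", "", label)
    if (cls %in% NONRAB_CLASSES) return(invisible(TRUE))
    stop("unknown non-Rab class '", cls, "' for id ", id,
         " (expected one of: ", paste(NONRAB_CLASSES, collapse = ", "), ")")
  }
  # RabL2/3/5 are not considered Rabs: the curation evidence places them with
  # Rans/Rhos/Arfs, so a bare "RabL2" (etc.) label is redirected explicitly.
  if (label %in% c("RabL2", "RabL3", "RabL5"))
    stop("id ", id, ": '", label, "' proteins are not members of the Rab ",
         "family; label them nonRab:", label)
  stop("unknown family_label '", label, "' for id ", id)
}

#' Load a curated reference set from FASTA plus manifest
#'
#' The manifest is a TSV with header columns `id`, `family_label`,
#' `subfamily`, `genome`, `taxon`. `family_label` is either `Rab` (then
#' `subfamily` is required) or `nonRab:<class>` with class one of Ras, Rho,
#' Ran, Arf, RabL2, RabL3, RabL5, other (then `subfamily` must be empty).
#' Every manifest id must exist in the FASTA; FASTA records without a manifest
#' row are dropped with a warning.
#'
#' @param fasta path to the reference FASTA.
#' @param manifest path to the manifest TSV.
#' @return data.frame of reference entries with class `rab_reference_entries`:
#'   columns id, residues, genome, taxon, family_label, subfamily.
#' @export
load_reference_manifest <- function(fasta, manifest) {
  seqs <- read_fasta(fasta)
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  need <- c("id", "family_label", "subfamily", "genome", "taxon")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  dup <- unique(man$id[duplicated(man$id)])
  if (length(dup)) stop("duplicate manifest id(s): ", paste(dup, collapse = ", "))
  missing <- setdiff(man$id, seqs$id)
  if (length(missing))
    stop("manifest id(s) absent from FASTA: ", paste(missing, collapse = ", "))
  extra <- setdiff(seqs$id, man$id)
  if (length(extra))
    warning(length(extra), " FASTA record(s) without manifest row dropped")
  reference_entries(seqs[match(man$id, seqs$id), , drop = FALSE],
                    man$family_label, man$subfamily, man$genome, man$taxon)
}

reference_entries <- function(seqs, family_label, subfamily, genome = NULL,
                              taxon = NULL) {
  for (i in seq_along(family_label)) check_family_label(family_label[i], seqs$id[i])
  subfamily[!nzchar(subfamily)] <- NA_character_
  is_rab <- family_label == "Rab"
  if (any(is_rab & is.na(subfamily)))
    stop("Rab entries need a subfamily: ",
         paste(seqs$id[is_rab & is.na(subfamily)], collapse = ", "))
  if (any(!is_rab & !is.na(subfamily)))
    stop("non-Rab entries must not carry a subfamily: ",
         paste(seqs$id[!is_rab & !is.na(subfamily)], collapse = ", "))
  out <- data.frame(id = seqs$id, residues = seqs$residues,
                    genome = if (is.null(genome)) seqs$genome else blank_na(genome),
                    taxon = if (is.null(taxon)) seqs$taxon else blank_na(taxon),
                    family_label = family_label,
                    subfamily = subfamily,
                    stringsAsFactors = FALSE)
  class(out) <- c("rab_reference_entries", "data.frame")
  out
}

blank_na <- function(x) {
  x <- as.character(x)
  x[!nzchar(x)] <- NA_character_
  x
}

#' Write a reference manifest TSV
#' @param entries reference entries (see [load_reference_manifest()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_manifest <- function(entries, path) {
  man <- entries[, c("id", "family_label", "subfamily", "genome", "taxon")]
  for (col in c("subfamily", "genome", "taxon"))
    man[[col]][is.na(man[[col]])] <- ""
  write_tsv(man, path)
  invisible(path)
}

# Deterministic TSV writer (fixed number formatting, "\n" endings).
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]]))
      df[[col]] <- sprintf("%.10g", df[[col]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
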