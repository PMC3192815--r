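#' Build the complete reference database
#'
#' From curated entries this derives everything the classifier needs:
#' redundancy-removed entries (90% identity ceiling by default, greedy
#' longest-first within each family/subfamily stratum), trained RabF motif
#' models, one PSSM per Rab subfamily with at least one member, and the pooled
#' G-domain profile built from all reference GTPases (Rab and non-Rab) with
#' its pass threshold calibrated so that every reference GTPase passes
#' (minimum reference bit score minus 1 bit of slack).
#'
#' @param entries reference entries from [load_reference_manifest()].
#' @param cfg [pipeline_config()].
#' @param motif_instances optional data.frame (motif_id, instance) of labelled
#'   RabF instances; when absent, models are trained by consensus-seeded
#'   harvesting from the reference Rabs.
#' @param dedupe apply redundancy removal (default TRUE).
#' @return list of class `rab_reference_db`: entries, subfamily_profiles,
#'   rabf_models, gdomain_profile, provenance.
#' @export
build_reference_db <- function(entries, cfg = pipeline_config(),
                               motif_instances = NULL, dedupe = TRUE) {
  cfg <- as_config(cfg)
  if (dedupe) {
    dd <- dedupe_reference(entries, cfg)
    entries <- dd$representatives
  }
  rabs <- entries[entries$family_label == "Rab", , drop = FALSE]
  if (nrow(rabs) == 0L) stop("reference set contains no Rab entries")
  models <- train_rabf_models(rabs, cfg, instances = motif_instances)
  profiles <- lapply(split(seq_len(nrow(rabs)), rabs$subfamily), function(ix)
    build_pssm(rabs[ix, , drop = FALSE], rabs$subfamily[ix[1]], cfg))
  profiles <- profiles[order(names(profiles))]
  gdom <- build_pssm(entries, "GDOMAIN", cfg)
  bits <- vapply(seq_len(nrow(entries)), function(i)
    pssm_score(entries[i, , drop = FALSE], gdom, cfg, gate = FALSE)$bit_score,
    numeric(1))
  gdom$calibration <- min(bits) - 1
  db <- list(entries = entries,
             subfamily_profiles = profiles,
             rabf_models = models,
             gdomain_profile = gdom,
             provenance = list(seed = cfg$seed, config = unclass(cfg)[
               !names(unclass(cfg)) %in% "background"]))
  class(db) <- "rab_reference_db"
  db
}

#' @export
print.rab_reference_db <- function(x, ...) {
  cat("Rab reference database\n")
  cat("  entries:   ", nrow(x$entries), " (",
      sum(x$entries$family_label == "Rab"), " Rab / ",
      sum(x$entries$family_label != "Rab"), " non-Rab)\n", sep = "")
  cat("  subfamilies:", length(x$subfamily_profiles), "\n")
  cat("  G-domain calibration:",
      sprintf("%.2f bits\n", x$gdomain_profile$calibration))
  invisible(x)
}

#' Serialize / load a reference database directory
#'
#' On-disk layout: `reference.faa`, `manifest.tsv`, `profiles/<id>.tsv`,
#' `motifs/rabf.meme`, `meta.tsv`. Writing the same database twice produces
#' byte-identical files.
#'
#' @param db a `rab_reference_db`.
#' @param dir target directory (created if needed).
#' @return `dir` (write) or the database (load).
#' @export
write_reference_db <- function(db, dir) {
  dir.create(file.path(dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "motifs"), showWarnings = FALSE)
  write_fasta(db$entries, file.path(dir, "reference.faa"))
  write_reference_manifest(db$entries, file.path(dir, "manifest.tsv"))
  for (p in db$subfamily_profiles)
    write_pssm_tsv(p, file.path(dir, "profiles", paste0(p$profile_id, ".tsv")))
  write_pssm_tsv(db$gdomain_profile, file.path(dir, "profiles", "GDOMAIN.tsv"))
  write_meme_minimal(db$rabf_models, file.path(dir, "motifs", "rabf.meme"))
  meta <- data.frame(key = c("seed", "format"),
                     value = c(db$provenance$seed, "1"))
  write_tsv(meta, file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' @rdname write_reference_db
#' @param dir database directory written by [write_reference_db()].
#' @export
read_reference_db <- function(dir) {
  if (!dir.exists(dir)) stop("reference database directory not found: ", dir)
  entries <- load_reference_manifest(file.path(dir, "reference.faa"),
                                     file.path(dir, "manifest.tsv"))
  pfiles <- list.files(file.path(dir, "profiles"), pattern = "\\.tsv$",
                       full.names = TRUE)
  profiles <- lapply(pfiles, read_pssm_tsv)
  names(profiles) <- vapply(profiles, `[[`, "", "profile_id")
  gdom <- profiles[["GDOMAIN"]]
  profiles <- profiles[setdiff(names(profiles), "GDOMAIN")]
  profiles <- profiles[order(names(profiles))]
  meta <- utils::read.delim(file.path(dir, "meta.tsv"),
                            colClasses = "character")
  db <- list(entries = entries,
             subfamily_profiles = profiles,
             rabf_models = read_meme_minimal(file.path(dir, "motifs",
                                                       "rabf.meme")),
             gdomain_profile = gdom,
             provenance = list(seed = as.integer(
               meta$value[meta$key == "seed"])))
  class(db) <- "rab_reference_db"
  db
}
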