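#' Pipeline configuration
#'
#' Collects every numeric threshold the classifier uses. Defaults follow the
#' operating point of the published pipeline: a 1e-10 E-value gate for the
#' family-level best-hit search, 1e-5 for profile (PSSM) hits, a 0.0005 motif
#' position p-value, a 40% identity gate before any subfamily is named, 70%
#' identity for clustering RabX sequences, 90% for reference-set redundancy
#' removal, Markov-clustering inflation 2.0 and a 0.4 confidence cutoff for the
#' high-confidence mode. Alignment scoring uses BLOSUM62 with affine gap costs
#' (a gap of length k costs `gap_open + k * gap_extend`) and gapped
#' Karlin-Altschul parameters `ka_lambda`/`ka_K` for E-values and bit scores.
#'
#' @param evalue_family E-value ceiling for family-level best hits.
#' @param evalue_profile E-value ceiling for subfamily profile hits.
#' @param motif_pvalue position p-value ceiling for a RabF motif hit.
#' @param identity_subfamily_gate minimum identity to the best hit required
#'   before a named subfamily call is allowed (fraction).
#' @param identity_cluster identity threshold for RabX clustering (fraction).
#' @param identity_dedupe identity ceiling for reference deduplication.
#' @param mcl_inflation Markov clustering inflation parameter (> 1).
#' @param confidence_cutoff confidence below which high-confidence mode demotes
#'   a named call to RabX.
#' @param gap_open,gap_extend affine gap penalties (positive integers).
#' @param ka_lambda,ka_K Karlin-Altschul parameters for gapped BLOSUM62(11,1).
#' @param background length-20 amino-acid background distribution, in the
#'   fixed alphabet order `ACDEFGHIKLMNPQRSTVWY`; must sum to 1.
#' @param seed integer seed recorded with every derived object.
#' @return A list of class `rab_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$confidence_cutoff
pipeline_config <- function(evalue_family = 1e-10,
                            evalue_profile = 1e-5,
                            motif_pvalue = 5e-4,
                            identity_subfamily_gate = 0.40,
                            identity_cluster = 0.70,
                            identity_dedupe = 0.90,
                            mcl_inflation = 2.0,
                            confidence_cutoff = 0.4,
                            gap_open = 11L,
                            gap_extend = 1L,
                            ka_lambda = 0.267,
                            ka_K = 0.041,
                            background = rep(1 / 20, 20),
                            seed = 1L) {
  stopifnot(evalue_family > 0, evalue_profile > 0, motif_pvalue > 0)
  fracs <- c(identity_subfamily_gate, identity_cluster, identity_dedupe,
             confidence_cutoff)
  if (any(fracs <= 0) || any(fracs > 1))
    stop("identity/confidence fractions must lie in (0, 1]")
  if (mcl_inflation <= 1) stop("mcl_inflation must exceed 1")
  if (gap_open < 1 || gap_extend < 1)
    stop("gap penalties must be positive integers")
  if (length(background) != 20L || any(background <= 0))
    stop("background must be 20 positive probabilities")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must sum to 1")
  cfg <- list(evalue_family = evalue_family,
              evalue_profile = evalue_profile,
              motif_pvalue = motif_pvalue,
              identity_subfamily_gate = identity_subfamily_gate,
              identity_cluster = identity_cluster,
              identity_dedupe = identity_dedupe,
              mcl_inflation = mcl_inflation,
              confidence_cutoff = confidence_cutoff,
              gap_open = as.integer(gap_open),
              gap_extend = as.integer(gap_extend),
              ka_lambda = ka_lambda,
              ka_K = ka_K,
              background = setNames(as.numeric(background), AA20),
              seed = as.integer(seed))
  class(cfg) <- "rab_config"
  cfg
}

as_config <- function(cfg) {
  if (is.null(cfg)) return(pipeline_config())
  if (!inherits(cfg, "rab_config")) stop("cfg must come from pipeline_config()")
  cfg
}
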