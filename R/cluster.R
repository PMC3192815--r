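# Identity under the short-sequence convention used for deduplication and
# RabX clustering: matches of the best local alignment divided by the length
# of the shorter sequence. Distinct from the aligned-column identity used by
# the 40% subfamily gate.
identity_short <- function(a_res, b_res, cfg) {
  pa <- Biostrings::pairwiseAlignment(
    aa_set(a_res), Biostrings::AAString(b_res), type = "local",
    substitutionMatrix = blosum62(),
    gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
  Biostrings::nmatch(pa) / pmin(nchar(a_res), nchar(b_res))
}

#' Remove redundancy from a reference set
#'
#' Greedy incremental clustering in the style of the classic deduplication
#' heuristic: within each (family_label, subfamily) stratum, sequences are
#' visited longest first; a sequence joins the first existing representative
#' it matches at `>= cfg$identity_dedupe` identity (matches over the shorter
#' length), otherwise it becomes a new representative.
#'
#' @param entries reference entries data frame.
#' @param cfg [pipeline_config()].
#' @return list: `representatives` (entries subset) and `removed`
#'   (data.frame id, representative, identity).
#' @export
dedupe_reference <- function(entries, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  keep <- logical(nrow(entries))
  removed <- list()
  strata <- paste(entries$family_label, entries$subfamily, sep = "\r")
  for (s in unique(strata)) {
    ix <- which(strata == s)
    ix <- ix[order(-nchar(entries$residues[ix]), entries$id[ix])]
    reps <- integer(0)
    for (i in ix) {
      assigned <- FALSE
      for (r in reps) {
        idy <- identity_short(entries$residues[i], entries$residues[r], cfg)
        if (idy >= cfg$identity_dedupe) {
          removed[[length(removed) + 1L]] <- data.frame(
            id = entries$id[i], representative = entries$id[r],
            identity = idy, stringsAsFactors = FALSE)
          assigned <- TRUE
          break
        }
      }
      if (!assigned) {
        reps <- c(reps, i)
        keep[i] <- TRUE
      }
    }
  }
  list(representatives = entries[keep, , drop = FALSE],
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(id = character(), representative = character(),
                    identity = numeric(), stringsAsFactors = FALSE))
}

#' Markov clustering of a weighted undirected graph
#'
#' The MCL iteration: add self-loops (weight = maximum incident edge weight,
#' 1 for isolated nodes), column-normalize, then alternate expansion (matrix
#' squaring) and inflation (entrywise power `inflation`, renormalize), pruning
#' entries below 1e-8, until the maximum entrywise change drops below 1e-6 or
#' 100 iterations. Attractors (nodes with positive diagonal mass) define
#' clusters; any overlap is resolved to the lexicographically smallest
#' attractor so the result is a partition.
#'
#' @param edges data.frame with columns `from`, `to`, `weight`
#'   (non-negative); may be empty.
#' @param nodes character vector of all node names (isolated nodes allowed).
#' @param inflation inflation parameter (> 1).
#' @return list of character vectors (clusters, each sorted); the list is
#'   ordered by decreasing size then smallest member. Clusters are disjoint
#'   and cover `nodes`.
#' @export
mcl_partition <- function(edges, nodes, inflation = 2.0) {
  if (inflation <= 1) stop("inflation must exceed 1")
  nodes <- sort(unique(nodes))
  n <- length(nodes)
  if (n == 0L) return(list())
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    if (any(edges$weight < 0)) stop("negative edge weight")
    for (k in seq_len(nrow(edges))) {
      i <- match(edges$from[k], nodes); j <- match(edges$to[k], nodes)
      A[i, j] <- max(A[i, j], edges$weight[k])
      A[j, i] <- A[i, j]
    }
  }
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(100L)) {
    E <- M %*% M                    # expansion
    E <- E^inflation                # inflation
    E[E < 1e-8] <- 0
    cs <- colSums(E)
    cs[cs == 0] <- 1
    E <- sweep(E, 2, cs, "/")
    delta <- max(abs(E - M))
    M <- E
    if (delta < 1e-6) break
  }
  attractors <- which(diag(M) > 1e-6)
  if (length(attractors) == 0L) attractors <- seq_len(n)
  assign_to <- character(n)
  for (v in seq_len(n)) {
    owners <- attractors[M[attractors, v] > 1e-6]
    if (length(owners) == 0L) owners <- if (v %in% attractors) v else v
    assign_to[v] <- nodes[min(owners)]   # lexicographic: nodes are sorted
  }
  cl <- split(nodes, assign_to)
  cl <- lapply(cl, sort)
  sizes <- vapply(cl, length, 1L)
  firsts <- vapply(cl, `[`, "", 1)
  cl <- cl[order(-sizes, firsts)]
  names(cl) <- NULL
  cl
}

#' Group RabX sequences into hypothetical subfamilies
#'
#' Two steps: within each genome, sequences are joined by edges where identity
#' (matches over the shorter length) is at least `cfg$identity_cluster` and
#' the identity-weighted graph is partitioned by Markov clustering at
#' `cfg$mcl_inflation`; then clusters are merged across genomes by single
#' linkage whenever at least one cross-cluster pair exceeds
#' `cfg$identity_cluster`. Records without a genome use their own id as
#' genome. Clusters are named `Novel1`, `Novel2`, ... by decreasing size then
#' smallest member id.
#'
#' @param rabx `rab_seqs` data frame of RabX sequences.
#' @param cfg [pipeline_config()].
#' @return data.frame: cluster_name, member_id, genome, taxon, category; the
#'   per-cluster summary (name, n, genomes, taxa, category) is attached as
#'   attribute `clusters`.
#' @export
cluster_rabx <- function(rabx, cfg = pipeline_config()) {
  cfg <- as_config(cfg)
  if (nrow(rabx) == 0L)
    return(structure(data.frame(cluster_name = character(),
                                member_id = character(), genome = character(),
                                taxon = character(), category = character(),
                                stringsAsFactors = FALSE),
                     clusters = data.frame()))
  genome <- ifelse(is.na(rabx$genome) | !nzchar(rabx$genome), rabx$id,
                   rabx$genome)
  # pairwise identity (computed once, reused by both steps)
  n <- nrow(rabx)
  idm <- matrix(0, n, n, dimnames = list(rabx$id, rabx$id))
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    vals <- vapply(js, function(j)
      identity_short(rabx$residues[i], rabx$residues[j], cfg), numeric(1))
    idm[i, js] <- vals
    idm[js, i] <- vals
  }
  # step 1: within-genome MCL partitions
  partitions <- list()
  for (g in unique(genome)) {
    ids <- rabx$id[genome == g]
    sub <- idm[ids, ids, drop = FALSE]
    pairs <- which(upper.tri(sub) & sub >= cfg$identity_cluster, arr.ind = TRUE)
    edges <- data.frame(from = ids[pairs[, 1]], to = ids[pairs[, 2]],
                        weight = sub[pairs], stringsAsFactors = FALSE)
    partitions <- c(partitions,
                    mcl_partition(edges, ids, cfg$mcl_inflation))
  }
  # step 2: single-linkage merge across genomes (> threshold, strict)
  k <- length(partitions)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    if (any(idm[partitions[[a]], partitions[[b]]] > cfg$identity_cluster)) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find, 1L)
  merged <- lapply(unique(roots), function(r)
    sort(unlist(partitions[roots == r], use.names = FALSE)))
  sizes <- vapply(merged, length, 1L)
  firsts <- vapply(merged, `[`, "", 1)
  merged <- merged[order(-sizes, firsts)]
  rows <- list()
  summaries <- list()
  for (ci in seq_along(merged)) {
    ids <- merged[[ci]]
    mix <- match(ids, rabx$id)
    g <- unique(genome[mix])
    t <- unique(rabx$taxon[mix][!is.na(rabx$taxon[mix])])
    cat_ <- categorize(length(t), length(g), length(ids))
    rows[[ci]] <- data.frame(cluster_name = paste0("Novel", ci),
                             member_id = ids, genome = genome[mix],
                             taxon = rabx$taxon[mix], category = cat_,
                             stringsAsFactors = FALSE)
    summaries[[ci]] <- data.frame(name = paste0("Novel", ci),
                                  n = length(ids), genomes = length(g),
                                  taxa = length(t), category = cat_,
                                  stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "clusters") <- do.call(rbind, summaries)
  out
}

#' Taxonomic-breadth category of a hypothetical subfamily
#'
#' Precedence: `multi_taxon` (members span more than one taxon), else
#' `multi_genome`, else `single_genome_multi_member`, else `singleton`.
#'
#' @param n_taxa,n_genomes,n_members counts for the cluster.
#' @return category string.
#' @export
categorize <- function(n_taxa, n_genomes, n_members) {
  if (n_taxa > 1) "multi_taxon"
  else if (n_genomes > 1) "multi_genome"
  else if (n_members > 1) "single_genome_multi_member"
  else "singleton"
}

#' Export an identity graph in abc format (node1 node2 weight)
#' @param edges data.frame from/to/weight.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abc_graph <- function(edges, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(edges))
    writeLines(sprintf("%s %s %.10g", edges$from, edges$to, edges$weight),
               con, sep = "\n")
  invisible(path)
}
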