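# helper: mutate the given positions deterministically; `alt` picks which
# replacement letter, so two mutants of the same parent can be made to
# disagree with each other as well as with the parent
mutate_n <- function(res, pos, alt = 1) {
  chars <- strsplit(res, "")[[1]]
  for (i in pos) chars[i] <- setdiff(AA, chars[i])[alt]
  paste(chars, collapse = "")
}

test_that("deduplication keeps representatives and assigns removals", {
  cfg <- pipeline_config()
  set.seed(61)
  base <- random_peptide(100)
  entries <- data.frame(
    id = c("dup1", "dup2", "far1", "far2", "far3"),
    residues = c(base, base,
                 mutate_n(base, 1:30),
                 mutate_n(base, 31:60),
                 mutate_n(base, 61:90)),
    genome = "g1", taxon = "t1", family_label = "Rab", subfamily = "Rab1",
    stringsAsFactors = FALSE)
  dd <- dedupe_reference(entries, cfg)
  expect_equal(nrow(dd$representatives), 4L)       # two identical collapse
  expect_equal(dd$removed$id, "dup2")
  expect_equal(dd$removed$representative, "dup1")
  expect_gte(dd$removed$identity, 0.9)
})

test_that("greedy chain deduplication follows the longest-first trace", {
  cfg <- pipeline_config()
  set.seed(67)
  A <- random_peptide(100)
  B <- mutate_n(A, 1:8)        # ~92% to A
  C <- mutate_n(B, 9:16)       # ~92% to B, ~84% to A
  entries <- data.frame(id = c("A", "B", "C"), residues = c(A, B, C),
                        genome = "g", taxon = "t", family_label = "Rab",
                        subfamily = "Rab1", stringsAsFactors = FALSE)
  dd <- dedupe_reference(entries, cfg)
  expect_setequal(dd$representatives$id, c("A", "C"))
  expect_equal(dd$removed$id, "B")
  expect_equal(dd$removed$representative, "A")
  expect_gte(dd$removed$identity, 0.9)
})

test_that("Markov clustering recovers planted graph structure", {
  # two disjoint 3-cliques
  cl3 <- function(v) expand.grid(from = v, to = v, stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"), weight = 1),
    data.frame(from = c("d", "d", "e"), to = c("e", "f", "f"), weight = 1))
  part <- mcl_partition(edges, letters[1:6], inflation = 2)
  expect_length(part, 2L)
  expect_setequal(part[[1]], c("a", "b", "c"))
  expect_setequal(part[[2]], c("d", "e", "f"))

  # single isolated node: a singleton cluster
  solo <- mcl_partition(data.frame(from = character(), to = character(),
                                   weight = numeric()), "x", 2)
  expect_equal(solo, list("x"))

  # complete graph with uniform weights: one cluster
  full <- expand.grid(from = letters[1:5], to = letters[1:5],
                      stringsAsFactors = FALSE)
  full <- full[full$from < full$to, ]
  full$weight <- 1
  expect_length(mcl_partition(full, letters[1:5], 2), 1L)

  expect_error(mcl_partition(data.frame(from = "a", to = "b", weight = -1),
                             c("a", "b"), 2), "negative")
  expect_error(mcl_partition(edges, letters[1:6], 1), "inflation")
})

test_that("Markov clustering partitions, is deterministic and label-invariant", {
  set.seed(71)
  for (rep_i in 1:5) {
    nodes <- sprintf("n%02d", 1:12)
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.25
    edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                        weight = runif(sum(keep), 0.5, 1),
                        stringsAsFactors = FALSE)
    p1 <- mcl_partition(edges, nodes, 2)
    # disjoint cover
    expect_setequal(unlist(p1), nodes)
    expect_equal(anyDuplicated(unlist(p1)), 0L)
    expect_identical(p1, mcl_partition(edges, nodes, 2))
    # relabeling invariance (reverse name map preserves cluster structure)
    map <- setNames(sprintf("m%02d", 12:1), nodes)
    edges2 <- data.frame(from = unname(map[edges$from]),
                         to = unname(map[edges$to]), weight = edges$weight,
                         stringsAsFactors = FALSE)
    p2 <- mcl_partition(edges2, unname(map), 2)
    canon <- function(p) {
      x <- lapply(p, sort)
      x[order(vapply(x, `[`, "", 1))]
    }
    expect_identical(canon(lapply(p1, function(cl) unname(map[cl]))),
                     canon(p2))
  }
})

test_that("raising inflation never merges separated two-clique partitions", {
  edges <- rbind(
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"), weight = 1),
    data.frame(from = c("d", "d", "e"), to = c("e", "f", "f"), weight = 1),
    data.frame(from = "c", to = "d", weight = 0.3))   # weak bridge
  sizes <- vapply(c(1.5, 2, 3, 4, 6), function(infl)
    length(mcl_partition(edges, letters[1:6], infl)), 1L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("RabX clustering merges across genomes by single linkage", {
  cfg <- pipeline_config()
  set.seed(73)
  base <- random_peptide(100)
  near <- mutate_n(base, 1:25)            # 75% identity: merges (> 70%)
  far <- mutate_n(base, 1:40, alt = 2)    # 60% to base, < 70% to near
  rabx <- seq_records(c("x1", "x2", "x3"), c(base, near, far),
                      genome = c("gA", "gB", "gC"),
                      taxon = c("Metazoa", "Metazoa", "Fungi"))
  out <- cluster_rabx(rabx, cfg)
  cl_x1 <- out$cluster_name[out$member_id == "x1"]
  expect_equal(out$cluster_name[out$member_id == "x2"], cl_x1)
  expect_false(out$cluster_name[out$member_id == "x3"] == cl_x1)
  expect_equal(out$category[out$member_id == "x3"], "singleton")
  expect_equal(out$category[out$member_id == "x1"], "multi_genome")

  # one genome, three mutually similar sequences: a single cluster of 3
  tri <- seq_records(c("t1", "t2", "t3"),
                     c(base, mutate_n(base, 1:10), mutate_n(base, 11:20)),
                     genome = "g1", taxon = "Metazoa")
  out2 <- cluster_rabx(tri, cfg)
  expect_equal(length(unique(out2$cluster_name)), 1L)
  expect_equal(nrow(out2), 3L)

  # partition invariant: disjoint cover, serial Novel names
  expect_equal(anyDuplicated(out$member_id), 0L)
  expect_setequal(out$member_id, rabx$id)
  expect_true(all(grepl("^Novel\\d+$", out$cluster_name)))
})

test_that("breadth categories follow the taxon > genome > size precedence", {
  expect_equal(categorize(2, 1, 3), "multi_taxon")
  expect_equal(categorize(1, 2, 3), "multi_genome")
  expect_equal(categorize(1, 1, 3), "single_genome_multi_member")
  expect_equal(categorize(1, 1, 1), "singleton")
})
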