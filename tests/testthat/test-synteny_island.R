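mk_rdha <- function(genome, contig, starts, widths = 1000L) {
  tibble::tibble(
    feature_id = sprintf("%s_r%d", genome, seq_along(starts)),
    genome_id = genome, contig_id = contig,
    start = as.integer(starts), end = as.integer(starts + widths - 1L),
    strand = "+"
  )
}

test_that("the 10 kb adjacency rule clusters and splits exactly", {
  # gap = start2 - end1 - 1
  two <- mk_rdha("g", "c", c(1, 11000))          # gap 9999 -> one cluster
  cl <- find_rdh_clusters(two, max_gap = 10000)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_members, 2L)
  expect_identical(cl$gaps[[1]], 9999L)
  split2 <- mk_rdha("g", "c", c(1, 11002))       # gap 10001 -> two clusters
  cl2 <- find_rdh_clusters(split2, max_gap = 10000)
  expect_identical(nrow(cl2), 2L)
  three <- mk_rdha("g", "c", c(1, 6001, 19002))  # gaps 5000 and 12000
  cl3 <- find_rdh_clusters(three, max_gap = 10000)
  expect_identical(sort(cl3$n_members), c(1L, 2L))
  expect_true(cl3$isolated[cl3$n_members == 1L])
})

test_that("cluster detection equals brute-force gap scan and ignores input order", {
  set.seed(51)
  for (rep in 1:50) {
    n <- sample(2:10, 1)
    starts <- sort(sample.int(80000, n)) * 3L
    widths <- sample(500:1500, n, replace = TRUE)
    feats <- mk_rdha("g", "c", starts, widths)
    feats$end <- feats$start + widths - 1L
    # guarantee non-overlap
    feats <- feats[c(TRUE, diff(feats$start) > widths[-n]), ]
    got <- find_rdh_clusters(feats, max_gap = 10000)
    want <- brute_gap_runs(feats$start, feats$end, 10000)
    expect_identical(sort(got$n_members), sort(as.integer(want)))
    shuffled <- feats[sample(nrow(feats)), ]
    got2 <- find_rdh_clusters(shuffled, max_gap = 10000)
    expect_identical(got$members, got2$members)
  }
})

test_that("truncation flags mark clusters near contig ends", {
  feats <- mk_rdha("g", "c", c(5000, 8000))
  lens <- tibble::tibble(genome_id = "g", contig_id = "c", length = 100000L)
  cl <- find_rdh_clusters(feats, max_gap = 10000, contig_len = lens)
  expect_true(cl$truncated_start)   # 4999 bp from the 5' end
  expect_false(cl$truncated_end)    # 91 kb from the 3' end
})

test_that("links respect tier identity bounds and best-match uniqueness", {
  ids <- c("a1", "a2", "b1", "b2", "b3")
  m <- matrix(50, 5, 5, dimnames = list(ids, ids)); diag(m) <- 100
  m["a1", "b1"] <- m["b1", "a1"] <- 93   # same OG -> solid
  m["a2", "b2"] <- m["b2", "a2"] <- 82   # umbrella tier
  m["a2", "b3"] <- m["b3", "a2"] <- 80   # weaker umbrella option
  part <- new_og_partition_for_test(
    ids = ids, labels = c("OG1", "U1", "OG1", "U2", "U2x"))
  umbrellas <- tibble::tibble(umbrella = "U", labels = list(c("U1", "U2")),
                              min_identity = 80, n_leaves = 2L)
  ca <- tibble::tibble(cluster_id = "A", genome_id = "gA", contig_id = "c",
                       start = 1L, end = 2000L, n_members = 2L,
                       members = list(c("a1", "a2")))
  cb <- tibble::tibble(cluster_id = "B", genome_id = "gB", contig_id = "c",
                       start = 1L, end = 3000L, n_members = 3L,
                       members = list(c("b1", "b2", "b3")))
  links <- link_clusters(ca, cb, part, umbrellas, m)
  expect_identical(links$tier[links$from == "a1"], "solid")
  expect_identical(links$to[links$from == "a1"], "b1")
  # a2-b2 share an umbrella at 82; a2-b3 do not share one
  expect_identical(links$to[links$from == "a2"], "b2")
  expect_identical(links$tier[links$from == "a2"], "umbrella")
  # every emitted link satisfies its tier bounds
  expect_true(all(links$identity[links$tier == "solid"] > 90))
  expect_true(all(links$identity[links$tier == "umbrella"] >= 75 &
                    links$identity[links$tier == "umbrella"] <= 90))
  expect_identical(anyDuplicated(links$from), 0L)
})

test_that("synteny conservation scores identical, disrupted and reversed clusters", {
  mk_cluster <- function(id, members) {
    tibble::tibble(cluster_id = id, genome_id = id, contig_id = "c",
                   start = 1L, end = 100L, n_members = length(members),
                   members = list(members))
  }
  a <- mk_cluster("A", c("x1", "x2", "x3"))
  links_identical <- tibble::tibble(from = c("x1", "x2", "x3"),
                                    to = c("y1", "y2", "y3"),
                                    i = 1:3, j = 1:3,
                                    tier = "solid", identity = 95)
  b <- mk_cluster("B", c("y1", "y2", "y3"))
  expect_equal(synteny_conservation(a, b, links_identical), 1)
  # reversed order in b remains reverse-colinear
  links_rev <- dplyr::mutate(links_identical, j = 3:1)
  expect_equal(synteny_conservation(a, b, links_rev), 1)
  # internal counterpart jumps break exactly the affected adjacency
  links_jump <- dplyr::mutate(links_identical, j = c(1L, 3L, 2L))
  expect_equal(synteny_conservation(a, b, links_jump), 0.5)
  # fewer than 2 links -> flagged NA
  expect_true(is.na(synteny_conservation(a, b, links_identical[1, ])))
})

test_that("island bounds are recovered exactly on the island fixture", {
  sim <- cached_fixture("island")
  scg_ids <- dplyr::filter(sim$truth$genes, category == "core")$feature_id
  for (gid in sim$truth$island$genome_id) {
    query <- dplyr::filter(sim$features, genome_id == gid,
                           grepl("isl_rdhA", feature_id))
    isl <- delimit_island(query, sim$genomes[[gid]], sim$features, scg_ids)
    truth <- dplyr::filter(sim$truth$island, genome_id == gid)
    expect_identical(isl$start, truth$start)
    expect_identical(isl$end, truth$end)
    expect_false(isl$open_start || isl$open_end)
    # flanks are the hotspot anchor and the gene 3' of it
    expect_match(isl$upstream_scg, "core")
    expect_match(isl$downstream_scg, "core")
  }
  # non-recipient genomes: the same flanks enclose only the empty ancestral
  # spacer (no island features)
  spacer_gid <- setdiff(names(sim$genomes), sim$truth$island$genome_id)[1]
  anchor <- dplyr::filter(sim$features, genome_id == spacer_gid,
                          feature_id == paste0(spacer_gid, "_core024"))
  isl0 <- delimit_island(anchor, sim$genomes[[spacer_gid]], sim$features, scg_ids)
  expect_lt(isl0$end - isl0$start, 5000)
})

test_that("query adjacent to a core gene starts at its inner edge", {
  g <- new_genome("g", c(c1 = strrep("ACGT", 2500)))
  feats <- tibble::tibble(
    feature_id = c("scg_up", "q", "scg_down"), genome_id = "g", contig_id = "c1",
    start = c(100L, 1001L, 5001L), end = c(1000L, 2000L, 6000L),
    strand = "+", kind = "CDS", product = "", is_pseudo = FALSE,
    is_partial = FALSE, pseudo_source = NA_character_
  )
  isl <- delimit_island(feats[2, ], g, feats, c("scg_up", "scg_down"))
  expect_identical(isl$start, 1001L)
  expect_identical(isl$end, 5000L)
  # open end when no downstream core gene exists
  isl_open <- delimit_island(feats[2, ], g, feats, "scg_up")
  expect_true(isl_open$open_end)
  expect_identical(isl_open$end, 10000L)
  expect_error(delimit_island(feats[2, ], g, feats, character(0)), "core")
})

test_that("island comparison reports shared blocks at the planted identity", {
  sim <- cached_fixture("island")
  scg_ids <- dplyr::filter(sim$truth$genes, category == "core")$feature_id
  isl <- purrr::map(c("A1", "B1"), function(gid) {
    q <- dplyr::filter(sim$features, genome_id == gid, grepl("isl_rdhA", feature_id))
    delimit_island(q, sim$genomes[[gid]], sim$features, scg_ids)
  })
  cmp <- compare_islands(isl[[1]], sim$genomes[["A1"]], isl[[2]], sim$genomes[["B1"]])
  expect_gte(nrow(cmp), 1)
  expect_lt(abs(attr(cmp, "mean_identity") - 98.5), 0.5)
  expect_gt(attr(cmp, "total_shared"),
            0.9 * (isl[[1]]$end - isl[[1]]$start + 1))
  # identical islands: one block covering everything at 100
  cmp_self <- compare_islands(isl[[1]], sim$genomes[["A1"]],
                              isl[[1]], sim$genomes[["A1"]])
  expect_identical(nrow(cmp_self), 1L)
  expect_equal(attr(cmp_self, "mean_identity"), 100)
  # unrelated sequences: zero blocks
  set.seed(52)
  rnd <- new_genome("rnd", c(c1 = paste(sample(c("A", "C", "G", "T"), 20000,
                                               replace = TRUE), collapse = "")))
  fake <- isl[[1]]; fake$genome_id <- "rnd"; fake$contig_id <- "c1"
  fake$start <- 1L; fake$end <- 20000L
  cmp0 <- compare_islands(fake, rnd, isl[[2]], sim$genomes[["B1"]])
  expect_identical(nrow(cmp0), 0L)
  expect_identical(attr(cmp0, "total_shared"), 0L)
})

test_that("MGE tallies follow the keyword table", {
  feats <- tibble::tibble(
    feature_id = sprintf("f%d", 1:7), genome_id = "g", contig_id = "c",
    start = 1:7 * 100L, end = 1:7 * 100L + 50L, strand = "+", kind = "CDS",
    product = c("IS256 family transposase", "putative transposase",
                "phage integrase", "phage integrase",
                "serine recombinase", "IS3 element protein",
                "DNA gyrase subunit A"),
    is_pseudo = FALSE, is_partial = FALSE, pseudo_source = NA_character_
  )
  tal <- mge_tally(feats)
  expect_identical(tal$transposon_is, 3L)      # includes the bare IS hit
  expect_identical(tal$conjugative_phage, 2L)
  expect_identical(tal$other_recombinase, 1L)
  expect_identical(tal$n_cds, 7L)
  # no matching products -> all zeros
  none <- dplyr::mutate(feats, product = "hypothetical protein")
  tal0 <- mge_tally(none)
  expect_identical(tal0$transposon_is + tal0$conjugative_phage +
                     tal0$other_recombinase, 0L)
  # tallies on the simulated island match its cargo design
  sim <- cached_fixture("island")
  scg_ids <- dplyr::filter(sim$truth$genes, category == "core")$feature_id
  q <- dplyr::filter(sim$features, genome_id == "A1", grepl("isl_rdhA", feature_id))
  isl <- delimit_island(q, sim$genomes[["A1"]], sim$features, scg_ids)
  tal_isl <- mge_tally(isl)
  expect_identical(tal_isl$transposon_is, 6L)
  expect_identical(tal_isl$conjugative_phage, 6L)
  expect_identical(tal_isl$other_recombinase, 2L)
})
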