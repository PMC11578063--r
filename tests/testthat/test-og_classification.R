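test_that("pairwise identity is symmetric, 100 on self, free at the ends", {
  set.seed(31)
  a <- random_protein(100)
  b <- mutate_to_identity(a, 0.90, seed = 1)
  expect_equal(pairwise_identity(a, a), 100)
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  # forced substitution count with no indels -> exactly 90
  expect_equal(pairwise_identity(a, b), 90)
  # free end gaps: appended residues cost nothing
  expect_equal(pairwise_identity(a, paste0(a, random_protein(10))), 100)
  expect_error(pairwise_identity("", a), "non-empty")
})

test_that("identity_matrix covers all pairs and matches pairwise_identity", {
  set.seed(32)
  seqs <- c(x = random_protein(80), y = random_protein(80))
  seqs["z"] <- mutate_to_identity(seqs[["x"]], 0.95, seed = 4)
  im <- identity_matrix(seqs)
  expect_identical(nrow(im), 3L)
  m <- identity_as_matrix(im)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_equal(m["x", "z"], pairwise_identity(seqs[["x"]], seqs[["z"]]))
})

test_that("OG assignment is single linkage with deterministic labels", {
  mk <- function(vals) {
    ids <- c("a", "b", "c")
    m <- matrix(100, 3, 3, dimnames = list(ids, ids))
    m["a", "b"] <- m["b", "a"] <- vals[1]
    m["b", "c"] <- m["c", "b"] <- vals[2]
    m["a", "c"] <- m["c", "a"] <- vals[3]
    m
  }
  p1 <- assign_ogs(mk(c(92, 91, 93)))
  expect_identical(unique(p1$label), "OG1")
  # chaining: a-c below threshold but linked through b
  p2 <- assign_ogs(mk(c(92, 91, 85)))
  expect_identical(unique(p2$label), "OG1")
  # below cutoff everywhere -> lettered singletons in lexicographic order
  p3 <- assign_ogs(mk(c(89, 80, 80)))
  expect_identical(p3$label[order(p3$id)], c("A", "B", "C"))
})

test_that("OG components equal a brute-force single-linkage on random matrices", {
  set.seed(33)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    ids <- sprintf("s%02d", 1:n)
    m <- matrix(runif(n * n, 50, 100), n, n, dimnames = list(ids, ids))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 100
    part <- assign_ogs(m, threshold = 90)
    got <- unname(lapply(split(part$id, part$label), sort))
    want <- brute_components(m, 90)
    expect_setequal(lapply(got, paste, collapse = "|"),
                    lapply(want, paste, collapse = "|"))
  }
})

test_that("NJ recovers a planted split with high bootstrap support", {
  set.seed(34)
  root <- random_protein(200)
  pA <- mutate_to_identity(root, 0.70, seed = 1)
  pB <- mutate_to_identity(root, 0.70, seed = 2)
  seqs <- c(A1 = mutate_to_identity(pA, 0.975, seed = 3),
            A2 = mutate_to_identity(pA, 0.975, seed = 4),
            B1 = mutate_to_identity(pB, 0.975, seed = 5),
            B2 = mutate_to_identity(pB, 0.975, seed = 6))
  im <- identity_matrix(seqs)
  aln <- Biostrings::AAStringSet(seqs)  # equal lengths: already aligned
  tree <- build_nj_tree(im, alignment = aln, bootstrap = 100, seed = 1)
  expect_true(dehalopan:::is_clan(tree, c("A1", "A2")))
  support <- as.integer(tree$node.label)
  expect_gte(max(support, na.rm = TRUE), 95)
  # determinism
  tree2 <- build_nj_tree(im, alignment = aln, bootstrap = 100, seed = 1)
  expect_identical(ape::write.tree(tree), ape::write.tree(tree2))
})

test_that("extreme p-distances are capped with a warning", {
  ids <- c("a", "b", "c")
  m <- matrix(2, 3, 3, dimnames = list(ids, ids))  # identity 2% -> p = 0.98
  diag(m) <- 100
  expect_warning(tree <- build_nj_tree(m, bootstrap = 0), "capped")
  expect_s3_class(tree, "phylo")
})

test_that("curation merges interleaved labels and absorbs nested singletons", {
  set.seed(35)
  anc <- random_protein(200)
  # OG {x1,x2} above the 95 cutoff; y shares x1's derived states (so it nests
  # inside the OG clade) but its extra divergence drops it below the cutoff
  x1 <- mutate_to_identity(anc, 0.98, seed = 1)
  x2 <- mutate_to_identity(anc, 0.98, seed = 2)
  y <- mutate_to_identity(x1, 0.93, seed = 3)
  far1 <- mutate_to_identity(anc, 0.60, seed = 4)
  far2 <- mutate_to_identity(far1, 0.97, seed = 5)
  seqs <- c(x1 = x1, x2 = x2, y = y, f1 = far1, f2 = far2)
  im <- identity_matrix(seqs)
  m <- identity_as_matrix(im)
  expect_gte(m["x1", "x2"], 95)
  expect_lt(m["x1", "y"], 95)
  part <- assign_ogs(im, threshold = 95)
  tree <- build_nj_tree(im, bootstrap = 0)
  expect_true(dehalopan:::is_clan(tree, c("x1", "y")))  # y nests next to x1
  cur <- curate_partition(part, tree, im)
  labs <- stats::setNames(cur$label, cur$id)
  expect_identical(labs[["x1"]], labs[["y"]])
  expect_identical(labs[["f1"]], labs[["f2"]])
  expect_false(labs[["x1"]] == labs[["f1"]])
  mp <- attr(cur, "merged_pairs")
  expect_gte(nrow(mp), 1)
  expect_equal(mp$min_cross_identity[1], min(m[c("x1", "x2"), "y"]))
  # two clean monophyletic labels stay unchanged
  part2 <- assign_ogs(im, threshold = 90)
  cur2 <- curate_partition(part2, tree, im)
  expect_identical(tidy(part2), tidy(cur2))
})

test_that("umbrella detection respects the 75% floor and maximality", {
  # constructed: OG(a,b) at 92, singleton c at ~80 to both, outgroup d at 40
  ids <- c("a", "b", "c", "d")
  m <- matrix(40, 4, 4, dimnames = list(ids, ids))
  diag(m) <- 100
  m["a", "b"] <- m["b", "a"] <- 92
  m["a", "c"] <- m["c", "a"] <- 80
  m["b", "c"] <- m["c", "b"] <- 80
  part <- assign_ogs(m)
  tree <- build_nj_tree(m, bootstrap = 0)
  umb <- detect_umbrellas(tree, m, part, floor = 75)
  expect_identical(nrow(umb), 1L)
  expect_setequal(umb$labels[[1]], unique(part$label[part$id %in% c("a", "b", "c")]))
  expect_gt(umb$min_identity, 75)
  # direct matrix lookup invariant for every emitted umbrella
  members <- part$id[part$label %in% umb$labels[[1]]]
  sub <- m[members, members]
  expect_gt(min(sub[upper.tri(sub)]), 75)
  # floor violation: push c down to 74
  m2 <- m
  m2["a", "c"] <- m2["c", "a"] <- 74
  umb2 <- detect_umbrellas(tree, m2, part, floor = 75)
  expect_false(any(purrr::map_lgl(umb2$labels, ~ "C" %in% .x && "OG1" %in% .x)))
})

test_that("clade concordance flags exactly the planted transfer", {
  sim <- cached_fixture("hgt-og")
  r <- retained_rdha(sim)
  im <- identity_matrix(r$seqs)
  part <- assign_ogs(im)
  tree <- build_nj_tree(im, bootstrap = 0)
  cur <- curate_partition(part, tree, im)
  clades <- stats::setNames(sim$truth$clades$clade, sim$truth$clades$genome_id)
  conc <- concordance_screen(cur, stats::setNames(r$retained$genome_id,
                                                  r$retained$protein_id),
                             clades, tree)
  transferred <- sim$truth$events$gene_id[sim$truth$events$type == "transfer"]
  tr_feature <- paste0(sim$truth$events$genome_id[1], "_", transferred)
  tr_label <- cur$label[cur$id == tr_feature]
  expect_identical(conc$verdict[conc$label == tr_label], "hgt_candidate")
  expect_true(all(conc$verdict[conc$label != tr_label] %in%
                    c("vertical", "not_applicable")))
  # the planted partition is recovered exactly
  truth_og <- stats::setNames(sim$truth$ogs$og, sim$truth$ogs$protein_id)
  expect_equal(mclust::adjustedRandIndex(cur$label, truth_og[cur$id]), 1)
})

test_that("an OG confined to one clade is not applicable", {
  tree <- ape::read.tree(text = "((p1:1,p2:1):1,(p3:1,p4:1):1);")
  res <- clade_concordance(
    tibble::tibble(rdha_id = c("p1", "p2"), genome_id = c("g1", "g2")),
    c(g1 = "A", g2 = "A"), tree
  )
  expect_identical(res$verdict, "not_applicable")
})
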