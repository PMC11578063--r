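test_that("mutate_to_identity places an exact substitution count", {
  set.seed(5)
  p <- random_protein(100)
  expect_identical(mutate_to_identity(p, 1.0, seed = 1), p)
  m <- mutate_to_identity(p, 0.90, seed = 2)
  diffs <- sum(strsplit(p, "")[[1]] != strsplit(m, "")[[1]])
  expect_identical(diffs, 10L)
  d <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  md <- mutate_to_identity(d, 0.95, seed = 3)
  expect_identical(sum(strsplit(d, "")[[1]] != strsplit(md, "")[[1]]), 10L)
  expect_error(mutate_to_identity(p, 1.5), "fraction")
  expect_error(mutate_to_identity(p, 0), "fraction")
})

test_that("two independent mutants of one parent can collide at some sites", {
  # brute-force expectation: two mutants at 0.95 of a length-200 parent differ
  # at <= 20 sites; expected pairwise identity ~0.902 but never below 0.90
  set.seed(6)
  p <- random_protein(200)
  ids <- replicate(30, {
    a <- mutate_to_identity(p, 0.95, seed = sample.int(1e6, 1))
    b <- mutate_to_identity(p, 0.95, seed = sample.int(1e6, 1))
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  })
  expect_true(all(ids >= 0.90))
  expect_lt(mean(ids), 0.93)
})

test_that("simulated divergence matches the Jukes-Cantor expectation", {
  sim <- cached_fixture("medium")
  tree <- ape::read.tree(text = sim$config$species_tree)
  d <- ape::cophenetic.phylo(tree)
  # compare realized spacer+gene divergence of two genome pairs to JC
  check_pair <- function(g1, g2) {
    s1 <- strsplit(as.character(sim$genomes[[g1]]$contigs[[1]]), "")[[1]]
    s2 <- strsplit(as.character(sim$genomes[[g2]]$contigs[[1]]), "")[[1]]
    # equal-length genomes by construction (no events in this fixture)
    expect_equal(length(s1), length(s2))
    p_obs <- mean(s1 != s2)
    p_exp <- 0.75 * (1 - exp(-4 * d[g1, g2] / 3))
    tol <- 3 * sqrt(p_exp * (1 - p_exp) / length(s1)) + 0.003  # frozen sites bias
    expect_lt(abs(p_obs - p_exp), max(tol, 0.004))
  }
  check_pair("A1", "A2")
  check_pair("A1", "B1")
})

test_that("within-clade genome identity exceeds every between-clade identity", {
  sim <- cached_fixture("medium")
  cl <- stats::setNames(sim$truth$clades$clade, sim$truth$clades$genome_id)
  ids <- names(sim$genomes)
  pid <- function(g1, g2) {
    s1 <- strsplit(as.character(sim$genomes[[g1]]$contigs[[1]]), "")[[1]]
    s2 <- strsplit(as.character(sim$genomes[[g2]]$contigs[[1]]), "")[[1]]
    mean(s1 == s2)
  }
  within <- c(); between <- c()
  for (i in 1:(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      v <- pid(ids[i], ids[j])
      if (cl[ids[i]] == cl[ids[j]]) within <- c(within, v) else between <- c(between, v)
    }
  }
  expect_gt(min(within), max(between))
  expect_gt(min(within), 0.98)
  expect_lt(max(between), 0.94)
})

test_that("the same seed reproduces byte-identical output; seeds differ", {
  s1 <- sim_fixture("small", seed = 4)
  s2 <- sim_fixture("small", seed = 4)
  s3 <- sim_fixture("small", seed = 5)
  expect_identical(purrr::map(s1$genomes, ~ as.character(.x$contigs)),
                   purrr::map(s2$genomes, ~ as.character(.x$contigs)))
  expect_identical(s1$features, s2$features)
  expect_false(identical(as.character(s1$genomes[[1]]$contigs),
                         as.character(s3$genomes[[1]]$contigs)))
})

test_that("island cargo exists only in carrier genomes and truth points at it", {
  sim <- cached_fixture("island")
  truth <- sim$truth$island
  expect_setequal(truth$genome_id, c("A1", "B1"))
  donor_seq <- as.character(sim$genomes[["B1"]]$contigs[[1]])
  cargo <- dplyr::filter(sim$features, genome_id == "B1",
                         grepl("isl_cargo01", feature_id))
  probe <- substr(donor_seq, cargo$start, cargo$end)
  for (gid in setdiff(names(sim$genomes), truth$genome_id)) {
    expect_false(grepl(probe, as.character(sim$genomes[[gid]]$contigs[[1]]),
                       fixed = TRUE))
  }
  # truth coordinates exactly bracket the island features
  for (gid in truth$genome_id) {
    row <- truth[truth$genome_id == gid, ]
    isl_feats <- dplyr::filter(sim$features, genome_id == gid,
                               grepl("_isl_", feature_id))
    expect_true(all(isl_feats$start >= row$start & isl_feats$end <= row$end))
    expect_identical(min(isl_feats$start), row$start)
  }
})

test_that("no-island configs carry an empty island truth table", {
  sim <- cached_fixture("small")
  expect_identical(nrow(sim$truth$island), 0L)
})

test_that("loss and duplication events land in genomes and truth", {
  cfg <- sim_config(seed = 9, n_clades = 2, genomes_per_clade = 2,
                    n_core_genes = 20, rdh_cluster_sizes = 3L,
                    losses = tibble::tibble(genome_id = "A2", gene_id = "core005"),
                    dups = tibble::tibble(genome_id = "B1", gene_id = "rdhA_c1p1"))
  sim <- simulate_pangenome(cfg)
  expect_false("A2_core005" %in% sim$features$feature_id)
  expect_true("A1_core005" %in% sim$features$feature_id)
  expect_true("B1_rdhA_c1p1_dup" %in% sim$features$feature_id)
  expect_setequal(sim$truth$events$type, c("loss", "duplication"))
})

test_that("island anchor lost from a carrier raises a config error", {
  cfg <- sim_config(seed = 2, n_clades = 2, genomes_per_clade = 2,
                    n_core_genes = 20, rdh_cluster_sizes = 3L,
                    island = list(donor = "B1", recipients = "A1",
                                  anchor_index = 12L),
                    losses = tibble::tibble(genome_id = "A1", gene_id = "core012"))
  expect_error(simulate_pangenome(cfg), "anchor")
})

test_that("emit_fixture writes a readable bundle", {
  dir <- withr::local_tempdir()
  emit_fixture("small", dir, seed = 1)
  expect_true(file.exists(file.path(dir, "A1.fna")))
  expect_true(file.exists(file.path(dir, "truth_clades.tsv")))
  back <- read_genome(file.path(dir, "A1.fna"), file.path(dir, "A1.gff3"),
                      genome_id = "A1")
  sim <- cached_fixture("small")
  expect_identical(as.character(back$genome$contigs),
                   as.character(sim$genomes[["A1"]]$contigs))
})
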