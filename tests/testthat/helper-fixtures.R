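# Shared fixtures: simulations are cached per test run so several test files
# can reuse them without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, seed = 1L) {
  key <- paste(name, seed, sep = "#")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- sim_fixture(name, seed = seed)
  }
  .fixture_cache[[key]]
}

# Retained planted rdhA proteins of a simulation (decoys and chance-motif
# core genes excluded via the truth table).
retained_rdha <- function(sim) {
  pt <- translate_features(sim$features, sim$genomes)
  sc <- screen_candidates(pt, sim$features)
  ret <- dplyr::semi_join(dplyr::filter(sc, verdict == "retained"),
                          sim$truth$ogs, by = "protein_id")
  seqs <- stats::setNames(pt$residues[match(ret$protein_id, pt$protein_id)],
                          ret$protein_id)
  list(screen = sc, retained = ret, seqs = seqs, proteins = pt)
}

new_og_partition_for_test <- function(ids, labels) {
  dehalopan:::new_og_partition(tibble::tibble(id = ids, label = labels),
                               threshold = 90)
}

random_protein <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H", "I",
                                           "K", "L", "M", "N", "P", "Q", "R", "S",
                                           "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Independent brute-force oracles ------------------------------------------

# Motif count: test every 8-residue window explicitly.
brute_motif_count <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  if (n < 8) return(0L)
  hits <- 0L
  for (i in 1:(n - 7)) {
    if (chars[i] == "C" && chars[i + 3] == "C" && chars[i + 7] == "C") hits <- hits + 1L
  }
  hits
}

# Single-linkage components by repeated set expansion.
brute_components <- function(m, threshold) {
  ids <- rownames(m)
  unassigned <- ids
  comps <- list()
  while (length(unassigned)) {
    comp <- unassigned[1]
    repeat {
      grow <- unique(unlist(lapply(comp, function(i) {
        ids[m[i, ] >= threshold & ids != i]
      })))
      new <- setdiff(intersect(grow, unassigned), comp)
      if (!length(new)) break
      comp <- c(comp, new)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    unassigned <- setdiff(unassigned, comp)
  }
  comps
}

# Gap-rule cluster scan by explicit pairwise walk.
brute_gap_runs <- function(starts, ends, max_gap) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  runs <- list(); cur <- 1L
  if (length(starts) >= 2) {
    for (k in 2:length(starts)) {
      if (starts[k] - ends[k - 1] - 1 > max_gap) {
        runs[[length(runs) + 1L]] <- cur:(k - 1)
        cur <- k
      }
    }
  }
  runs[[length(runs) + 1L]] <- cur:length(starts)
  lengths(runs)
}
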