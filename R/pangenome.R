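# Homologous gene clustering across genomes, single-copy core extraction,
# alignment homogeneity scoring, marker selection and the concatenated
# species tree.

# 4-mer Jaccard prescreen: unrelated proteins share essentially no 4-mers,
# homologues at >= 50% identity share many, so pairs below the screen are
# safely skipped before alignment.
kmer_sets <- function(seqs, k = 4L) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
}

#' Cluster homologous genes across genomes
#'
#' Builds edges between proteins at identity >= `min_identity`% over at
#' least `min_coverage`% of the shorter sequence, then takes connected
#' components as gene clusters (the graph realization of an MCL-style
#' pangenome clustering at desk scale).  Each cluster is aligned with the
#' package's center-star aligner.
#'
#' @param protein_tbl Tibble from [translate_features()] (columns
#'   `protein_id`, `genome_id`, `residues`).
#' @param min_identity Percent identity threshold (default 50).
#' @param min_coverage Percent of the shorter sequence that must be aligned
#'   (default 80).
#' @param prescreen_jaccard 4-mer Jaccard floor below which pairs are not
#'   aligned (default 0.03).
#' @return A tibble of class `gene_clusters` with columns `cluster_id`,
#'   `protein_id`, `genome_id`; attribute `alignments` is a named list of
#'   aligned `AAStringSet`s per cluster.
#' @export
cluster_genes <- function(protein_tbl, min_identity = 50, min_coverage = 80,
                          prescreen_jaccard = 0.03) {
  if (length(unique(protein_tbl$genome_id)) < 2L) {
    stop("need proteins from at least 2 genomes", call. = FALSE)
  }
  seqs <- stats::setNames(protein_tbl$residues, protein_tbl$protein_id)
  ids <- names(seqs)
  n <- length(ids)
  km <- kmer_sets(seqs)
  lens <- nchar(seqs)
  aa <- Biostrings::AAStringSet(seqs)
  # inverted k-mer index -> shared-k-mer counts per protein pair
  inv <- split(rep(seq_len(n), lengths(km)), unlist(km, use.names = FALSE))
  inv <- inv[lengths(inv) > 1L]
  pair_mats <- lapply(inv, function(v) {
    v <- sort(unique(v))
    if (length(v) < 2L) return(NULL)
    t(utils::combn(v, 2L))
  })
  edge_from <- character(0); edge_to <- character(0)
  pair_mat <- do.call(rbind, pair_mats)
  if (!is.null(pair_mat) && nrow(pair_mat)) {
    key <- paste(pair_mat[, 1], pair_mat[, 2])
    shared <- table(key)
    uk <- strsplit(names(shared), " ", fixed = TRUE)
    i_vec <- as.integer(vapply(uk, `[[`, character(1), 1L))
    j_vec <- as.integer(vapply(uk, `[[`, character(1), 2L))
    n_km <- lengths(km)
    jac <- as.integer(shared) /
      (n_km[i_vec] + n_km[j_vec] - as.integer(shared))
    keep <- jac >= prescreen_jaccard
    cand <- tibble::tibble(i = i_vec[keep], j = j_vec[keep])
    for (jj in unique(cand$j)) {
      i_cand <- cand$i[cand$j == jj]
      aln <- Biostrings::pairwiseAlignment(
        aa[i_cand], aa[[jj]], type = "overlap",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1
      )
      ncols <- nchar(as.character(Biostrings::alignedPattern(aln)))
      ident <- ifelse(ncols == 0, 0, 100 * Biostrings::nmatch(aln) / ncols)
      cover <- 100 * ncols / pmin(lens[i_cand], lens[jj])
      hit <- ident >= min_identity & cover >= min_coverage
      edge_from <- c(edge_from, ids[i_cand][hit])
      edge_to <- c(edge_to, rep(ids[jj], sum(hit)))
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edge_from, to = edge_to),
    directed = FALSE, vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)
  members <- split(ids, comp$membership[ids])
  ord <- order(-lengths(members), vapply(members, min, character(1)))
  members <- members[ord]
  cluster_ids <- sprintf("GC%04d", seq_along(members))
  assignment <- dplyr::bind_rows(unname(purrr::map2(members, cluster_ids, function(mem, cid) {
    tibble::tibble(cluster_id = cid, protein_id = mem)
  }))) |>
    dplyr::left_join(dplyr::select(protein_tbl, "protein_id", "genome_id"),
                     by = "protein_id")
  alignments <- stats::setNames(
    purrr::map(members, ~ align_center_star(seqs[.x])), cluster_ids)
  structure(assignment, alignments = alignments,
            class = c("gene_clusters", class(tibble::as_tibble(assignment))))
}

#' Copy-number profile of gene clusters
#'
#' @param clusters A `gene_clusters` table.
#' @param genome_ids Optional full genome set (so genomes with zero copies
#'   appear).
#' @return Tibble `cluster_id` x `genome_id` with `n_copies`.
#' @export
copy_number <- function(clusters, genome_ids = NULL) {
  genome_ids <- genome_ids %||% unique(clusters$genome_id)
  tidyr::expand_grid(cluster_id = unique(clusters$cluster_id),
                     genome_id = genome_ids) |>
    dplyr::left_join(
      dplyr::count(tibble::as_tibble(clusters), .data$cluster_id, .data$genome_id,
                   name = "n_copies"),
      by = c("cluster_id", "genome_id")
    ) |>
    dplyr::mutate(n_copies = tidyr::replace_na(.data$n_copies, 0L))
}

#' Single-copy core clusters
#'
#' Clusters present exactly once in every genome: the marker candidates for
#' phylogenomics and the anchors for genomic-island delimitation.
#'
#' @inheritParams copy_number
#' @return Tibble with `cluster_id` (one row per single-copy core cluster).
#' @export
single_copy_core <- function(clusters, genome_ids = NULL) {
  copy_number(clusters, genome_ids) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(scc = all(.data$n_copies == 1L), .groups = "drop") |>
    dplyr::filter(.data$scc) |>
    dplyr::select("cluster_id")
}

#' Geometric and functional homogeneity of a cluster alignment
#'
#' Geometric homogeneity measures gap-pattern agreement: 1 minus the mean
#' over columns of the fraction of member pairs that disagree in gap /
#' non-gap state.  Functional homogeneity measures residue conservation:
#' the mean over non-fully-gapped columns of the modal residue's frequency
#' among non-gap members.  Both lie in `[0, 1]`; identical ungapped
#' sequences score 1 on both.
#'
#' @param alignment An aligned `AAStringSet` (>= 2 members).
#' @return One-row tibble: `geometric`, `functional`.
#' @export
homogeneity <- function(alignment) {
  if (length(alignment) < 2L) {
    stop("homogeneity undefined for single-member clusters", call. = FALSE)
  }
  mat <- alignment_as_matrix(alignment)
  n <- nrow(mat)
  n_pairs <- n * (n - 1) / 2
  gap <- mat == "-"
  n_gap <- colSums(gap)
  disagree <- n_gap * (n - n_gap) / n_pairs
  geometric <- 1 - mean(disagree)
  keep <- n_gap < n
  modal_freq <- vapply(which(keep), function(j) {
    col <- mat[!gap[, j], j]
    max(table(col)) / length(col)
  }, numeric(1))
  tibble::tibble(geometric = geometric, functional = mean(modal_freq))
}

#' Score homogeneity for many clusters
#'
#' @param clusters A `gene_clusters` table (its `alignments` attribute is
#'   used).
#' @param cluster_ids Clusters to score (default: all with >= 2 members).
#' @return Tibble `cluster_id`, `geometric`, `functional`.
#' @export
homogeneity_scores <- function(clusters, cluster_ids = NULL) {
  alns <- attr(clusters, "alignments")
  cluster_ids <- cluster_ids %||% names(alns)[lengths(alns) >= 2L]
  purrr::map_dfr(cluster_ids, function(cid) {
    dplyr::bind_cols(tibble::tibble(cluster_id = cid), homogeneity(alns[[cid]]))
  })
}

#' Select phylogenomic markers
#'
#' Ranks scored single-copy core clusters by (geometric descending,
#' functional ascending) -- favouring clean alignments whose residues still
#' vary enough to resolve strains -- and takes the top `n` (the study-scale
#' convention is 42).  Ties break by cluster id.
#'
#' @param scored Tibble with `cluster_id`, `geometric`, `functional`.
#' @param n Number of markers to keep.
#' @return The selected rows, ranked.
#' @export
select_markers <- function(scored, n = 42L) {
  if (nrow(scored) < n) {
    warning(sprintf("only %d candidates available (requested %d)", nrow(scored), n))
  }
  scored |>
    dplyr::arrange(dplyr::desc(.data$geometric), .data$functional, .data$cluster_id) |>
    utils::head(n)
}

#' Concatenated marker tree
#'
#' Concatenates the per-genome aligned sequences of the selected single-copy
#' core markers, computes Poisson-corrected distances and builds a
#' neighbour-joining tree.  Bootstrap resamples whole markers (genes) with
#' replacement, respecting gene-level correlation.
#'
#' @param markers Tibble with `cluster_id` (e.g. from [select_markers()]).
#' @param clusters The `gene_clusters` the markers come from.
#' @param bootstrap Number of replicates (default 100).
#' @param seed Integer seed.
#' @return A `phylo` over the genomes, with bootstrap support counts in
#'   `node.label` when `bootstrap > 0`.
#' @export
concat_tree <- function(markers, clusters, bootstrap = 100L, seed = 1L) {
  alns <- attr(clusters, "alignments")
  tbl <- tibble::as_tibble(clusters)
  genome_ids <- sort(unique(tbl$genome_id))
  if (length(genome_ids) < 3L) stop("need at least 3 genomes", call. = FALSE)
  # per-marker matrix with rows renamed genome -> aligned row
  marker_mats <- purrr::map(markers$cluster_id, function(cid) {
    mem <- dplyr::filter(tbl, .data$cluster_id == cid)
    mat <- alignment_as_matrix(alns[[cid]])[mem$protein_id, , drop = FALSE]
    rownames(mat) <- mem$genome_id
    mat[genome_ids, , drop = FALSE]
  })
  tree_from <- function(mats) {
    big <- do.call(cbind, mats)
    ape::nj(corrected_dist(alignment_identity(big)))
  }
  tree <- tree_from(marker_mats)
  if (bootstrap > 0L && length(marker_mats) > 1L) {
    reps <- with_seed(seed, {
      lapply(seq_len(bootstrap), function(i) {
        tree_from(sample(marker_mats, replace = TRUE))
      })
    })
    supports <- ape::prop.clades(tree, reps, rooted = FALSE)
    supports[is.na(supports)] <- 0L
    tree$node.label <- as.character(supports)
  }
  tree
}
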