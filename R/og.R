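# Orthologue-group classification of RdhA sequences.

#' Assign orthologue groups at an identity cutoff
#'
#' Single-linkage components of the graph whose edges join sequence pairs at
#' identity >= `threshold` (the field's 90% amino-acid identity convention).
#' Components of size >= 2 are numbered `OG1`, `OG2`, ... in order of (size
#' descending, lexicographically smallest member); singleton components get
#' letter labels (A..Z, AA, ...) in lexicographic order of member id.
#'
#' @param identity An [identity_matrix()] table (or symmetric matrix).
#' @param threshold Percent identity cutoff (default 90).
#' @return An `og_partition`: tibble with columns `id`, `label`, plus
#'   attributes `threshold` and `merged_pairs` (empty until
#'   [curate_partition()]).
#' @export
assign_ogs <- function(identity, threshold = 90) {
  m <- if (is.matrix(identity)) identity else identity_as_matrix(identity)
  ids <- rownames(m)
  edges <- which(m >= threshold & upper.tri(m), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]]),
    directed = FALSE, vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)
  members <- split(ids, comp$membership[ids])
  sizes <- lengths(members)
  groups <- members[sizes >= 2L]
  singles <- members[sizes == 1L]
  ord <- order(-lengths(groups), vapply(groups, min, character(1)))
  groups <- groups[ord]
  singles <- singles[order(vapply(singles, min, character(1)))]
  group_tbl <- dplyr::bind_rows(unname(purrr::map2(
    groups, seq_along(groups),
    function(mem, i) tibble::tibble(id = sort(mem), label = paste0("OG", i))
  )))
  single_tbl <- if (length(singles)) {
    tibble::tibble(id = unlist(singles, use.names = FALSE),
                   label = letter_labels(length(singles)))
  } else NULL
  assignment <- dplyr::bind_rows(group_tbl, single_tbl)
  assignment <- dplyr::arrange(assignment, .data$id)
  new_og_partition(assignment, threshold = threshold)
}

new_og_partition <- function(assignment, threshold,
                             merged_pairs = NULL) {
  merged_pairs <- merged_pairs %||% tibble::tibble(
    label_kept = character(), label_merged = character(), min_cross_identity = numeric())
  structure(assignment,
            threshold = threshold, merged_pairs = merged_pairs,
            class = c("og_partition", class(tibble::as_tibble(assignment))))
}

#' @export
print.og_partition <- function(x, ...) {
  labs <- table(x$label)
  cat(sprintf("<og_partition> %d sequences, %d OGs, %d singletons (threshold %s%%)\n",
              nrow(x), sum(labs >= 2), sum(labs == 1), attr(x, "threshold")))
  NextMethod()
}

#' @method tidy og_partition
#' @export
tidy.og_partition <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("id", "label")])
}

#' @method glance og_partition
#' @export
glance.og_partition <- function(x, ...) {
  labs <- table(x$label)
  tibble::tibble(
    n_sequences = nrow(x),
    n_ogs = sum(labs >= 2),
    n_singletons = sum(labs == 1),
    n_merges = nrow(attr(x, "merged_pairs")),
    threshold = attr(x, "threshold")
  )
}

# Is `tips` a clan of the (possibly unrooted) tree, i.e. separable by one
# edge?  Realized by rooting at any leaf outside the set.
is_clan <- function(tree, tips) {
  tips <- intersect(tips, tree$tip.label)
  k <- length(tips)
  n <- ape::Ntip(tree)
  if (k <= 1L || k >= n - 1L) return(TRUE)
  out <- setdiff(tree$tip.label, tips)[1]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}

#' Neighbour-joining gene tree from identities
#'
#' Distances are Poisson-corrected p-distances,
#' `d = -(19/20) * log(1 - (20/19) * p)` with `p = 1 - identity/100`;
#' p >= 0.95 (where the correction diverges) is capped at a documented
#' maximum with a warning.  Bootstrap supports come from column resampling
#' of the supplied multiple alignment (required for supports; omit it to
#' skip the bootstrap).
#'
#' @param identity An [identity_matrix()] table or symmetric matrix.
#' @param alignment Optional aligned `AAStringSet` over the same ids (e.g.
#'   from the package's center-star aligner) used for bootstrap resampling.
#' @param bootstrap Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the resampling.
#' @return An unrooted `phylo`; when bootstrapped, `node.label` carries
#'   support counts out of `bootstrap`.
#' @export
build_nj_tree <- function(identity, alignment = NULL, bootstrap = 100L, seed = 1L) {
  m <- if (is.matrix(identity)) identity else identity_as_matrix(identity)
  if (nrow(m) < 3L) stop("need at least 3 sequences for a tree", call. = FALSE)
  tree <- ape::nj(corrected_dist(m))
  if (!is.null(alignment) && bootstrap > 0L) {
    aln <- alignment_as_matrix(alignment)
    aln <- aln[tree$tip.label, , drop = FALSE]
    reps <- with_seed(seed, {
      lapply(seq_len(bootstrap), function(i) {
        cols <- sample.int(ncol(aln), replace = TRUE)
        ape::nj(corrected_dist(alignment_identity(aln[, cols, drop = FALSE])))
      })
    })
    supports <- ape::prop.clades(tree, reps, rooted = FALSE)
    supports[is.na(supports)] <- 0L
    tree$node.label <- as.character(supports)
  }
  tree
}

corrected_dist <- function(identity_matrix) {
  p <- 1 - identity_matrix / 100
  cap <- p >= 0.95
  if (any(cap & upper.tri(p))) {
    warning("p-distance >= 0.95 capped before Poisson correction")
    p[cap] <- 0.9499
  }
  d <- -(19 / 20) * log(1 - (20 / 19) * p)
  stats::as.dist(d)
}

# All splits of an unrooted tree as leaf sets (one side per edge), plus the
# full leaf set.
tree_splits <- function(tree) {
  n <- ape::Ntip(tree)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  splits <- lapply(seq_len(nrow(tree$edge)), function(e) desc[[tree$edge[e, 2]]])
  c(splits, list(tree$tip.label))
}

# Smallest clan (edge-defined leaf set, or its complement) containing all of
# `tips` -- the unrooted analogue of "the clade spanned by a label".
min_clan <- function(splits, all_tips, tips) {
  best <- all_tips
  for (s in splits) {
    if (all(tips %in% s) && length(s) < length(best)) best <- s
    comp <- setdiff(all_tips, s)
    if (all(tips %in% comp) && length(comp) < length(best)) best <- comp
  }
  best
}

# Two labels interleave when the minimal clan spanned by one captures members
# of the other (so neither comprises a single unique clade of its own).
labels_interleave <- function(splits, all_tips, ta, tb) {
  ca <- min_clan(splits, all_tips, ta)
  cb <- min_clan(splits, all_tips, tb)
  any(tb %in% ca) || any(ta %in% cb)
}

#' Curate an OG partition with a gene tree
#'
#' Merges label pairs whose leaf sets interleave on the tree: the minimal
#' clan spanned by one label's members captures members of the other (so
#' neither comprises a single unique clade).  This
#' resolves orthologue groups split by the hard identity cutoff and absorbs
#' singletons nested inside an OG clade.  The minimum cross identity of each
#' merge is recorded (not enforced).
#'
#' @param partition An [assign_ogs()] result.
#' @param tree A `phylo` whose leaves cover the partition members.
#' @param identity The identity table/matrix used for the record.
#' @return A curated `og_partition` with the `merged_pairs` attribute filled.
#' @export
curate_partition <- function(partition, tree, identity) {
  m <- if (is.matrix(identity)) identity else identity_as_matrix(identity)
  labels <- unique(partition$label)
  members <- split(partition$id, partition$label)[labels]
  parent <- stats::setNames(seq_along(labels), labels)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  merges <- list()
  splits <- tree_splits(tree)
  if (length(labels) >= 2L) {
    for (pair in utils::combn(seq_along(labels), 2L, simplify = FALSE)) {
      la <- labels[pair[1]]; lb <- labels[pair[2]]
      ta <- members[[la]]; tb <- members[[lb]]
      if (!all(c(ta, tb) %in% tree$tip.label)) next
      if (labels_interleave(splits, tree$tip.label, ta, tb)) {
        cross <- min(m[ta, tb, drop = FALSE])
        # keep the lexicographically earlier OG label; letters yield to OGs
        keep_a <- grepl("^OG", la) || !grepl("^OG", lb)
        kept <- if (keep_a) la else lb
        merged <- if (keep_a) lb else la
        merges[[length(merges) + 1L]] <- tibble::tibble(
          label_kept = kept, label_merged = merged, min_cross_identity = cross)
        ra <- find(pair[1]); rb <- find(pair[2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  merged_pairs <- dplyr::bind_rows(merges) %||% NULL
  if (length(merges)) {
    root_of <- vapply(seq_along(labels), find, integer(1))
    # representative label per merged component: prefer OG labels, then first
    rep_label <- vapply(split(labels, root_of), function(ls) {
      ogs <- ls[grepl("^OG", ls)]
      if (length(ogs)) ogs[1] else ls[1]
    }, character(1))
    map <- stats::setNames(rep_label[as.character(root_of)], labels)
    assignment <- dplyr::mutate(tidy(partition), label = unname(map[.data$label]))
  } else {
    assignment <- tidy(partition)
  }
  new_og_partition(assignment, threshold = attr(partition, "threshold"),
                   merged_pairs = if (length(merges)) merged_pairs else NULL)
}

#' Detect OG/singleton umbrellas
#'
#' For each label's clade, walk one node rootward; if every leaf pair under
#' that parent node stays above the identity floor (default 75%) and the node
#' covers at least two labels, the covered labels form an umbrella.  Only
#' maximal umbrellas are kept (none nested inside another).
#'
#' @param tree A rooted or unrooted `phylo` (unrooted trees are midpoint
#'   rooted internally for ancestor lookups).
#' @param identity Identity table/matrix over the leaves.
#' @param partition Curated `og_partition`.
#' @param floor Identity floor in percent (default 75).
#' @return Tibble with columns `umbrella`, `labels` (list-column),
#'   `min_identity`, `n_leaves`.
#' @export
detect_umbrellas <- function(tree, identity, partition, floor = 75) {
  m <- if (is.matrix(identity)) identity else identity_as_matrix(identity)
  rooted <- if (ape::is.rooted(tree)) tree else phangorn::midpoint(tree)
  label_of <- stats::setNames(partition$label, partition$id)
  n_tip <- ape::Ntip(rooted)
  candidates <- list()
  for (lab in unique(partition$label)) {
    mem <- intersect(partition$id[partition$label == lab], rooted$tip.label)
    if (!length(mem)) next
    node <- if (length(mem) == 1L) {
      match(mem, rooted$tip.label)
    } else {
      ape::getMRCA(rooted, mem)
    }
    parent_edge <- rooted$edge[rooted$edge[, 2] == node, 1]
    if (!length(parent_edge)) next
    leaves <- ape::extract.clade(rooted, parent_edge)$tip.label
    sub <- m[leaves, leaves, drop = FALSE]
    min_id <- min(sub[upper.tri(sub)])
    labs <- sort(unique(label_of[leaves]))
    if (min_id > floor && length(labs) >= 2L) {
      candidates[[length(candidates) + 1L]] <- list(
        leaves = leaves, labels = labs, min_identity = min_id)
    }
  }
  if (!length(candidates)) {
    return(tibble::tibble(umbrella = character(), labels = list(),
                          min_identity = numeric(), n_leaves = integer()))
  }
  # maximal only
  keep <- rep(TRUE, length(candidates))
  for (i in seq_along(candidates)) {
    for (j in seq_along(candidates)) {
      if (i != j && keep[i] &&
          all(candidates[[i]]$leaves %in% candidates[[j]]$leaves) &&
          length(candidates[[i]]$leaves) < length(candidates[[j]]$leaves)) {
        keep[i] <- FALSE
      }
    }
  }
  candidates <- candidates[keep]
  # dedupe identical leaf sets
  sig <- vapply(candidates, function(cc) paste(sort(cc$leaves), collapse = "|"), character(1))
  candidates <- candidates[!duplicated(sig)]
  tibble::tibble(
    umbrella = paste0("U", seq_along(candidates)),
    labels = purrr::map(candidates, "labels"),
    min_identity = purrr::map_dbl(candidates, "min_identity"),
    n_leaves = purrr::map_int(candidates, ~ length(.x$leaves))
  )
}

#' Clade-concordance screen for one orthologue group
#'
#' Tests whether an OG's gene tree is compatible with vertical descent:
#' the gene tree is restricted to the OG's members and each genome clade
#' with >= 2 members is tested for monophyly (clan on the unrooted subtree).
#' Zero violations reads as vertical inheritance; any violation flags the OG
#' as a horizontal-transfer candidate.
#'
#' @param og_members Tibble with columns `rdha_id`, `genome_id`.
#' @param clades Named vector (genome -> clade) or tibble with `genome_id`,
#'   `clade`.
#' @param gene_tree A `phylo` over (at least) the OG's rdhA ids.
#' @return One-row tibble: `n_members`, `n_clades`, `violations`, `verdict`
#'   (`vertical`, `hgt_candidate` or `not_applicable`).
#' @export
clade_concordance <- function(og_members, clades, gene_tree) {
  if (is.data.frame(clades)) clades <- stats::setNames(clades$clade, clades$genome_id)
  og_members <- dplyr::mutate(og_members, clade = unname(clades[.data$genome_id]))
  n_mem <- nrow(og_members)
  n_clades <- length(unique(og_members$clade))
  if (n_mem < 3L || n_clades < 2L) {
    return(tibble::tibble(n_members = n_mem, n_clades = n_clades,
                          violations = NA_integer_, verdict = "not_applicable"))
  }
  sub <- ape::keep.tip(gene_tree, intersect(og_members$rdha_id, gene_tree$tip.label))
  violations <- 0L
  for (cl in unique(og_members$clade)) {
    tips <- og_members$rdha_id[og_members$clade == cl]
    tips <- intersect(tips, sub$tip.label)
    if (length(tips) >= 2L && !is_clan(sub, tips)) violations <- violations + 1L
  }
  tibble::tibble(n_members = n_mem, n_clades = n_clades, violations = violations,
                 verdict = ifelse(violations == 0L, "vertical", "hgt_candidate"))
}

#' Concordance screen across a whole partition
#'
#' Applies [clade_concordance()] to every label of a partition.
#'
#' @param partition An `og_partition`.
#' @param genome_of Named vector protein id -> genome id (or tibble with
#'   `protein_id`, `genome_id`).
#' @param clades Genome -> clade mapping (vector or tibble).
#' @param gene_tree `phylo` over the partition members.
#' @return Tibble with one row per label plus the [clade_concordance()]
#'   columns.
#' @export
concordance_screen <- function(partition, genome_of, clades, gene_tree) {
  if (is.data.frame(genome_of)) {
    genome_of <- stats::setNames(genome_of$genome_id, genome_of$protein_id)
  }
  purrr::map_dfr(unique(partition$label), function(lab) {
    mem <- partition$id[partition$label == lab]
    res <- clade_concordance(
      tibble::tibble(rdha_id = mem, genome_id = unname(genome_of[mem])),
      clades, gene_tree
    )
    dplyr::bind_cols(tibble::tibble(label = lab), res)
  })
}
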