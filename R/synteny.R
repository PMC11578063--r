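# RDase cluster detection by genomic adjacency, cross-genome synteny links,
# genomic-island delimitation by flanking core genes, and MGE keyword
# tallies.

#' Detect RDase clusters by adjacency
#'
#' Maximal runs of rdhA features on one contig where each inter-feature gap
#' (end of one to start of the next, exclusive of both boundaries) is at
#' most `max_gap` (the 10 kb adjacency rule).  Isolated rdhA emerge as
#' size-1 clusters flagged `isolated`; truncation flags mark clusters whose
#' outermost member lies within `max_gap` of a contig end (the cluster may
#' continue past an assembly break).
#'
#' @param rdha_features Feature tibble restricted to retained rdhA (columns
#'   `feature_id`, `genome_id`, `contig_id`, `start`, `end`, `strand`).
#' @param max_gap Maximum gap in bp (default 10000).
#' @param contig_len Named vector contig id -> length (or a tibble
#'   `genome_id`, `contig_id`, `length`) used for truncation flags; omit to
#'   skip them.
#' @return Tibble of class `rdh_clusters`: `cluster_id`, `genome_id`,
#'   `contig_id`, `start`, `end`, `n_members`, `members` (list-column of
#'   feature ids 5'->3'), `gaps` (list-column), `isolated`,
#'   `truncated_start`, `truncated_end`.
#' @export
find_rdh_clusters <- function(rdha_features, max_gap = 10000L, contig_len = NULL) {
  if (is.data.frame(contig_len)) {
    contig_len <- stats::setNames(contig_len$length,
                                  paste(contig_len$genome_id, contig_len$contig_id))
  }
  feats <- dplyr::arrange(rdha_features, .data$genome_id, .data$contig_id, .data$start)
  out <- feats |>
    dplyr::group_by(.data$genome_id, .data$contig_id) |>
    dplyr::group_map(function(grp, key) {
      gap_prev <- c(Inf, grp$start[-1] - grp$end[-nrow(grp)] - 1L)
      run <- cumsum(gap_prev > max_gap)
      purrr::map_dfr(split(seq_len(nrow(grp)), run), function(idx) {
        rows <- grp[idx, ]
        clen <- if (is.null(contig_len)) NA_integer_ else {
          unname(contig_len[paste(key$genome_id, key$contig_id)])
        }
        tibble::tibble(
          genome_id = key$genome_id, contig_id = key$contig_id,
          start = min(rows$start), end = max(rows$end),
          n_members = nrow(rows),
          members = list(rows$feature_id),
          gaps = list(if (nrow(rows) > 1L) rows$start[-1] - rows$end[-nrow(rows)] - 1L
                      else integer(0)),
          isolated = nrow(rows) == 1L,
          truncated_start = isTRUE((min(rows$start) - 1L) <= max_gap & !is.na(clen)),
          truncated_end = isTRUE((clen - max(rows$end)) <= max_gap)
        )
      })
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$genome_id, .data$contig_id, .data$start)
  out$cluster_id <- sprintf("%s_rc%d", out$genome_id,
                            stats::ave(seq_len(nrow(out)), out$genome_id,
                                       FUN = seq_along))
  out <- dplyr::relocate(out, "cluster_id")
  structure(out, class = c("rdh_clusters", class(tibble::as_tibble(out))))
}

#' Synteny links between two RDase clusters
#'
#' Solid links join cross-cluster member pairs in the same orthologue group
#' (>90% identity tier); umbrella links join pairs whose labels co-occur in
#' an umbrella and whose identity lies in `[75, 90]`.  Each member links to
#' at most one counterpart per tier (best identity wins; ties go to the
#' smaller index).
#'
#' @param a,b Rows (one each) of a [find_rdh_clusters()] table.
#' @param partition Curated `og_partition` over the members.
#' @param umbrellas [detect_umbrellas()] table.
#' @param identity Identity table/matrix over the members.
#' @return Tibble: `from`, `to` (feature ids), `i`, `j` (member indices),
#'   `tier` (`solid`/`umbrella`), `identity`.
#' @export
link_clusters <- function(a, b, partition, umbrellas, identity) {
  m <- if (is.matrix(identity)) identity else identity_as_matrix(identity)
  label_of <- stats::setNames(partition$label, partition$id)
  mem_a <- a$members[[1]]; mem_b <- b$members[[1]]
  shared_umbrella <- function(la, lb) {
    any(purrr::map_lgl(umbrellas$labels, ~ la %in% .x && lb %in% .x))
  }
  cand <- tidyr::expand_grid(i = seq_along(mem_a), j = seq_along(mem_b)) |>
    dplyr::mutate(
      from = mem_a[.data$i], to = mem_b[.data$j],
      identity = m[cbind(.data$from, .data$to)],
      la = unname(label_of[.data$from]), lb = unname(label_of[.data$to])
    ) |>
    dplyr::mutate(tier = dplyr::case_when(
      .data$la == .data$lb ~ "solid",
      .data$identity >= 75 & .data$identity <= 90 &
        purrr::map2_lgl(.data$la, .data$lb, shared_umbrella) ~ "umbrella",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$tier))
  if (!nrow(cand)) {
    return(tibble::tibble(from = character(), to = character(), i = integer(),
                          j = integer(), tier = character(), identity = numeric()))
  }
  # best counterpart per member per tier, both directions
  best <- cand |>
    dplyr::arrange(dplyr::desc(.data$identity), .data$i, .data$j) |>
    dplyr::group_by(.data$tier, .data$i) |>
    dplyr::slice(1L) |>
    dplyr::group_by(.data$tier, .data$j) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  dplyr::select(best, "from", "to", "i", "j", "tier", "identity") |>
    dplyr::arrange(.data$i)
}

#' Synteny conservation between two linked clusters
#'
#' Fraction of adjacent linked member pairs in `a` whose counterparts are
#' also adjacent in `b`; whole-cluster reversals count as conserved
#' (reverse-colinear), matching orientation-free cluster comparisons.
#'
#' @param a,b Cluster rows (as in [link_clusters()]).
#' @param links A [link_clusters()] table for this cluster pair.
#' @return Fraction in `[0, 1]`, or `NA` (flagged by attribute `reason`)
#'   when fewer than 2 members of `a` are linked.
#' @export
synteny_conservation <- function(a, b, links) {
  mem_a <- a$members[[1]]
  # best link per a-member (any tier, solid preferred)
  lk <- links |>
    dplyr::mutate(tier_rank = ifelse(.data$tier == "solid", 0L, 1L)) |>
    dplyr::arrange(.data$tier_rank, dplyr::desc(.data$identity)) |>
    dplyr::distinct(.data$i, .keep_all = TRUE)
  j_of <- stats::setNames(lk$j, lk$i)
  linked_i <- sort(as.integer(names(j_of)))
  if (length(linked_i) < 2L) {
    return(structure(NA_real_, reason = "fewer than 2 linked members"))
  }
  adj <- 0L; conserved <- 0L
  for (k in seq_len(length(linked_i) - 1L)) {
    i1 <- linked_i[k]; i2 <- linked_i[k + 1L]
    if (i2 - i1 != 1L) next  # only adjacent pairs in a
    adj <- adj + 1L
    d <- j_of[[as.character(i2)]] - j_of[[as.character(i1)]]
    if (abs(d) == 1L) conserved <- conserved + 1L
  }
  if (adj == 0L) return(structure(NA_real_, reason = "no adjacent linked pairs"))
  conserved / adj
}

#' Delimit a genomic island by flanking core genes
#'
#' The island spans from the inner boundary of the nearest single-copy core
#' gene upstream of the query locus to the inner boundary of the nearest one
#' downstream (the flanking genes themselves are excluded; set
#' `inclusive = TRUE` to include them).  Where a side has no core gene the
#' island extends to the contig end and is flagged open.
#'
#' @param query One feature row (or a list with `contig_id`, `start`, `end`)
#'   on a single contig.
#' @param genome The `genome` object.
#' @param features Feature tibble for the genome.
#' @param scg_features Character vector of feature ids belonging to
#'   single-copy core clusters (the SCG map).
#' @param inclusive Include the flanking core genes in the island bounds.
#' @return One-row tibble of class `genomic_island`: `genome_id`,
#'   `contig_id`, `start`, `end`, `upstream_scg`, `downstream_scg`,
#'   `open_start`, `open_end`, `n_enclosed`, `enclosed` (list-column of
#'   enclosed feature rows).
#' @export
delimit_island <- function(query, genome, features, scg_features,
                           inclusive = FALSE) {
  if (!length(scg_features)) stop("no single-copy core map supplied", call. = FALSE)
  qc <- query$contig_id[[1]]
  if (length(unique(query$contig_id)) > 1L) {
    stop("query spans multiple contigs", call. = FALSE)
  }
  qs <- min(query$start); qe <- max(query$end)
  feats <- dplyr::filter(features, .data$genome_id == genome$genome_id,
                         .data$contig_id == qc)
  scg <- dplyr::filter(feats, .data$feature_id %in% scg_features)
  up <- dplyr::filter(scg, .data$end < qs)
  down <- dplyr::filter(scg, .data$start > qe)
  clen <- contig_lengths(genome)[[qc]]
  if (nrow(up)) {
    up_row <- up[which.max(up$end), ]
    start <- if (inclusive) up_row$start else up_row$end + 1L
    upstream <- up_row$feature_id
    open_start <- FALSE
  } else {
    start <- 1L; upstream <- NA_character_; open_start <- TRUE
  }
  if (nrow(down)) {
    down_row <- down[which.min(down$start), ]
    end <- if (inclusive) down_row$end else down_row$start - 1L
    downstream <- down_row$feature_id
    open_end <- FALSE
  } else {
    end <- clen; downstream <- NA_character_; open_end <- TRUE
  }
  isl_start <- start; isl_end <- end
  enclosed <- dplyr::filter(feats, .data$start >= .env$isl_start,
                            .data$end <= .env$isl_end)
  out <- tibble::tibble(
    genome_id = genome$genome_id, contig_id = qc, start = start, end = end,
    upstream_scg = upstream, downstream_scg = downstream,
    open_start = open_start, open_end = open_end,
    n_enclosed = nrow(enclosed), enclosed = list(enclosed)
  )
  structure(out, class = c("genomic_island", class(tibble::as_tibble(out))))
}

island_sequence <- function(island, genome) {
  Biostrings::subseq(genome$contigs[[island$contig_id]], island$start, island$end)
}

#' Compare two genomic islands
#'
#' Fragments island `a` (1 kb windows), finds the best local alignment of
#' each fragment against island `b` (blastn when available, exact dynamic
#' programming otherwise), and greedily chains colinear consecutive hits at
#' >= `min_block_identity`% into non-overlapping shared blocks of >=
#' `min_block_len` bp.
#'
#' @param island_a,island_b [delimit_island()] rows.
#' @param genome_a,genome_b Their `genome` objects.
#' @param min_block_len Minimum reported block length (default 1000 bp).
#' @param min_block_identity Identity floor per fragment (default 90).
#' @param frag_len Fragment size (default 1000 bp).
#' @param backend `"auto"`, `"blast"` or `"exact"`.
#' @return Tibble of blocks (`start_a`, `end_a`, `length`, `identity`) with
#'   attributes `total_shared` (bp) and `mean_identity` (length-weighted).
#' @export
compare_islands <- function(island_a, genome_a, island_b, genome_b,
                            min_block_len = 1000L, min_block_identity = 90,
                            frag_len = 1000L, backend = c("auto", "blast", "exact")) {
  backend <- match.arg(backend)
  if (backend == "auto") backend <- if (has_blast()) "blast" else "exact"
  seq_a <- island_sequence(island_a, genome_a)
  seq_b <- island_sequence(island_b, genome_b)
  ga <- new_genome("islA", stats::setNames(as.character(seq_a), "isl"))
  gb <- new_genome("islB", stats::setNames(as.character(seq_b), "isl"))
  fragments <- fragment_genome(ga, frag_len)
  hits <- if (backend == "blast") {
    blast_fragments(fragments, gb)
  } else {
    exact_fragments(fragments, gb)
  }
  starts <- as.integer(sub("^isl_", "", names(fragments)))
  frag_tbl <- tibble::tibble(
    fragment = names(fragments), frag_start = starts,
    frag_len = Biostrings::width(fragments)
  ) |>
    dplyr::left_join(hits, by = "fragment") |>
    dplyr::arrange(.data$frag_start) |>
    dplyr::mutate(good = !is.na(.data$identity) &
                    .data$identity >= min_block_identity &
                    .data$coverage >= 70)
  if (!any(frag_tbl$good)) {
    return(structure(tibble::tibble(start_a = integer(), end_a = integer(),
                                    length = integer(), identity = numeric()),
                     total_shared = 0L, mean_identity = NA_real_))
  }
  runs <- rle(frag_tbl$good)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  blocks <- purrr::map_dfr(which(runs$values), function(r) {
    rows <- frag_tbl[idx_start[r]:idx_end[r], ]
    tibble::tibble(
      start_a = min(rows$frag_start),
      end_a = max(rows$frag_start + rows$frag_len - 1L),
      length = sum(rows$frag_len),
      identity = stats::weighted.mean(rows$identity, rows$frag_len)
    )
  }) |>
    dplyr::filter(.data$length >= min_block_len)
  structure(blocks,
            total_shared = sum(blocks$length),
            mean_identity = if (nrow(blocks)) {
              stats::weighted.mean(blocks$identity, blocks$length)
            } else NA_real_)
}

#' Default MGE keyword table
#'
#' Versioned, keyword-estimated surrogate for model-based MGE classifiers:
#' product text is matched case-insensitively, first-matching category wins.
#'
#' @return Named list of keyword vectors (`transposon_is`,
#'   `conjugative_phage`, `other_recombinase`) with a `version` attribute.
#' @export
default_mge_keywords <- function() {
  structure(list(
    transposon_is = c("transposase", "insertion sequence", "\\bIS\\d"),
    conjugative_phage = c("integrase", "conjugal", "conjugative", "relaxase",
                          "phage", "terminase", "mobilization"),
    other_recombinase = c("recombinase", "resolvase", "invertase")
  ), version = "1")
}

#' Tally MGE-associated genes in an island
#'
#' Case-insensitive keyword match on enclosed CDS product text; the first
#' matching category (in table order) wins per feature.
#'
#' @param island A [delimit_island()] row (its `enclosed` features are
#'   used), or a plain feature tibble.
#' @param keywords Keyword table (see [default_mge_keywords()]).
#' @return One-row tibble with one count column per category plus
#'   `n_cds` and `keyword_version`.
#' @export
mge_tally <- function(island, keywords = default_mge_keywords()) {
  feats <- if (inherits(island, "genomic_island")) island$enclosed[[1]] else island
  cds <- dplyr::filter(feats, .data$kind == "CDS")
  cats <- names(keywords)
  assign_cat <- function(product) {
    for (cat in cats) {
      for (kw in keywords[[cat]]) {
        hit <- if (grepl("\\\\", kw)) {
          grepl(kw, product, perl = TRUE)
        } else {
          grepl(tolower(kw), tolower(product), fixed = TRUE)
        }
        if (hit) return(cat)
      }
    }
    NA_character_
  }
  hits <- vapply(cds$product, assign_cat, character(1), USE.NAMES = FALSE)
  counts <- stats::setNames(
    lapply(cats, function(cat) sum(hits == cat, na.rm = TRUE)), cats)
  dplyr::bind_cols(
    tibble::as_tibble(counts),
    tibble::tibble(n_cds = nrow(cds),
                   keyword_version = attr(keywords, "version"))
  )
}
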