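# Fragment-based bidirectional average nucleotide identity (ANIb-style)
# and single-linkage species delineation at the 95% threshold.

has_blast <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

# Chop a genome's contigs into consecutive windows of frag_len (the trailing
# short window is kept and its coverage judged against its own length).
fragment_genome <- function(genome, frag_len) {
  out <- list()
  for (cid in names(genome$contigs)) {
    seq <- genome$contigs[[cid]]
    n <- length(seq)
    starts <- seq.int(1L, n, by = frag_len)
    ends <- pmin(starts + frag_len - 1L, n)
    keep <- (ends - starts + 1L) >= 100L
    frags <- Biostrings::DNAStringSet(seq, start = starts[keep], end = ends[keep])
    names(frags) <- sprintf("%s_%d", cid, starts[keep])
    out[[cid]] <- frags
  }
  do.call(c, unname(out))
}

# blastn backend: best local hit per fragment against the reference.
blast_fragments <- function(fragments, reference, db_dir = NULL) {
  db_dir <- db_dir %||% tempfile("anidb")
  dir.create(db_dir, showWarnings = FALSE, recursive = TRUE)
  db <- file.path(db_dir, paste0(reference$genome_id, "_db"))
  if (!file.exists(paste0(db, ".nsq")) && !file.exists(paste0(db, ".00.nsq"))) {
    ref_fa <- paste0(db, ".fna")
    Biostrings::writeXStringSet(reference$contigs, ref_fa)
    status <- system2("makeblastdb",
                      c("-in", ref_fa, "-dbtype", "nucl", "-out", db),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0) stop("makeblastdb failed", call. = FALSE)
  }
  q_fa <- tempfile(fileext = ".fna")
  on.exit(unlink(q_fa), add = TRUE)
  Biostrings::writeXStringSet(fragments, q_fa)
  out <- system2("blastn",
                 c("-task", "blastn", "-dust", "no", "-xdrop_gap_final", "150",
                   "-evalue", "1e-6", "-query", q_fa, "-db", db,
                   "-outfmt", shQuote("6 qseqid pident length qlen bitscore")),
                 stdout = TRUE, stderr = FALSE)
  if (!length(out)) {
    return(tibble::tibble(fragment = character(), identity = numeric(),
                          coverage = numeric()))
  }
  hits <- utils::read.table(text = out, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("fragment", "pident", "length", "qlen",
                                          "bitscore"))
  hits |>
    dplyr::group_by(.data$fragment) |>
    dplyr::slice_max(.data$bitscore, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(fragment = .data$fragment, identity = .data$pident,
                     coverage = 100 * .data$length / .data$qlen)
}

# Exact dynamic-programming backend (both strands), blastn-like scoring.
exact_fragments <- function(fragments, reference) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  refs <- reference$contigs
  refs_rc <- Biostrings::reverseComplement(refs)
  purrr::map_dfr(seq_along(fragments), function(i) {
    frag <- fragments[[i]]
    best <- NULL
    for (ref in c(as.list(refs), as.list(refs_rc))) {
      aln <- Biostrings::pairwiseAlignment(frag, ref, type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 5, gapExtension = 2)
      if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best)) best <- aln
    }
    ncol <- nchar(as.character(Biostrings::alignedPattern(best)))
    qaln <- Biostrings::nchar(Biostrings::pattern(best))
    tibble::tibble(
      fragment = names(fragments)[i],
      identity = if (ncol == 0) 0 else 100 * Biostrings::nmatch(best) / ncol,
      coverage = 100 * qaln / length(frag)
    )
  })
}

#' Directional fragment-based ANI
#'
#' The query genome is chopped into consecutive `frag_len` windows, each
#' fragment is aligned to the reference (best local alignment over both
#' strands), and fragments are retained when identity and aligned coverage
#' clear the thresholds.  ANI is the mean identity of retained fragments;
#' `aligned_fraction` is retained/total.  Defaults mirror the ANIb
#' convention (1020 bp fragments, 30% identity / 70% coverage retention).
#'
#' @param query,reference `genome` objects.
#' @param frag_len Fragment length in bp.
#' @param min_frag_identity,min_frag_coverage Retention thresholds (percent).
#' @param backend `"auto"` (blastn when available, else exact dynamic
#'   programming), `"blast"` or `"exact"`.
#' @param db_dir Optional directory for cached blast databases (reused
#'   across calls by [ani_matrix()]).
#' @return One-row tibble: `query`, `reference`, `ani` (NA when no fragment
#'   is retained), `aligned_fraction`, `n_fragments`.
#' @export
directional_ani <- function(query, reference, frag_len = 1020L,
                            min_frag_identity = 30, min_frag_coverage = 70,
                            backend = c("auto", "blast", "exact"),
                            db_dir = NULL) {
  backend <- match.arg(backend)
  if (backend == "auto") backend <- if (has_blast()) "blast" else "exact"
  fragments <- fragment_genome(query, frag_len)
  hits <- if (backend == "blast") {
    blast_fragments(fragments, reference, db_dir = db_dir)
  } else {
    exact_fragments(fragments, reference)
  }
  retained <- dplyr::filter(hits, .data$identity >= min_frag_identity,
                            .data$coverage >= min_frag_coverage)
  tibble::tibble(
    query = query$genome_id, reference = reference$genome_id,
    ani = if (nrow(retained)) mean(retained$identity) else NA_real_,
    aligned_fraction = nrow(retained) / length(fragments),
    n_fragments = length(fragments)
  )
}

#' All-pairs bidirectional ANI
#'
#' Computes [directional_ani()] for every ordered genome pair, plus the
#' symmetric summary (mean of the two directions, the package default for
#' reducing bidirectional values to one per pair; `"median"` instead takes
#' the median of the two directions' retained-fragment identities, which for
#' two values coincides with the mean).
#'
#' @param genomes Named list of `genome` objects (>= 2).
#' @param ... Passed to [directional_ani()].
#' @return A tibble of class `ani_tbl` with the directional values; the
#'   symmetric summary is available via [ani_summary()].
#' @export
ani_matrix <- function(genomes, ...) {
  if (length(genomes) < 2L) stop("need at least 2 genomes", call. = FALSE)
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  names(genomes) <- ids
  db_dir <- tempfile("anidbs")
  dir.create(db_dir)
  on.exit(unlink(db_dir, recursive = TRUE), add = TRUE)
  pairs <- expand.grid(query = ids, reference = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$query != pairs$reference, ]
  out <- purrr::pmap_dfr(pairs, function(query, reference) {
    directional_ani(genomes[[query]], genomes[[reference]], db_dir = db_dir, ...)
  })
  structure(out, class = c("ani_tbl", class(tibble::as_tibble(out))))
}

#' Symmetric ANI summary
#'
#' @param ani An `ani_tbl` from [ani_matrix()].
#' @return Tibble with one row per unordered pair: `genome_a`, `genome_b`,
#'   `ani` (mean of the two directions; NA propagates when either direction
#'   is missing).
#' @export
ani_summary <- function(ani) {
  ani |>
    dplyr::mutate(
      genome_a = pmin(.data$query, .data$reference),
      genome_b = pmax(.data$query, .data$reference)
    ) |>
    dplyr::group_by(.data$genome_a, .data$genome_b) |>
    dplyr::summarise(ani = mean(.data$ani), .groups = "drop")
}

#' @method tidy ani_tbl
#' @export
tidy.ani_tbl <- function(x, ...) ani_summary(x)

#' @method glance ani_tbl
#' @export
glance.ani_tbl <- function(x, ...) {
  s <- ani_summary(x)
  tibble::tibble(
    n_genomes = length(unique(c(x$query, x$reference))),
    n_pairs = nrow(s),
    min_ani = min(s$ani, na.rm = TRUE),
    max_ani = max(s$ani, na.rm = TRUE),
    median_ani = stats::median(s$ani, na.rm = TRUE)
  )
}

#' Delineate species at an ANI threshold
#'
#' Single-linkage clustering of genomes whose summary ANI meets the species
#' threshold (95% by convention).  Species labels are deterministic:
#' `sp_<smallest member id>`.
#'
#' @param ani An `ani_tbl` or its [ani_summary()] tibble.
#' @param threshold Percent ANI cutoff (default 95).
#' @return A tibble of class `species_partition`: `genome_id`, `species`;
#'   attribute `threshold`.
#' @export
delineate_species <- function(ani, threshold = 95) {
  s <- if (inherits(ani, "ani_tbl")) ani_summary(ani) else ani
  ids <- sort(unique(c(s$genome_a, s$genome_b)))
  edges <- dplyr::filter(s, !is.na(.data$ani), .data$ani >= threshold)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$genome_a, to = edges$genome_b),
    directed = FALSE, vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)
  members <- split(ids, comp$membership[ids])
  out <- dplyr::bind_rows(unname(purrr::map(members, function(mem) {
    tibble::tibble(genome_id = sort(mem), species = paste0("sp_", min(mem)))
  }))) |>
    dplyr::arrange(.data$genome_id)
  structure(out, threshold = threshold,
            class = c("species_partition", class(tibble::as_tibble(out))))
}

#' @method glance species_partition
#' @export
glance.species_partition <- function(x, ...) {
  tibble::tibble(
    n_genomes = nrow(x),
    n_species = length(unique(x$species)),
    threshold = attr(x, "threshold")
  )
}
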