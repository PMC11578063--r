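# RdhA candidate mining: iron-sulphur motif scan and the retention filter
# (length >= 200 aa, >= 1 motif, not pseudo, not truncated, optional
# reference-panel domain evidence).

#' Count iron-sulphur cluster motifs
#'
#' Counts start positions of the 8-residue motif CXXCXXXC (cysteines at
#' offsets 0, 3 and 7); overlapping occurrences each count.
#'
#' @param protein A protein sequence (character or `AAString`).
#' @return Non-negative integer.
#' @export
count_motifs <- function(protein) {
  s <- as_character_seq(protein)
  if (!nzchar(s)) return(0L)
  hits <- gregexpr("(?=C..C...C)", s, perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

#' Screen RdhA candidates
#'
#' A candidate is retained iff, in this order: length >= `min_len` (200 aa
#' by the field's convention), at least one CXXCXXXC motif, not a
#' pseudogene, not truncated (the annotation's partial flag), and -- when a
#' reference panel is supplied -- best panel identity >= `min_domain_identity`
#' over >= 50% coverage of the shorter sequence (a desk-scale surrogate for
#' an RDase-domain HMM search).  Every rejection carries exactly the first
#' failing reason.
#'
#' @param protein_tbl Tibble from [translate_features()] (columns
#'   `protein_id`, `genome_id`, `residues`, `length_aa`, `is_partial`).
#' @param features Feature tibble supplying `is_pseudo` per feature id.
#' @param reference_panel Optional named character vector / `AAStringSet` of
#'   reference RdhA proteins.
#' @param min_len Minimum length in aa (default 200).
#' @param min_domain_identity Minimum best-panel identity in percent
#'   (default 25).
#' @return Tibble: `protein_id`, `genome_id`, `length_aa`, `motif_count`,
#'   `domain_score`, `is_pseudo`, `is_partial`, `verdict`
#'   (`retained`/`rejected`), `reason` (`too_short`, `no_motif`,
#'   `pseudogene`, `truncated`, `no_domain`, or NA when retained).
#' @export
screen_candidates <- function(protein_tbl, features, reference_panel = NULL,
                              min_len = 200L, min_domain_identity = 25) {
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", protein_tbl$residues)
  if (any(bad)) {
    stop("protein residues outside the amino-acid alphabet: ",
         paste(protein_tbl$protein_id[bad], collapse = ", "), call. = FALSE)
  }
  pseudo_of <- stats::setNames(features$is_pseudo, features$feature_id)
  panel <- if (!is.null(reference_panel)) {
    Biostrings::AAStringSet(as.character(reference_panel))
  }
  out <- protein_tbl |>
    dplyr::mutate(
      motif_count = purrr::map_int(.data$residues, count_motifs),
      is_pseudo = dplyr::coalesce(unname(pseudo_of[.data$protein_id]), FALSE),
      domain_score = NA_real_
    )
  # panel identity only where the cheaper filters already pass
  if (!is.null(panel)) {
    need <- which(out$length_aa >= min_len & out$motif_count >= 1L &
                    !out$is_pseudo & !out$is_partial)
    out$domain_score[need] <- vapply(need, function(i) {
      best <- 0
      query <- Biostrings::AAString(out$residues[i])
      for (j in seq_along(panel)) {
        aln <- Biostrings::pairwiseAlignment(
          query, panel[[j]], type = "overlap",
          substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
        ncol <- nchar(as.character(Biostrings::alignedPattern(aln)))
        if (ncol == 0) next
        cover <- ncol / min(out$length_aa[i], length(panel[[j]]))
        if (cover >= 0.5) best <- max(best, 100 * Biostrings::nmatch(aln) / ncol)
      }
      best
    }, numeric(1))
  }
  out |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$length_aa < min_len ~ "too_short",
        .data$motif_count < 1L ~ "no_motif",
        .data$is_pseudo ~ "pseudogene",
        .data$is_partial ~ "truncated",
        !is.null(panel) & !is.na(.data$domain_score) &
          .data$domain_score < min_domain_identity ~ "no_domain",
        TRUE ~ NA_character_
      ),
      verdict = ifelse(is.na(.data$reason), "retained", "rejected")
    ) |>
    dplyr::select("protein_id", "genome_id", "length_aa", "motif_count",
                  "domain_score", "is_pseudo", "is_partial", "verdict", "reason")
}
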