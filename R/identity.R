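# Pairwise protein identity and multiple alignment helpers.

#' Pairwise amino-acid identity
#'
#' Global alignment with free end gaps (BLOSUM62, gap open 11, extend 1);
#' identity is matches / aligned columns, where terminal-gap columns are
#' excluded by the free-end-gap alignment itself.  This is the quantity the
#' 90% orthologue-group cutoff is applied to.
#'
#' @param a,b Protein sequences (character or `AAString`).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- as_character_seq(a); b <- as_character_seq(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "overlap",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1
  )
  ncol <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (ncol == 0) return(0)
  100 * Biostrings::nmatch(aln) / ncol
}

#' All-pairs identity table
#'
#' Computes [pairwise_identity()] for every unordered pair of sequences.
#'
#' @param proteins Named character vector or `AAStringSet`.
#' @return A tibble of class `identity_tbl` with columns `id_a`, `id_b`,
#'   `identity` (one row per unordered pair) and attribute `ids`.
#' @export
identity_matrix <- function(proteins) {
  seqs <- stats::setNames(as.character(proteins), names(proteins))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("proteins must carry unique names", call. = FALSE)
  }
  ids <- names(seqs)
  n <- length(ids)
  rows <- list()
  if (n >= 2L) {
    aa <- Biostrings::AAStringSet(seqs)
    for (j in 2:n) {
      pats <- aa[1:(j - 1L)]
      aln <- Biostrings::pairwiseAlignment(
        pats, aa[[j]], type = "overlap",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1
      )
      ncols <- nchar(as.character(Biostrings::alignedPattern(aln)))
      ident <- ifelse(ncols == 0, 0, 100 * Biostrings::nmatch(aln) / ncols)
      rows[[j]] <- tibble::tibble(id_a = ids[1:(j - 1L)], id_b = ids[j],
                                  identity = as.numeric(ident))
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, ids = ids, class = c("identity_tbl", class(out)))
}

#' Identity table as a symmetric matrix
#'
#' @param x An `identity_tbl` (or compatible tibble with `id_a`, `id_b`,
#'   `identity`).
#' @param ids Optional id ordering; defaults to the table's `ids` attribute.
#' @return Symmetric numeric matrix with 100 on the diagonal.
#' @export
identity_as_matrix <- function(x, ids = NULL) {
  ids <- ids %||% attr(x, "ids") %||% sort(unique(c(x$id_a, x$id_b)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  m[cbind(x$id_a, x$id_b)] <- x$identity
  m[cbind(x$id_b, x$id_a)] <- x$identity
  m
}

# Center-star multiple alignment: anchor on the longest sequence, align all
# others to it pairwise (global), then merge the anchor gap patterns.
# Adequate for substitution-dominated clusters at desk scale.
align_center_star <- function(proteins) {
  seqs <- stats::setNames(as.character(proteins), names(proteins))
  n <- length(seqs)
  if (n == 1L) return(Biostrings::AAStringSet(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) == 1L) {
    # equal lengths: stack directly (substitution-only data)
    return(Biostrings::AAStringSet(seqs))
  }
  center_i <- which.max(widths)
  center <- seqs[[center_i]]
  nC <- nchar(center)
  others <- seqs[-center_i]
  # per-alignment: gap lengths before each center residue (slots 0..nC) and
  # the subject chunks aligned to each slot/residue
  parse_aln <- function(s) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s), Biostrings::AAString(center), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1
    )
    Ca <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    Sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    gaps <- integer(nC + 1L)   # gap run lengths per slot
    chunks <- vector("list", nC + 1L)  # subject chars in each gap run
    res_chars <- character(nC)         # subject char opposite each center residue
    slot <- 0L; buf <- character(0)
    for (k in seq_along(Ca)) {
      if (Ca[k] == "-") {
        buf <- c(buf, Sa[k])
      } else {
        gaps[slot + 1L] <- length(buf); chunks[[slot + 1L]] <- buf
        slot <- slot + 1L
        res_chars[slot] <- Sa[k]
        buf <- character(0)
      }
    }
    gaps[nC + 1L] <- length(buf); chunks[[nC + 1L]] <- buf
    list(gaps = gaps, chunks = chunks, res = res_chars)
  }
  parsed <- lapply(others, parse_aln)
  G <- Reduce(pmax, lapply(parsed, `[[`, "gaps"), integer(nC + 1L))
  pad <- function(chunk, width) {
    c(rep("-", width - length(chunk)), chunk)
  }
  rebuild <- function(p) {
    out <- character(0)
    for (slot in 0:(nC - 1L)) {
      out <- c(out, pad(p$chunks[[slot + 1L]], G[slot + 1L]), p$res[slot + 1L])
    }
    paste(c(out, pad(p$chunks[[nC + 1L]], G[nC + 1L])), collapse = "")
  }
  center_chars <- strsplit(center, "")[[1]]
  center_row <- character(0)
  for (slot in 0:(nC - 1L)) {
    center_row <- c(center_row, rep("-", G[slot + 1L]), center_chars[slot + 1L])
  }
  center_row <- paste(c(center_row, rep("-", G[nC + 1L])), collapse = "")
  rows <- c(stats::setNames(list(center_row), names(seqs)[center_i]),
            stats::setNames(lapply(parsed, rebuild), names(others)))
  Biostrings::AAStringSet(unlist(rows)[names(seqs)])
}

# Percent-identity matrix from an alignment (matches / columns where both
# rows are non-gap); used by bootstrap resampling.
alignment_identity <- function(aln_mat) {
  n <- nrow(aln_mat)
  m <- matrix(100, n, n, dimnames = list(rownames(aln_mat), rownames(aln_mat)))
  if (n < 2) return(m)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      both <- aln_mat[i, ] != "-" & aln_mat[j, ] != "-"
      ncol <- sum(aln_mat[i, ] != "-" | aln_mat[j, ] != "-")
      idt <- if (ncol == 0) 0 else 100 * sum(aln_mat[i, both] == aln_mat[j, both]) / ncol
      m[i, j] <- m[j, i] <- idt
    }
  }
  m
}

alignment_as_matrix <- function(aln) {
  mat <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(mat) <- names(aln)
  mat
}
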