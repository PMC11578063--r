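#' Construct a genome object
#'
#' A genome is a named set of contig sequences plus bookkeeping (circularity,
#' optional clade label).  Sequences are normalized to uppercase; IUPAC
#' ambiguity codes other than N are converted to N with a warning so that all
#' downstream base counts are deterministic.
#'
#' @param genome_id Single string identifying the genome.
#' @param contigs Named character vector or [Biostrings::DNAStringSet] of
#'   contig sequences; names are the contig ids.
#' @param circular Logical, recycled across contigs.
#' @param clade Optional clade label.
#' @return An object of class `genome`: a list with elements `genome_id`,
#'   `contigs` (a `DNAStringSet`), `circular` and `clade`.
#' @export
new_genome <- function(genome_id, contigs, circular = TRUE, clade = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  nm <- names(contigs)
  seqs <- stats::setNames(toupper(as.character(contigs)), nm)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("contigs must carry unique names", call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) stop("contig sequences must be non-empty", call. = FALSE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning("non-ACGTN characters normalized to N in genome ", genome_id)
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  structure(
    list(
      genome_id = genome_id,
      contigs = Biostrings::DNAStringSet(seqs),
      circular = rep_len(circular, length(seqs)),
      clade = clade
    ),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$genome_id,
      sprintf("(%d contig(s), %s bp%s)\n",
              length(x$contigs),
              format(sum(Biostrings::width(x$contigs)), big.mark = ","),
              if (!is.null(x$clade)) paste0(", clade ", x$clade) else ""))
  invisible(x)
}

contig_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome$contigs), names(genome$contigs))
}

# Validate a feature table against its genome; stops on out-of-bounds rows.
validate_features <- function(features, genome) {
  lens <- contig_lengths(genome)
  feats <- dplyr::filter(features, .data$genome_id == genome$genome_id)
  unknown <- setdiff(unique(feats$contig_id), names(lens))
  if (length(unknown)) {
    stop("features reference unknown contig(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- feats$start < 1L | feats$end > lens[feats$contig_id] | feats$end < feats$start
  if (any(bad)) {
    stop("feature coordinates out of bounds: ",
         paste(feats$feature_id[bad], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(feats$feature_id)) {
    stop("duplicated feature ids within genome ", genome$genome_id, call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a genome from FASTA (and optionally GFF3)
#'
#' Coordinates are kept 1-based inclusive exactly as in the GFF3.  A feature
#' is flagged pseudo when the record carries a `pseudo=true` or `pseudogene`
#' attribute (whichever fired is recorded in `pseudo_source`), and partial
#' when it carries `partial=true`.
#'
#' @param fasta_path Path to a (multi-)FASTA of contigs.
#' @param gff_path Optional path to a GFF3 file of features.
#' @param genome_id Genome identifier; defaults to the FASTA basename.
#' @return A list with elements `genome` (a [new_genome()] object) and
#'   `features` (a tibble with columns `feature_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand`, `kind`, `product`, `is_pseudo`, `is_partial`,
#'   `pseudo_source`).
#' @export
read_genome <- function(fasta_path, gff_path = NULL, genome_id = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path, call. = FALSE)
  genome_id <- genome_id %||% sub("\\.(fa|fna|fasta)$", "", basename(fasta_path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA ", fasta_path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome <- new_genome(genome_id, seqs)
  features <- empty_features()
  if (!is.null(gff_path)) {
    features <- read_gff3(gff_path, genome_id)
    validate_features(features, genome)
  }
  list(genome = genome, features = features)
}

empty_features <- function() {
  tibble::tibble(
    feature_id = character(), genome_id = character(), contig_id = character(),
    start = integer(), end = integer(), strand = character(), kind = character(),
    product = character(), is_pseudo = logical(), is_partial = logical(),
    pseudo_source = character()
  )
}

read_gff3 <- function(gff_path, genome_id) {
  if (!file.exists(gff_path)) stop("GFF3 not found: ", gff_path, call. = FALSE)
  lines <- readLines(gff_path, warn = FALSE)
  rows <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(rows)) return(empty_features())
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 9L)) {
    stop("malformed GFF3 at line ", rows[which(nfield != 9L)[1]],
         " of ", gff_path, ": expected 9 tab-separated fields", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed GFF3 at line ", rows[which(is.na(start) | is.na(end))[1]],
         " of ", gff_path, ": non-numeric coordinates", call. = FALSE)
  }
  attr_field <- m[, 9]
  get_attr <- function(key) {
    val <- stringr::str_match(attr_field, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    val
  }
  ids <- get_attr("ID")
  ids[is.na(ids)] <- paste0("feat", seq_along(ids))[is.na(ids)]
  product <- get_attr("product")
  product[is.na(product)] <- ""
  product <- utils::URLdecode(product)
  pseudo_attr <- tolower(get_attr("pseudo"))
  pseudogene_attr <- get_attr("pseudogene")
  is_pseudo <- (!is.na(pseudo_attr) & pseudo_attr %in% c("true", "1")) |
    !is.na(pseudogene_attr) | m[, 3] == "pseudogene"
  pseudo_source <- dplyr::case_when(
    !is.na(pseudo_attr) & pseudo_attr %in% c("true", "1") ~ "pseudo=true",
    !is.na(pseudogene_attr) ~ "pseudogene attribute",
    m[, 3] == "pseudogene" ~ "pseudogene type",
    TRUE ~ NA_character_
  )
  partial_attr <- tolower(get_attr("partial"))
  kind <- ifelse(m[, 3] %in% c("CDS", "rRNA", "tRNA"), m[, 3], "other")
  tibble::tibble(
    feature_id = ids, genome_id = genome_id, contig_id = m[, 1],
    start = start, end = end,
    strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "+"),
    kind = kind, product = product,
    is_pseudo = is_pseudo,
    is_partial = !is.na(partial_attr) & partial_attr %in% c("true", "1"),
    pseudo_source = pseudo_source
  )
}

#' Write a genome (FASTA) and its features (GFF3)
#'
#' @param genome A [new_genome()] object.
#' @param features Feature tibble as returned by [read_genome()].
#' @param fasta_path,gff_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, features = NULL, fasta_path = NULL, gff_path = NULL) {
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(genome$contigs, fasta_path, width = 80L)
  }
  if (!is.null(gff_path)) {
    feats <- features %||% empty_features()
    feats <- dplyr::filter(feats, .data$genome_id == genome$genome_id)
    if (nrow(feats)) validate_features(feats, genome)
    attrs <- paste0(
      "ID=", feats$feature_id,
      ifelse(nzchar(feats$product),
             paste0(";product=", gsub(";", "%3B", feats$product)), ""),
      ifelse(feats$is_pseudo, ";pseudo=true", ""),
      ifelse(feats$is_partial, ";partial=true", "")
    )
    body <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t0\t%s",
                    feats$contig_id, "dehalopan", feats$kind,
                    feats$start, feats$end, feats$strand, attrs)
    regions <- sprintf("##sequence-region %s 1 %d",
                       names(genome$contigs), Biostrings::width(genome$contigs))
    writeLines(c("##gff-version 3", regions, body), gff_path)
  }
  invisible(c(fasta = fasta_path, gff = gff_path))
}

#' GC content of a genome
#'
#' Fraction (G+C)/(A+C+G+T); N bases are excluded from both numerator and
#' denominator.
#'
#' @param x A `genome` object, `DNAStringSet`, or character vector of
#'   sequences.
#' @return A single fraction in `[0, 1]`.
#' @export
gc_content <- function(x) {
  seqs <- if (inherits(x, "genome")) x$contigs else Biostrings::DNAStringSet(toupper(as.character(x)))
  counts <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  denom <- sum(counts)
  if (denom == 0) stop("GC content undefined: no unambiguous A/C/G/T bases", call. = FALSE)
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

#' Windowed GC skew along a contig
#'
#' Per-window skew (G-C)/(G+C) (0 where a window has no G or C) plus the
#' running cumulative skew, the standard diagnostic for replication origin /
#' terminus placement and mis-ordered contigs in closed bacterial genomes.
#'
#' @param contig A single sequence (character or `DNAString`), or a `genome`
#'   object with one contig.
#' @param window Window size in bp.
#' @param step Step between window starts in bp (default: `window`, i.e.
#'   non-overlapping).
#' @return Tibble with columns `start`, `midpoint`, `skew`, `cumulative`.
#' @export
gc_skew <- function(contig, window = 10000L, step = window) {
  if (inherits(contig, "genome")) {
    if (length(contig$contigs) != 1L) stop("gc_skew expects a single contig", call. = FALSE)
    contig <- as.character(contig$contigs[[1]])
  }
  seq <- toupper(as.character(contig))
  assert_scalar_number(window, "window", lower = 1)
  assert_scalar_number(step, "step", lower = 1)
  n <- nchar(seq)
  if (window > n) stop("window exceeds contig length", call. = FALSE)
  starts <- seq.int(1L, n - window + 1L, by = step)
  views <- Biostrings::Views(Biostrings::DNAString(seq), start = starts, width = window)
  freq <- Biostrings::letterFrequency(views, c("G", "C"))
  gc <- freq[, "G"] + freq[, "C"]
  skew <- ifelse(gc == 0, 0, (freq[, "G"] - freq[, "C"]) / gc)
  tibble::tibble(
    start = starts,
    midpoint = starts + (window - 1) / 2,
    skew = as.numeric(skew),
    cumulative = cumsum(as.numeric(skew))
  )
}

#' Translate CDS features to proteins
#'
#' Uses the bacterial genetic code (translation table 11); minus-strand
#' features are reverse-complemented first.  Alternative start codons
#' (GTG/TTG) are rendered as M at position 1 only.  A single trailing stop is
#' stripped; internal stops are kept as `*` and flagged rather than raised as
#' errors.  Features whose length is not a multiple of 3 are flagged partial
#' and translated over the full codons only.
#'
#' @param features Feature tibble (rows of kind `CDS` are translated; other
#'   kinds are skipped).
#' @param genome The `genome` the features belong to, or a named list of
#'   genomes when `features` spans several.
#' @return Tibble with columns `protein_id` (= feature id), `genome_id`,
#'   `residues`, `length_aa`, `internal_stop`, `is_partial`.
#' @export
translate_features <- function(features, genome) {
  genomes <- if (inherits(genome, "genome")) {
    stats::setNames(list(genome), genome$genome_id)
  } else {
    genome
  }
  cds <- dplyr::filter(features, .data$kind == "CDS")
  if (!nrow(cds)) {
    return(tibble::tibble(protein_id = character(), genome_id = character(),
                          residues = character(), length_aa = integer(),
                          internal_stop = logical(), is_partial = logical()))
  }
  code <- Biostrings::getGeneticCode("11")
  out <- purrr::pmap(cds, function(feature_id, genome_id, contig_id, start, end,
                                   strand, is_partial, ...) {
    g <- genomes[[genome_id]]
    if (is.null(g)) stop("no genome supplied for ", genome_id, call. = FALSE)
    dna <- Biostrings::subseq(g$contigs[[contig_id]], start, end)
    if (strand == "-") dna <- Biostrings::reverseComplement(dna)
    partial <- isTRUE(is_partial) || (length(dna) %% 3L != 0L)
    ncod <- length(dna) %/% 3L
    if (ncod == 0L) {
      return(tibble::tibble(protein_id = feature_id, genome_id = genome_id,
                            residues = "", length_aa = 0L,
                            internal_stop = FALSE, is_partial = TRUE))
    }
    aa <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::subseq(dna, 1L, ncod * 3L),
      genetic.code = code, if.fuzzy.codon = "X"
    )))
    first_codon <- as.character(Biostrings::subseq(dna, 1L, 3L))
    if (first_codon %in% c("GTG", "TTG", "ATG")) {
      substr(aa, 1L, 1L) <- "M"
    }
    trailing_stop <- endsWith(aa, "*")
    if (trailing_stop) aa <- substr(aa, 1L, nchar(aa) - 1L)
    tibble::tibble(
      protein_id = feature_id, genome_id = genome_id, residues = aa,
      length_aa = nchar(aa),
      internal_stop = grepl("*", aa, fixed = TRUE),
      is_partial = partial || !trailing_stop
    )
  })
  dplyr::bind_rows(out)
}

# Convenience: AAStringSet view of a translate_features() table.
proteins_as_aastringset <- function(protein_tbl) {
  stats::setNames(Biostrings::AAStringSet(protein_tbl$residues), protein_tbl$protein_id)
}
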