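# Pangenome simulator with known ground truth.
#
# Genomes are gene sequences interleaved with intergenic spacers; every
# element (genes and spacers alike) descends from a single root layout and
# diverges along the species tree under Jukes-Cantor substitution, so that
# whole-genome nucleotide identity tracks tree path length.  Coding genes
# keep their start/stop codons (and, for rdhA, the iron-sulphur motif
# cysteines) frozen, and substitutions that would create internal stop
# codons are repaired, so planted genes stay translatable and minable.

DNA_BASES <- c("A", "C", "G", "T")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_table <- function() {
  code <- Biostrings::getGeneticCode("11")
  tibble::tibble(codon = names(code), aa = unname(code))
}

.sim_env <- new.env(parent = emptyenv())
get_codon_table <- function() {
  if (is.null(.sim_env$codons)) .sim_env$codons <- codon_table()
  .sim_env$codons
}
sense_codons <- function() dplyr::filter(get_codon_table(), .data$aa != "*")
codons_for_aa <- function(a) dplyr::filter(get_codon_table(), .data$aa == a)$codon

# Random coding DNA: ATG start, TAA stop, no internal stops.  `motif_at`
# gives amino-acid positions at which to plant CXXCXXXC iron-sulphur motifs.
random_gene_dna <- function(n_aa, motif_at = integer(0)) {
  sc <- sense_codons()$codon
  body <- sample(sc, n_aa - 2L, replace = TRUE)
  gene <- c("ATG", body, "TAA")
  for (pos in motif_at) {
    cys <- pos + c(0L, 3L, 7L)
    gene[cys + 1L] <- sample(c("TGT", "TGC"), 3L, replace = TRUE)
  }
  paste(gene, collapse = "")
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# Frozen nucleotide positions of a coding gene: start codon, stop codon and
# any motif cysteine codons (aa positions in `motif_at`).
frozen_sites <- function(n_nt, motif_at = integer(0)) {
  sites <- c(1:3, (n_nt - 2L):n_nt)
  for (pos in motif_at) {
    for (cys in pos + c(0L, 3L, 7L)) {
      sites <- c(sites, (cys * 3L + 1L):(cys * 3L + 3L))
    }
  }
  sort(unique(sites))
}

#' Mutate a sequence to an exact target identity
#'
#' Places `length(x) - round(length(x) * target)` substitutions at uniformly
#' chosen sites without replacement, so the realized identity to the input is
#' exactly `round(n * target) / n`.  DNA substitutions are drawn from the
#' other three bases and protein substitutions from the other nineteen
#' residues; no indels are introduced.
#'
#' @param seq A single DNA or protein sequence (character, `DNAString` or
#'   `AAString`).
#' @param target_identity Fraction in (0, 1].
#' @param seed Integer seed making the draw reproducible.
#' @param alphabet `"auto"` (default), `"dna"` or `"protein"`.
#' @return The mutated sequence as a character string.
#' @export
mutate_to_identity <- function(seq, target_identity, seed = 1L, alphabet = "auto") {
  s <- toupper(as_character_seq(seq))
  if (!is.numeric(target_identity) || length(target_identity) != 1L ||
      is.na(target_identity) || target_identity <= 0 || target_identity > 1) {
    stop("target_identity must be a fraction in (0, 1]", call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  alphabet <- match.arg(alphabet, c("auto", "dna", "protein"))
  if (alphabet == "auto") {
    alphabet <- if (all(chars %in% c(DNA_BASES, "N"))) "dna" else "protein"
  }
  pool <- if (alphabet == "dna") DNA_BASES else AA20
  n <- length(chars)
  n_sub <- n - round(n * target_identity)
  if (n_sub == 0L) return(s)
  with_seed(seed, {
    sites <- sample.int(n, n_sub)
    chars[sites] <- vapply(chars[sites],
                           function(b) sample(setdiff(pool, b), 1L), character(1))
  })
  paste(chars, collapse = "")
}

# Jukes-Cantor per-site substitution probability for branch length t
# (expected substitutions/site).
jc_p <- function(t) 0.75 * (1 - exp(-4 * t / 3))

# Per-site Bernoulli substitution over mutable sites; coding genes get
# internal stop codons repaired (replaced by a random sense codon).
branch_mutate <- function(dna, bl, frozen = integer(0), coding = FALSE) {
  p <- jc_p(bl)
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  n <- length(chars)
  mutable <- setdiff(seq_len(n), frozen)
  hit <- mutable[runif(length(mutable)) < p]
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
  }
  if (coding && n >= 9L) {
    ncod <- n %/% 3L
    starts <- seq.int(1L, by = 3L, length.out = ncod)
    cods <- substring(paste(chars, collapse = ""), starts, starts + 2L)
    bad <- which(cods %in% STOP_CODONS)
    bad <- setdiff(bad, c(1L, ncod))
    for (k in bad) {
      repl <- strsplit(sample(sense_codons()$codon, 1L), "")[[1]]
      chars[(3L * (k - 1L) + 1L):(3L * k)] <- repl
    }
  }
  paste(chars, collapse = "")
}

# Change exactly round(n_aa * (1 - aa_target)) codons (outside frozen codons)
# to codons of a different amino acid; never introduces stops.
mutate_coding_exact <- function(dna, aa_target, frozen_codons = integer(0)) {
  n_aa <- nchar(dna) %/% 3L
  n_change <- n_aa - round(n_aa * aa_target)
  if (n_change == 0L) return(dna)
  starts <- seq.int(1L, by = 3L, length.out = n_aa)
  cods <- substring(dna, starts, starts + 2L)
  tab <- get_codon_table()
  aa_of <- stats::setNames(tab$aa, tab$codon)
  candidates <- setdiff(2:(n_aa - 1L), frozen_codons)
  pick <- sample(candidates, n_change)
  for (k in pick) {
    cur <- aa_of[[cods[k]]]
    new_aa <- sample(setdiff(AA20, cur), 1L)
    opts <- codons_for_aa(new_aa)
    cods[k] <- opts[sample.int(length(opts), 1L)]
  }
  paste(cods, collapse = "")
}

core_product_vocab <- c(
  "DNA gyrase subunit A", "50S ribosomal protein L2", "elongation factor Tu",
  "ATP synthase subunit beta", "chaperonin GroEL", "DNA polymerase III subunit alpha",
  "preprotein translocase subunit SecY", "flagellar basal body rod protein FlgC",
  "phosphoglycerate kinase", "enolase", "recombination protein RecA",
  "signal recognition particle protein", "transcription termination factor Rho",
  "ribosome recycling factor", "tRNA ligase", "cell division protein FtsZ"
)

island_cargo_products <- function(n_cargo) {
  fixed <- c(
    rep("IS256 family transposase", 4L),
    rep("IS4 family transposase", 2L),
    rep("site-specific integrase", 3L),
    rep("phage terminase large subunit", 2L),
    "conjugal transfer relaxase MobA",
    rep("serine recombinase", 2L),
    "dichloromethane dehalogenase cassette protein MecA",
    "dichloromethane dehalogenase cassette protein MecB"
  )
  c(utils::head(fixed, n_cargo),
    rep("hypothetical protein", max(0L, n_cargo - length(fixed))))
}

#' Build a simulation configuration
#'
#' Defines the study conditions a simulated pangenome emulates: a species
#' tree with clades whose within-clade nucleotide identity sits near 99% and
#' between-clade identity in the low 90s, per-genome RDase gene clusters
#' whose members form orthologue groups, optional mobile-island insertion at
#' a shared hotspot, and gene loss / duplication / transfer events.
#'
#' @param seed Integer; with the configuration it fully determines the output.
#' @param species_tree Newick string with branch lengths in expected
#'   substitutions/site, or `NULL` to build a balanced tree from `n_clades`,
#'   `genomes_per_clade`, `within_bl` and `between_bl`.  Default branch
#'   lengths give ~99% within-clade and ~93% between-clade nucleotide
#'   identity.
#' @param n_clades,genomes_per_clade Shape of the default tree (tips are
#'   labelled A1..A_k, B1.., ...).
#' @param within_bl,between_bl Terminal and clade-stem branch lengths of the
#'   default tree.
#' @param n_core_genes Number of core genes per genome.
#' @param core_len_aa Range of core-gene protein lengths.
#' @param rdh_cluster_sizes Integer vector: number of rdhA genes in each
#'   RDase cluster (each cluster position is one planted orthologue group).
#' @param rdh_len_aa Range of rdhA protein lengths (kept >= 220 aa so planted
#'   genes pass the 200 aa mining floor).
#' @param og_parent_identity Range of amino-acid identity between each
#'   orthologue-group ancestor and its cluster ancestor; the default gives
#'   between-OG identities in the 60-85% band while within-OG identity stays
#'   >= 90%.
#' @param intergenic_mean Mean intergenic spacer length in bp (geometric).
#' @param island Optional list `list(donor=, recipients=, n_cargo=,
#'   identity=, anchor_index=)` describing a mobile island inserted
#'   immediately 3' of a hotspot anchor core gene; the island replaces the
#'   intergenic span so that its true bounds are exactly the inter-core-gene
#'   interval.
#' @param losses,dups Tibbles with columns `genome_id`, `gene_id`.
#' @param transfers Tibble with columns `donor`, `recipient`, `gene_id`,
#'   `identity` describing horizontal replacement of a gene copy.
#' @param decoys Plant per-genome negative controls for RdhA mining (a short
#'   motif-bearing protein, a motif-free "dehalogenase", a pseudogene copy).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       species_tree = NULL,
                       n_clades = 3L, genomes_per_clade = 3L,
                       within_bl = 0.004, between_bl = 0.03,
                       n_core_genes = 40L, core_len_aa = c(220L, 360L),
                       rdh_cluster_sizes = c(5L, 3L),
                       rdh_len_aa = c(280L, 420L),
                       og_parent_identity = c(0.80, 0.90),
                       intergenic_mean = 180,
                       island = NULL,
                       losses = NULL, dups = NULL, transfers = NULL,
                       decoys = TRUE) {
  if (is.null(species_tree)) {
    clades <- LETTERS[seq_len(n_clades)]
    sub <- vapply(clades, function(cl) {
      tips <- paste0(cl, seq_len(genomes_per_clade), ":", within_bl)
      paste0("(", paste(tips, collapse = ","), "):", between_bl)
    }, character(1))
    species_tree <- paste0("(", paste(sub, collapse = ","), ");")
  }
  tree <- ape::read.tree(text = species_tree)
  if (is.null(tree) || ape::Ntip(tree) < 2L) {
    stop("species_tree must have at least 2 leaves", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), species_tree = species_tree,
    n_core_genes = as.integer(n_core_genes), core_len_aa = core_len_aa,
    rdh_cluster_sizes = as.integer(rdh_cluster_sizes), rdh_len_aa = rdh_len_aa,
    og_parent_identity = og_parent_identity, intergenic_mean = intergenic_mean,
    island = island, losses = losses, dups = dups, transfers = transfers,
    decoys = isTRUE(decoys)
  ), class = "sim_config")
}

# Root layout: ordered elements, each with an id, type, root DNA, strand,
# product and frozen sites.  Spacer elements evolve unconstrained.
build_root_layout <- function(config) {
  n_core <- config$n_core_genes
  spacer_len <- function() min(9000L, stats::rgeom(1L, 1 / config$intergenic_mean) + 30L)
  elements <- list()
  add <- function(el) elements[[length(elements) + 1L]] <<- el
  gene_el <- function(id, type, n_aa, product, motif_at = integer(0), og = NA_character_) {
    dna <- random_gene_dna(n_aa, motif_at)
    list(id = id, type = type, dna = dna,
         strand = if (runif(1) < 0.8) "+" else "-",
         product = product, frozen = frozen_sites(nchar(dna), motif_at),
         motif_at = motif_at, og = og)
  }
  spacer_el <- function(id) list(id = id, type = "spacer", dna = random_dna(spacer_len()),
                                 strand = "+", product = "", frozen = integer(0),
                                 motif_at = integer(0), og = NA_character_)
  # positions after which the RDase clusters are inserted
  cluster_after <- unique(pmax(1L, floor(n_core * seq_along(config$rdh_cluster_sizes) /
                                           (length(config$rdh_cluster_sizes) + 1L))))
  anchor_index <- if (!is.null(config$island)) {
    config$island$anchor_index %||% max(2L, floor(n_core * 0.6))
  } else -1L
  add(spacer_el("spc_head"))
  for (i in seq_len(n_core)) {
    len <- sample(seq(config$core_len_aa[1], config$core_len_aa[2]), 1L)
    prod <- if (i == anchor_index + 1L) {
      "23S rRNA (uracil-C(5))-methyltransferase RumA"
    } else {
      core_product_vocab[(i - 1L) %% length(core_product_vocab) + 1L]
    }
    add(gene_el(sprintf("core%03d", i), "core", len, prod))
    if (i == anchor_index) {
      add(list(id = "island_slot", type = "island_slot", dna = "", strand = "+",
               product = "", frozen = integer(0), motif_at = integer(0),
               og = NA_character_))
    } else {
      add(spacer_el(sprintf("spc_core%03d", i)))
    }
    if (i %in% cluster_after) {
      ci <- match(i, cluster_after)
      size <- config$rdh_cluster_sizes[ci]
      # one cluster ancestor; each position (planted OG) diverges from it
      anc_len <- sample(seq(config$rdh_len_aa[1], config$rdh_len_aa[2]), 1L)
      motif_at <- c(40L, 120L)
      anc <- random_gene_dna(anc_len, motif_at)
      frozen_cod <- unique(unlist(lapply(motif_at, function(p) p + c(0L, 3L, 7L)))) + 1L
      for (p in seq_len(size)) {
        tgt <- runif(1, config$og_parent_identity[1], config$og_parent_identity[2])
        dna <- mutate_coding_exact(anc, tgt, frozen_codons = frozen_cod)
        og <- sprintf("sim_c%dp%d", ci, p)
        add(list(id = sprintf("rdhA_c%dp%d", ci, p), type = "rdhA", dna = dna,
                 strand = "+", product = "reductive dehalogenase catalytic subunit RdhA",
                 frozen = frozen_sites(nchar(dna), motif_at), motif_at = motif_at,
                 og = og))
        add(gene_el(sprintf("rdhB_c%dp%d", ci, p), "rdhB", 85L,
                    "reductive dehalogenase membrane anchor protein RdhB"))
        add(spacer_el(sprintf("spc_c%dp%d", ci, p)))
      }
    }
  }
  if (isTRUE(config$decoys)) {
    add(gene_el("decoy_short", "decoy", 150L,
                "reductive dehalogenase catalytic subunit, fragment",
                motif_at = c(30L)))
    add(spacer_el("spc_d1"))
    add(gene_el("decoy_nomotif", "decoy", 260L, "putative reductive dehalogenase"))
    add(spacer_el("spc_d2"))
    add(gene_el("decoy_pseudo", "decoy_pseudo", 250L,
                "reductive dehalogenase catalytic subunit RdhA",
                motif_at = c(40L)))
    add(spacer_el("spc_d3"))
  }
  elements
}

# Island: alternating cargo genes and short spacers; returns element list
# (same shape as layout elements).
build_island <- function(n_cargo) {
  products <- island_cargo_products(n_cargo)
  els <- list()
  add <- function(el) els[[length(els) + 1L]] <<- el
  motif_at <- c(40L, 120L)
  rdh_dna <- random_gene_dna(320L, motif_at)
  add(list(id = "isl_rdhA", type = "island_rdhA", dna = rdh_dna, strand = "+",
           product = "reductive dehalogenase catalytic subunit RdhA",
           frozen = frozen_sites(nchar(rdh_dna), motif_at), motif_at = motif_at,
           og = "sim_island"))
  bdna <- random_gene_dna(85L)
  add(list(id = "isl_rdhB", type = "island_cargo", dna = bdna, strand = "+",
           product = "reductive dehalogenase membrane anchor protein RdhB",
           frozen = frozen_sites(nchar(bdna)), motif_at = integer(0), og = NA_character_))
  for (k in seq_len(n_cargo)) {
    len <- sample(180:320, 1L)
    dna <- random_gene_dna(len)
    add(list(id = sprintf("isl_cargo%02d", k), type = "island_cargo", dna = dna,
             strand = if (runif(1) < 0.7) "+" else "-", product = products[k],
             frozen = frozen_sites(nchar(dna)), motif_at = integer(0),
             og = NA_character_))
    add(list(id = sprintf("isl_spc%02d", k), type = "spacer",
             dna = random_dna(stats::rgeom(1L, 1 / 120) + 20L), strand = "+",
             product = "", frozen = integer(0), motif_at = integer(0),
             og = NA_character_))
  }
  els
}

# Mutate every element of an island copy toward `identity` (coding genes via
# exact codon changes at the matching DNA fraction, spacers via exact DNA
# substitution).
diverge_island <- function(island_els, identity, seed) {
  with_seed(seed, {
    lapply(island_els, function(el) {
      if (el$type == "spacer") {
        el$dna <- mutate_to_identity(el$dna, identity,
                                     seed = sample.int(2^31 - 1, 1L), alphabet = "dna")
      } else {
        frozen_cod <- if (length(el$motif_at)) {
          unique(unlist(lapply(el$motif_at, function(p) p + c(0L, 3L, 7L)))) + 1L
        } else integer(0)
        el$dna <- mutate_coding_exact(el$dna, identity, frozen_codons = frozen_cod)
      }
      el
    })
  })
}

#' Simulate a pangenome with known truth
#'
#' Evolves a fixed root gene/spacer layout along the configured species tree
#' (Jukes-Cantor substitutions, per-branch RNG streams derived from the seed
#' and the child-node label), applies loss/duplication/transfer events,
#' splices the mobile island into donor and recipient genomes at the hotspot
#' anchor, and assembles one circular contig per genome.
#'
#' @param config A [sim_config()].
#' @return A list of class `pangenome_sim` with elements `genomes` (named
#'   list of `genome` objects), `features` (tibble across genomes), `truth`
#'   (list of tibbles: `clades`, `ogs`, `island`, `events`, `genes`) and
#'   `config`.
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- ape::read.tree(text = config$species_tree)
  tips <- tree$tip.label
  layout <- with_seed(derive_seed(config$seed, "root"), build_root_layout(config))
  island_els <- NULL
  if (!is.null(config$island)) {
    island_els <- with_seed(derive_seed(config$seed, "island"),
                            build_island(config$island$n_cargo %||% 22L))
  }

  # evolve layout along the tree; per-branch streams keyed by child label
  n_tip <- ape::Ntip(tree)
  node_label <- function(v) if (v <= n_tip) tips[v] else paste0("node", v)
  node_seqs <- list()
  root <- n_tip + 1L
  node_seqs[[node_label(root)]] <- layout
  tree <- stats::reorder(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(tree$edge))) {
    parent <- node_label(tree$edge[e, 1]); child <- node_label(tree$edge[e, 2])
    bl <- tree$edge.length[e]
    parent_layout <- node_seqs[[parent]]
    node_seqs[[child]] <- with_seed(derive_seed(config$seed, paste0("branch:", child)), {
      lapply(parent_layout, function(el) {
        if (el$type %in% c("spacer", "island_slot")) {
          if (nchar(el$dna)) el$dna <- branch_mutate(el$dna, bl)
          el
        } else {
          el$dna <- branch_mutate(el$dna, bl, frozen = el$frozen, coding = TRUE)
          el
        }
      })
    })
  }

  clade_of <- stats::setNames(sub("[0-9]+$", "", tips), tips)
  carriers <- if (!is.null(config$island)) {
    c(config$island$donor, config$island$recipients)
  } else character(0)
  if (!is.null(config$island) && !is.null(config$losses)) {
    anchor_id <- sprintf("core%03d",
                         config$island$anchor_index %||% max(2L, floor(config$n_core_genes * 0.6)))
    hit <- config$losses$genome_id %in% carriers & config$losses$gene_id == anchor_id
    if (any(hit)) {
      stop("island anchor gene absent from carrier genome(s): ",
           paste(config$losses$genome_id[hit], collapse = ", "), call. = FALSE)
    }
  }

  # per-tip event application + assembly
  genomes <- list(); features_all <- list(); truth_ogs <- list()
  truth_island <- list(); truth_events <- list(); truth_genes <- list()
  for (tip in tips) {
    els <- node_seqs[[tip]]
    ids <- vapply(els, `[[`, character(1), "id")
    ev_seed <- derive_seed(config$seed, paste0("events:", tip))
    with_seed(ev_seed, {
      # losses
      if (!is.null(config$losses)) {
        lose <- config$losses$gene_id[config$losses$genome_id == tip]
        if (length(lose)) {
          keep <- !(ids %in% lose)
          els <- els[keep]; ids <- ids[keep]
          for (g in lose) {
            truth_events[[length(truth_events) + 1L]] <- tibble::tibble(
              type = "loss", genome_id = tip, gene_id = g, donor = NA_character_)
          }
        }
      }
      # duplications: tandem copy at 99% aa identity, inserted after original
      if (!is.null(config$dups)) {
        dup <- config$dups$gene_id[config$dups$genome_id == tip]
        for (g in dup) {
          k <- match(g, ids)
          if (is.na(k)) next
          el <- els[[k]]
          frozen_cod <- if (length(el$motif_at)) {
            unique(unlist(lapply(el$motif_at, function(p) p + c(0L, 3L, 7L)))) + 1L
          } else integer(0)
          el$dna <- mutate_coding_exact(el$dna, 0.99, frozen_codons = frozen_cod)
          el$id <- paste0(g, "_dup")
          els <- append(els, list(el), after = k)
          ids <- vapply(els, `[[`, character(1), "id")
          truth_events[[length(truth_events) + 1L]] <- tibble::tibble(
            type = "duplication", genome_id = tip, gene_id = g, donor = NA_character_)
        }
      }
      # transfers: replace recipient copy with a near-identical donor copy
      if (!is.null(config$transfers)) {
        tr <- dplyr::filter(config$transfers, .data$recipient == tip)
        if (nrow(tr)) {
          for (r in seq_len(nrow(tr))) {
            k <- match(tr$gene_id[r], ids)
            donor_els <- node_seqs[[tr$donor[r]]]
            dk <- match(tr$gene_id[r], vapply(donor_els, `[[`, character(1), "id"))
            if (is.na(k) || is.na(dk)) next
            el <- donor_els[[dk]]
            frozen_cod <- if (length(el$motif_at)) {
              unique(unlist(lapply(el$motif_at, function(p) p + c(0L, 3L, 7L)))) + 1L
            } else integer(0)
            tr_id <- if ("identity" %in% names(tr)) tr$identity[r] else 0.995
            el$dna <- mutate_coding_exact(el$dna, tr_id, frozen_codons = frozen_cod)
            els[[k]] <- el
            truth_events[[length(truth_events) + 1L]] <- tibble::tibble(
              type = "transfer", genome_id = tip, gene_id = tr$gene_id[r],
              donor = tr$donor[r])
          }
        }
      }
    })

    # island splice
    tip_island <- NULL
    if (!is.null(island_els) && tip %in% carriers) {
      tip_island <- if (tip == config$island$donor) {
        island_els
      } else {
        diverge_island(island_els, config$island$identity %||% 0.985,
                       derive_seed(config$seed, paste0("island:", tip)))
      }
    }

    # assemble contig
    pos <- 1L
    feat_rows <- list(); seq_parts <- character(0)
    emit <- function(el, suffix = "") {
      dna <- el$dna
      if (el$type != "spacer" && el$strand == "-") {
        dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
      }
      seq_parts[[length(seq_parts) + 1L]] <<- dna
      if (el$type != "spacer" && el$type != "island_slot") {
        fid <- paste0(tip, "_", el$id, suffix)
        feat_rows[[length(feat_rows) + 1L]] <<- tibble::tibble(
          feature_id = fid, genome_id = tip, contig_id = "chr",
          start = pos, end = pos + nchar(dna) - 1L, strand = el$strand,
          kind = "CDS", product = el$product,
          is_pseudo = el$type == "decoy_pseudo", is_partial = FALSE,
          pseudo_source = ifelse(el$type == "decoy_pseudo", "pseudo=true", NA_character_)
        )
        truth_genes[[length(truth_genes) + 1L]] <<- tibble::tibble(
          feature_id = fid, genome_id = tip, category = el$type, gene_id = el$id)
        if (!is.na(el$og)) {
          truth_ogs[[length(truth_ogs) + 1L]] <<- tibble::tibble(
            protein_id = fid, genome_id = tip, og = el$og)
        }
      }
      pos <<- pos + nchar(dna)
    }
    for (el in els) {
      if (el$type == "island_slot") {
        if (!is.null(tip_island)) {
          isl_start <- pos
          for (iel in tip_island) emit(iel)
          truth_island[[length(truth_island) + 1L]] <- tibble::tibble(
            genome_id = tip, contig_id = "chr", start = isl_start, end = pos - 1L,
            role = ifelse(tip == config$island$donor, "donor", "recipient"))
        } else {
          # non-carriers keep the ancestral intergenic span
          emit(list(id = el$id, type = "spacer", dna = el$dna, strand = "+",
                    product = "", motif_at = integer(0), og = NA_character_))
        }
      } else {
        emit(el)
      }
    }
    genomes[[tip]] <- new_genome(tip, stats::setNames(paste(seq_parts, collapse = ""), "chr"),
                                 circular = TRUE, clade = clade_of[[tip]])
    features_all[[tip]] <- dplyr::bind_rows(feat_rows)
  }

  structure(list(
    genomes = genomes,
    features = dplyr::bind_rows(features_all),
    truth = list(
      clades = tibble::tibble(genome_id = tips, clade = unname(clade_of[tips])),
      ogs = dplyr::bind_rows(truth_ogs),
      island = dplyr::bind_rows(truth_island),
      events = dplyr::bind_rows(truth_events),
      genes = dplyr::bind_rows(truth_genes)
    ),
    config = config
  ), class = "pangenome_sim")
}

#' Simulate a genome pair at an exact site identity
#'
#' Generates one random genome and derives the second by exact-count uniform
#' substitution, so the planted nucleotide identity is exact.  Used to
#' calibrate ANI estimates against known divergence.
#'
#' @param site_identity Fraction in (0, 1].
#' @param length Genome length in bp.
#' @param seed Integer seed.
#' @return List with `genome_a`, `genome_b` and `planted_identity`.
#' @export
simulate_genome_pair <- function(site_identity, length = 60000L, seed = 1L) {
  g1 <- with_seed(derive_seed(seed, "pair_a"), random_dna(length))
  g2 <- mutate_to_identity(g1, site_identity, seed = derive_seed(seed, "pair_b"),
                           alphabet = "dna")
  list(
    genome_a = new_genome("gA", c(chr = g1)),
    genome_b = new_genome("gB", c(chr = g2)),
    planted_identity = round(length * site_identity) / length
  )
}

#' Simulate a protein benchmark of planted orthologue groups
#'
#' Generates `n_ogs` orthologue-group ancestors from one grand ancestor
#' (each at 82-88% identity to it, so between-OG identities land in the
#' 65-85% band) and `members_per_og` members per group at `within_identity`
#' to their ancestor (pairwise within-OG identity therefore at least
#' `2 * within_identity - 1`: >= 94% at the default, and >= 92% for any
#' `within_identity >= 0.96`).  Exact-count substitution keeps the identity
#' arithmetic sharp for threshold tests.
#'
#' @param n_ogs Number of planted groups (default 8).
#' @param members_per_og Members per group (default 5).
#' @param length_aa Protein length (default 320).
#' @param within_identity Member-to-ancestor identity (default 0.97).
#' @param seed Integer seed.
#' @return List with `proteins` (named character vector) and `truth`
#'   (tibble `protein_id`, `og`).
#' @export
simulate_og_benchmark <- function(n_ogs = 8L, members_per_og = 5L,
                                  length_aa = 320L, within_identity = 0.97,
                                  seed = 1L) {
  anc <- with_seed(derive_seed(seed, "og_anc"), {
    paste(sample(AA20, length_aa, replace = TRUE), collapse = "")
  })
  proteins <- character(0)
  truth <- list()
  for (g in seq_len(n_ogs)) {
    t_g <- 0.82 + 0.06 * (g - 1) / max(1L, n_ogs - 1L)
    parent <- mutate_to_identity(anc, t_g, seed = derive_seed(seed, paste0("par", g)),
                                 alphabet = "protein")
    for (k in seq_len(members_per_og)) {
      id <- sprintf("og%02d_m%d", g, k)
      proteins[[id]] <- mutate_to_identity(
        parent, within_identity,
        seed = derive_seed(seed, paste0("mem", g, "_", k)), alphabet = "protein")
      truth[[length(truth) + 1L]] <- tibble::tibble(protein_id = id,
                                                    og = sprintf("og%02d", g))
    }
  }
  list(proteins = proteins, truth = dplyr::bind_rows(truth))
}

#' Named simulation fixtures
#'
#' Small registry of ready-made study conditions: `"small"` (4 genomes, 2
#' clades), `"medium"` (9 genomes, 3 clades; within-clade nucleotide identity
#' ~99%, between ~93%), `"island"` (6 genomes, a ~20 kb mobile island carried
#' by a donor and one recipient across clades) and `"hgt-og"` (6 genomes with
#' one rdhA orthologue group member transferred across clades, against a
#' backdrop of vertically inherited OGs).
#'
#' @param name Fixture name.
#' @param seed Integer seed.
#' @return A `pangenome_sim` (see [simulate_pangenome()]).
#' @export
sim_fixture <- function(name = c("small", "medium", "island", "hgt-og"), seed = 1L) {
  name <- match.arg(name)
  config <- switch(
    name,
    small = sim_config(seed = seed, n_clades = 2L, genomes_per_clade = 2L,
                       n_core_genes = 30L, rdh_cluster_sizes = 4L),
    medium = sim_config(seed = seed, n_clades = 3L, genomes_per_clade = 3L,
                        n_core_genes = 40L, rdh_cluster_sizes = c(5L, 3L)),
    island = sim_config(seed = seed, n_clades = 2L, genomes_per_clade = 3L,
                        n_core_genes = 40L, rdh_cluster_sizes = 4L,
                        island = list(donor = "B1", recipients = "A1",
                                      n_cargo = 22L, identity = 0.985)),
    `hgt-og` = sim_config(seed = seed, n_clades = 2L, genomes_per_clade = 3L,
                          n_core_genes = 40L, rdh_cluster_sizes = 5L,
                          within_bl = 0.003, between_bl = 0.012,
                          transfers = tibble::tibble(
                            donor = "A1", recipient = "B2",
                            gene_id = "rdhA_c1p2", identity = 0.995))
  )
  simulate_pangenome(config)
}

#' Write a fixture bundle to disk
#'
#' Emits per-genome FASTA and GFF3 plus truth TSVs (clades, orthologue
#' groups, island bounds, events) under `dir`.
#'
#' @param name Fixture name (see [sim_fixture()]).
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the output directory.
#' @export
emit_fixture <- function(name, dir, seed = 1L) {
  sim <- sim_fixture(name, seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in sim$genomes) {
    write_genome(g, sim$features,
                 fasta_path = file.path(dir, paste0(g$genome_id, ".fna")),
                 gff_path = file.path(dir, paste0(g$genome_id, ".gff3")))
  }
  for (nm in c("clades", "ogs", "island", "events")) {
    utils::write.table(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
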