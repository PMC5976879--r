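# Synthetic data: two homologous ~320-aa protein families (a BSH-like and a
# PVA-like family, confusable at the sequence level), planted conserved
# motifs with the catalytic Cys at consensus position 2, reverse-translated
# and embedded as ORFs in genome-like nucleotide records with species/strain
# structure, lifestyle labels, and a complete truth table.

#' Specification of a simulated protein family
#'
#' Motif blocks pin anchor residues that are never mutated, emulating
#' active-site constraints. The default blocks place Met1/Cys2 at the
#' N-terminus (the catalytic cysteine of choloylglycine hydrolases) plus five
#' further short blocks, giving six "active sites" to audit downstream.
#'
#' @param name family name, e.g. `"BSH-like"` or `"PVA-like"`
#' @param consensus_len consensus length in residues
#' @param motif_blocks list of blocks, each `list(start =, residues =)` with
#'   1-based start column and an anchor residue string (length >= 3 for
#'   motif-calling tests; the Met1/Cys2 block is part of the first block)
#' @param divergence expected substituted fraction per simulated member
#' @param shared_ancestry fraction of consensus positions identical between
#'   the two families
#' @return a `family_spec` list
#' @export
family_spec <- function(name = "BSH-like",
                        consensus_len = 320,
                        motif_blocks = default_motif_blocks(),
                        divergence = 0.3,
                        shared_ancestry = 0.4) {
  stopifnot(consensus_len >= 1)
  if (!(divergence >= 0 && divergence < 1)) {
    stop("divergence must be in [0, 1)", call. = FALSE)
  }
  if (!(shared_ancestry >= 0 && shared_ancestry <= 1)) {
    stop("shared_ancestry must be in [0, 1]", call. = FALSE)
  }
  ends <- integer(0)
  blocks <- lapply(motif_blocks, function(b) {
    stopifnot(is.numeric(b$start), is.character(b$residues))
    b$start <- as.integer(b$start)
    b$len <- nchar(b$residues)
    if (b$start < 1 || b$start + b$len - 1L > consensus_len) {
      stop("motif block outside consensus range", call. = FALSE)
    }
    b
  })
  pos <- unlist(lapply(blocks, function(b) seq(b$start, b$start + b$len - 1L)))
  if (anyDuplicated(pos)) stop("motif blocks overlap", call. = FALSE)
  structure(list(name = name, consensus_len = as.integer(consensus_len),
                 motif_blocks = blocks, divergence = divergence,
                 shared_ancestry = shared_ancestry),
            class = "family_spec")
}

#' Default motif blocks for simulated families
#'
#' Six disjoint anchor blocks within a 320-residue consensus; the first
#' carries Met1 and the catalytic Cys2.
#'
#' @return list of motif blocks usable in [family_spec()]
#' @export
default_motif_blocks <- function() {
  list(list(start = 1L,   residues = "MCTG"),
       list(start = 58L,  residues = "NDAG"),
       list(start = 80L,  residues = "GLN"),
       list(start = 130L, residues = "RFE"),
       list(start = 172L, residues = "DGS"),
       list(start = 224L, residues = "WLAR"))
}

anchor_positions <- function(spec) {
  unlist(lapply(spec$motif_blocks,
                function(b) seq(b$start, b$start + b$len - 1L)))
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

substitute_residue <- function(chars, at) {
  # uniform replacement over the 19 alternative residues
  for (i in at) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1)
  }
  chars
}

place_anchors <- function(chars, spec) {
  for (b in spec$motif_blocks) {
    chars[seq(b$start, b$start + b$len - 1L)] <-
      strsplit(b$residues, "")[[1]]
  }
  chars
}

#' Generate a pair of family consensus sequences
#'
#' Draws a random consensus for the first family, then copies each non-anchor
#' position into the second family's consensus with probability
#' `shared_ancestry` (otherwise substituting a different residue), and stamps
#' each family's motif anchors exactly.
#'
#' @param spec_a,spec_b [family_spec()] objects of equal `consensus_len`
#' @param seed integer seed
#' @return named list of two consensus protein strings
#' @export
make_consensus_pair <- function(spec_a, spec_b, seed) {
  if (spec_a$consensus_len != spec_b$consensus_len) {
    stop("consensus lengths differ; shared-ancestry construction undefined",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- spec_a$consensus_len
  a <- strsplit(random_protein(n), "")[[1]]
  a <- place_anchors(a, spec_a)
  b <- a
  # anchors are shared by construction when both specs use the same blocks;
  # pick the number of additionally-shared free positions so that the overall
  # identical fraction hits shared_ancestry as closely as the anchors allow
  free <- setdiff(seq_len(n), anchor_positions(spec_b))
  n_keep <- max(0L, min(length(free),
                        round(spec_b$shared_ancestry * n) -
                          (n - length(free))))
  keep <- if (n_keep > 0) sample(free, n_keep) else integer(0)
  diverge <- setdiff(free, keep)
  b <- substitute_residue(b, diverge)
  b <- place_anchors(b, spec_b)
  out <- list(paste(a, collapse = ""), paste(b, collapse = ""))
  names(out) <- c(spec_a$name, spec_b$name)
  out
}

#' Evolve a family member from a consensus
#'
#' Substitutes non-anchor sites independently at the per-site `divergence`
#' rate; anchor residues are never mutated; no indels.
#'
#' @param consensus consensus protein string
#' @param divergence per-site substitution probability in `[0, 1)`
#' @param motif_blocks anchor blocks as in [family_spec()]
#' @param seed integer seed
#' @return protein string of the same length
#' @export
evolve_member <- function(consensus, divergence, motif_blocks = list(),
                          seed = NULL) {
  if (!(divergence >= 0 && divergence < 1)) {
    stop("divergence must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  chars <- strsplit(consensus, "")[[1]]
  anchors <- unlist(lapply(motif_blocks, function(b) {
    len <- if (!is.null(b$len)) b$len else nchar(b$residues)
    seq(as.integer(b$start), as.integer(b$start) + len - 1L)
  }))
  free <- setdiff(seq_along(chars), anchors)
  hit <- free[runif(length(free)) < divergence]
  chars <- substitute_residue(chars, hit)
  paste(chars, collapse = "")
}

codon_table_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(protein) {
  by_aa <- codon_table_by_aa()
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- by_aa[[a]]
    if (a == "M") return("ATG")  # simplified bacterial start handling
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste(codons, collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Embed proteins as ORFs in a synthetic genome record
#'
#' Each protein (which must start with Met) is reverse-translated with
#' uniform synonymous codon choice, given an ATG start and a stop codon,
#' framed by an in-frame upstream stop so the ATG founds a maximal ORF,
#' placed on a random strand, and separated by random non-coding flanks.
#' Forward-strand 0-based half-open coordinates of the coding span (start
#' codon through stop codon) are recorded in the truth rows.
#'
#' @param proteins character vector of protein sequences (or a `seq_records`
#'   data frame); each must begin with `M`
#' @param flank_len random flank length in nucleotides between genes
#' @param seed integer seed (`NULL` to use the current RNG state)
#' @param genome_id id for the generated record
#' @param species,strain provenance stored on the record
#' @return list with `genome` (one-row `seq_records`) and `truth` (data frame
#'   with `protein_id`, `strand`, `start`, `end`)
#' @export
embed_in_genome <- function(proteins, flank_len = 60, seed = NULL,
                            genome_id = "g1", species = NA_character_,
                            strain = NA_character_) {
  if (is.data.frame(proteins)) {
    ids <- proteins$id
    seqs <- proteins$sequence
  } else {
    nms <- names(proteins)
    seqs <- as.character(proteins)
    ids <- if (!is.null(nms) && all(nzchar(nms))) {
      nms
    } else {
      paste0("p", seq_along(seqs))
    }
  }
  if (length(seqs) == 0) stop("no proteins to embed", call. = FALSE)
  if (any(substr(seqs, 1, 1) != "M")) {
    stop("embedded proteins must start with Met (ATG start codon model)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  pieces <- character(0)
  cursor <- 0L
  truth <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    flank <- random_dna(flank_len)
    # in-frame stop immediately 5' of the gene start: the ATG founds the ORF
    cds_fwd <- paste0(reverse_translate(seqs[i]),
                      sample(c("TAA", "TAG", "TGA"), 1))
    lead <- paste0(flank, "TAA")
    strand <- sample(c("+", "-"), 1)
    if (strand == "+") {
      block <- paste0(lead, cds_fwd)
      start <- cursor + nchar(lead)
      end <- start + nchar(cds_fwd)
    } else {
      block <- paste0(revcomp(cds_fwd), revcomp(lead))
      start <- cursor
      end <- start + nchar(cds_fwd)
    }
    pieces <- c(pieces, block)
    truth[[i]] <- data.frame(protein_id = ids[i], strand = strand,
                             start = start, end = end,
                             stringsAsFactors = FALSE)
    cursor <- cursor + nchar(block)
  }
  pieces <- c(pieces, random_dna(flank_len))
  genome <- new_seq_records(id = genome_id, species = species,
                            strain = strain,
                            sequence = paste(pieces, collapse = ""),
                            kind = "nucleotide")
  truth <- do.call(rbind, truth)
  truth$genome_id <- genome_id
  list(genome = genome, truth = truth)
}

#' Simulation configuration for a full synthetic dataset
#'
#' Defaults emulate the survey design: species-structured genomes whose
#' per-species BSH copy numbers fall in 0..3 (mirroring the published
#' per-species "1 BSH / 2 BSH / 3 BSH" layout), reference sets of 26 BSH-like
#' and 8 PVA-like members, and per-genome decoy proteins unrelated to either
#' family that exercise the 30%-identity screen and the E-value retention
#' rule.
#'
#' @param n_species number of species
#' @param strains_per_species strains per species (recycled)
#' @param bsh_copies per-species BSH gene copies, each in 0..3 (recycled)
#' @param pva_copies per-species PVA gene copies (recycled)
#' @param lifestyles per-species lifestyle labels (recycled)
#' @param n_decoys decoy proteins per genome
#' @param decoy_len decoy protein length in residues
#' @param divergence per-site substitution rate from the family consensus
#' @param shared_ancestry consensus identity between the two families
#' @param ref_divergence divergence used for reference-set members
#' @param n_ref_bsh,n_ref_pva reference-set sizes
#' @param consensus_len family consensus length in residues
#' @param flank_len intergenic flank length in nucleotides
#' @param motif_blocks anchor blocks for both families (see [family_spec()]);
#'   must fit within `consensus_len`
#' @return a `sim_config` list
#' @export
sim_config <- function(n_species = 6,
                       strains_per_species = 2,
                       bsh_copies = c(1, 2, 3, 0, 1, 0),
                       pva_copies = c(0, 1, 0, 1, 1, 0),
                       lifestyles = c("vertebrate-adapted", "vertebrate-adapted",
                                      "free-living", "unknown",
                                      "nomadic", "free-living"),
                       n_decoys = 1,
                       decoy_len = 150,
                       divergence = 0.3,
                       shared_ancestry = 0.4,
                       ref_divergence = 0.15,
                       n_ref_bsh = 26,
                       n_ref_pva = 8,
                       consensus_len = 320,
                       flank_len = 60,
                       motif_blocks = default_motif_blocks()) {
  if (n_species > 0) {
    bsh_copies <- rep_len(as.integer(bsh_copies), n_species)
    pva_copies <- rep_len(as.integer(pva_copies), n_species)
    lifestyles <- rep_len(as.character(lifestyles), n_species)
    strains_per_species <- rep_len(as.integer(strains_per_species), n_species)
  }
  if (n_species > 0 && !all(bsh_copies %in% 0:3 & pva_copies %in% 0:3)) {
    stop("per-species copy numbers must be in 0..3", call. = FALSE)
  }
  if (n_species > 0 && !all(lifestyles %in% LIFESTYLES)) {
    stop("invalid lifestyle label in sim_config", call. = FALSE)
  }
  structure(list(n_species = as.integer(n_species),
                 strains_per_species = strains_per_species,
                 bsh_copies = bsh_copies, pva_copies = pva_copies,
                 lifestyles = lifestyles, n_decoys = as.integer(n_decoys),
                 decoy_len = as.integer(decoy_len),
                 divergence = divergence, shared_ancestry = shared_ancestry,
                 ref_divergence = ref_divergence,
                 n_ref_bsh = as.integer(n_ref_bsh),
                 n_ref_pva = as.integer(n_ref_pva),
                 consensus_len = as.integer(consensus_len),
                 flank_len = as.integer(flank_len),
                 motif_blocks = motif_blocks),
            class = "sim_config")
}

family_reference_set <- function(consensus, spec, n, prefix) {
  seqs <- vapply(seq_len(n), function(i) {
    evolve_member(consensus, spec$ref_divergence %||% 0.15,
                  spec$motif_blocks)
  }, character(1))
  new_seq_records(id = sprintf("%s_ref%02d", prefix, seq_len(n)),
                  species = NA_character_, strain = NA_character_,
                  sequence = seqs, kind = "protein")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a complete synthetic dataset bundle
#'
#' Deterministic under `(config, seed)`. Produces genomes with planted BSH-
#' and PVA-family ORFs plus decoys, the two reference protein sets with their
#' (indel-free) reference alignments, strain metadata, and the ground-truth
#' table. If `dir` is given, all files are also written in the formats the
#' readers in this package consume.
#'
#' @param config a [sim_config()]
#' @param seed integer seed
#' @param dir optional output directory for the file bundle
#' @return list with `genomes`, `refs_bsh`, `refs_pva`, `msa_bsh`, `msa_pva`,
#'   `metadata`, `truth`, `consensus`, and `config`
#' @export
generate_dataset <- function(config = sim_config(), seed = 1, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  spec_bsh <- family_spec("BSH-like", config$consensus_len,
                          motif_blocks = config$motif_blocks,
                          divergence = config$divergence,
                          shared_ancestry = config$shared_ancestry)
  spec_pva <- family_spec("PVA-like", config$consensus_len,
                          motif_blocks = config$motif_blocks,
                          divergence = config$divergence,
                          shared_ancestry = config$shared_ancestry)
  cons <- make_consensus_pair(spec_bsh, spec_pva, seed = sample.int(2^31 - 1, 1))
  spec_bsh$ref_divergence <- config$ref_divergence
  spec_pva$ref_divergence <- config$ref_divergence
  refs_bsh <- family_reference_set(cons[[1]], spec_bsh, config$n_ref_bsh, "BSH")
  refs_pva <- family_reference_set(cons[[2]], spec_pva, config$n_ref_pva, "PVA")
  msa_bsh <- msa(refs_bsh$id, refs_bsh$sequence)  # indel-free families
  msa_pva <- msa(refs_pva$id, refs_pva$sequence)

  genomes <- list(); truth <- list(); meta <- list()
  if (config$n_species > 0) {
    for (s in seq_len(config$n_species)) {
      species <- sprintf("Species_%02d", s)
      for (k in seq_len(config$strains_per_species[s])) {
        strain <- sprintf("st%02d", k)
        gid <- sprintf("%s_%s", species, strain)
        prot_seq <- character(0); prot_lab <- character(0)
        nb <- config$bsh_copies[s]; np <- config$pva_copies[s]
        if (nb > 0) {
          prot_seq <- c(prot_seq, vapply(seq_len(nb), function(i)
            evolve_member(cons[[1]], config$divergence,
                          spec_bsh$motif_blocks), character(1)))
          prot_lab <- c(prot_lab, rep("BSH", nb))
        }
        if (np > 0) {
          prot_seq <- c(prot_seq, vapply(seq_len(np), function(i)
            evolve_member(cons[[2]], config$divergence,
                          spec_pva$motif_blocks), character(1)))
          prot_lab <- c(prot_lab, rep("PVA", np))
        }
        if (config$n_decoys > 0) {
          prot_seq <- c(prot_seq, vapply(seq_len(config$n_decoys), function(i)
            paste0("M", random_protein(config$decoy_len - 1L)), character(1)))
          prot_lab <- c(prot_lab, rep("decoy", config$n_decoys))
        }
        if (length(prot_seq) == 0) {
          genomes[[gid]] <- new_seq_records(gid, species, strain,
                                            random_dna(6 * config$flank_len),
                                            "nucleotide")
        } else {
          names(prot_seq) <- sprintf("%s_p%02d", gid, seq_along(prot_seq))
          emb <- embed_in_genome(prot_seq, flank_len = config$flank_len,
                                 genome_id = gid, species = species,
                                 strain = strain)
          genomes[[gid]] <- emb$genome
          tr <- emb$truth
          tr$species <- species; tr$strain <- strain; tr$family <- prot_lab
          tr$sequence <- unname(prot_seq)
          truth[[gid]] <- tr
        }
        meta[[gid]] <- data.frame(species = species, strain = strain,
                                  lifestyle = config$lifestyles[s],
                                  stringsAsFactors = FALSE)
      }
    }
  }
  genomes <- if (length(genomes)) do.call(rbind, c(genomes, make.row.names = FALSE))
             else empty_seq_records("nucleotide")
  attr(genomes, "kind") <- "nucleotide"
  class(genomes) <- c("seq_records", "data.frame")
  truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
           else data.frame(protein_id = character(), strand = character(),
                           start = integer(), end = integer(),
                           genome_id = character(), species = character(),
                           strain = character(), family = character(),
                           sequence = character(), stringsAsFactors = FALSE)
  meta <- if (length(meta)) do.call(rbind, c(meta, make.row.names = FALSE))
          else data.frame(species = character(), strain = character(),
                          lifestyle = character(), stringsAsFactors = FALSE)
  bundle <- list(genomes = genomes, refs_bsh = refs_bsh, refs_pva = refs_pva,
                 msa_bsh = msa_bsh, msa_pva = msa_pva, metadata = meta,
                 truth = truth, consensus = cons, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genomes, file.path(dir, "genomes.fasta"))
    write_fasta(refs_bsh, file.path(dir, "refs_bsh.faa"))
    write_fasta(refs_pva, file.path(dir, "refs_pva.faa"))
    write_stockholm(msa_bsh, file.path(dir, "refs_bsh.sto"))
    write_stockholm(msa_pva, file.path(dir, "refs_pva.sto"))
    write_metadata(meta, file.path(dir, "metadata.tsv"))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  bundle
}
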