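# Built-in deterministic multiple alignment for cluster representatives: a
# center-star construction. The longest sequence (ties by id) is the
# center; every other sequence is globally aligned to it with affine gaps,
# and the pairwise alignments are projected onto a shared gapped frame by
# merging the per-slot insertion lengths. Exact for indel-free inputs, a
# reasonable approximation for the moderately diverged protein families this
# pipeline aligns; a precomputed Stockholm alignment can be supplied instead
# anywhere an alignment is consumed.

parse_vs_center <- function(pa, pc) {
  # pa: aligned sequence, pc: aligned center. Returns, per center slot
  # 0..L (before residue 1, between residues, after residue L), the inserted
  # characters of `pa`, plus the character of `pa` opposite each center
  # residue.
  ca <- strsplit(pa, "")[[1]]
  cc <- strsplit(pc, "")[[1]]
  L <- sum(cc != "-")
  ins <- vector("list", L + 1L)
  for (k in seq_len(L + 1L)) ins[[k]] <- character(0)
  opp <- character(L)
  slot <- 1L
  for (i in seq_along(cc)) {
    if (cc[i] == "-") {
      ins[[slot]] <- c(ins[[slot]], ca[i])
    } else {
      opp[slot] <- ca[i]
      slot <- slot + 1L
    }
  }
  list(ins = ins, opp = opp)
}

#' Center-star multiple alignment of proteins
#'
#' @param proteins data frame with `id` and `sequence`
#' @param matrix,gap_open,gap_extend pairwise alignment scoring
#' @return an [msa()] with rows in input order
#' @export
star_align <- function(proteins, matrix = "BLOSUM62", gap_open = 11,
                       gap_extend = 1) {
  n <- nrow(proteins)
  if (n == 0) stop("nothing to align", call. = FALSE)
  if (n == 1) return(msa(proteins$id, proteins$sequence))
  center <- order(-nchar(proteins$sequence), proteins$id)[1]
  cen_seq <- proteins$sequence[center]
  L <- nchar(cen_seq)
  others <- setdiff(seq_len(n), center)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(proteins$sequence[others]),
    Biostrings::AAString(cen_seq), type = "global",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pc <- as.character(Biostrings::alignedSubject(aln))
  parsed <- lapply(seq_along(others), function(i) parse_vs_center(pa[i], pc[i]))
  max_ins <- integer(L + 1L)
  for (p in parsed) {
    lens <- lengths(p$ins)
    max_ins <- pmax(max_ins, lens)
  }
  project <- function(ins, opp) {
    out <- character(0)
    for (k in seq_len(L + 1L)) {
      block <- c(ins[[k]], rep("-", max_ins[k] - length(ins[[k]])))
      out <- c(out, block)
      if (k <= L) out <- c(out, opp[k])
    }
    paste(out, collapse = "")
  }
  rows <- character(n)
  cen_chars <- strsplit(cen_seq, "")[[1]]
  rows[center] <- project(lapply(seq_len(L + 1L), function(k) character(0)),
                          cen_chars)
  for (i in seq_along(others)) {
    rows[others[i]] <- project(parsed[[i]]$ins, parsed[[i]]$opp)
  }
  msa(proteins$id, rows)
}
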