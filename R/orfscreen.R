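# Translated-search screening stage: six-frame translation of genome
# records, ATG-to-stop ORF extraction with a minimum-length floor, and local
# alignment of each ORF against the curated reference proteins with an
# identity floor. Re-creates what a BLASTX search plus result filtering did,
# without heuristic seeding.

translate_frame <- function(dna_string, offset) {
  len <- Biostrings::nchar(dna_string) - offset
  len <- len - (len %% 3L)
  if (len < 3L) return("")
  sub <- Biostrings::subseq(dna_string, start = offset + 1L,
                            width = len)
  as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Six-frame translation of a nucleotide sequence
#'
#' Frames `+1..+3` read the forward sequence at offsets 0..2; `-1..-3` read
#' the reverse complement at offsets 0..2. Trailing partial codons are
#' dropped; stop codons are rendered `*`; codons containing `N` translate to
#' `X`.
#'
#' @param sequence nucleotide string, or a one-row `seq_records` data frame
#' @return named character vector of the six translations
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`)
#' @export
six_frame_translate <- function(sequence) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  if (nchar(sequence) < 3) {
    warning("sequence shorter than one codon; returning empty frames")
    return(setNames(rep("", 6), c("+1", "+2", "+3", "-1", "-2", "-3")))
  }
  fwd <- Biostrings::DNAString(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  out <- c(vapply(0:2, function(o) translate_frame(fwd, o), character(1)),
           vapply(0:2, function(o) translate_frame(rev, o), character(1)))
  setNames(out, c("+1", "+2", "+3", "-1", "-2", "-3"))
}

orfs_in_frame <- function(aa, frame, genome_len, min_orf_len) {
  if (!nzchar(aa)) return(NULL)
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  stops <- which(chars == "*")
  seg_starts <- c(1L, stops + 1L)
  seg_stops <- c(stops, length(chars) + 1L)  # position of terminating stop
  out <- list()
  for (k in seq_along(seg_starts)) {
    if (seg_stops[k] <= seg_starts[k]) next
    seg <- seg_starts[k]:(seg_stops[k] - 1L)
    m <- seg[which(chars[seg] == "M")[1]]
    if (is.na(m)) next
    has_stop <- seg_stops[k] <= length(chars)
    protein <- paste(chars[m:(seg_stops[k] - 1L)], collapse = "")
    if (nchar(protein) < min_orf_len) next
    offset <- abs(frame) - 1L
    # codon coordinates within the translated frame, 0-based
    c_start <- m - 1L
    c_end <- if (has_stop) seg_stops[k] else seg_stops[k] - 1L  # incl. stop
    s <- offset + 3L * c_start
    e <- offset + 3L * c_end
    if (frame < 0) {
      tmp <- genome_len - e
      e <- genome_len - s
      s <- tmp
    }
    out[[length(out) + 1L]] <- data.frame(
      frame = if (frame > 0) paste0("+", frame) else as.character(frame),
      start = s, end = e, protein = protein, has_stop = has_stop,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Extract ORFs from genome records
#'
#' An ORF is a maximal ATG-to-stop segment within one of the six reading
#' frames: the first Met after the previous in-frame stop opens the ORF,
#' which runs to the next stop (or to the frame end, for truncated genes).
#' ORFs whose encoded protein is shorter than `min_orf_len` residues are
#' discarded; a protein of exactly `min_orf_len` is retained.
#'
#' @param genomes `seq_records` data frame of nucleotide records
#' @param min_orf_len minimum protein length in residues
#' @return data frame with `genome_id`, `orf_id`, `frame`, `start`, `end`
#'   (0-based half-open forward-strand nucleotide coordinates including the
#'   stop codon when present), `protein`, `has_stop`
#' @export
extract_orfs <- function(genomes, min_orf_len = 100) {
  stopifnot(min_orf_len >= 1)
  res <- list()
  for (i in seq_len(nrow(genomes))) {
    frames <- six_frame_translate(genomes$sequence[i])
    glen <- nchar(genomes$sequence[i])
    per <- lapply(c(1L, 2L, 3L, -1L, -2L, -3L), function(f) {
      key <- if (f > 0) paste0("+", f) else as.character(f)
      orfs_in_frame(frames[[key]], f, glen, min_orf_len)
    })
    per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
    if (is.null(per) || nrow(per) == 0) next
    per$genome_id <- genomes$id[i]
    per$species <- genomes$species[i]
    per$strain <- genomes$strain[i]
    res[[length(res) + 1L]] <- per
  }
  if (!length(res)) {
    return(data.frame(genome_id = character(), species = character(),
                      strain = character(), orf_id = character(),
                      frame = character(), start = integer(),
                      end = integer(), protein = character(),
                      has_stop = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out$orf_id <- sprintf("%s|%s|%d-%d", out$genome_id, out$frame,
                        out$start, out$end)
  rownames(out) <- NULL
  out[, c("genome_id", "species", "strain", "orf_id", "frame", "start",
          "end", "protein", "has_stop")]
}

#' Optimal local alignment of two proteins with affine gaps
#'
#' Smith-Waterman alignment under a substitution matrix with affine gap
#' penalties (defaults match translated-BLAST scoring: BLOSUM62, open 11,
#' extend 1). Identity is reported two ways: `identity`, identical aligned
#' pairs over aligned columns including internal gap columns (BLAST-style),
#' and `identity_short`, identical pairs over the length of the shorter
#' input (the convention of identity-threshold clustering tools).
#'
#' @param a,b protein strings
#' @param matrix substitution matrix name (e.g. `"BLOSUM62"`) or a numeric
#'   matrix
#' @param gap_open,gap_extend affine gap penalties (positive numbers)
#' @return list with `score`, `identity`, `identity_short`, `aligned_a`,
#'   `aligned_b`; a best score of zero or less is reported as no alignment
#'   (identity 0, empty aligned strings)
#' @export
smith_waterman <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend)
  score <- Biostrings::score(aln)
  if (score <= 0) {
    return(list(score = score, identity = 0, identity_short = 0,
                aligned_a = "", aligned_b = ""))
  }
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  n_ident <- sum(ca == cb & ca != "-")
  list(score = score,
       identity = n_ident / length(ca),
       identity_short = n_ident / min(nchar(a), nchar(b)),
       aligned_a = pa, aligned_b = pb)
}

# Vectorised best-identity of one ORF protein against a reference set.
best_reference_hit <- function(protein, references, matrix = "BLOSUM62",
                               gap_open = 11, gap_extend = 1,
                               identity = "short") {
  pats <- Biostrings::AAStringSet(references$sequence)
  aln <- Biostrings::pairwiseAlignment(
    pats, Biostrings::AAString(protein), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend)
  scores <- Biostrings::score(aln)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  idents <- vapply(seq_along(pa), function(i) {
    if (scores[i] <= 0) return(0)
    ca <- strsplit(pa[i], "")[[1]]
    cb <- strsplit(pb[i], "")[[1]]
    n_ident <- sum(ca == cb & ca != "-")
    denom <- if (identity == "short") {
      min(nchar(references$sequence[i]), nchar(protein))
    } else {
      length(ca)
    }
    n_ident / denom
  }, numeric(1))
  best <- which.max(idents)
  list(best_ref_id = references$id[best], best_identity = idents[best],
       score = scores[best])
}

#' Screen ORFs against a reference protein set
#'
#' Aligns every ORF to every reference, retains ORFs whose best identity is
#' at least `min_ref_identity` (an ORF at exactly the threshold is kept), and
#' collapses overlapping retained ORFs at the same genomic locus to the
#' single highest-identity candidate.
#'
#' By default the screening identity uses the shorter-sequence denominator
#' (identical aligned positions over the length of the shorter of ORF and
#' reference). The aligned-column denominator (`identity = "alignment"`) is
#' available but unreliable here: without E-value filtering of short
#' high-scoring pairs, a chance 3-of-4-column local alignment of an
#' unrelated ORF scores 75% identity, so unrelated sequences would pass any
#' identity floor.
#'
#' @param orfs output of [extract_orfs()]
#' @param references `seq_records` data frame of reference proteins
#' @param min_ref_identity identity floor (fraction)
#' @param identity `"short"` (default) or `"alignment"`, see Details
#' @param matrix,gap_open,gap_extend alignment scoring, see
#'   [smith_waterman()]
#' @return candidate data frame: `genome_id`, `species`, `strain`, `orf_id`,
#'   `frame`, `start`, `end`, `protein`, `best_ref_id`, `best_identity`,
#'   `score`
#' @export
screen_candidates <- function(orfs, references, min_ref_identity = 0.30,
                              identity = c("short", "alignment"),
                              matrix = "BLOSUM62", gap_open = 11,
                              gap_extend = 1) {
  identity <- match.arg(identity)
  if (nrow(references) == 0) {
    stop("reference set is empty", call. = FALSE)
  }
  hits <- lapply(orfs$protein, best_reference_hit, references = references,
                 matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, identity = identity)
  out <- orfs
  out$best_ref_id <- vapply(hits, `[[`, "", "best_ref_id")
  out$best_identity <- vapply(hits, `[[`, 0, "best_identity")
  out$score <- vapply(hits, `[[`, 0, "score")
  out <- out[out$best_identity >= min_ref_identity, , drop = FALSE]
  if (nrow(out) == 0) { rownames(out) <- NULL; return(out) }
  # collapse overlapping same-genome loci: highest identity wins
  keep <- logical(nrow(out))
  for (g in unique(out$genome_id)) {
    idx <- which(out$genome_id == g)
    ord <- idx[order(-out$best_identity[idx], out$orf_id[idx])]
    taken_start <- numeric(0); taken_end <- numeric(0)
    for (i in ord) {
      overlaps <- any(out$start[i] < taken_end & out$end[i] > taken_start)
      if (!overlaps) {
        keep[i] <- TRUE
        taken_start <- c(taken_start, out$start[i])
        taken_end <- c(taken_end, out$end[i])
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
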