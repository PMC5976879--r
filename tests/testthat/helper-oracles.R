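# Independent oracles used across the test suite. Each reimplements the
# quantity under test from first principles (per-codon lookup, explicit
# dynamic programming, exhaustive path enumeration, direct counting), sharing
# no code with the package internals beyond the public API being exercised.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

random_aa <- function(len) paste(sample(AA20, len, replace = TRUE),
                                 collapse = "")

random_nt <- function(len) paste(sample(c("A","C","G","T"), len,
                                        replace = TRUE), collapse = "")

# ---- translation oracle: hard-coded standard genetic code ----------------

CODON_TABLE <- c(
  TTT="F", TTC="F", TTA="L", TTG="L", CTT="L", CTC="L", CTA="L", CTG="L",
  ATT="I", ATC="I", ATA="I", ATG="M", GTT="V", GTC="V", GTA="V", GTG="V",
  TCT="S", TCC="S", TCA="S", TCG="S", CCT="P", CCC="P", CCA="P", CCG="P",
  ACT="T", ACC="T", ACA="T", ACG="T", GCT="A", GCC="A", GCA="A", GCG="A",
  TAT="Y", TAC="Y", TAA="*", TAG="*", CAT="H", CAC="H", CAA="Q", CAG="Q",
  AAT="N", AAC="N", AAA="K", AAG="K", GAT="D", GAC="D", GAA="E", GAG="E",
  TGT="C", TGC="C", TGA="*", TGG="W", CGT="R", CGC="R", CGA="R", CGG="R",
  AGT="S", AGC="S", AGA="R", AGG="R", GGT="G", GGC="G", GGA="G", GGG="G")

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_translate_frame <- function(dna, offset) {
  n <- nchar(dna) - offset
  n <- n - n %% 3
  if (n < 3) return("")
  starts <- seq(offset + 1, offset + n, by = 3)
  codons <- substring(dna, starts, starts + 2)
  aa <- CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"  # any codon containing N
  paste(aa, collapse = "")
}

oracle_six_frames <- function(dna) {
  rc <- oracle_revcomp(dna)
  setNames(c(vapply(0:2, function(o) oracle_translate_frame(dna, o), ""),
             vapply(0:2, function(o) oracle_translate_frame(rc, o), "")),
           c("+1", "+2", "+3", "-1", "-2", "-3"))
}

# ---- local-alignment oracle: explicit three-state affine-gap DP ----------

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA20, AA20]
})

oracle_sw_score <- function(a, b, open = 11, extend = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M  <- matrix(0,   n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                              Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                              Iy[i + 1, j] - extend)
      s <- blosum62[ca[i], cb[j]]
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) + s)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# ---- forward-probability oracle: exhaustive state-path enumeration -------
#
# Sums P(seq, path | model) over every legal match/insert/delete path of a
# profile HMM, by depth-first recursion in probability space. Exponential in
# the problem size; only for toy models (n_match <= 3, sequences <= 4).

oracle_forward_bits <- function(hmm, seq) {
  idx <- match(strsplit(seq, "")[[1]], AA20)
  stopifnot(!anyNA(idx))
  K <- hmm$n_match
  L <- length(idx)
  total <- 0
  rec <- function(state, node, pos, p) {
    if (p == 0) return(invisible(NULL))
    trans <- switch(state, M = hmm$trans_m, I = hmm$trans_i,
                    D = hmm$trans_d)[node + 1L, ]
    if (node == K) {
      if (pos == L + 1L) total <<- total + p * trans[1]   # -> end
    } else {
      if (pos <= L) {                                     # -> M_{node+1}
        rec("M", node + 1L, pos + 1L,
            p * trans[1] * hmm$match_emissions[node + 1L, idx[pos]])
      }
      rec("D", node + 1L, pos, p * trans[3])              # -> D_{node+1}
    }
    if (pos <= L) {                                       # -> I_node
      rec("I", node, pos + 1L,
          p * trans[2] * hmm$insert_emissions[node + 1L, idx[pos]])
    }
    invisible(NULL)
  }
  rec("M", 0L, 1L, 1)
  lp_bg <- sum(log(hmm$background[AA20[idx]]))
  (log(total) - lp_bg) / log(2)
}

# ---- small constructors ---------------------------------------------------

# A protein whose local alignment against `ref` spans it end to end without
# gaps and carries exactly `k` identical positions: matches are W (self-score
# 11) spread evenly; elsewhere ref has A and the variant S (BLOSUM62 A/S = 1,
# positive, so the alignment never gains by trimming).
identity_controlled_pair <- function(len, k) {
  stopifnot(k >= 1, k <= len)
  at <- (seq_len(k) * len) %/% k  # k distinct, roughly even positions
  stopifnot(length(unique(at)) == k)
  ref <- rep("A", len); var <- rep("S", len)
  ref[at] <- "W"; var[at] <- "W"
  list(ref = paste(ref, collapse = ""), var = paste(var, collapse = ""),
       identical = k)
}

# Perturb a protein at exactly n_sub positions (never position 1).
perturb_protein <- function(protein, n_sub) {
  ch <- strsplit(protein, "")[[1]]
  at <- sample(2:length(ch), n_sub)
  for (i in at) ch[i] <- sample(setdiff(AA20, ch[i]), 1)
  paste(ch, collapse = "")
}

# Motif anchor blocks that fit the short consensi used in fast tests.
small_blocks <- function() {
  list(list(start = 1L, residues = "MCTG"),
       list(start = 40L, residues = "NDAG"),
       list(start = 80L, residues = "GLN"))
}

# Random additive distance matrix: draw a random topology with positive
# branch lengths and return its exact path-length matrix plus the tree.
random_additive_case <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(tree)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tree, d = d)
}
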