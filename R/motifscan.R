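# Column-conservation profiling of a protein alignment, motif extraction
# (maximal runs of conserved columns), active-site auditing, and a
# per-column residue-frequency (logo) matrix.

#' Per-column conservation profile of an alignment
#'
#' The default score of a column is the fraction of rows carrying the modal
#' non-gap residue, with gaps counted in the denominator, so an all-gap
#' column scores 0 and a fully conserved column scores 1. A Shannon-entropy
#' alternative (`method = "entropy"`, 1 - H/log2(20) over non-gap residues,
#' scaled by non-gap fraction) is exposed for comparison.
#'
#' @param x an [msa()] object
#' @param method `"modal"` (default) or `"entropy"`
#' @return a `conservation_profile`: data frame with `column`, `score`,
#'   `consensus` (modal residue, alphabetical tie-break; `-` for all-gap)
#' @export
column_conservation <- function(x, method = c("modal", "entropy")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "msa"))
  mat <- msa_matrix(x)
  n <- nrow(mat)
  res <- lapply(seq_len(ncol(mat)), function(cc) {
    col <- mat[, cc]
    col <- col[col != "-"]
    if (length(col) == 0) {
      return(data.frame(column = cc, score = 0, consensus = "-",
                        stringsAsFactors = FALSE))
    }
    tab <- table(col)
    modal <- sort(names(tab)[tab == max(tab)])[1]
    score <- if (method == "modal") {
      max(tab) / n
    } else {
      p <- as.numeric(tab) / length(col)
      (1 - (-sum(p * log2(p))) / log2(20)) * (length(col) / n)
    }
    data.frame(column = cc, score = score, consensus = modal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Find conserved motifs in a conservation profile
#'
#' Motifs are maximal runs of consecutive columns whose score is at least
#' `threshold`, kept when the run spans at least `min_len` columns;
#' non-overlapping by construction and ordered by start column.
#'
#' @param profile a [column_conservation()] result
#' @param threshold minimum per-column conservation score
#' @param min_len minimum motif length in columns
#' @return data frame with 1-based inclusive `start_col`, `end_col`,
#'   `length`, `consensus`, `min_score`
#' @export
find_motifs <- function(profile, threshold = 0.75, min_len = 3) {
  stopifnot(min_len >= 1)
  ok <- profile$score >= threshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len)
  out <- data.frame(start_col = starts[keep], end_col = ends[keep])
  out$length <- out$end_col - out$start_col + 1L
  out$consensus <- vapply(seq_len(nrow(out)), function(i) {
    paste(profile$consensus[out$start_col[i]:out$end_col[i]], collapse = "")
  }, character(1))
  out$min_score <- vapply(seq_len(nrow(out)), function(i) {
    min(profile$score[out$start_col[i]:out$end_col[i]])
  }, numeric(1))
  out
}

#' Map alignment columns to ungapped residue positions of one row
#'
#' @param x an [msa()] object
#' @param id row identifier
#' @return integer vector over alignment columns: 1-based residue position
#'   in the ungapped sequence, `NA` at that row's gap columns
#' @export
column_to_residue_map <- function(x, id) {
  row <- x$aligned[match(id, x$ids)]
  if (is.na(row)) stop("no row with id '", id, "'", call. = FALSE)
  chars <- strsplit(row, "")[[1]]
  pos <- cumsum(chars != "-")
  pos[chars == "-"] <- NA
  pos
}

#' Audit canonical active-site residues against a conservation profile
#'
#' For each specified site (expected residue + 1-based alignment column)
#' reports whether the column is conserved at `threshold`, whether it falls
#' inside one of the supplied motifs, and whether the column consensus
#' matches the expected residue.
#'
#' @param x an [msa()] object
#' @param motifs a [find_motifs()] result
#' @param site_spec data frame with `name`, `residue`, `column`
#' @param threshold conservation threshold
#' @param method conservation scoring method
#' @return `site_spec` with `score`, `consensus`, `conserved`, `in_motif`,
#'   `residue_matches` columns added
#' @export
audit_active_sites <- function(x, motifs, site_spec, threshold = 0.75,
                               method = "modal") {
  profile <- column_conservation(x, method = method)
  if (any(site_spec$column < 1 | site_spec$column > nrow(profile))) {
    stop("active-site column outside the alignment", call. = FALSE)
  }
  site_spec$score <- profile$score[site_spec$column]
  site_spec$consensus <- profile$consensus[site_spec$column]
  site_spec$conserved <- site_spec$score >= threshold
  site_spec$in_motif <- vapply(site_spec$column, function(cc) {
    any(motifs$start_col <= cc & motifs$end_col >= cc)
  }, logical(1))
  site_spec$residue_matches <- site_spec$consensus == site_spec$residue
  site_spec
}

#' Default active-site specification
#'
#' Only the N-terminal catalytic cysteine (consensus position 2) is pinned
#' by default; the remaining canonical sites are data-dependent and supplied
#' by the user.
#'
#' @return one-row site-spec data frame
#' @export
default_active_sites <- function() {
  data.frame(name = "Cys2", residue = "C", column = 2L,
             stringsAsFactors = FALSE)
}

#' Per-column residue-frequency (logo) matrix
#'
#' Frequencies over the 20 residues per alignment column, gaps excluded from
#' numerator and denominator; rows of non-empty columns sum to 1, all-gap
#' columns are all-zero.
#'
#' @param x an [msa()] object
#' @return numeric matrix, `n_cols` rows by 20 residue columns
#' @export
logo_matrix <- function(x) {
  stopifnot(inherits(x, "msa"))
  mat <- msa_matrix(x)
  out <- t(apply(mat, 2, function(col) {
    col <- col[col != "-" & col %in% AA_ALPHABET]
    if (length(col) == 0) return(setNames(numeric(20), AA_ALPHABET))
    as.numeric(table(factor(col, levels = AA_ALPHABET))) / length(col)
  }))
  colnames(out) <- AA_ALPHABET
  out
}
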