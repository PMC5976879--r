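# Distance-based phylogenetics: p-distance / Poisson-corrected distances
# under pairwise gap deletion, a deterministic Saitou-Nei neighbor-joining
# implementation (negative branch lengths clamped with the deficit shifted
# to the sister edge; ties broken by smallest index pair), column-resampled
# bootstrap support, and Newick I/O. Trees are `ape::phylo` objects
# throughout.

#' Pairwise distance matrix from an alignment
#'
#' For each pair of rows, columns where either row is gapped are excluded
#' (pairwise deletion); `p` is the mismatch fraction over the compared
#' columns. The Poisson correction is `-ln(1 - p)`, an error when `p >= 1`.
#'
#' @param x an [msa()] object (amino-acid or nucleotide rows)
#' @param model `"p-distance"` (default) or `"poisson"`
#' @return symmetric `dist_matrix` (numeric matrix, zero diagonal, id
#'   dimnames)
#' @export
pairwise_distance <- function(x, model = c("p-distance", "poisson")) {
  model <- match.arg(model)
  stopifnot(inherits(x, "msa"))
  mat <- msa_matrix(x)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(x$ids, x$ids))
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        stop(sprintf("rows '%s' and '%s' share no ungapped column",
                     x$ids[i], x$ids[j]), call. = FALSE)
      }
      p <- mean(mat[i, ok] != mat[j, ok])
      if (model == "poisson") {
        if (p >= 1) {
          stop(sprintf("Poisson correction undefined for p = 1 ('%s' vs '%s')",
                       x$ids[i], x$ids[j]), call. = FALSE)
        }
        p <- -log(1 - p)
      }
      d[i, j] <- p
      d[j, i] <- p
    }
  }
  class(d) <- c("dist_matrix", class(d))
  d
}

clamp_pair <- function(vi, vj) {
  # shift any negative-length deficit to the sister edge, then clamp
  if (vi < 0) { vj <- vj + vi; vi <- 0 }
  if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
  c(vi, vj)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the canonical Q criterion. Deterministic:
#' among tied Q minima the smallest `(i, j)` index pair (current matrix
#' order, merged nodes appended last) is joined. Negative branch lengths are
#' clamped to zero with the deficit moved to the sister edge. Exact on
#' additive matrices.
#'
#' @param d symmetric numeric distance matrix with id dimnames (>= 3 taxa)
#' @return an unrooted `ape::phylo` tree
#' @export
neighbor_joining <- function(d) {
  d <- unclass(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active node is a Newick fragment without a trailing branch length
  frags <- vapply(labels, quote_newick_label, character(1))
  act <- d
  while (nrow(act) > 3) {
    m <- nrow(act)
    r <- rowSums(act)
    q <- (m - 2) * act - outer(r, r, `+`)
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    vi <- 0.5 * act[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- act[i, j] - vi
    v <- clamp_pair(vi, vj)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frags[i], v[1], frags[j], v[2])
    du <- 0.5 * (act[i, ] + act[j, ] - act[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], du[keep]),
                 c(du[keep], 0))
    frags <- c(frags[keep], newfrag)
  }
  # closed-form star for the final three nodes
  va <- max(0, 0.5 * (act[1, 2] + act[1, 3] - act[2, 3]))
  vb <- max(0, 0.5 * (act[1, 2] + act[2, 3] - act[1, 3]))
  vc <- max(0, 0.5 * (act[1, 3] + act[2, 3] - act[1, 2]))
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    frags[1], va, frags[2], vb, frags[3], vc)
  tree <- ape::read.tree(text = newick)
  # the parser keeps the quoting; restore the original labels
  tree$tip.label <- vapply(tree$tip.label, unquote_newick_label, character(1),
                           USE.NAMES = FALSE)
  tree
}

# Newick single-quote convention for labels containing metacharacters;
# embedded quotes are doubled
quote_newick_label <- function(s) {
  # "]" first and "[" last make the brackets literal inside the class
  if (grepl("[][ ():,;'\"]", s)) paste0("'", gsub("'", "''", s), "'") else s
}

unquote_newick_label <- function(s) {
  if (startsWith(s, "'") && endsWith(s, "'") && nchar(s) >= 2) {
    gsub("''", "'", substr(s, 2L, nchar(s) - 1L), fixed = TRUE)
  } else s
}

#' Canonical bipartition set of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the side not containing the
#' alphabetically first leaf, with its members sorted and joined by `|`,
#' identifies the bipartition. Trivial splits (single leaves) are excluded.
#'
#' @param tree an `ape::phylo`
#' @return character vector of canonical bipartition keys
#' @export
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(p) {
    side <- tree$tip.label[p]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

resample_columns <- function(x, cols) {
  mat <- msa_matrix(x)
  msa_obj <- list(ids = x$ids,
                  aligned = apply(mat[, cols, drop = FALSE], 1, paste,
                                  collapse = ""),
                  n_cols = length(cols))
  class(msa_obj) <- "msa"
  msa_obj
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_reps` times, rebuilds the tree per replicate, and labels
#' each internal node of the full-data tree with the percentage of
#' replicates containing its bipartition. Deterministic under `seed`.
#'
#' @param x an [msa()] object
#' @param n_reps bootstrap replicates (>= 1)
#' @param seed integer seed
#' @param model distance model, see [pairwise_distance()]
#' @return an `ape::phylo` with `node.label` support percentages (empty for
#'   nodes whose split is trivial)
#' @export
bootstrap_support <- function(x, n_reps = 100, seed = 1,
                              model = "p-distance") {
  stopifnot(n_reps >= 1)
  main <- neighbor_joining(pairwise_distance(x, model))
  keys <- tree_bipartitions(main)
  counts <- setNames(integer(length(keys)), keys)
  set.seed(as.integer(seed))
  for (b in seq_len(n_reps)) {
    cols <- sample.int(x$n_cols, x$n_cols, replace = TRUE)
    rep_tree <- neighbor_joining(pairwise_distance(resample_columns(x, cols),
                                                   model))
    hit <- intersect(keys, tree_bipartitions(rep_tree))
    counts[hit] <- counts[hit] + 1L
  }
  support <- 100 * counts / n_reps
  # attach supports as node labels of the (rooted representation of the) tree
  main$node.label <- vapply(seq_len(main$Nnode), function(k) {
    node <- length(main$tip.label) + k
    tips <- main$tip.label[phangorn_descendants(main, node)]
    ref <- sort(main$tip.label)[1]
    side <- if (ref %in% tips) setdiff(main$tip.label, tips) else tips
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) sprintf("%g", support[key]) else ""
  }, character(1))
  attr(main, "bipartition_support") <- support
  main
}

# tip indices descending from an internal node (small trees; no recursion
# depth concerns)
phangorn_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    if (nd <= n_tip) out <- c(out, nd)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == nd, 2])
  }
  sort(out)
}

#' Read a Newick tree file
#'
#' @param path Newick file path
#' @return an `ape::phylo`
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("Newick parse error in '", path, "'", call. = FALSE)
  tree$tip.label <- vapply(tree$tip.label, unquote_newick_label, character(1),
                           USE.NAMES = FALSE)
  tree
}

#' Write a tree as Newick
#'
#' Branch lengths and internal-node support labels are preserved.
#'
#' @param tree an `ape::phylo`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  # ape::write.tree rewrites metacharacters in labels instead of quoting;
  # swap in safe placeholders, then substitute the quoted originals back
  labs <- tree$tip.label
  ph <- sprintf("bshscreenTIP%dX", seq_along(labs))
  tree$tip.label <- ph
  txt <- ape::write.tree(tree)
  for (i in seq_along(labs)) {
    txt <- sub(ph[i], quote_newick_label(labs[i]), txt, fixed = TRUE)
  }
  writeLines(txt, path)
  invisible(path)
}

#' Path-length (patristic) distance matrix of a tree
#'
#' @param tree an `ape::phylo` with branch lengths
#' @return symmetric matrix of leaf-to-leaf path lengths, rows/cols in
#'   `tree$tip.label` order
#' @export
tree_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
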