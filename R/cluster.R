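# Greedy representative-based clustering at an identity threshold, replacing
# a CD-HIT run: sequences are taken longest-first, each founds a cluster or
# joins the first representative it matches at or above the threshold.
# Identity uses the short-sequence denominator (identical positions over the
# shorter sequence's length), the convention of identity-threshold
# clustering tools; the screen's alignment-column convention is available
# via `identity = "alignment"`.

cluster_identity_fun <- function(identity, matrix, gap_open, gap_extend) {
  field <- if (identity == "short") "identity_short" else "identity"
  function(a, b) {
    smith_waterman(a, b, matrix = matrix, gap_open = gap_open,
                   gap_extend = gap_extend)[[field]]
  }
}

#' Greedy identity clustering of proteins
#'
#' Sorts sequences by length descending (ties by id ascending). The first
#' unassigned sequence founds a cluster and becomes its representative; each
#' subsequent sequence joins the first existing cluster whose representative
#' it matches at `threshold` identity or better, otherwise founds a new
#' cluster.
#'
#' @param proteins `seq_records`-like data frame with `id`, `sequence` (and
#'   optionally `species`)
#' @param threshold identity threshold in (0, 1]
#' @param identity `"short"` (identical positions / shorter length, default)
#'   or `"alignment"` (identical positions / aligned columns)
#' @param matrix,gap_open,gap_extend alignment scoring
#' @return a `protein_clusters` object: list of clusters, each with
#'   `representative` (id), `members` (data frame of `id`, `identity`), and
#'   the threshold used
#' @export
greedy_cluster <- function(proteins, threshold = 0.95,
                           identity = c("short", "alignment"),
                           matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  identity <- match.arg(identity)
  if (nrow(proteins) == 0) stop("no proteins to cluster", call. = FALSE)
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  idfun <- cluster_identity_fun(identity, matrix, gap_open, gap_extend)
  ord <- order(-nchar(proteins$sequence), proteins$id)
  prot <- proteins[ord, , drop = FALSE]
  reps <- integer(0)       # row indices of representatives, in founding order
  assignment <- integer(nrow(prot))
  ident_to_rep <- numeric(nrow(prot))
  for (i in seq_len(nrow(prot))) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      idv <- idfun(prot$sequence[i], prot$sequence[reps[k]])
      if (idv >= threshold) {
        assignment[i] <- k
        ident_to_rep[i] <- idv
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assignment[i] <- length(reps)
      ident_to_rep[i] <- 1
    }
  }
  clusters <- lapply(seq_along(reps), function(k) {
    rows <- which(assignment == k)
    list(representative = prot$id[reps[k]],
         representative_sequence = prot$sequence[reps[k]],
         members = data.frame(id = prot$id[rows],
                              species = if (!is.null(prot$species))
                                prot$species[rows] else NA_character_,
                              identity = ident_to_rep[rows],
                              stringsAsFactors = FALSE))
  })
  structure(list(clusters = clusters, threshold = threshold,
                 identity = identity),
            class = "protein_clusters")
}

#' @export
print.protein_clusters <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) nrow(cl$members), integer(1))
  cat(sprintf("%d clusters of %d proteins at %.0f%% identity (%s convention)\n",
              length(x$clusters), sum(sizes), 100 * x$threshold, x$identity))
  invisible(x)
}

species_epithet <- function(species) {
  # "Lactobacillus gasseri" -> "gasseri"; single-token names pass through
  vapply(strsplit(species, "\\s+"), function(p) tolower(p[length(p)]),
         character(1))
}

#' Name clusters after their constituent species
#'
#' Cluster names join the sorted unique species epithets with `_and_` and
#' append a per-name-combination ordinal, e.g. `gasseri_1`, `gasseri_2`,
#' `gasseri_and_hominis_1`.
#'
#' @param x a `protein_clusters` object
#' @param provenance optional named character vector mapping protein id to
#'   species; defaults to the `species` column captured at clustering time
#' @return `x` with a `name` added to each cluster
#' @export
name_clusters <- function(x, provenance = NULL) {
  stopifnot(inherits(x, "protein_clusters"))
  base <- vapply(x$clusters, function(cl) {
    sp <- if (!is.null(provenance)) {
      miss <- setdiff(cl$members$id, names(provenance))
      if (length(miss) > 0) {
        stop("no species provenance for: ", paste(miss, collapse = ", "),
             call. = FALSE)
      }
      provenance[cl$members$id]
    } else cl$members$species
    if (any(is.na(sp))) {
      stop("missing species provenance in cluster with representative ",
           cl$representative, call. = FALSE)
    }
    paste(sort(unique(species_epithet(sp))), collapse = "_and_")
  }, character(1))
  ordinal <- stats::ave(seq_along(base), base, FUN = seq_along)
  for (k in seq_along(x$clusters)) {
    x$clusters[[k]]$name <- sprintf("%s_%d", base[k], ordinal[k])
  }
  x
}

#' Representative sequences of a clustering
#'
#' @param x a `protein_clusters` object
#' @return `seq_records`-style data frame of representatives (named clusters
#'   use the cluster name as the id)
#' @export
cluster_representatives <- function(x) {
  stopifnot(inherits(x, "protein_clusters"))
  ids <- vapply(x$clusters, function(cl)
    if (!is.null(cl$name)) cl$name else cl$representative, character(1))
  data.frame(id = ids,
             representative = vapply(x$clusters, `[[`, "", "representative"),
             sequence = vapply(x$clusters, `[[`, "",
                               "representative_sequence"),
             stringsAsFactors = FALSE)
}

#' All-vs-all percent identity matrix
#'
#' Pairwise local-alignment identities of the representative sequences,
#' scaled to percent; symmetric by construction (each pair computed once),
#' diagonal 100.
#'
#' @param representatives data frame with `id` and `sequence` (at least two
#'   rows)
#' @param identity,matrix,gap_open,gap_extend see [greedy_cluster()]
#' @return an `identity_matrix`: numeric matrix with id dimnames
#' @export
identity_matrix <- function(representatives,
                            identity = c("short", "alignment"),
                            matrix = "BLOSUM62", gap_open = 11,
                            gap_extend = 1) {
  identity <- match.arg(identity)
  n <- nrow(representatives)
  if (n < 2) stop("need at least two representatives", call. = FALSE)
  idfun <- cluster_identity_fun(identity, matrix, gap_open, gap_extend)
  m <- diag(100, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- 100 * idfun(representatives$sequence[i],
                       representatives$sequence[j])
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  dimnames(m) <- list(representatives$id, representatives$id)
  class(m) <- c("identity_matrix", class(m))
  m
}

#' Write clusters in a CD-HIT-like .clstr text format plus TSV
#'
#' @param x a `protein_clusters` object
#' @param path_clstr path for the `.clstr`-style file
#' @param path_tsv optional path for a flat TSV (cluster, member, identity)
#' @return `path_clstr`, invisibly
#' @export
write_clusters <- function(x, path_clstr, path_tsv = NULL) {
  stopifnot(inherits(x, "protein_clusters"))
  con <- file(path_clstr, "w")
  on.exit(close(con))
  for (k in seq_along(x$clusters)) {
    cl <- x$clusters[[k]]
    writeLines(sprintf(">Cluster %d%s", k - 1L,
                       if (!is.null(cl$name)) paste0(" ", cl$name) else ""),
               con)
    for (i in seq_len(nrow(cl$members))) {
      id <- cl$members$id[i]
      tag <- if (id == cl$representative) "*"
             else sprintf("at %.2f%%", 100 * cl$members$identity[i])
      writeLines(sprintf("%d\t%s... %s", i - 1L, id, tag), con)
    }
  }
  if (!is.null(path_tsv)) {
    rows <- do.call(rbind, lapply(seq_along(x$clusters), function(k) {
      cl <- x$clusters[[k]]
      data.frame(cluster = k,
                 name = if (!is.null(cl$name)) cl$name else NA_character_,
                 representative = cl$representative,
                 member = cl$members$id, species = cl$members$species,
                 identity = cl$members$identity, stringsAsFactors = FALSE)
    }))
    write.table(rows, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path_clstr)
}
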