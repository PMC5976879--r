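# Sequence and metadata I/O: FASTA (via Biostrings), Stockholm 1.0 (no
# installed package reads it, so the dialect is parsed here), strain metadata
# TSV, and the YAML run configuration.

validate_sequence <- function(seq, kind, id) {
  # proteins admit 'X' for residues translated from ambiguous (N) codons
  alphabet <- if (kind == "nucleotide") NUC_ALPHABET else c(AA_ALPHABET, "X")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0) {
    stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                 kind, chars[bad[1]], id, bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

parse_fasta_header <- function(header) {
  # Dialect: "id key=value ..." where a value runs to the next "key=" token.
  # Anything unparseable keeps the full header as the id.
  parts <- strsplit(header, "\\s+(?=\\w+=)", perl = TRUE)[[1]]
  if (length(parts) == 1 && !grepl("=", parts[1])) {
    return(list(id = header, species = NA_character_, strain = NA_character_))
  }
  id <- sub("\\s.*$", "", parts[1])
  fields <- list(species = NA_character_, strain = NA_character_)
  for (kv in parts[-1]) {
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    if (key %in% names(fields)) fields[[key]] <- val
  }
  list(id = id, species = fields$species, strain = fields$strain)
}

format_fasta_header <- function(id, species, strain) {
  h <- id
  if (!is.na(species) && nzchar(species)) h <- paste0(h, " species=", species)
  if (!is.na(strain) && nzchar(strain)) h <- paste0(h, " strain=", strain)
  h
}

new_seq_records <- function(id, species, strain, sequence, kind) {
  stopifnot(kind %in% c("nucleotide", "protein"))
  df <- data.frame(id = as.character(id),
                   species = as.character(species),
                   strain = as.character(strain),
                   sequence = toupper(as.character(sequence)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) {
    stop("duplicate record ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$sequence))) {
    stop("empty sequence in record '", df$id[!nzchar(df$sequence)][1], "'",
         call. = FALSE)
  }
  mapply(validate_sequence, df$sequence, kind, df$id)
  attr(df, "kind") <- kind
  class(df) <- c("seq_records", "data.frame")
  df
}

empty_seq_records <- function(kind) {
  df <- data.frame(id = character(), species = character(),
                   strain = character(), sequence = character(),
                   stringsAsFactors = FALSE)
  attr(df, "kind") <- kind
  class(df) <- c("seq_records", "data.frame")
  df
}

#' Read sequences from a FASTA file
#'
#' Headers follow the dialect `id species=... strain=...`; headers that do not
#' match keep the whole line as the record id. Sequences are uppercased and
#' validated against the nucleotide (`ACGTN`) or 20-letter amino-acid
#' alphabet.
#'
#' @param path path to a FASTA file
#' @param kind `"nucleotide"` or `"protein"`
#' @return a `seq_records` data frame with columns `id`, `species`, `strain`,
#'   `sequence`
#' @export
read_fasta <- function(path, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_seq_records(kind))
  if (!startsWith(lines[1], ">")) {
    stop(sprintf("malformed FASTA in '%s': line 1 does not start with '>'",
                 path), call. = FALSE)
  }
  starts <- which(startsWith(lines, ">"))
  ends <- c(starts[-1] - 1L, length(lines))
  headers <- sub("^>\\s*", "", lines[starts])
  seqs <- vapply(seq_along(starts), function(i) {
    if (ends[i] < starts[i] + 1L) return("")
    paste(lines[(starts[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  meta <- lapply(headers, parse_fasta_header)
  new_seq_records(id = vapply(meta, `[[`, "", "id"),
                  species = vapply(meta, `[[`, "", "species"),
                  strain = vapply(meta, `[[`, "", "strain"),
                  sequence = gsub("\\s", "", seqs),
                  kind = kind)
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()] on valid records.
#'
#' @param records a `seq_records` data frame (or any data frame with `id`,
#'   `species`, `strain`, `sequence` columns)
#' @param path output path
#' @param width line-wrap width in characters
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- format_fasta_header(records$id[i], records$species[i],
                                  records$strain[i])
    writeLines(paste0(">", header), con)
    s <- records$sequence[i]
    idx <- seq(1, nchar(s), by = width)
    writeLines(substring(s, idx, pmin(idx + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' @param ids row identifiers
#' @param aligned aligned sequences over residues and `-` gaps, all the same
#'   length
#' @return an `msa` object (list with `ids`, `aligned`, `n_cols`)
#' @export
msa <- function(ids, aligned) {
  ids <- as.character(ids)
  aligned <- toupper(as.character(aligned))
  if (length(ids) != length(aligned)) stop("ids/aligned length mismatch")
  n_cols <- unique(nchar(aligned))
  if (length(aligned) > 0 && length(n_cols) != 1) {
    stop("ragged alignment: row lengths ", paste(unique(nchar(aligned)),
         collapse = ", "), call. = FALSE)
  }
  if (length(aligned) == 0) n_cols <- 0L
  for (i in seq_along(aligned)) {
    ungapped <- gsub("-", "", aligned[i], fixed = TRUE)
    if (nzchar(ungapped)) validate_sequence(ungapped, "protein", ids[i])
  }
  structure(list(ids = ids, aligned = aligned, n_cols = as.integer(n_cols)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Multiple sequence alignment: %d rows x %d columns\n",
              length(x$ids), x$n_cols))
  invisible(x)
}

#' Read a Stockholm 1.0 alignment
#'
#' Requires the `# STOCKHOLM 1.0` header and the `//` terminator; annotation
#' (`#=G...`) lines are ignored; interleaved blocks are concatenated per id.
#'
#' @param path path to a Stockholm file
#' @return an [msa()] object, rows in file order
#' @export
read_stockholm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^#\\s*STOCKHOLM\\s+1\\.0", lines[1])) {
    stop("not a Stockholm 1.0 file (missing '# STOCKHOLM 1.0' header): ",
         path, call. = FALSE)
  }
  term <- which(trimws(lines) == "//")
  if (length(term) == 0) {
    stop("Stockholm file lacks '//' terminator: ", path, call. = FALSE)
  }
  body <- lines[2:(term[1] - 1L)]
  body <- body[nzchar(trimws(body))]
  body <- body[!startsWith(trimws(body), "#")]
  ids <- character()
  seqs <- list()
  for (ln in body) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) {
      stop("malformed Stockholm sequence line: '", ln, "'", call. = FALSE)
    }
    if (parts[1] %in% ids) {
      seqs[[parts[1]]] <- paste0(seqs[[parts[1]]], parts[2])
    } else {
      ids <- c(ids, parts[1])
      seqs[[parts[1]]] <- parts[2]
    }
  }
  aligned <- unlist(seqs[ids], use.names = FALSE)
  aligned <- chartr(".", "-", aligned)
  msa(ids, aligned)
}

#' Write a Stockholm 1.0 alignment
#'
#' @param x an [msa()] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_stockholm <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  pad <- max(nchar(x$ids), 0)
  lines <- c("# STOCKHOLM 1.0", "",
             sprintf("%-*s  %s", pad, x$ids, x$aligned),
             "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read strain metadata (species, strain, lifestyle) from TSV
#'
#' Lifestyle must be one of the closed set `vertebrate-adapted`,
#' `free-living`, `insect-adapted`, `nomadic`, `unknown`; anything else is an
#' error, never coerced.
#'
#' @param path TSV path with a `species`/`strain`/`lifestyle` header
#' @return data frame with those three character columns, file order preserved
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("species", "strain", "lifestyle")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("metadata file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$lifestyle %in% LIFESTYLES)
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid lifestyle '%s' (row %d); legal values: %s",
      df$lifestyle[bad[1]], bad[1], paste(LIFESTYLES, collapse = ", ")),
      call. = FALSE)
  }
  df[, need]
}

#' Write strain metadata TSV
#'
#' @param metadata data frame with `species`, `strain`, `lifestyle`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_metadata <- function(metadata, path) {
  stopifnot(all(c("species", "strain", "lifestyle") %in% names(metadata)))
  write.table(metadata[, c("species", "strain", "lifestyle")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Houses the screening and classification thresholds: ORFs shorter than
#' `min_orf_len` residues are dropped, candidates below `min_ref_identity` to
#' every reference are dropped, candidates whose best-model E-value exceeds
#' `retention_evalue` are removed, BSH hits are clustered at
#' `cluster_identity`, and motifs are runs of at least `min_motif_len`
#' alignment columns at conservation `conservation_threshold` or higher.
#'
#' @param min_orf_len minimum ORF protein length in residues
#' @param min_ref_identity minimum identity fraction to a reference protein
#' @param retention_evalue E-value bound for retaining a classified candidate
#' @param cluster_identity identity threshold for greedy clustering
#' @param conservation_threshold column-conservation score threshold
#' @param min_motif_len minimum motif length in alignment columns
#' @param bootstrap_reps bootstrap replicates for tree support
#' @param rng_seed integer seed governing all stochastic stages
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(min_orf_len = 100,
                            min_ref_identity = 0.30,
                            retention_evalue = 1e-99,
                            cluster_identity = 0.95,
                            conservation_threshold = 0.75,
                            min_motif_len = 3,
                            bootstrap_reps = 100,
                            rng_seed = 1L) {
  cfg <- list(min_orf_len = as.integer(min_orf_len),
              min_ref_identity = min_ref_identity,
              retention_evalue = retention_evalue,
              cluster_identity = cluster_identity,
              conservation_threshold = conservation_threshold,
              min_motif_len = as.integer(min_motif_len),
              bootstrap_reps = as.integer(bootstrap_reps),
              rng_seed = as.integer(rng_seed))
  for (f in c("min_ref_identity", "cluster_identity")) {
    if (!(cfg[[f]] > 0 && cfg[[f]] <= 1)) {
      stop(f, " must be in (0, 1]", call. = FALSE)
    }
  }
  if (cfg$min_orf_len < 1) stop("min_orf_len must be >= 1", call. = FALSE)
  if (cfg$min_motif_len < 1) stop("min_motif_len must be >= 1", call. = FALSE)
  if (!(cfg$conservation_threshold >= 0 && cfg$conservation_threshold <= 1)) {
    stop("conservation_threshold must be in [0, 1]", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a YAML pipeline configuration file
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments
#' @return a validated `pipeline_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  legal <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), legal)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}
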