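# Profile hidden Markov models: match/insert/delete architecture estimated
# from a reference alignment, scored against candidate proteins with the
# forward algorithm in log space. The model is global over the profile with
# flanking insert states (candidates are pre-trimmed ORFs of roughly
# full-length proteins), without local begin/end probabilities.

#' Select match columns of an alignment
#'
#' A column becomes a match state iff its gap fraction is strictly below
#' `gap_fraction_threshold` (a column at exactly the threshold is an insert
#' column).
#'
#' @param x an [msa()] object
#' @param gap_fraction_threshold gap-fraction cutoff
#' @return integer vector of 1-based match column indices
#' @export
select_match_columns <- function(x, gap_fraction_threshold = 0.5) {
  stopifnot(inherits(x, "msa"))
  if (length(x$ids) == 0) stop("empty alignment", call. = FALSE)
  mat <- msa_matrix(x)
  gap_frac <- colMeans(mat == "-")
  cols <- which(gap_frac < gap_fraction_threshold)
  if (length(cols) == 0) {
    stop("no match columns: alignment is gap-dominated in every column",
         call. = FALSE)
  }
  cols
}

msa_matrix <- function(x) {
  do.call(rbind, strsplit(x$aligned, "", fixed = TRUE))
}

laplace_rows <- function(counts) {
  (counts + 1) / (rowSums(counts) + ncol(counts))
}

#' Fit a profile HMM to a reference alignment
#'
#' Match columns are chosen by gap fraction; emissions use +1 Laplace
#' smoothing, `(count + 1) / (column total + 20)`; transitions are tallied
#' from each row's implied match/insert/delete state path with +1 smoothing;
#' the background is the Laplace-smoothed mean residue frequency of the
#' ungapped reference residues (smoothing keeps rare residues scoreable).
#'
#' @param x an [msa()] object
#' @param gap_fraction_threshold see [select_match_columns()]
#' @param pseudocount Laplace pseudocount added to every emission and
#'   transition count
#' @param name optional model name
#' @return an object of class `profile_hmm`
#' @export
profile_hmm <- function(x, gap_fraction_threshold = 0.5, pseudocount = 1,
                        name = "profile") {
  match_cols <- select_match_columns(x, gap_fraction_threshold)
  mat <- msa_matrix(x)
  K <- length(match_cols)
  n_aa <- length(AA_ALPHABET)

  em_counts <- matrix(0, K, n_aa, dimnames = list(NULL, AA_ALPHABET))
  ins_counts <- matrix(0, K + 1, n_aa, dimnames = list(NULL, AA_ALPHABET))
  # transition counts: rows j = 0..K, targets {next-M (end at K), I_j, next-D}
  tm <- matrix(0, K + 1, 3); ti <- matrix(0, K + 1, 3); td <- matrix(0, K + 1, 3)

  is_match_col <- logical(ncol(mat))
  is_match_col[match_cols] <- TRUE
  node_of_col <- cumsum(is_match_col)  # insert residues belong to node_of_col

  for (r in seq_len(nrow(mat))) {
    row <- mat[r, ]
    state <- "M"  # begin treated as M_0
    node <- 0L
    for (cc in seq_along(row)) {
      ch <- row[cc]
      if (is_match_col[cc]) {
        to_state <- if (ch == "-") "D" else "M"
        if (state == "M") tm[node + 1L, if (to_state == "M") 1L else 3L] <-
            tm[node + 1L, if (to_state == "M") 1L else 3L] + 1
        if (state == "I") ti[node + 1L, if (to_state == "M") 1L else 3L] <-
            ti[node + 1L, if (to_state == "M") 1L else 3L] + 1
        if (state == "D") td[node + 1L, if (to_state == "M") 1L else 3L] <-
            td[node + 1L, if (to_state == "M") 1L else 3L] + 1
        node <- node + 1L
        state <- to_state
        if (to_state == "M" && ch %in% AA_ALPHABET) {
          em_counts[node, ch] <- em_counts[node, ch] + 1
        }
      } else if (ch != "-") {
        if (state == "M") tm[node + 1L, 2L] <- tm[node + 1L, 2L] + 1
        if (state == "I") ti[node + 1L, 2L] <- ti[node + 1L, 2L] + 1
        if (state == "D") td[node + 1L, 2L] <- td[node + 1L, 2L] + 1
        state <- "I"
        if (ch %in% AA_ALPHABET) {
          ins_counts[node + 1L, ch] <- ins_counts[node + 1L, ch] + 1
        }
      }
    }
    # exit to end state (target slot 1 at node K)
    if (state == "M") tm[node + 1L, 1L] <- tm[node + 1L, 1L] + 1
    if (state == "I") ti[node + 1L, 1L] <- ti[node + 1L, 1L] + 1
    if (state == "D") td[node + 1L, 1L] <- td[node + 1L, 1L] + 1
  }

  smooth_trans <- function(cnt) {
    cnt <- cnt + pseudocount
    cnt[K + 1L, 3L] <- 0  # no delete state beyond the last node
    cnt / rowSums(cnt)
  }
  tm_p <- smooth_trans(tm); ti_p <- smooth_trans(ti); td_p <- smooth_trans(td)
  td_p[1L, ] <- c(1, 0, 0)  # D_0 does not exist; row never reached

  em <- (em_counts + pseudocount) /
    (rowSums(em_counts) + pseudocount * n_aa)
  ins <- (ins_counts + pseudocount) /
    (rowSums(ins_counts) + pseudocount * n_aa)

  residues <- mat[mat != "-" & mat %in% AA_ALPHABET]
  bg_counts <- table(factor(residues, levels = AA_ALPHABET))
  background <- (as.numeric(bg_counts) + pseudocount) /
    (sum(bg_counts) + pseudocount * n_aa)
  names(background) <- AA_ALPHABET

  consensus <- AA_ALPHABET[apply(em, 1, which.max)]

  structure(list(name = name, n_match = K, match_columns = match_cols,
                 match_emissions = em, insert_emissions = ins,
                 trans_m = tm_p, trans_i = ti_p, trans_d = td_p,
                 background = background,
                 consensus = paste(consensus, collapse = ""),
                 n_train = length(x$ids),
                 train_len = mean(nchar(gsub("-", "", x$aligned, fixed = TRUE)))),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("Profile HMM '%s': %d match states, trained on %d sequences\n",
              x$name, x$n_match, x$n_train))
  invisible(x)
}

#' @export
summary.profile_hmm <- function(object, ...) {
  ic <- apply(object$match_emissions, 1, function(p) {
    sum(p * log2(p / object$background))
  })
  res <- list(name = object$name, n_match = object$n_match,
              n_train = object$n_train,
              mean_match_information_bits = mean(ic),
              consensus = object$consensus)
  class(res) <- "summary.profile_hmm"
  res
}

#' @export
print.summary.profile_hmm <- function(x, ...) {
  cat(sprintf("Profile HMM '%s'\n", x$name))
  cat(sprintf("  match states:        %d\n", x$n_match))
  cat(sprintf("  training sequences:  %d\n", x$n_train))
  cat(sprintf("  mean match-state relative entropy: %.2f bits\n",
              x$mean_match_information_bits))
  cat(sprintf("  consensus: %s...\n", substr(x$consensus, 1, 40)))
  invisible(x)
}

hmm_log_tables <- function(hmm) {
  list(tM = log(hmm$trans_m), tI = log(hmm$trans_i), tD = log(hmm$trans_d),
       eM = log(hmm$match_emissions), eI = log(hmm$insert_emissions))
}

#' Forward-algorithm log-odds score of a sequence under a profile HMM
#'
#' Computes `log2( P(seq | model) / P(seq | background) )` by the forward
#' recursion over match/insert/delete states in log space; numerically safe
#' for sequences of at least 10,000 residues. Residues outside the 20-letter
#' alphabet (e.g. `X`) emit with probability one under both model and
#' background, contributing zero log-odds.
#'
#' @param hmm a [profile_hmm()]
#' @param seq protein string (or character vector of them)
#' @return numeric vector of bit scores
#' @export
forward_score <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"))
  lt <- hmm_log_tables(hmm)
  lbg <- log(hmm$background)
  vapply(as.character(seq), function(s) {
    if (!nzchar(s)) stop("empty sequence", call. = FALSE)
    idx <- aa_index(strsplit(s, "")[[1]])
    lp_model <- forward_logprob_cpp(lt$tM, lt$tI, lt$tD, lt$eM, lt$eI,
                                    as.integer(idx))
    lp_bg <- sum(lbg[idx[idx > 0]])
    (lp_model - lp_bg) / log(2)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Simulate sequences from a profile HMM
#'
#' Samples state paths and emissions from the fitted model; delete states
#' yield shorter sequences, insert states longer ones.
#'
#' @param object a `profile_hmm`
#' @param nsim number of sequences
#' @param seed optional integer seed
#' @param ... unused
#' @return character vector of simulated protein sequences
#' @export
simulate.profile_hmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  K <- object$n_match
  out <- character(nsim)
  for (r in seq_len(nsim)) {
    chars <- character(0)
    state <- "M"; node <- 0L
    repeat {
      probs <- switch(state,
                      M = object$trans_m[node + 1L, ],
                      I = object$trans_i[node + 1L, ],
                      D = object$trans_d[node + 1L, ])
      nxt <- sample(c("M", "I", "D"), 1, prob = probs)
      if (nxt == "I") {
        chars <- c(chars, sample(AA_ALPHABET, 1,
                                 prob = object$insert_emissions[node + 1L, ]))
        state <- "I"
        next
      }
      node <- node + 1L
      if (node > K) break
      if (nxt == "M") {
        chars <- c(chars, sample(AA_ALPHABET, 1,
                                 prob = object$match_emissions[node, ]))
      }
      state <- nxt
    }
    out[r] <- paste(chars, collapse = "")
  }
  out
}

#' Score new sequences with a fitted profile HMM
#'
#' @param object a `profile_hmm`
#' @param newdata protein string vector or `seq_records` data frame
#' @param ... unused
#' @return numeric vector of forward bit scores
#' @export
predict.profile_hmm <- function(object, newdata, ...) {
  seqs <- if (is.data.frame(newdata)) newdata$sequence else newdata
  forward_score(object, seqs)
}

#' Plot match-state information content of a profile HMM
#'
#' @param x a `profile_hmm`
#' @param ... passed to [graphics::barplot()]
#' @export
plot.profile_hmm <- function(x, ...) {
  ic <- apply(x$match_emissions, 1, function(p) sum(p * log2(p / x$background)))
  graphics::barplot(ic, border = NA, xlab = "match state",
                    ylab = "relative entropy (bits)",
                    main = sprintf("Profile HMM '%s'", x$name), ...)
  invisible(x)
}

#' Write a profile HMM to a plain-text file
#'
#' Documented serialization: a header with the match-state count and
#' alphabet, then labelled matrix blocks (match emissions, insert emissions,
#' transitions, background), whitespace-separated, full double precision.
#'
#' @param hmm a `profile_hmm`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_profile <- function(hmm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("bshscreen-profile 1",
               paste("name", hmm$name),
               paste("n_match", hmm$n_match),
               paste("alphabet", paste(AA_ALPHABET, collapse = ""))), con)
  blk <- function(label, m) {
    writeLines(paste("block", label, nrow(m), ncol(m)), con)
    writeLines(apply(m, 1, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  }
  blk("match_emissions", hmm$match_emissions)
  blk("insert_emissions", hmm$insert_emissions)
  blk("trans_m", hmm$trans_m)
  blk("trans_i", hmm$trans_i)
  blk("trans_d", hmm$trans_d)
  blk("background", matrix(hmm$background, nrow = 1))
  writeLines(paste("match_columns",
                   paste(hmm$match_columns, collapse = " ")), con)
  invisible(path)
}

#' Read a profile HMM written by [write_profile()]
#'
#' @param path file path
#' @return a `profile_hmm`
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "bshscreen-profile")) {
    stop("not a bshscreen profile file: ", path, call. = FALSE)
  }
  name <- sub("^name ", "", lines[2])
  k <- as.integer(sub("^n_match ", "", lines[3]))
  i <- 5L
  blocks <- list()
  while (i <= length(lines)) {
    if (startsWith(lines[i], "block ")) {
      hdr <- strsplit(lines[i], " ")[[1]]
      nr <- as.integer(hdr[3])
      m <- do.call(rbind, lapply(lines[(i + 1L):(i + nr)], function(ln)
        as.numeric(strsplit(trimws(ln), "\\s+")[[1]])))
      blocks[[hdr[2]]] <- m
      i <- i + nr + 1L
    } else if (startsWith(lines[i], "match_columns")) {
      blocks$match_columns <-
        as.integer(strsplit(lines[i], "\\s+")[[1]][-1])
      i <- i + 1L
    } else i <- i + 1L
  }
  colnames(blocks$match_emissions) <- AA_ALPHABET
  colnames(blocks$insert_emissions) <- AA_ALPHABET
  bg <- as.numeric(blocks$background)
  names(bg) <- AA_ALPHABET
  consensus <- AA_ALPHABET[apply(blocks$match_emissions, 1, which.max)]
  structure(list(name = name, n_match = k,
                 match_columns = blocks$match_columns,
                 match_emissions = blocks$match_emissions,
                 insert_emissions = blocks$insert_emissions,
                 trans_m = blocks$trans_m, trans_i = blocks$trans_i,
                 trans_d = blocks$trans_d, background = bg,
                 consensus = paste(consensus, collapse = ""),
                 n_train = NA_integer_, train_len = NA_real_),
            class = "profile_hmm")
}
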