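# End-to-end orchestration: screen -> classify -> cluster the BSH subset ->
# align representatives -> motifs -> trees -> repertoire summaries, with a
# run manifest (config snapshot, input/output digests, stage timings, seed)
# that makes reruns verifiable.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full discovery pipeline on a dataset bundle
#'
#' Stages, in order: six-frame ORF screening of the genomes against the
#' combined reference sets; dual profile-HMM classification of candidates;
#' greedy clustering of BSH-labelled proteins; center-star alignment of the
#' cluster representatives; conservation/motif profiling with the
#' active-site audit; neighbor-joining tree of the representatives with
#' bootstrap support; repertoire summaries and lifestyle cross-tabs. All
#' stage outputs are written under `out_dir`; a failure in any stage aborts
#' with an error naming the stage.
#'
#' @param bundle a [generate_dataset()] bundle, or a list with `genomes`,
#'   `refs_bsh`, `refs_pva`, `msa_bsh`, `msa_pva`, `metadata` in those
#'   formats
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @return a `run_manifest` list: `config`, `rng_seed`, `input_digests`,
#'   `outputs` (files with md5 digests), `stage_seconds`, and the in-memory
#'   stage `results`
#' @export
run_all <- function(bundle, config = pipeline_config(), out_dir = tempfile()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  results <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  refs_all <- rbind(bundle$refs_bsh, bundle$refs_pva)
  attr(refs_all, "kind") <- "protein"

  results$candidates <- stage("screen", {
    orfs <- extract_orfs(bundle$genomes, config$min_orf_len)
    screen_candidates(orfs, refs_all, config$min_ref_identity)
  })
  write_tsv(results$candidates[, setdiff(names(results$candidates),
                                         "protein")],
            file.path(out_dir, "candidates.tsv"))
  write_fasta(data.frame(id = results$candidates$orf_id,
                         species = results$candidates$species,
                         strain = results$candidates$strain,
                         sequence = results$candidates$protein),
              file.path(out_dir, "candidates.faa"))

  results$classifier <- stage("classify_fit", {
    bsh_classifier(bundle$msa_bsh, bundle$msa_pva,
                   seed = config$rng_seed)
  })
  results$classification <- stage("classify", {
    cls <- predict(results$classifier, results$candidates,
                   retention_evalue = config$retention_evalue)
    cbind(results$candidates[, c("genome_id", "species", "strain")], cls)
  })
  write_tsv(results$classification[, c("candidate_id", "score_bsh",
                                       "score_pva", "evalue_bsh",
                                       "evalue_pva", "label")],
            file.path(out_dir, "classification.tsv"))

  bsh_hits <- results$classification[results$classification$label == "BSH", ]
  results$clusters <- stage("cluster", {
    # note: no early return() here -- the stage expression is forced in this
    # function's frame, so return() would exit run_all itself
    if (nrow(bsh_hits) == 0) NULL else {
      prot <- data.frame(id = bsh_hits$candidate_id,
                         species = bsh_hits$species,
                         sequence = results$candidates$protein[
                           match(bsh_hits$candidate_id,
                                 results$candidates$orf_id)],
                         stringsAsFactors = FALSE)
      name_clusters(greedy_cluster(prot, config$cluster_identity))
    }
  })
  if (!is.null(results$clusters)) {
    write_clusters(results$clusters, file.path(out_dir, "bsh_clusters.clstr"),
                   file.path(out_dir, "bsh_clusters.tsv"))
  }

  results$rep_msa <- stage("align", {
    if (is.null(results$clusters)) NULL
    else star_align(cluster_representatives(results$clusters))
  })
  if (!is.null(results$rep_msa)) {
    write_stockholm(results$rep_msa, file.path(out_dir, "representatives.sto"))
  }

  results$motifs <- stage("motifs", {
    if (is.null(results$rep_msa)) NULL else {
    profile <- column_conservation(results$rep_msa)
    motifs <- find_motifs(profile, config$conservation_threshold,
                          config$min_motif_len)
    audit <- audit_active_sites(results$rep_msa, motifs,
                                default_active_sites(),
                                config$conservation_threshold)
    write_tsv(profile, file.path(out_dir, "conservation.tsv"))
    write_tsv(motifs, file.path(out_dir, "motifs.tsv"))
    write_tsv(audit, file.path(out_dir, "active_sites.tsv"))
    list(profile = profile, motifs = motifs, audit = audit)
    }
  })

  results$tree <- stage("tree", {
    if (is.null(results$rep_msa) || length(results$rep_msa$ids) < 3) {
      NULL
    } else {
      tree <- bootstrap_support(results$rep_msa, config$bootstrap_reps,
                                seed = config$rng_seed)
      write_newick(tree, file.path(out_dir, "bsh_representatives.nwk"))
      tree
    }
  })

  results$repertoire <- stage("summarize", {
    records <- strain_call_records(results$classification, bundle$metadata)
    summaries <- tryCatch(summarize_species(records),
                          error = function(e) NULL)
    total_species <- length(unique(bundle$metadata$species))
    breakdown <- category_breakdown(records, total_species)
    crosstab <- lifestyle_crosstab(records, bundle$metadata)
    write_tsv(records, file.path(out_dir, "strain_calls.tsv"))
    if (!is.null(summaries)) {
      write_tsv(summaries, file.path(out_dir, "species_summary.tsv"))
    }
    write_tsv(breakdown, file.path(out_dir, "category_breakdown.tsv"))
    if (!is.null(crosstab)) {
      write_tsv(crosstab, file.path(out_dir, "lifestyle_crosstab.tsv"))
    }
    presence <- stats::aggregate(cbind(bsh = n_bsh >= 1, pva = n_pva >= 1) ~
                                   species, data = records, FUN = any)
    presence$bsh <- as.integer(presence$bsh)
    presence$pva <- as.integer(presence$pva)
    write_tsv(presence, file.path(out_dir, "presence_absence.tsv"))
    list(records = records, summaries = summaries, breakdown = breakdown,
         crosstab = crosstab, presence = presence)
  })

  digest_obj <- function(obj) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(capture.output(write.table(as.data.frame(obj),
                                          row.names = FALSE)), f)
    unname(tools::md5sum(f))
  }
  input_digests <- list(genomes = digest_obj(bundle$genomes),
                        refs_bsh = digest_obj(bundle$refs_bsh),
                        refs_pva = digest_obj(bundle$refs_pva),
                        metadata = digest_obj(bundle$metadata))

  outputs <- sort(list.files(out_dir, full.names = TRUE))
  manifest <- list(config = unclass(config), rng_seed = config$rng_seed,
                   input_digests = input_digests,
                   stage_seconds = as.list(timings),
                   outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                                              basename(outputs))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  structure(c(manifest, list(out_dir = out_dir, results = results)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat(sprintf("  output dir: %s\n", x$out_dir))
  cat(sprintf("  seed: %d\n", x$rng_seed))
  for (s in names(x$stage_seconds)) {
    cat(sprintf("  stage %-12s %7.2fs\n", s, x$stage_seconds[[s]]))
  }
  cat(sprintf("  %d output files\n", length(x$outputs)))
  invisible(x)
}
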