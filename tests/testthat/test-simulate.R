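# Synthetic-data generator: consensus construction, member evolution,
# genome embedding, and dataset determinism.

test_that("consensus pair hits the shared-ancestry contract", {
  for (s in c(0.4, 0.7)) {
    spec_a <- family_spec("A", 320, shared_ancestry = s)
    spec_b <- family_spec("B", 320, shared_ancestry = s)
    cons <- make_consensus_pair(spec_a, spec_b, seed = 5)
    ca <- strsplit(cons[[1]], "")[[1]]
    cb <- strsplit(cons[[2]], "")[[1]]
    expect_equal(length(ca), 320)
    frac <- mean(ca == cb)
    expect_true(abs(frac - s) <= 0.05,
                info = sprintf("shared %g, observed %g", s, frac))
  }
})

test_that("shared_ancestry = 1 gives identical consensi", {
  spec_a <- family_spec("A", 100, shared_ancestry = 1,
                        motif_blocks = small_blocks())
  spec_b <- family_spec("B", 100, shared_ancestry = 1,
                        motif_blocks = small_blocks())
  cons <- make_consensus_pair(spec_a, spec_b, seed = 1)
  expect_identical(cons[[1]], cons[[2]])
})

test_that("both consensi carry the motif anchors exactly", {
  spec_a <- family_spec("A", 320)
  spec_b <- family_spec("B", 320)
  cons <- make_consensus_pair(spec_a, spec_b, seed = 9)
  for (c1 in cons) {
    for (b in default_motif_blocks()) {
      expect_equal(substr(c1, b$start, b$start + nchar(b$residues) - 1L),
                   b$residues)
    }
  }
})

test_that("consensus construction is deterministic under the seed", {
  spec_a <- family_spec("A", 200, motif_blocks = small_blocks())
  spec_b <- family_spec("B", 200, motif_blocks = small_blocks())
  expect_identical(make_consensus_pair(spec_a, spec_b, 7),
                   make_consensus_pair(spec_a, spec_b, 7))
  expect_false(identical(make_consensus_pair(spec_a, spec_b, 7),
                         make_consensus_pair(spec_a, spec_b, 8)))
})

test_that("family_spec rejects overlapping or out-of-range motif blocks", {
  expect_error(family_spec(motif_blocks = list(
    list(start = 1, residues = "MCT"), list(start = 3, residues = "GGG"))),
    "overlap")
  expect_error(family_spec(consensus_len = 10, motif_blocks = list(
    list(start = 9, residues = "MCT"))), "outside consensus range")
  expect_error(family_spec(divergence = 1), "divergence")
})

test_that("evolve_member: divergence 0 is the identity map", {
  cons <- random_aa(100)
  expect_identical(evolve_member(cons, 0, seed = 1), cons)
})

test_that("evolve_member substitutes at the divergence rate, sparing anchors", {
  spec <- family_spec("A", 320)
  cons <- make_consensus_pair(spec, family_spec("B", 320), seed = 2)[[1]]
  anchors <- unlist(lapply(default_motif_blocks(), function(b)
    seq(b$start, b$start + nchar(b$residues) - 1L)))
  set.seed(99)
  n_rep <- 300
  fracs <- numeric(n_rep)
  cc <- strsplit(cons, "")[[1]]
  for (r in seq_len(n_rep)) {
    m <- strsplit(evolve_member(cons, 0.3, spec$motif_blocks), "")[[1]]
    expect_identical(m[anchors], cc[anchors])
    fracs[r] <- mean(m[-anchors] != cc[-anchors])
  }
  # mean over 300 members of a Binomial(299 free sites, 0.3) fraction
  expect_true(abs(mean(fracs) - 0.3) < 0.01,
              info = sprintf("mean divergence %.4f", mean(fracs)))
})

test_that("embedded genes translate back to their proteins at true coordinates", {
  set.seed(21)
  prots <- c(pA = paste0("M", random_aa(119)), pB = paste0("M", random_aa(149)))
  emb <- embed_in_genome(prots, flank_len = 30, seed = 4, genome_id = "gX")
  expect_equal(emb$truth$protein_id, c("pA", "pB"))
  g <- emb$genome$sequence
  for (i in 1:2) {
    tr <- emb$truth[i, ]
    span <- substr(g, tr$start + 1L, tr$end)  # 0-based half-open
    if (tr$strand == "-") span <- oracle_revcomp(span)
    aa <- oracle_translate_frame(span, 0)
    expect_equal(aa, paste0(unname(prots[tr$protein_id]), "*"))
  }
})

test_that("embedded genes found maximal ORFs recovered by extract_orfs", {
  set.seed(8)
  prots <- c(p1 = paste0("M", random_aa(119)))
  emb <- embed_in_genome(prots, flank_len = 40, seed = 31)
  orfs <- extract_orfs(emb$genome, min_orf_len = 100)
  hit <- orfs[orfs$start == emb$truth$start & orfs$end == emb$truth$end, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$protein, unname(prots))
  expect_true(hit$has_stop)
})

test_that("embed_in_genome rejects proteins without an ATG start", {
  expect_error(embed_in_genome(c(p = "KLMN"), seed = 1),
               "must start with Met")
})

test_that("generate_dataset is deterministic and writes a readable bundle", {
  cfg <- sim_config(n_species = 2, strains_per_species = 1,
                    bsh_copies = c(1, 0), pva_copies = c(0, 1),
                    n_decoys = 1, consensus_len = 120, n_ref_bsh = 4,
                    n_ref_pva = 4, flank_len = 30,
                    motif_blocks = small_blocks())
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- generate_dataset(cfg, seed = 5, dir = d1)
  b2 <- generate_dataset(cfg, seed = 5, dir = d2)
  files <- list.files(d1)
  expect_setequal(files, c("genomes.fasta", "refs_bsh.faa", "refs_pva.faa",
                           "refs_bsh.sto", "refs_pva.sto", "metadata.tsv",
                           "truth.tsv"))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # files re-read to the in-memory bundle
  expect_equal(read_fasta(file.path(d1, "genomes.fasta"),
                          "nucleotide")$sequence, b1$genomes$sequence)
  expect_equal(read_stockholm(file.path(d1, "refs_bsh.sto"))$aligned,
               b1$msa_bsh$aligned)
  expect_equal(read_metadata(file.path(d1, "metadata.tsv")),
               b1$metadata)
  # truth proteins present and labelled
  expect_setequal(unique(b1$truth$family), c("BSH", "PVA", "decoy"))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("sim_config validates copy numbers and lifestyles", {
  expect_error(sim_config(bsh_copies = 4), "0\\.\\.3")
  expect_error(sim_config(lifestyles = "martian"), "invalid lifestyle")
})
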