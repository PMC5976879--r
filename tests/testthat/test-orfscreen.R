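# Six-frame translation, ORF extraction, local alignment, and the screening
# stage, each checked against independent oracles.

test_that("six-frame translation of a minimal gene", {
  fr <- six_frame_translate("ATGGCTTAA")  # M A *
  expect_equal(fr[["+1"]], "MA*")
  expect_equal(fr[["+2"]], "WL")
  expect_equal(fr[["+3"]], "GL")
  expect_equal(fr[["-1"]], "LSH")  # revcomp TTAAGCCAT
})

test_that("six-frame translation matches the per-codon oracle on random genomes", {
  set.seed(17)
  for (r in 1:60) {
    g <- random_nt(sample(30:400, 1))
    expect_identical(six_frame_translate(g), oracle_six_frames(g), info = g)
  }
})

test_that("codons containing N translate to X; short input warns", {
  fr <- six_frame_translate("ATGANTGGG")
  expect_equal(fr[["+1"]], "MXG")
  expect_warning(fr2 <- six_frame_translate("AT"), "shorter than one codon")
  expect_true(all(fr2 == ""))
})

test_that("ORF extraction enforces the length floor inclusively", {
  # gene of exactly 100 residues retained, 99 dropped
  for (len in c(99L, 100L)) {
    set.seed(len)
    p <- paste0("M", random_aa(len - 1L))
    emb <- embed_in_genome(c(x = p), flank_len = 30, seed = len)
    orfs <- extract_orfs(emb$genome, min_orf_len = 100)
    found <- any(orfs$protein == p)
    expect_equal(found, len >= 100L, info = sprintf("len %d", len))
  }
})

test_that("ORF coordinates and strands match the embedding truth table", {
  set.seed(40)
  prots <- setNames(vapply(1:6, function(i) paste0("M", random_aa(109)), ""),
                    paste0("p", 1:6))
  emb <- embed_in_genome(prots, flank_len = 45, seed = 12)
  orfs <- extract_orfs(emb$genome, min_orf_len = 100)
  for (i in seq_len(nrow(emb$truth))) {
    tr <- emb$truth[i, ]
    hit <- orfs[orfs$protein == unname(prots[tr$protein_id]), ]
    expect_equal(nrow(hit), 1L, info = tr$protein_id)
    expect_equal(hit$start, tr$start)
    expect_equal(hit$end, tr$end)
    expect_equal(startsWith(hit$frame, "+"), tr$strand == "+")
  }
})

test_that("a frame-end gene without a stop codon is reported has_stop = FALSE", {
  cds <- "ATGGCTGCAGCTGCGGCCGCA"  # M A A A A A A, no stop, at 3' end
  g <- data.frame(id = "g", species = NA, strain = NA,
                  sequence = paste0("TTTT", cds),
                  stringsAsFactors = FALSE)
  orfs <- extract_orfs(g, min_orf_len = 5)
  hit <- orfs[orfs$frame == "+2" & orfs$protein == "MAAAAAA", ]
  expect_equal(nrow(hit), 1L)
  expect_false(hit$has_stop)
  expect_equal(hit$end - hit$start, 21)  # no stop codon in the span
})

test_that("smith_waterman equals the explicit affine-gap DP on random pairs", {
  set.seed(23)
  for (r in 1:40) {
    a <- random_aa(sample(8:35, 1))
    b <- if (r %% 2 == 0) random_aa(sample(8:35, 1)) else {
      ch <- strsplit(a, "")[[1]]
      if (length(ch) > 10) ch <- ch[-sample(length(ch), 2)]
      ch[sample(length(ch), 3)] <- sample(AA20, 3, TRUE)
      paste(ch, collapse = "")
    }
    got <- smith_waterman(a, b)
    expect_equal(max(got$score, 0), oracle_sw_score(a, b),
                 info = paste(a, b))
  }
})

test_that("smith_waterman identity conventions on a constructed case", {
  got <- smith_waterman("MKKKKLC", "MKKKKLC")
  expect_equal(got$identity, 1)
  expect_equal(got$identity_short, 1)
  # no positive-scoring alignment at all
  none <- smith_waterman("AAAA", "GGGG")
  expect_equal(none$identity, 0)
  expect_equal(none$aligned_a, "")
  # gapped case: identity denominator includes the gap column
  got2 <- smith_waterman("WWWAWWWW", "WWWWWWW")
  ncols <- nchar(got2$aligned_a)
  ca <- strsplit(got2$aligned_a, "")[[1]]
  cb <- strsplit(got2$aligned_b, "")[[1]]
  n_id <- sum(ca == cb & ca != "-")
  expect_equal(got2$identity, n_id / ncols)
  expect_equal(got2$identity_short, n_id / 7)
})

test_that("screening retains at exactly the identity floor and not below", {
  # 30 identical of 100 -> 0.30 retained; 29 -> 0.29 dropped
  for (k in c(29L, 30L)) {
    pair <- identity_controlled_pair(100, k)
    refs <- data.frame(id = "ref1", species = NA, strain = NA,
                       sequence = pair$ref, stringsAsFactors = FALSE)
    orfs <- data.frame(genome_id = "g", species = "s", strain = "t",
                       orf_id = "o1", frame = "+1", start = 0L, end = 300L,
                       protein = pair$var, has_stop = TRUE,
                       stringsAsFactors = FALSE)
    out <- screen_candidates(orfs, refs, min_ref_identity = 0.30)
    expect_equal(nrow(out), as.integer(k >= 30L), info = sprintf("k=%d", k))
    if (nrow(out) == 1) expect_equal(out$best_identity, k / 100)
  }
})

test_that("raising the identity floor never adds candidates", {
  set.seed(61)
  cfg <- sim_config(n_species = 2, strains_per_species = 1,
                    bsh_copies = c(1, 1), pva_copies = c(0, 0),
                    n_decoys = 1, consensus_len = 110, n_ref_bsh = 3,
                    n_ref_pva = 2, flank_len = 30,
                    motif_blocks = small_blocks())
  b <- generate_dataset(cfg, seed = 3)
  orfs <- extract_orfs(b$genomes, 100)
  refs <- rbind(b$refs_bsh, b$refs_pva)
  lo <- screen_candidates(orfs, refs, 0.30)
  hi <- screen_candidates(orfs, refs, 0.55)
  expect_true(all(hi$orf_id %in% lo$orf_id))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("screening recovers planted genes and excludes decoys", {
  cfg <- sim_config(n_species = 2, strains_per_species = 1,
                    bsh_copies = c(1, 1), pva_copies = c(1, 0),
                    n_decoys = 2, decoy_len = 120, consensus_len = 120,
                    n_ref_bsh = 4, n_ref_pva = 3, flank_len = 30,
                    motif_blocks = small_blocks())
  b <- generate_dataset(cfg, seed = 11)
  orfs <- extract_orfs(b$genomes, 100)
  out <- screen_candidates(orfs, rbind(b$refs_bsh, b$refs_pva), 0.30)
  planted <- b$truth[b$truth$family != "decoy", ]
  decoys <- b$truth[b$truth$family == "decoy", ]
  expect_true(all(planted$sequence %in% out$protein))
  expect_false(any(decoys$sequence %in% out$protein))
})

test_that("overlap collapse keeps the single best candidate per locus", {
  pair_hi <- identity_controlled_pair(100, 80)
  pair_lo <- identity_controlled_pair(100, 40)
  refs <- data.frame(id = "ref1", species = NA, strain = NA,
                     sequence = pair_hi$ref, stringsAsFactors = FALSE)
  orfs <- data.frame(genome_id = "g", species = "s", strain = "t",
                     orf_id = c("oHI", "oLO"), frame = c("+1", "-1"),
                     start = c(0L, 50L), end = c(300L, 350L),
                     protein = c(pair_hi$var, pair_lo$var), has_stop = TRUE,
                     stringsAsFactors = FALSE)
  out <- screen_candidates(orfs, refs, 0.30)
  expect_equal(out$orf_id, "oHI")
  # non-overlapping loci are both kept
  orfs$start <- c(0L, 400L); orfs$end <- c(300L, 700L)
  out2 <- screen_candidates(orfs, refs, 0.30)
  expect_setequal(out2$orf_id, c("oHI", "oLO"))
})
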