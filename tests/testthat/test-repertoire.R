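# Repertoire summaries: per-species content, category breakdown,
# multiplicity, lifestyle cross-tabs, and the shipped survey fixtures.

test_that("strain call records tally labels per strain, with metadata zeros", {
  results <- data.frame(
    species = c("sp1", "sp1", "sp1", "sp2"),
    strain = c("s1", "s1", "s2", "s1"),
    label = c("BSH", "PVA", "BSH", "removed"),
    stringsAsFactors = FALSE)
  md <- data.frame(species = c("sp1", "sp1", "sp2", "sp3"),
                   strain = c("s1", "s2", "s1", "s1"),
                   lifestyle = "unknown", stringsAsFactors = FALSE)
  rec <- strain_call_records(results, md)
  expect_equal(rec$species, c("sp1", "sp1", "sp2", "sp3"))
  expect_equal(rec$n_bsh, c(1L, 1L, 0L, 0L))
  expect_equal(rec$n_pva, c(1L, 0L, 0L, 0L))
})

test_that("species summaries report only BSH-positive species with exact shares", {
  rec <- data.frame(
    species = c(rep("spA", 4), rep("spB", 2), rep("spC", 3)),
    strain = c(paste0("s", 1:4), paste0("s", 1:2), paste0("s", 1:3)),
    n_bsh = c(1, 1, 2, 0, 0, 0, 3, 1, 1),
    n_pva = 0L, stringsAsFactors = FALSE)
  s <- summarize_species(rec)
  expect_equal(s$species, c("spA", "spC"))  # spB has no positive strain
  expect_equal(s$n_with_bsh, c(3L, 3L))
  expect_equal(s$pct_with_bsh, c(75, 100))
  expect_equal(s$n_with_1, c(2L, 2L))
  expect_equal(s$n_with_2, c(1L, 0L))
  expect_equal(s$n_with_3, c(0L, 1L))
})

test_that("half-up rounding matches the printed-table convention", {
  expect_equal(round_half_up(100 * 147 / 182, 2), 80.77)
  expect_equal(round_half_up(2.675, 2), 2.68)   # would be 2.67 under round()
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-2.675, 2), -2.68)
  expect_equal(round_half_up(64.5, 0), 65)
})

test_that("category breakdown counts BSH/PVA/both/neither inclusively", {
  rec <- data.frame(
    species = c("a", "a", "b", "c", "d"),
    strain = c("s1", "s2", "s1", "s1", "s1"),
    n_bsh = c(1, 0, 0, 2, 0),
    n_pva = c(0, 1, 1, 1, 0),
    stringsAsFactors = FALSE)
  br <- category_breakdown(rec, total_species = 10)
  expect_equal(br$n_species_bsh, 2L)     # a, c
  expect_equal(br$n_species_pva, 3L)     # a, b, c
  expect_equal(br$n_species_both, 2L)    # a, c
  expect_equal(br$n_species_neither, 7L) # d plus 6 unobserved
  expect_equal(br$pct_species_bsh, 20)
  # identity: bsh + pva - both + neither = total
  expect_equal(br$n_species_bsh + br$n_species_pva - br$n_species_both +
                 br$n_species_neither, 10L)
  expect_error(category_breakdown(rec, 3), "smaller than")
})

test_that("multiplicity classes are exclusive and sum to all species", {
  s <- data.frame(species = c("a", "b", "c", "d"),
                  total_strains = 4L, n_with_bsh = 2L, pct_with_bsh = 50,
                  n_with_1 = c(2, 1, 1, 0), n_with_2 = c(0, 1, 0, 0),
                  n_with_3 = c(0, 0, 1, 2), stringsAsFactors = FALSE)
  m <- bsh_multiplicity(s)
  expect_equal(c(m$n_single, m$n_double, m$n_triple), c(1L, 1L, 2L))
  expect_equal(m$n_single + m$n_double + m$n_triple, m$n_species)
  expect_equal(c(m$pct_single, m$pct_double, m$pct_triple), c(25, 25, 50))
})

test_that("lifestyle cross-tab percentages are per-enzyme over encoding species", {
  rec <- data.frame(species = c("a", "b", "c"), strain = "s1",
                    n_bsh = c(1, 1, 0), n_pva = c(0, 1, 1),
                    stringsAsFactors = FALSE)
  md <- data.frame(species = c("a", "b", "c"), strain = "s1",
                   lifestyle = c("vertebrate-adapted", "vertebrate-adapted",
                                 "free-living"), stringsAsFactors = FALSE)
  ct <- lifestyle_crosstab(rec, md)
  bsh <- ct[ct$enzyme == "BSH", ]
  expect_equal(bsh$n_species[bsh$lifestyle == "vertebrate-adapted"], 2L)
  expect_equal(bsh$pct_species[bsh$lifestyle == "vertebrate-adapted"], 100)
  pva <- ct[ct$enzyme == "PVA", ]
  expect_equal(sort(pva$pct_species[pva$n_species > 0]), c(50, 50))
  # percentages within each enzyme sum to ~100
  expect_equal(sum(bsh$pct_species), 100)
  # conflicting lifestyles for one species are an error
  md2 <- rbind(md, data.frame(species = "a", strain = "s2",
                              lifestyle = "nomadic"))
  expect_error(lifestyle_crosstab(rec, md2), "more than one lifestyle")
  expect_error(lifestyle_crosstab(rec, md[-1, ]), "missing from metadata")
})

test_that("the shipped per-species content table is internally consistent", {
  tab <- table2_bsh_content()
  expect_equal(nrow(tab), 39L)
  expect_true(all(tab$n_with_1 + tab$n_with_2 + tab$n_with_3 ==
                    tab$n_with_bsh))
  expect_true(all(tab$n_with_bsh <= tab$total_strains))
  expect_equal(tab$pct_with_bsh,
               round_half_up(100 * tab$n_with_bsh / tab$total_strains, 2))
  # expansion to strain records reproduces the table
  rec <- table2_strain_calls(tab)
  expect_equal(nrow(rec), sum(tab$total_strains))
  s <- summarize_species(rec)
  tab_sorted <- tab[order(tab$species), ]
  expect_equal(s$species, tab_sorted$species)
  expect_equal(s$pct_with_bsh, tab_sorted$pct_with_bsh)
  expect_equal(s$n_with_2, tab_sorted$n_with_2)
})

test_that("the synthetic survey table reproduces every published marginal", {
  sv <- synthetic_survey_table()
  expect_equal(nrow(sv), 170L)
  expect_equal(sum(sv$bsh), 39L)
  expect_equal(sum(sv$pva), 82L)
  expect_equal(sum(sv$bsh & sv$pva), 8L)
  expect_equal(sum(!sv$bsh & !sv$pva), 57L)
  bsh_ls <- table(sv$lifestyle[sv$bsh == 1])
  expect_equal(as.integer(bsh_ls[c("vertebrate-adapted", "unknown",
                                   "nomadic")]),
               c(33L, 5L, 1L))
  pva_ls <- table(sv$lifestyle[sv$pva == 1])
  expect_equal(as.integer(pva_ls[c("vertebrate-adapted", "free-living",
                                   "unknown", "nomadic")]),
               c(11L, 33L, 33L, 5L))
})
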