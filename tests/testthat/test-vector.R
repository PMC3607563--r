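test_that("the fixture vector carries single cloning sites around the stuffer", {
  vec <- make_fixture_vector("KK")
  expect_s3_class(vec, "platform_vector")
  expect_equal(vec$variant, "KK")
  expect_false(is.na(vec$xhoi_start))
  # destroying the PvuII site must be detected
  bad <- chartr("CAGCTG", "CAGGTG", vec$seq)  # no-op chartr guard below
  noPv <- sub("CAGCTG", "CAGGTG", vec$seq, fixed = TRUE)
  expect_error(platform_vector(noPv), "PvuII")
  noBs <- sub("GTATAC", "GTATTC", vec$seq, fixed = TRUE)
  expect_error(platform_vector(noBs), "BstZ17I")
  dup <- paste0(vec$seq, "CAGCTG")
  expect_error(platform_vector(dup), "one PvuII")
})

test_that("digestion drops the stuffer and leaves a T-tailed backbone without residual sites", {
  vec <- make_fixture_vector()
  bb <- digest_and_tail(vec)
  expect_true(bb$t_tailed)
  expect_equal(nchar(bb$seq) + nchar(bb$stuffer), vec$length)
  # backbone starts at the BstZ17I cut (TAC...) and ends at the PvuII cut (...CAG)
  expect_equal(substr(bb$seq, 1, 3), "TAC")
  expect_equal(substr(bb$seq, nchar(bb$seq) - 2, nchar(bb$seq)), "CAG")
  # the cut destroys both recognition sites: re-digestion finds nothing
  expect_false(grepl("CAGCTG", bb$seq, fixed = TRUE))
  expect_false(grepl("GTATAC", bb$seq, fixed = TRUE))
  # T3 promoter is inside the backbone at the recorded offset
  expect_equal(substr(bb$seq, bb$t3_offset + 1, bb$t3_offset + nchar(bb$t3_primer)),
               bb$t3_primer)
})

test_that("TA cloning returns both orientations differing by reverse complement", {
  bb <- digest_and_tail(make_fixture_vector())
  ins <- simulate_overlap_assembly(fragments_for(c("GCC", "TGG", "CTG", "GAG")))[[1]]$seq
  cons <- ta_clone(ins, bb)
  expect_named(cons, c("forward", "reverse"))
  expect_equal(cons$forward$insert, ins)
  expect_equal(cons$reverse$insert, revcomp(ins))
  expect_equal(nchar(cons$forward$seq), nchar(bb$seq) + nchar(ins) + 2L)
  expect_error(ta_clone("", bb), "empty insert")
  expect_warning(ta_clone(ins, bb, a_tailed = FALSE), "A-tailed")
})

test_that("the forward-orientation construct translates NLS, ZF array and FokI stub in frame", {
  bb <- digest_and_tail(make_fixture_vector())
  ins <- simulate_overlap_assembly(fragments_for(c("GCC", "TGG", "CTG", "GAG")))[[1]]$seq
  fwd <- ta_clone(ins, bb)$forward
  circ <- paste0(fwd$seq, fwd$seq)  # read through the origin
  atg <- regexpr("ATGGATTACAAGGATGACGACGATAAG", circ, fixed = TRUE)[1]
  orf <- substr(circ, atg, atg + 3L * 200L - 1L)
  aa <- translate_dna(orf)
  stop_at <- regexpr("*", aa, fixed = TRUE)[1]
  expect_gt(stop_at, 0)
  peptide <- substr(aa, 1, stop_at - 1L)
  expect_true(startsWith(peptide, "MDYKDDDDKPKKKRKV"))         # FLAG + NLS
  expect_true(grepl("DCRDLAR.+RSDHLTT.+RNDALTE.+RSDNLAR", peptide))  # fingers in order
  expect_true(grepl("QLVKSELEEKKSELRHKLKYV", peptide))         # FokI-like stub
  # five-finger arrays stay in frame too (the insert repeat is 84 nt)
  ins5 <- simulate_overlap_assembly(fragments_for(c("GCC", "TGG", "CTG", "GAG", "GCA")))[[1]]$seq
  fwd5 <- ta_clone(ins5, bb)$forward
  circ5 <- paste0(fwd5$seq, fwd5$seq)
  atg5 <- regexpr("ATGGATTACAAGGATGACGACGATAAG", circ5, fixed = TRUE)[1]
  aa5 <- translate_dna(substr(circ5, atg5, atg5 + 3L * 240L - 1L))
  pep5 <- substr(aa5, 1, regexpr("*", aa5, fixed = TRUE)[1] - 1L)
  expect_true(grepl("QSGDLTR", pep5))
  expect_true(grepl("QLVKSELEEKKSELRHKLKYV", pep5))
})

test_that("colony PCR discriminates insert orientation", {
  bb <- digest_and_tail(make_fixture_vector())
  plan <- plan_reactions(c("GCC", "TGG", "CTG", "GAG"), the_registry)
  ins <- simulate_overlap_assembly(fragments_for(c("GCC", "TGG", "CTG", "GAG")))[[1]]$seq
  cons <- ta_clone(ins, bb)
  rv <- plan$third_pcr$primer[2]
  len_fwd <- colony_pcr_check(cons$forward, rv)
  len_rev <- colony_pcr_check(cons$reverse, rv)
  expect_false(is.na(len_fwd))
  expect_true(is.na(len_rev))
  # the product runs from the T3 promoter to the end of the insert
  dist_t3_to_insert <- nchar(bb$seq) - bb$t3_offset + 1L  # remaining backbone + scar T
  expect_equal(len_fwd, dist_t3_to_insert + nchar(ins))
  # longer inserts give proportionally longer screens
  ins5 <- simulate_overlap_assembly(fragments_for(c("GCC", "TGG", "CTG", "GAG", "GCA")))[[1]]$seq
  plan5 <- plan_reactions(c("GCC", "TGG", "CTG", "GAG", "GCA"), the_registry)
  len5 <- colony_pcr_check(ta_clone(ins5, bb)$forward, plan5$third_pcr$primer[2])
  expect_equal(len5 - len_fwd, 84L)
})
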