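test_that("build_template reconstructs the annealing references from the cloning primers", {
  tm <- build_template()
  # the reverse reference is itself the zero-mismatch GAG reverse primer
  expect_equal(tm$rev_ref, lookup_helix("GAG", the_registry)$rev_primer)
  expect_equal(count_mismatches(tm$rev_ref, lookup_helix("GAG", the_registry)$rev_primer), 0L)
  # the forward reference encodes the template's own helix-1
  expect_equal(translate_dna(substr(tm$fwd_ref, 1, 21)), "RSDALTR")
  expect_equal(substr(tm$fwd_ref, 22, 29), "CATATCCG")
  expect_equal(substr(tm$rev_ref, 23, 29), "ACTGAAG")
  # the template coding strand starts with fwd_ref and ends with rc(rev_ref)
  expect_equal(substr(tm$seq, 1, 29), tm$fwd_ref)
  expect_equal(substr(tm$seq, tm$total_length - 28, tm$total_length), revcomp(tm$rev_ref))
  expect_error(build_template(fwd_cloning_primer = substr(OLTA_FWD_CLONING_PRIMER, 1, 28)),
               "29 nt")
  expect_error(build_template(rev_cloning_primer = "CGGGCAAGATTATCCGAGCGACTGAAGA"), "27 nt")
  expect_error(build_template(internal_framework = "ACGTX"), "outside")
})

test_that("count_mismatches is a case-insensitive Hamming distance", {
  tm <- the_template
  expect_equal(count_mismatches("CGCTCGGATaatCTTgCCCGCCATATCCG", tm$fwd_ref), 4L)
  expect_equal(count_mismatches(tm$fwd_ref, tm$fwd_ref), 0L)
  expect_equal(count_mismatches("GttcGGtAAGcgcgTCattGCGACTGAAG", tm$rev_ref), 11L)
  expect_error(count_mismatches("ACGT", "ACG"), "unequal")
})

test_that("3' anchors hold at the published lengths", {
  tm <- the_template
  for (i in seq_len(nrow(the_registry))) {
    expect_true(check_three_prime_anchor(the_registry$fwd_primer[i], tm$fwd_ref, 8),
                info = the_registry$triplet[i])
    expect_true(check_three_prime_anchor(the_registry$rev_primer[i], tm$rev_ref, 7),
                info = the_registry$triplet[i])
  }
  gat_rev <- lookup_helix("GAT", the_registry)$rev_primer
  expect_true(check_three_prime_anchor(gat_rev, tm$rev_ref, 7))
  expect_false(check_three_prime_anchor(gat_rev, tm$rev_ref, 9))
  expect_true(check_three_prime_anchor(tm$fwd_ref, tm$fwd_ref, 29))
})

test_that("the designer reproduces the template's own helices with zero cost", {
  tm <- the_template
  d1 <- design_primer_pair("RSDALTR", tm)
  expect_equal(d1$fwd_ndn, 0L)
  expect_equal(d1$fwd_primer, tm$fwd_ref)
  d2 <- design_primer_pair("RSDNLAR", tm)
  expect_equal(d2$rev_ndn, 0L)
  expect_equal(d2$rev_primer, tm$rev_ref)
  # the slot the helix does not belong to costs 4, as published
  expect_equal(d2$fwd_ndn, 4L)
  expect_equal(d1$rev_ndn, 4L)
  expect_error(design_primer_pair("XXXXXXX", tm), "invalid amino-acid")
})

test_that("designed primers carry self-consistent counts, anchors and structure", {
  set.seed(7)
  for (k in 1:10) {
    h <- random_helix()
    d <- design_primer_pair(h, the_template, max_mismatch = 42L)
    expect_equal(count_mismatches(d$fwd_primer, the_template$fwd_ref), d$fwd_ndn)
    expect_equal(count_mismatches(d$rev_primer, the_template$rev_ref), d$rev_ndn)
    expect_true(d$fwd_anchor_ok)
    expect_true(d$rev_anchor_ok)
    expect_equal(nchar(d$fwd_primer), 29L)
    expect_equal(nchar(d$rev_primer), 29L)
    expect_equal(translate_dna(substr(d$fwd_primer, 1, 21)), h)
    # forward and reverse primers of one helix encode the same codons
    expect_equal(revcomp(substr(d$rev_primer, 2, 22)), substr(d$fwd_primer, 1, 21))
  }
})

test_that("designer mismatch totals equal the exhaustive synonymous-codon minimum", {
  set.seed(11)
  helices <- c(the_registry$helix[c(1, 5, 13, 21)], replicate(6, random_helix()))
  for (h in helices) {
    d <- design_primer_pair(h, the_template, max_mismatch = 42L)
    oracle <- brute_force_design(h, the_template)
    expect_equal(d$fwd_ndn + d$rev_ndn, oracle$min_total, info = h)
    expect_gte(oracle$n_combos, prod(rep(1, 7)))  # enumeration actually ran
  }
})

test_that("designer never does worse than the published manual designs", {
  for (i in seq_len(nrow(the_registry))) {
    d <- design_primer_pair(the_registry$helix[i], the_template)
    pf <- count_mismatches(the_registry$fwd_primer[i], the_template$fwd_ref)
    pr <- count_mismatches(the_registry$rev_primer[i], the_template$rev_ref)
    expect_lte(d$fwd_ndn, pf)
    expect_lte(d$rev_ndn, pr)
  }
})

test_that("the mismatch cap raises a constraint error that carries the best design", {
  err <- tryCatch(design_primer_pair("WWWWWWW", the_template, max_mismatch = 3L),
                  olta_design_error = function(e) e)
  expect_s3_class(err, "olta_design_error")
  expect_s3_class(err$best_design, "designed_primers")
  expect_gt(err$best_design$fwd_ndn, 3L)
})

test_that("primer_order_sheet flattens designs into an exportable table", {
  d <- design_primer_pair("RSDNLAR", the_template)
  sheet <- primer_order_sheet(list(d))
  expect_equal(nrow(sheet), 2L)
  expect_equal(sheet$sequence[1], d$fwd_primer)
  expect_true(all(sheet$anchor_ok))
})
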