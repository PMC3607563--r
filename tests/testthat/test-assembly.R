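test_that("reaction planning emits n-1 first-PCR reactions with the published primer pairing", {
  plan <- plan_reactions(c("GCC", "TGG", "CTG", "GAG"), the_registry)
  expect_equal(nrow(plan$fragments), 3L)
  expect_equal(plan$fragments$fwd_name, c("GCC-Fw", "TGG-Fw", "CTG-Fw"))
  expect_equal(plan$fragments$rev_name, c("TGG-Rv", "CTG-Rv", "GAG-Rv"))
  expect_equal(plan$third_pcr$name, c("GCC-Fw", "GAG-Rv"))
  for (n in 4:6) {
    arr <- the_registry$triplet[seq_len(n)]
    expect_equal(nrow(plan_reactions(arr, the_registry)$fragments), n - 1L)
  }
  expect_error(plan_reactions(c("GCC", "TGG"), the_registry), "fingers")
  expect_error(plan_reactions(c("AAA", "TGG", "CTG", "GAG"), the_registry),
               "no helix available")
})

test_that("the second-PCR mixing recipe follows the published volumes per array size", {
  mix4 <- plan_reactions(the_registry$triplet[1:4], the_registry)$second_pcr
  expect_equal(mix4$volume_ul, c(0.5, 1.5, 0.5))
  mix5 <- plan_reactions(the_registry$triplet[1:5], the_registry)$second_pcr
  expect_equal(mix5$volume_ul, c(0.5, 1.5, 1.5, 0.5))
  mix6 <- plan_reactions(the_registry$triplet[1:6], the_registry)$second_pcr
  expect_equal(mix6$volume_ul, c(0.5, 0.5, 1.5, 0.5, 0.5))
  expect_equal(mix6$fragment, c("ZF1-ZF2", "ZF2-ZF3", "ZF3-ZF4", "ZF4-ZF5", "ZF5-ZF6"))
})

test_that("fragments substitute the helix slots and keep the template length", {
  tm <- the_template
  # identity helices reproduce the template itself
  fr <- synthesize_fragment(tm, "RSDALTR", "RSDNLAR")
  expect_equal(fr$seq, tm$seq)
  expect_equal(substr(fr$seq, 1, 29), tm$fwd_ref)
  expect_equal(substr(fr$seq, fr$length - 28, fr$length), revcomp(tm$rev_ref))
  # any helix pair preserves the length
  set.seed(21)
  for (k in 1:5) {
    h1 <- random_helix(); h2 <- random_helix()
    f <- synthesize_fragment(tm, h1, h2, max_mismatch = 42L)
    expect_equal(f$length, tm$total_length)
    expect_equal(translate_dna(substr(f$seq, 1, 21)), h1)
    expect_equal(translate_dna(substr(f$seq, f$length - 21, f$length - 1)), h2)
  }
  expect_equal(translate_dna(substr(
    synthesize_fragment(tm, "QSGDLTR", "TSGSLVR")$seq, 1, 21)), "QSGDLTR")
})

test_that("distinct-helix arrays assemble into exactly one on-pathway chain", {
  frags <- fragments_for(c("GCC", "TGG", "CTG", "GAG"))
  prods <- simulate_overlap_assembly(frags)
  expect_length(prods, 1L)
  expect_false(attr(prods, "ambiguous"))
  expect_true(prods[[1]]$on_pathway)
  expect_equal(prods[[1]]$helices,
               vapply(c("GCC", "TGG", "CTG", "GAG"),
                      function(t) lookup_helix(t, the_registry)$helix, character(1),
                      USE.NAMES = FALSE))
  # consecutive fragments share the designed 22-nt overlap (helix + 1 nt)
  expect_equal(prods[[1]]$length, 3L * the_template$total_length - 2L * 22L)
})

test_that("a repeated helix creates branch points and flagged off-pathway chains", {
  frags <- fragments_for(c("GAG", "TGG", "GAG", "GCA"))
  prods <- simulate_overlap_assembly(frags)
  expect_gt(length(prods), 1L)
  expect_true(attr(prods, "ambiguous"))
  expect_true(any(vapply(prods, `[[`, logical(1), "on_pathway")))
  expect_true(any(!vapply(prods, `[[`, logical(1), "on_pathway")))
})

test_that("a single fragment is returned unchanged", {
  fr <- synthesize_fragment(the_template, "RSDALTR", "RSDNLAR")
  prods <- simulate_overlap_assembly(list(fr))
  expect_length(prods, 1L)
  expect_equal(prods[[1]]$seq, fr$seq)
})

test_that("chains with more fragments are strictly longer", {
  lens <- vapply(4:6, function(n) {
    frags <- fragments_for(the_registry$triplet[seq_len(n)])
    simulate_overlap_assembly(frags)[[1]]$length
  }, integer(1))
  expect_true(all(diff(lens) > 0))
  expect_equal(diff(lens), rep(the_template$total_length - 22L, 2))
})

test_that("assembled arrays translate to the helices joined by the invariant framework", {
  frags <- fragments_for(c("GCC", "TGG", "CTG", "GAG"))
  seqa <- simulate_overlap_assembly(frags)[[1]]$seq
  aa <- translate_dna(substr(seqa, 1, 21 + 3 * 84))
  expect_equal(aa, paste0("DCRDLAR", "HIRIHTGQKPFQCRICMRNFS",
                          "RSDHLTT", "HIRIHTGQKPFQCRICMRNFS",
                          "RNDALTE", "HIRIHTGQKPFQCRICMRNFS",
                          "RSDNLAR"))
})

test_that("the third PCR keeps anchor-matched chains and marks the intended band", {
  plan <- plan_reactions(c("GCC", "TGG", "CTG", "GAG"), the_registry)
  prods <- simulate_overlap_assembly(fragments_for(c("GCC", "TGG", "CTG", "GAG")))
  bands <- simulate_third_pcr(prods, plan$third_pcr$primer[1], plan$third_pcr$primer[2])
  expect_equal(nrow(bands), 1L)
  expect_true(bands$intended)
  expect_true(bands$a_tailed)
  # ambiguous assemblies give a ladder of several bands
  prods2 <- simulate_overlap_assembly(fragments_for(c("GAG", "TGG", "GAG", "GCA")))
  plan2 <- plan_reactions(c("GAG", "TGG", "GAG", "GCA"), the_registry)
  bands2 <- simulate_third_pcr(prods2, plan2$third_pcr$primer[1], plan2$third_pcr$primer[2])
  expect_gt(nrow(bands2), 1L)
  # primers whose anchors match no product end retain nothing
  none <- simulate_third_pcr(prods, paste(rep("A", 29), collapse = ""),
                             plan$third_pcr$primer[2])
  expect_equal(nrow(none), 0L)
})
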