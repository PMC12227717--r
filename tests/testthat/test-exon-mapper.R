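test_that("all exons of an unmutated locus are recovered exactly", {
  m <- fixture_model()
  sim <- evolve_along_tree(m, "(A:1,B:1);", 0, 0, seed = 8)
  locus <- orient_locus(sim$loci$A, m)
  hits <- locate_exons(m, locus)
  expect_true(all(vapply(hits, `[[`, TRUE, "found")))
  expect_true(all(vapply(hits, `[[`, 1, "identity") == 1))
  truth <- sim$truth$per_species$A$exon_intervals
  got <- t(vapply(hits, `[[`, c(0L, 0L), "target_interval"))
  expect_equal(got[, 1], truth$start)
  expect_equal(got[, 2], truth$end)
  # colinearity: strictly increasing intervals
  expect_true(all(diff(got[, 1]) > 0))
  expect_true(all(got[, 2] > got[, 1]))
})

test_that("reverse-complemented loci give identical hits after orientation", {
  m <- fixture_model()
  sim <- evolve_along_tree(m, "(A:1,B:1);", 0.01, 0, seed = 9)
  fwd <- orient_locus(sim$loci$A, m)
  rl <- sim$loci$A
  rl$sequence <- genloss:::revcomp(rl$sequence)
  rev <- orient_locus(rl, m)
  expect_identical(rev$orientation, "reverse")
  expect_identical(rev$sequence, fwd$sequence)
  h1 <- locate_exons(m, fwd)
  h2 <- locate_exons(m, rev)
  expect_identical(lapply(h1, `[[`, "target_interval"),
                   lapply(h2, `[[`, "target_interval"))
})

test_that("a deleted exon is reported absent, not mislocated", {
  m <- fixture_model()
  sim <- evolve_along_tree(m, "(A:1,B:1);", 0, 0,
                           list(deletion_event("A", 7)), seed = 10)
  hits <- locate_exons(m, orient_locus(sim$loci$A, m))
  found <- vapply(hits, `[[`, TRUE, "found")
  exn <- vapply(hits, `[[`, 1L, "exon_number")
  expect_false(found[exn == 7])
  expect_true(all(found[exn != 7]))
})

test_that("random sequence yields a no-gene-found error", {
  m <- fixture_model()
  L <- nchar(assemble_reference_locus(m))
  set.seed(14)
  for (i in 1:20) {
    rnd <- target_locus("r", "r", paste(
      sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
    expect_error(orient_locus(rnd, m), "no gene found")
  }
})

test_that("splice dinucleotides are read from fixed flanking offsets", {
  m <- fixture_model()
  sim <- evolve_along_tree(m, "(A:1,B:1);", 0, 0,
                           list(splice_event("A", 11, "donor", "AT")),
                           seed = 12)
  locus <- orient_locus(sim$loci$A, m)
  hits <- locate_exons(m, locus)
  exn <- vapply(hits, `[[`, 1L, "exon_number")
  h11 <- hits[[which(exn == 11)]]
  expect_identical(h11$donor_dinucleotide, "AT")
  expect_identical(h11$acceptor_dinucleotide, "AG")
  h5 <- hits[[which(exn == 5)]]
  d <- extract_splice_dinucleotides(locus, h5)
  expect_identical(unname(d["donor"]), m$exons[[which(exn == 5)]]$expected_donor)
  # a hit flush with the locus end has no donor side
  trimmed <- target_locus("A", "t",
                          substr(locus$sequence, 1,
                                 hits[[length(hits)]]$target_interval[2]))
  h_end <- locate_exons(m, trimmed)
  last <- h_end[[length(h_end)]]
  expect_true(last$found)
  expect_true(is.na(extract_splice_dinucleotides(trimmed, last)["donor"]))
})

test_that("self-alignment is optimal for the local aligner", {
  sp <- score_params()
  set.seed(21)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    self <- Biostrings::score(genloss:::local_align(x, x, sp))
    cross <- Biostrings::score(genloss:::local_align(x, y, sp))
    expect_gte(self, cross)
  }
})

test_that("assembly gaps are detected as locus-quality flags", {
  l <- target_locus("s", "g", paste0(strrep("A", 60), strrep("N", 60),
                                     strrep("C", 60)))
  q <- locus_quality(l)
  expect_true(q$has_gap)
  expect_equal(q$gaps$start, 60)
  expect_equal(q$gaps$end, 120)
  expect_false(locus_quality(target_locus("s", "g", "ACGTNNNACGT"))$has_gap)
})
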