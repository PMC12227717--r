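test_that("splice-site classification follows the canonical/tolerated/mutated rule", {
  expect_equal(as.character(classify_splice_site("GT", "donor")), "CANONICAL")
  expect_equal(as.character(classify_splice_site("GC", "donor")),
               "NONCANONICAL_TOLERATED")
  expect_equal(as.character(classify_splice_site("AT", "donor")), "MUTATED")
  expect_equal(as.character(classify_splice_site("AG", "acceptor")),
               "CANONICAL")
  expect_equal(as.character(classify_splice_site("AC", "acceptor")),
               "NONCANONICAL_TOLERATED")
  expect_equal(as.character(classify_splice_site("AG", "donor")), "MUTATED")
  n <- classify_splice_site("GN", "donor")
  expect_equal(as.character(n), "MUTATED")
  expect_true(attr(n, "low_confidence"))
  expect_error(classify_splice_site("G", "donor"), "2 nt")
})

test_that("lesion calling separates frameshifts, in-frame indels and premature STOPs", {
  m <- fixture_model()
  tree <- "(A:1,B:1,C:1);"
  sim <- evolve_along_tree(m, tree, 0, 0, list(
    indel_event("A", 6, offset = 30L, "del", length = 1L),
    indel_event("B", 6, offset = 30L, "del", length = 3L),
    stop_event(m, "C", 6)), seed = 31)

  vA <- evaluate_locus(m, sim$loci$A, orient = FALSE)
  fs <- vA$lesions[vA$lesions$kind == "FRAMESHIFT_INDEL", ]
  expect_equal(nrow(fs), 1)
  expect_equal(fs$exon_number, 6L)
  expect_true(fs$disrupting)
  expect_identical(vA$status, "PSEUDOGENE")
  # downstream out-of-frame STOPs are attributed to the frameshift
  cons <- vA$lesions[vA$lesions$kind == "PREMATURE_STOP", ]
  expect_true(all(cons$note == "frameshift_consequence"))

  vB <- evaluate_locus(m, sim$loci$B, orient = FALSE)
  inf <- vB$lesions[vB$lesions$kind == "INFRAME_INDEL", ]
  expect_equal(nrow(inf), 1)
  expect_false(inf$disrupting)
  expect_identical(vB$status, "INTACT")

  vC <- evaluate_locus(m, sim$loci$C, orient = FALSE)
  ps <- vC$lesions[vC$lesions$kind == "PREMATURE_STOP", ]
  expect_equal(nrow(ps), 1)
  expect_equal(ps$exon_number, 6L)
  expect_identical(ps$note, "")
  expect_identical(vC$status, "PSEUDOGENE")

  v0 <- evaluate_locus(m, evolve_along_tree(m, tree, 0, 0,
                                            seed = 31)$loci$A,
                       orient = FALSE)
  expect_equal(nrow(v0$lesions), 0)
  expect_identical(v0$status, "INTACT")
})

test_that("a clean 99-nt retained intron is called as a 33-residue fusion", {
  m <- fixture_model()
  sim <- fixture_sim0()
  locus <- orient_locus(sim$loci$E, m, min_identity = 0.6)
  hits <- locate_exons(m, locus)
  exn <- vapply(hits, `[[`, 1L, "exon_number")
  i <- which(exn == 11)
  fc <- detect_exon_fusion(locus, hits[[i]], hits[[i + 1]], m)
  expect_s3_class(fc, "fusion_call")
  expect_equal(fc$intron_length, 99L)
  expect_equal(fc$incorporated_residues, 33L)
  expect_true(fc$in_frame)

  v <- evaluate_locus(m, sim$loci$E)
  expect_identical(v$status, "INTACT_FUSION")
  expect_equal(nchar(v$cds), nchar(model_cds(m)) + 99L)
  don <- v$lesions[v$lesions$kind == "SPLICE_DONOR_MUT", ]
  expect_false(don$disrupting)
  expect_identical(don$note, "rescued_by_fusion")
})

test_that("a mutated donor with an unclean or frame-breaking intron is no fusion", {
  m <- fixture_model()
  sim <- evolve_along_tree(m, "(A:1,B:1);", 0, 0,
                           list(splice_event("A", 11, "donor", "AT")),
                           seed = 33)
  locus <- orient_locus(sim$loci$A, m)
  hits <- locate_exons(m, locus)
  exn <- vapply(hits, `[[`, 1L, "exon_number")
  i <- which(exn == 11)
  expect_null(detect_exon_fusion(locus, hits[[i]], hits[[i + 1]], m))
  # intact GT donor never fuses either
  expect_null(detect_exon_fusion(locus, hits[[i - 1]], hits[[i]], m))
})

test_that("rescue-site scan respects proximity, frame and canonical motif", {
  boundary <- 40L
  hit <- structure(list(exon_number = 5L, found = TRUE,
                        target_interval = c(10L, boundary)),
                   class = "exon_hit")
  mk <- function(intron) target_locus("s", "g", paste0(
    strrep("C", boundary), intron, strrep("C", 30)))
  # GT six nt downstream, frame-preserving: rescue at +6
  l1 <- mk("ATCCCCGTCCCCCCCCCCCCCCCCCCCCAG")
  expect_equal(scan_rescue_splice_site(l1, hit, "donor"), 6L)
  # GT only at +7: frame broken, no rescue
  l2 <- mk("ATCCCCCGTCCCCCCCCCCCCCCCCCCAG")
  expect_null(scan_rescue_splice_site(l2, hit, "donor"))
  # no canonical dinucleotide in the window at all
  l3 <- mk(strrep("C", 30))
  expect_null(scan_rescue_splice_site(l3, hit, "donor"))
})

test_that("assembled CDS reproduces the reference at zero divergence and tracks fusions and frameshifts", {
  m <- fixture_model()
  sim <- fixture_sim0()
  vC <- evaluate_locus(m, sim$loci$C)
  expect_identical(vC$cds, model_cds(m))
  expect_identical(vC$status, "INTACT")

  locus <- orient_locus(sim$loci$B, m)
  hits <- locate_exons(m, locus)
  les <- call_locus_lesions(hits, m)
  asm <- assemble_cds(hits, les, list(), m, locus)
  expect_false(asm$orf_continuous)
  expect_false(is.na(asm$first_premature_stop))
  aa <- translate_cds(asm$cds)
  first_stop <- as.integer(gregexpr("*", aa, fixed = TRUE)[[1]][1])
  expect_equal(asm$first_premature_stop, (first_stop - 1L) * 3L + 1L)
  expect_error(assemble_cds(list(empty_hit(2L)), NULL, list(), m, locus),
               "no assembly possible")
})

test_that("verdicts follow the matrix semantics and their invariants", {
  m <- fixture_model()
  # cetacean-style lesion stack: donor muts after exons 5 and 9, acceptor
  # ahead of 11, plus a frameshift
  sim <- evolve_along_tree(m, "(A:1,B:1);", 0, 0, list(
    splice_event("A", 5, "donor", "AT"),
    splice_event("A", 9, "donor", "AA"),
    splice_event("A", 11, "acceptor", "GG"),
    indel_event("A", 7, offset = 25L, "del", length = 2L)), seed = 35)
  v <- evaluate_locus(m, sim$loci$A)
  expect_identical(v$status, "PSEUDOGENE")
  expect_identical(v$confidence, "")
  expect_setequal(
    v$lesions$kind[v$lesions$disrupting & v$lesions$note == ""],
    c("SPLICE_DONOR_MUT", "SPLICE_ACCEPTOR_MUT", "FRAMESHIFT_INDEL"))

  # splice-only pseudogene carries the hedging flag
  sim2 <- evolve_along_tree(m, "(A:1,B:1);", 0, 0,
                            list(splice_event("A", 5, "donor", "AT")),
                            seed = 36)
  v2 <- evaluate_locus(m, sim2$loci$A)
  expect_identical(v2$status, "PSEUDOGENE")
  expect_identical(v2$confidence, "splice_only")

  # fusion neutrality: a fusion call alone never yields PSEUDOGENE
  vf <- classify_gene(list(structure(list(exon_number = 2L, found = TRUE),
                                     class = "exon_hit")),
                      genloss:::empty_lesions(),
                      fusions = list(structure(list(upstream_exon = 11L),
                                               class = "fusion_call")),
                      species_id = "x", gene_id = "g")
  expect_identical(vf$status, "INTACT_FUSION")
})

test_that("adding a disrupting lesion never moves a verdict toward INTACT", {
  rank <- c(INTACT = 1, INTACT_FUSION = 2, PSEUDOGENE = 3)
  hits <- list(structure(list(exon_number = 2L, found = TRUE),
                         class = "exon_hit"))
  base_lesions <- list(
    genloss:::empty_lesions(),
    genloss:::lesion_row("INFRAME_INDEL", 5L, 10L, "", "AAA", FALSE),
    genloss:::lesion_row("FRAMESHIFT_INDEL", 5L, 10L, "", "A", TRUE))
  extra <- genloss:::lesion_row("PREMATURE_STOP", 7L, 3L, "TGA", "", TRUE)
  for (les in base_lesions) {
    for (fus in list(list(), list(structure(list(upstream_exon = 11L),
                                            class = "fusion_call")))) {
      before <- classify_gene(hits, les, fus)$status
      after <- classify_gene(hits, rbind(les, extra), fus)$status
      expect_gte(rank[[after]], rank[[before]])
      expect_identical(after, "PSEUDOGENE")
    }
  }
})

test_that("assembly gaps produce INCOMPLETE rather than a missing-exon pseudogene call", {
  m <- fixture_model()
  sim <- evolve_along_tree(m, "(A:1,B:1);", 0, 0, seed = 37)
  l <- sim$loci$A
  iv <- sim$truth$per_species$A$exon_intervals
  i7 <- iv[iv$exon_number == 7, ]
  # blank exon 7 (and some flanking intron) with an N run
  substr(l$sequence, i7$start - 10L, i7$end + 10L) <-
    strrep("N", i7$end - i7$start + 21L)
  v <- evaluate_locus(m, l)
  expect_identical(v$status, "INCOMPLETE")
  # the same absence without any N run is a disrupting missing-exon lesion
  sim2 <- evolve_along_tree(m, "(A:1,B:1);", 0, 0,
                            list(deletion_event("A", 7)), seed = 37)
  v2 <- evaluate_locus(m, sim2$loci$A)
  expect_identical(v2$status, "PSEUDOGENE")
  expect_true("EXON_MISSING" %in% v2$lesions$kind)
})
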