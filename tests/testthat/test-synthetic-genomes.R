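test_that("model generation is deterministic and honours donor options", {
  m1 <- build_reference_model(12, seed = 1)
  m2 <- build_reference_model(12, seed = 1)
  expect_identical(m1, m2)
  expect_true(all(vapply(m1$exons[-12], `[[`, "", "expected_donor") == "GT"))
  mgc <- build_reference_model(12, gc_donor_fraction = 1, seed = 1)
  expect_true(all(vapply(mgc$exons[-12], `[[`, "", "expected_donor") == "GC"))
  expect_true(all(substr(mgc$introns, 1, 2) == "GC"))
})

test_that("zero rates reproduce the reference locus at every tip", {
  m <- fixture_model()
  sim <- evolve_along_tree(m, "((A:1,B:2):1,C:3);", 0, 0, seed = 4)
  ref <- assemble_reference_locus(m)
  for (l in sim$loci) expect_identical(l$sequence, ref)
  ti <- sim$truth$per_species$A$exon_intervals
  expect_identical(ti$exon_number, vapply(m$exons, `[[`, 1L, "exon_number"))
})

test_that("planted events are inherited by exactly the descendants of their branch", {
  sim <- fixture_sim0()
  by_sp <- lapply(sim$truth$per_species, function(ps)
    vapply(ps$events, function(e) paste(e$kind, e$exon_number), ""))
  expect_setequal(by_sp$A, "SPLICE_DONOR_MUT 5")
  expect_setequal(by_sp$B, c("SPLICE_DONOR_MUT 5", "FRAMESHIFT_INDEL 9"))
  expect_setequal(by_sp$C, character(0))
  expect_setequal(by_sp$D, "PREMATURE_STOP 8")
  expect_setequal(by_sp$E, "EXON_FUSION 11")
  expect_setequal(by_sp$F, "EXON_FUSION 11")
})

test_that("per-branch substitution counts follow the Poisson expectation", {
  m <- fixture_model()
  L <- nchar(assemble_reference_locus(m))
  rate <- 0.005
  counts <- vapply(1:200, function(i) {
    sim <- evolve_along_tree(m, "(A:1,B:0);", rate, 0, seed = 1000L + i)
    sim$truth$per_species$A$n_substitutions
  }, 1L)
  lambda <- rate * L
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se + 0.02 * lambda)
  expect_equal(vapply(1:3, function(i) {
    evolve_along_tree(m, "(A:1,B:0);", rate, 0,
                      seed = 1001L)$truth$per_species$B$n_substitutions
  }, 1L), rep(0L, 3))  # zero-length branch gets no substitutions
})

test_that("fixtures round-trip and are byte-stable; seeds move background but not planted coordinates", {
  sim <- fixture_sim0()
  d1 <- withr::local_tempdir()
  write_fixture(sim$loci, sim$truth, d1, config = list(seed = 11))
  back <- read_fixture(d1)
  expect_identical(lapply(back$loci, `[[`, "sequence"),
                   lapply(sim$loci, `[[`, "sequence"))
  expect_equal(length(back$truth$events), length(sim$truth$events))
  expect_identical(back$truth$per_species$B$exon_intervals$start,
                   sim$truth$per_species$B$exon_intervals$start)

  d2 <- withr::local_tempdir()
  write_fixture(sim$loci, sim$truth, d2, config = list(seed = 11))
  f1 <- file.path(d1, "truth.json"); f2 <- file.path(d2, "truth.json")
  expect_identical(readLines(f1), readLines(f2))

  m <- fixture_model()
  simA <- evolve_along_tree(m, sim$tree, 0.02, 0, sim$planted, seed = 21)
  simB <- evolve_along_tree(m, sim$tree, 0.02, 0, sim$planted, seed = 22)
  expect_false(identical(simA$loci$C$sequence, simB$loci$C$sequence))
  evA <- simA$truth$per_species$D$events[[1]]
  evB <- simB$truth$per_species$D$events[[1]]
  expect_identical(evA$detail$offset, evB$detail$offset)
  expect_identical(evA$exon_number, evB$exon_number)
})

test_that("an event on a deleted exon is refused with a named conflict", {
  m <- fixture_model()
  planted <- list(deletion_event("N1", 7),
                  stop_event(m, "A", 7))
  expect_error(
    evolve_along_tree(m, "((A:1,B:1)N1:1,C:1);", 0, 0, planted, seed = 1),
    "deleted exon")
})

test_that("event constructors enforce their invariants", {
  m <- fixture_model()
  expect_error(indel_event("A", 5, 10, "del", length = 3L) -> ev, NA)
  expect_identical(ev$kind, "INFRAME_INDEL")
  expect_identical(indel_event("A", 5, 10, "del", length = 2L)$kind,
                   "FRAMESHIFT_INDEL")
  expect_error(planted_event("A", "FRAMESHIFT_INDEL", 5,
                             list(op = "del", length = 3L)), "multiple of 3")
  expect_error(splice_event("A", 5, "donor", "GT"), "non-functional")
  expect_error(fusion_event(m, "A", 5, intron_length = 100L))
  fe <- fusion_event(m, "A", 5, intron_length = 99L)
  expect_equal(nchar(fe$detail$intron_sequence), 99L)
  # read-through of the constructed intron is STOP-free in the running frame
  p <- m$exons[[5]]$phase
  ex4 <- m$exons[[4]]$sequence
  tailp <- if (p > 0) substr(ex4, nchar(ex4) - p + 1, nchar(ex4)) else ""
  spill <- (3 - p) %% 3
  ctx <- paste0(tailp, fe$detail$intron_sequence,
                substr(m$exons[[5]]$sequence, 1, spill))
  expect_false(grepl("*", translate_cds(ctx), fixed = TRUE))
})
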