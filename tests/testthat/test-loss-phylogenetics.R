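mk_lesion <- function(kind, exon, offset, observed)
  genloss:::lesion_row(kind, exon, offset, observed, "", TRUE)

test_that("lesion signatures implement identity and offset-bucket semantics", {
  a <- mk_lesion("SPLICE_DONOR_MUT", 5L, 186L, "AT")
  b <- mk_lesion("SPLICE_DONOR_MUT", 5L, 190L, "AT")  # same boundary lesion
  c <- mk_lesion("SPLICE_DONOR_MUT", 5L, 186L, "AC")
  expect_identical(lesion_signature(a, "g"), lesion_signature(b, "g"))
  expect_false(lesion_signature(a, "g") == lesion_signature(c, "g"))
  # two 1-nt deletions 2 nt apart fall in one 3-nt bucket
  d1 <- mk_lesion("FRAMESHIFT_INDEL", 7L, 30L, "")
  d2 <- mk_lesion("FRAMESHIFT_INDEL", 7L, 32L, "")
  d3 <- mk_lesion("FRAMESHIFT_INDEL", 7L, 36L, "")
  expect_identical(lesion_signature(d1, "g", 3L), lesion_signature(d2, "g", 3L))
  expect_false(lesion_signature(d1, "g", 3L) == lesion_signature(d3, "g", 3L))
})

test_that("shared signatures map to the carriers' MRCA with Dollo event counts", {
  tr <- "((A,B)AB,C)R;"
  ev <- map_events_on_tree(list(A = "s1", B = "s1", C = character(0)), tr)
  expect_equal(ev$n_events, 1L)
  expect_identical(ev$placement_node, "AB")
  expect_true(ev$monophyletic)
  ev2 <- map_events_on_tree(list(A = "s1", B = character(0), C = "s1"), tr)
  expect_equal(ev2$n_events, 2L)
  expect_false(ev2$monophyletic)
  expect_error(map_events_on_tree(list(Z = "s1"), tr), "absent from tree")
})

test_that("a whole-clade signature is placed as one basal event", {
  # cetacean-like: every tip of one clade shares the lesion, the sister
  # clade is clean -> a single origin on the carrier clade stem
  tr <- "(((D1,D2)Odo,(W1,W2)Mys)Cet,(H,Cow)Terr)R;"
  sig <- list(D1 = "don5", D2 = "don5", W1 = "don5", W2 = "don5",
              H = character(0), Cow = character(0))
  ev <- map_events_on_tree(sig, tr)
  expect_equal(ev$n_events, 1L)
  expect_identical(ev$placement_node, "Cet")
})

test_that("minimum loss counts respect Dollo and INCOMPLETE wildcards", {
  expect_equal(min_loss_events(c(A = "P", B = "P", C = "I"),
                               "((A,B),C);")$n_events, 1L)
  expect_equal(min_loss_events(c(A = "I", B = "I", C = "I"),
                               "((A,B),C);")$n_events, 0L)
  # independent losses: the two elephant-seal-like tips form a clade but
  # the Weddell-like tip is separated by intact lineages
  r <- min_loss_events(c(M1 = "P", M2 = "P", I1 = "I", W = "P", I2 = "I"),
                       "(((M1,M2)M,I1)X,(W,I2)Y)R;")
  expect_equal(r$n_events, 2L)
  expect_setequal(r$stem_branches, c("M", "W"))
  # an INCOMPLETE tip inside the carrier clade does not split the event
  expect_equal(min_loss_events(c(A = "P", B = "U", C = "P", D = "I"),
                               "(((A,B),C),D);")$n_events, 1L)
  expect_error(min_loss_events(c(A = "P"), ape::read.tree(text = "();")))
})

test_that("Dollo counts match exhaustive search on random scenarios", {
  set.seed(77)
  for (r in 1:100) {
    n <- sample(3:8, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
    tr$node.label <- paste0("N", seq_len(tr$Nnode))
    st <- sample(c("P", "I", "U"), n, replace = TRUE, prob = c(.4, .4, .2))
    names(st) <- tr$tip.label
    mine <- min_loss_events(st, tr)$n_events
    oracle <- oracle_dollo_min(tr, names(st)[st == "P"],
                               names(st)[st == "U"])
    expect_equal(mine, oracle,
                 info = paste(ape::write.tree(tr), paste(st, collapse = "")))
  }
})

test_that("adding a carrier never decreases the event count or deepens past the old MRCA", {
  set.seed(78)
  for (r in 1:30) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
    tr$node.label <- paste0("N", seq_len(tr$Nnode))
    carriers <- sample(tr$tip.label, sample(1:(n - 1), 1))
    extra <- sample(setdiff(tr$tip.label, carriers), 1)
    before <- genloss:::dollo_gain_count(tr, carriers)
    after <- genloss:::dollo_gain_count(tr, c(carriers, extra))
    expect_gte(after$n_events, 1L)
    # the new carrier can merge events but never invent reversals
    expect_lte(after$n_events, before$n_events + 1L)
    mrca_before <- if (length(carriers) == 1)
      match(carriers, tr$tip.label) else ape::getMRCA(tr, carriers)
    mrca_after <- ape::getMRCA(tr, c(carriers, extra))
    below_after <- genloss:::tip_descendants(tr, mrca_after)
    expect_true(all(genloss:::tip_descendants(tr, mrca_before) %in%
                      below_after))
  }
})

test_that("planted losses are recovered on their planting branch at zero divergence", {
  m <- fixture_model()
  sim <- fixture_sim0()
  verdicts <- lapply(sim$loci, function(l) evaluate_locus(m, l))
  sigs <- lapply(verdicts, verdict_signatures)
  ev <- map_events_on_tree(sigs, sim$tree)
  don5 <- ev[grepl("exon5\\|SPLICE_DONOR_MUT", ev$signature), ]
  expect_identical(don5$placement_node, "AB")
  expect_equal(don5$n_events, 1L)
  stop8 <- ev[grepl("PREMATURE_STOP", ev$signature), ]
  expect_identical(stop8$placement_node, "D")
  statuses <- vapply(verdicts, `[[`, "", "status")
  loss <- min_loss_events(statuses, sim$tree)
  expect_equal(loss$n_events, 2L)  # AB clade + D; E's fusion stays intact
  expect_setequal(loss$stem_branches, c("AB", "D"))
  nk <- annotate_loss_tree(sim$tree, loss$stem_branches)
  expect_match(nk, "AB#loss")
  expect_match(nk, "D#loss")
})
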