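test_that("NG86 site counts match hand-derived values and sum to 3", {
  expect_equal(ng86_site_counts("TTT"), c(n = 8 / 3, s = 1 / 3))
  expect_equal(ng86_site_counts("TGG"), c(n = 3, s = 0))
  set.seed(41)
  for (i in 1:20) {
    cod <- random_codon()
    sc <- ng86_site_counts(cod)
    expect_equal(unname(sum(sc)), 3)
    expect_equal(sc, oracle_site_counts(cod))
  }
  expect_error(ng86_site_counts("TAA"), "STOP")
  expect_error(ng86_site_counts("TT"), "3-mer")
})

test_that("pairwise dN/dS handles identity, single and multi-step differences", {
  r0 <- ng86_pairwise("TTTAAA", "TTTAAA")
  expect_equal(r0$Nd, 0); expect_equal(r0$Sd, 0)
  expect_true(is.na(r0$omega))

  r1 <- ng86_pairwise("TTT", "TTC")
  expect_equal(r1$Sd, 1); expect_equal(r1$Nd, 0)
  expect_true(r1$flagged)  # pS = 3 on a single codon: saturation flag
  # diluted over more codons the same difference gives omega = 0
  r1b <- ng86_pairwise("TTTAAACCCGGG", "TTCAAACCCGGG")
  expect_equal(r1b$omega, 0)

  # TTT -> GTA: path via GTT is V->V (1 nonsyn + 1 syn), via TTA is
  # L then V (2 nonsyn); equal-weight average 1.5 / 0.5
  r2 <- ng86_pairwise("TTT", "GTA")
  expect_equal(r2$Nd, 1.5); expect_equal(r2$Sd, 0.5)

  # gap- and N-containing codons are skipped pairwise
  r3 <- ng86_pairwise("TTT---AAA", "TTCTTTAAN")
  expect_equal(r3$n_codons, 1L)
  expect_equal(r3$n_skipped, 2L)
  expect_error(ng86_pairwise("TTT", "TTTA"), "equal length")
})

test_that("pairwise dN/dS is symmetric in its arguments", {
  set.seed(42)
  for (i in 1:10) {
    a <- paste(replicate(30, random_codon()), collapse = "")
    b <- paste(replicate(30, random_codon()), collapse = "")
    ra <- ng86_pairwise(a, b); rb <- ng86_pairwise(b, a)
    expect_equal(ra$Nd, rb$Nd); expect_equal(ra$Sd, rb$Sd)
    expect_equal(ra$N, rb$N); expect_equal(ra$S, rb$S)
  }
})

test_that("Jukes-Cantor correction reduces to the raw proportions at low divergence", {
  base <- paste(rep("CTT", 300), collapse = "")
  var <- base
  substr(var, 3, 3) <- "G"    # CTT->CTG synonymous
  substr(var, 31, 31) <- "G"  # CTT->GTT nonsynonymous
  r <- ng86_pairwise(base, var)
  expect_lt(abs(r$dN - r$pN), r$pN * 0.01)
  expect_lt(abs(r$dS - r$pS), r$pS * 0.01)
})

test_that("on a two-tip tree the pooled partition counts equal the pairwise counts", {
  # single-step codon differences only, so ancestor placement cannot
  # redistribute syn/nonsyn classifications
  a <- paste(c("TTT", "GGA", "ATG", "CCC", "AAA", "CGT"), collapse = "")
  b <- paste(c("TTC", "GGA", "ATG", "ACC", "AAA", "CGC"), collapse = "")
  pw <- ng86_pairwise(a, b)
  cd <- clade_partition_dnds(c(A = a, B = b), "(A:1,B:1);", "A")
  expect_equal(cd$foreground$Nd + cd$background$Nd, pw$Nd)
  expect_equal(cd$foreground$Sd + cd$background$Sd, pw$Sd)
  expect_equal(cd$N, pw$N)
  expect_equal(cd$S, pw$S)
})

test_that("foreground and background omega are both near 1 under neutral simulation", {
  tree <- "((A:1,B:1)F1:1,(C:1,D:1)F2:1,(E:1,G:1)F3:1)R;"
  om <- vapply(1:6, function(i) {
    aln <- simulate_codon_alignment(tree, 150, 0.05, seed = 100 + i)
    cd <- clade_partition_dnds(aln, tree, c("A", "B"))
    c(cd$omega_foreground, cd$omega_background)
  }, c(0, 0))
  expect_lt(abs(mean(om[1, ]) - 1), 0.25)
  expect_lt(abs(mean(om[2, ]) - 1), 0.25)
})

test_that("suppressing background nonsynonymous change elevates relative foreground omega", {
  tree <- "((A:1,B:1)F1:1,(C:1,D:1)F2:1,(E:1,G:1)F3:1)R;"
  hits <- vapply(1:8, function(i) {
    aln <- simulate_codon_alignment(tree, 150, 0.08, seed = 200 + i,
                                    foreground = c("A", "B"),
                                    bg_nonsyn_accept = 0.1)
    cd <- clade_partition_dnds(aln, tree, c("A", "B"))
    cd$omega_foreground > cd$omega_background
  }, TRUE)
  expect_true(all(hits))
  expect_error(clade_partition_dnds(
    simulate_codon_alignment(tree, 30, 0.02, seed = 1), tree,
    c("A", "C")), "not a clade")
})

test_that("per-site counting flags a strongly synonymous site as negatively selected", {
  # seven tips differing only by synonymous third positions at site 1
  leu <- c("CTT", "CTC", "CTA", "CTG", "CTT", "CTC", "CTA")
  tips <- paste0("t", 1:7)
  const <- paste(rep("ATG", 19), collapse = "")
  seqs <- setNames(paste0(leu, const), tips)
  tree <- paste0("(", paste0(tips, ":1", collapse = ","), ");")
  ss <- site_selection_counts(seqs, tree, alpha = 0.1)
  expect_identical(ss$sites$label[1], "negative")
  expect_gte(ss$sites$syn[1], 3)
  expect_equal(ss$sites$nonsyn[1], 0)
  # invariant sites stay neutral with zero changes
  expect_true(all(ss$sites$label[-1] == "neutral"))
  expect_true(all(ss$sites$syn[-1] == 0))
  expect_equal(ss$n_positive + ss$n_negative + ss$n_neutral, 20L)
})

test_that("simulated alignments are deterministic given a seed", {
  tree <- "((A:1,B:1):1,C:1);"
  a1 <- simulate_codon_alignment(tree, 50, 0.05, seed = 9)
  a2 <- simulate_codon_alignment(tree, 50, 0.05, seed = 9)
  expect_identical(a1, a2)
})
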