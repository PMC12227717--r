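test_that("translation handles phase, N codons and STOP marks", {
  expect_equal(translate_cds("ATGGCT"), "MA")
  expect_equal(translate_cds("TAA"), "*")
  # 1-base phase offset reads TGG and drops the trailing partial codon
  expect_equal(translate_cds("ATGGCT", 1), "W")
  expect_equal(translate_cds("ATGNNT"), "MX")
  expect_equal(translate_cds("ATNA"), "X")  # N -> X, partial codon dropped
  expect_error(translate_cds(""), "malformed")
  expect_error(translate_cds("ATGQ"), "malformed")
})

test_that("translation length is floor(len/3) for any input", {
  set.seed(1)
  for (i in 1:25) {
    n <- sample(0:40, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    if (n == 0) next
    expect_equal(nchar(translate_cds(s)), n %/% 3)
  }
})

test_that("a generated reference model validates cleanly and its ORF has one terminal STOP", {
  m <- fixture_model()
  expect_equal(nrow(validate_gene_model(m)), 0)
  aa <- translate_cds(model_cds(m))
  stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
  expect_length(stops, 1)
  expect_equal(as.integer(stops), nchar(aa))
})

test_that("validation reports planted defects with location", {
  m <- fixture_model()
  m_bad <- m
  m_bad$exons[[5]]$phase <- (m_bad$exons[[5]]$phase + 1L) %% 3L
  v <- validate_gene_model(m_bad)
  expect_true(any(v$check == "phase" & grepl("exon 6", v$location)))

  # plant an in-frame TGA inside exon 7 (exon number 8)
  m_stop <- m
  ex <- m_stop$exons[[7]]
  off <- (3L - ex$phase) %% 3L + 30L
  substr(m_stop$exons[[7]]$sequence, off + 1L, off + 3L) <- "TGA"
  v2 <- validate_gene_model(m_stop)
  expect_true(any(v2$check == "orf" & grepl("exon 8", v2$location)))
})

test_that("gene model JSON and exon FASTA round-trip", {
  m <- fixture_model()
  p <- withr::local_tempfile(fileext = ".json")
  write_gene_model(m, p)
  m2 <- read_gene_model(p)
  expect_equal(m2$gene_id, m$gene_id)
  expect_equal(length(m2$exons), length(m$exons))
  expect_identical(model_cds(m2), model_cds(m))
  expect_identical(unlist(m2$introns), unlist(m$introns))
  expect_equal(nrow(validate_gene_model(m2)), 0)

  fa <- withr::local_tempfile(fileext = ".fa")
  write_exon_fasta(m, fa)
  ss <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(ss), length(m$exons))
  expect_match(names(ss)[1], "\\|exon2$")
  expect_identical(as.character(ss[[1]]), m$exons[[1]]$sequence)
})
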