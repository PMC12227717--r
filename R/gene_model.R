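#' Exon definition
#'
#' One exon of a reference gene model: its label, coding sequence, reading
#' frame phase, and the splice dinucleotides expected on its intronic flanks.
#'
#' @param exon_number Integer label. Multi-exon sodium-channel genes are
#'   conventionally numbered 2-13, with the start codon on the first core
#'   exon and the STOP on the last; any strictly increasing labelling works.
#' @param sequence Exonic nucleotide sequence (A/C/G/T).
#' @param phase Cumulative CDS length upstream of this exon, mod 3.
#' @param expected_donor Splice-donor dinucleotide expected 3' of the exon
#'   (usually "GT", rarely "GC"), or `NA` for the terminal exon.
#' @param expected_acceptor Splice-acceptor dinucleotide expected 5' of the
#'   exon (usually "AG"), or `NA` for the first exon.
#' @return A list of class `exon_def`.
#' @export
exon_def <- function(exon_number, sequence, phase = 0L,
                     expected_donor = NA_character_,
                     expected_acceptor = NA_character_) {
  stopifnot(is.numeric(exon_number), length(exon_number) == 1L)
  sequence <- toupper(sequence)
  structure(
    list(exon_number = as.integer(exon_number), sequence = sequence,
         phase = as.integer(phase) %% 3L,
         expected_donor = expected_donor,
         expected_acceptor = expected_acceptor),
    class = "exon_def")
}

#' Reference gene model
#'
#' Container for the exon architecture of a reference (template) gene, in
#' the role the intact alpaca orthologue plays for a comparative screen of a
#' gene family: all downstream exon mapping, lesion calling and verdicts are
#' relative to this model.
#'
#' @param gene_id Gene label, e.g. `"SCNN1D-like"`.
#' @param exons List of [exon_def()] objects in genomic order.
#' @param introns Optional list of intron sequences (length `length(exons) -
#'   1`); carried so the simulator can assemble a full reference locus.
#' @param codon_table Genetic code identifier; only `"standard"` is
#'   supported (vertebrate nuclear genes).
#' @param start_exon Index (into `exons`) of the exon carrying the ATG.
#' @param stop_exon Index of the exon carrying the STOP codon.
#' @param flank5,flank3 Optional flanking sequences outside the gene span.
#' @return A list of class `gene_model`.
#' @seealso [validate_gene_model()], [write_gene_model()]
#' @export
gene_model <- function(gene_id, exons, introns = NULL,
                       codon_table = "standard",
                       start_exon = 1L, stop_exon = length(exons),
                       flank5 = "", flank3 = "") {
  stopifnot(length(exons) >= 1L)
  if (codon_table != "standard")
    stop("only the standard nuclear codon table is supported")
  structure(
    list(gene_id = gene_id, exons = exons, introns = introns,
         codon_table = codon_table,
         start_exon = as.integer(start_exon),
         stop_exon = as.integer(stop_exon),
         flank5 = flank5, flank3 = flank3),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d exons (%s), CDS %d nt\n",
              x$gene_id, length(x$exons),
              paste(range(vapply(x$exons, `[[`, 1L, "exon_number")),
                    collapse = "-"),
              nchar(model_cds(x))))
  invisible(x)
}

#' Concatenated reference CDS of a gene model
#'
#' @param model A [gene_model()].
#' @return The exon sequences from `start_exon` through `stop_exon`
#'   concatenated, i.e. the reference coding sequence.
#' @export
model_cds <- function(model) {
  paste(vapply(model$exons[model$start_exon:model$stop_exon],
               `[[`, "", "sequence"), collapse = "")
}

#' Translate a coding sequence
#'
#' Translates nucleotides to amino acids under the standard nuclear code.
#' `phase` leading bases are skipped (they complete an upstream codon), a
#' trailing partial codon is dropped, codons containing N translate to `X`
#' (never counted as STOP), and STOP codons are rendered as `*`.
#'
#' @param cds Nucleotide string over A/C/G/T/N.
#' @param phase Integer 0-2; number of leading bases belonging to the
#'   previous codon.
#' @return Amino-acid string with `*` marking STOP codons.
#' @examples
#' translate_cds("ATGGCT")       # "MA"
#' translate_cds("ATGGCT", 1)    # "W" (reads TGG, drops the trailing CT)
#' @export
translate_cds <- function(cds, phase = 0L) {
  if (!is.character(cds) || length(cds) != 1L || nchar(cds) == 0L)
    stop("malformed CDS: expected a non-empty nucleotide string")
  phase <- as.integer(phase)
  stopifnot(phase >= 0L, phase <= 2L)
  cds <- toupper(cds)
  if (grepl("[^ACGTN]", cds))
    stop("malformed CDS: characters outside {A,C,G,T,N}")
  s <- substr(cds, phase + 1L, nchar(cds))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(s, starts, starts + 2L)
  aa <- character(n_codon)
  has_n <- grepl("N", codons, fixed = TRUE)
  aa[has_n] <- "X"
  aa[!has_n] <- codon_aa(codons[!has_n])
  paste(aa, collapse = "")
}

#' Validate a gene model
#'
#' Checks the structural invariants of a reference model and returns every
#' violation found (an empty data frame means the model is valid). Checked:
#' exon sequences over A/C/G/T, strictly increasing exon numbers, phase
#' consistency with cumulative upstream CDS length, declared donor/acceptor
#' context for internal exons, an ATG at the configured start exon, and a
#' concatenated ORF containing exactly one STOP, at its final codon.
#'
#' @param model A [gene_model()].
#' @return Data frame with columns `check`, `location`, `message`;
#'   zero rows when valid.
#' @export
validate_gene_model <- function(model) {
  v <- list()
  add <- function(check, location, message)
    v[[length(v) + 1L]] <<- data.frame(check = check, location = location,
                                       message = message)
  nums <- vapply(model$exons, `[[`, 1L, "exon_number")
  if (any(diff(nums) <= 0))
    add("exon_order", "model", "exon numbers not strictly increasing")
  cum <- 0L
  for (i in seq_along(model$exons)) {
    ex <- model$exons[[i]]
    loc <- paste0("exon ", ex$exon_number)
    if (grepl("[^ACGT]", ex$sequence))
      add("alphabet", loc, "sequence has characters outside {A,C,G,T}")
    if (i >= model$start_exon && i <= model$stop_exon) {
      if (ex$phase != cum %% 3L)
        add("phase", loc, sprintf("declared phase %d, expected %d",
                                  ex$phase, cum %% 3L))
      cum <- cum + nchar(ex$sequence)
    }
    if (i < length(model$exons) && is.na(ex$expected_donor))
      add("splice_context", loc, "internal exon lacks a declared donor")
    if (i > 1L && is.na(ex$expected_acceptor))
      add("splice_context", loc, "internal exon lacks a declared acceptor")
  }
  cds <- model_cds(model)
  if (substr(cds, 1L, 3L) != "ATG")
    add("start_codon", paste0("exon ",
                              model$exons[[model$start_exon]]$exon_number),
        "start exon does not begin with ATG")
  aa <- translate_cds(cds)
  stops <- gregexpr("*", aa, fixed = TRUE)[[1L]]
  if (identical(as.integer(stops), -1L)) {
    add("orf", "model", "no STOP codon in the concatenated ORF")
  } else {
    n_aa <- nchar(aa)
    internal <- stops[stops < n_aa]
    for (p in internal) {
      cds_pos <- (p - 1L) * 3L
      ex_idx <- exon_of_cds_position(model, cds_pos)
      add("orf", paste0("exon ", ex_idx),
          sprintf("internal STOP at codon %d", p))
    }
    if (stops[length(stops)] != n_aa)
      add("orf", "model", "ORF does not end at a STOP codon")
  }
  if (length(v) == 0L)
    return(data.frame(check = character(), location = character(),
                      message = character()))
  do.call(rbind, v)
}

# Map a 0-based CDS offset to the exon number containing it.
exon_of_cds_position <- function(model, cds_pos) {
  cum <- 0L
  for (i in model$start_exon:model$stop_exon) {
    len <- nchar(model$exons[[i]]$sequence)
    if (cds_pos < cum + len) return(model$exons[[i]]$exon_number)
    cum <- cum + len
  }
  model$exons[[model$stop_exon]]$exon_number
}

#' Target genomic locus
#'
#' A pre-extracted genomic region expected to contain one copy of the
#' modelled gene, for one species.
#'
#' @param species_id,locus_id Labels.
#' @param sequence Nucleotide string; may contain N for assembly gaps.
#' @param orientation `"forward"` or `"reverse"`, as resolved (or as known
#'   from simulation).
#' @return A list of class `target_locus`.
#' @export
target_locus <- function(species_id, locus_id, sequence,
                         orientation = "forward") {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("locus sequence must be non-empty")
  structure(list(species_id = species_id, locus_id = locus_id,
                 sequence = sequence, orientation = orientation),
            class = "target_locus")
}

#' Read/write a gene model as JSON
#'
#' The on-disk form records `gene_id`, ordered exon records (number,
#' sequence, phase, expected splice dinucleotides), intron sequences when
#' present, and start/stop exon indices.
#'
#' @param model A [gene_model()].
#' @param path File path.
#' @return `write_gene_model` returns `path` invisibly; `read_gene_model`
#'   returns a [gene_model()].
#' @export
write_gene_model <- function(model, path) {
  obj <- list(
    gene_id = model$gene_id,
    codon_table = model$codon_table,
    start_exon = model$start_exon,
    stop_exon = model$stop_exon,
    flank5 = model$flank5, flank3 = model$flank3,
    exons = lapply(model$exons, function(e)
      list(exon_number = e$exon_number, sequence = e$sequence,
           phase = e$phase, expected_donor = e$expected_donor,
           expected_acceptor = e$expected_acceptor)),
    introns = model$introns)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  obj <- jsonlite::read_json(path)
  exons <- lapply(obj$exons, function(e)
    exon_def(e$exon_number, e$sequence, e$phase,
             e$expected_donor %||% NA_character_,
             e$expected_acceptor %||% NA_character_))
  gene_model(obj$gene_id, exons,
             introns = if (length(obj$introns)) unlist(obj$introns) else NULL,
             codon_table = obj$codon_table %||% "standard",
             start_exon = obj$start_exon %||% 1L,
             stop_exon = obj$stop_exon %||% length(exons),
             flank5 = obj$flank5 %||% "", flank3 = obj$flank3 %||% "")
}

#' Export exon sequences as multi-FASTA
#'
#' Headers follow the `gene|exon<N>` convention.
#'
#' @param model A [gene_model()].
#' @param path Output FASTA path.
#' @export
write_exon_fasta <- function(model, path) {
  seqs <- Biostrings::DNAStringSet(vapply(model$exons, `[[`, "", "sequence"))
  names(seqs) <- vapply(model$exons, function(e)
    sprintf("%s|exon%d", model$gene_id, e$exon_number), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
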