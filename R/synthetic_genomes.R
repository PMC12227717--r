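# Simulation of gene loci along a phylogeny with truth-logged lesions.
#
# A locus lineage is represented as an ordered list of segments
# (flank5, exon, intron, ..., flank3), each a list(type, exon_number, seq).
# Planted events edit segments; background substitutions and indels are
# applied per branch from a branch-local random stream.

EVENT_KINDS <- c("SPLICE_DONOR_MUT", "SPLICE_ACCEPTOR_MUT",
                 "FRAMESHIFT_INDEL", "INFRAME_INDEL", "PREMATURE_STOP",
                 "EXON_DELETION", "EXON_FUSION")

#' Build a random reference gene model
#'
#' Generates a multi-exon gene with a continuous ORF (ATG on the first
#' exon, a single STOP ending the last), GT or GC splice donors, AG
#' acceptors, and intron sequences, suitable as the template for simulated
#' comparative screens. Intron sizes default to the compact range typical
#' of a condensed delta-subunit-like gene.
#'
#' @param n_exons Number of exons (>= 2).
#' @param exon_length_range,intron_length_range Integer ranges (nt).
#' @param gc_donor_fraction Probability that a donor is the rare
#'   non-canonical GC rather than GT.
#' @param seed Integer seed; the same seed reproduces the model byte for
#'   byte.
#' @param gene_id Label for the model.
#' @param flank_length Length of random flanking sequence on each side.
#' @param first_exon_number Label of the first exon (2 by the conventional
#'   core-region numbering).
#' @return A valid [gene_model()] carrying intron sequences.
#' @export
build_reference_model <- function(n_exons = 12L,
                                  exon_length_range = c(80L, 250L),
                                  intron_length_range = c(100L, 400L),
                                  gc_donor_fraction = 0,
                                  seed = 1L,
                                  gene_id = "simgene",
                                  flank_length = 100L,
                                  first_exon_number = 2L) {
  stopifnot(n_exons >= 2L, min(exon_length_range) >= 3L,
            min(intron_length_range) >= 6L)
  with_seed(seed, {
    exon_len <- sample(exon_length_range[1]:exon_length_range[2], n_exons,
                       replace = TRUE)
    total <- sum(exon_len)
    exon_len[n_exons] <- exon_len[n_exons] + (3L - total %% 3L) %% 3L
    n_codons <- sum(exon_len) %/% 3L
    sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
    codons <- c("ATG", sample(sense, n_codons - 2L, replace = TRUE),
                sample(STOP_CODONS, 1L))
    cds <- paste(codons, collapse = "")
    ends <- cumsum(exon_len)
    starts <- c(1L, head(ends, -1L) + 1L)
    exon_seq <- substring(cds, starts, ends)
    phases <- c(0L, head(cumsum(exon_len), -1L) %% 3L)
    donors <- ifelse(runif(n_exons - 1L) < gc_donor_fraction, "GC", "GT")
    exons <- vector("list", n_exons)
    for (i in seq_len(n_exons)) {
      exons[[i]] <- exon_def(
        first_exon_number + i - 1L, exon_seq[i], phases[i],
        expected_donor = if (i < n_exons) donors[i] else NA_character_,
        expected_acceptor = if (i > 1L) "AG" else NA_character_)
    }
    introns <- character(n_exons - 1L)
    for (i in seq_len(n_exons - 1L)) {
      len <- sample(intron_length_range[1]:intron_length_range[2], 1L)
      introns[i] <- paste0(donors[i], random_dna(len - 4L), "AG")
    }
    model <- gene_model(gene_id, exons, introns = introns,
                        flank5 = random_dna(flank_length),
                        flank3 = random_dna(flank_length))
    viol <- validate_gene_model(model)
    if (nrow(viol) > 0L)
      stop("reference model generation failed validation: ",
           paste(viol$message, collapse = "; "))
    model
  })
}

# Segment-list form of the reference locus.
model_segments <- function(model) {
  segs <- list()
  if (nchar(model$flank5) > 0L)
    segs[[length(segs) + 1L]] <- list(type = "flank", exon_number = NA_integer_,
                                      seq = model$flank5)
  n <- length(model$exons)
  for (i in seq_len(n)) {
    segs[[length(segs) + 1L]] <- list(type = "exon",
                                      exon_number = model$exons[[i]]$exon_number,
                                      seq = model$exons[[i]]$sequence)
    if (i < n)
      segs[[length(segs) + 1L]] <- list(type = "intron",
                                        exon_number = model$exons[[i]]$exon_number,
                                        seq = model$introns[[i]])
  }
  if (nchar(model$flank3) > 0L)
    segs[[length(segs) + 1L]] <- list(type = "flank", exon_number = NA_integer_,
                                      seq = model$flank3)
  segs
}

segments_sequence <- function(segs)
  paste(vapply(segs, `[[`, "", "seq"), collapse = "")

# 0-based half-open exon intervals implied by a segment list.
segment_exon_intervals <- function(segs) {
  pos <- 0L
  rows <- list()
  for (s in segs) {
    len <- nchar(s$seq)
    if (s$type == "exon")
      rows[[length(rows) + 1L]] <- data.frame(exon_number = s$exon_number,
                                              start = pos, end = pos + len)
    pos <- pos + len
  }
  do.call(rbind, rows)
}

#' Assemble the reference locus sequence of a model
#'
#' @param model A [gene_model()] with intron sequences.
#' @return Flank + exon/intron concatenation as one string.
#' @export
assemble_reference_locus <- function(model) {
  if (is.null(model$introns)) stop("model carries no intron sequences")
  segments_sequence(model_segments(model))
}

#' Planted inactivating or structural event
#'
#' Constructor for one event to be introduced on a tree branch during
#' simulation and inherited by every descendant (Dollo-consistent; no
#' reversal). Prefer the convenience constructors [splice_event()],
#' [indel_event()], [stop_event()], [deletion_event()] and [fusion_event()].
#'
#' @param branch Tree-edge id: the label of the child node (tip label, or
#'   internal node label) of the edge the event occurs on.
#' @param kind One of `r paste(EVENT_KINDS, collapse=", ")`.
#' @param exon_number Exon the event applies to.
#' @param detail Kind-specific list (replacement dinucleotide, indel
#'   offset/sequence, stop codon, fusion intron sequence).
#' @return A list of class `planted_event`.
#' @export
planted_event <- function(branch, kind, exon_number, detail = list()) {
  kind <- match.arg(kind, EVENT_KINDS)
  if (kind == "FRAMESHIFT_INDEL") {
    len <- if (identical(detail$op, "ins")) nchar(detail$sequence) else detail$length
    if (len %% 3L == 0L)
      stop("FRAMESHIFT_INDEL length must not be a multiple of 3")
  }
  if (kind == "INFRAME_INDEL") {
    len <- if (identical(detail$op, "ins")) nchar(detail$sequence) else detail$length
    if (len %% 3L != 0L)
      stop("INFRAME_INDEL length must be a multiple of 3")
  }
  if (kind %in% c("SPLICE_DONOR_MUT", "SPLICE_ACCEPTOR_MUT", "EXON_FUSION")) {
    ok <- if (kind == "SPLICE_ACCEPTOR_MUT") c("AG", "AC") else c("GT", "GC")
    if (detail$dinucleotide %in% ok)
      stop("replacement splice dinucleotide must be non-functional")
  }
  if (kind == "EXON_FUSION") {
    if (nchar(detail$intron_sequence) %% 3L != 0L)
      stop("fusion intron length must be a multiple of 3")
  }
  structure(list(branch = branch, kind = kind,
                 exon_number = as.integer(exon_number), detail = detail),
            class = "planted_event")
}

#' Convenience constructors for planted events
#'
#' @param branch Child-node label of the target branch.
#' @param exon_number Exon the event applies to.
#' @param side `"donor"` (intron 3' of the exon) or `"acceptor"` (5').
#' @param dinucleotide Replacement splice dinucleotide (must be
#'   non-functional, e.g. `"AT"`).
#' @return A [planted_event()].
#' @export
splice_event <- function(branch, exon_number, side = c("donor", "acceptor"),
                         dinucleotide = "AT") {
  side <- match.arg(side)
  planted_event(branch,
                if (side == "donor") "SPLICE_DONOR_MUT" else "SPLICE_ACCEPTOR_MUT",
                exon_number, list(dinucleotide = dinucleotide))
}

#' @rdname splice_event
#' @param offset 0-based offset within the exon.
#' @param op `"del"` or `"ins"`.
#' @param length Deletion length (for `op = "del"`).
#' @param sequence Inserted sequence (for `op = "ins"`).
#' @export
indel_event <- function(branch, exon_number, offset, op = c("del", "ins"),
                        length = 1L, sequence = NULL) {
  op <- match.arg(op)
  len <- if (op == "ins") nchar(sequence) else length
  detail <- list(op = op, offset = as.integer(offset))
  if (op == "ins") detail$sequence <- toupper(sequence) else detail$length <- as.integer(length)
  planted_event(branch,
                if (len %% 3L == 0L) "INFRAME_INDEL" else "FRAMESHIFT_INDEL",
                exon_number, detail)
}

#' @rdname splice_event
#' @param model The reference [gene_model()] (used to pick an in-frame
#'   offset and validate frames).
#' @param codon Replacement STOP codon.
#' @export
stop_event <- function(model, branch, exon_number, codon = "TGA",
                       offset = NULL) {
  stopifnot(codon %in% STOP_CODONS)
  idx <- which(vapply(model$exons, `[[`, 1L, "exon_number") == exon_number)
  if (length(idx) != 1L) stop("exon not in model: ", exon_number)
  ex <- model$exons[[idx]]
  if (is.null(offset)) {
    # nearest in-frame codon start to the middle of the exon
    first_inframe <- (3L - ex$phase) %% 3L
    mid <- nchar(ex$sequence) %/% 2L
    offset <- first_inframe + ((mid - first_inframe) %/% 3L) * 3L
  }
  if ((ex$phase + offset) %% 3L != 0L)
    stop("premature-STOP offset is not at a codon boundary")
  planted_event(branch, "PREMATURE_STOP", exon_number,
                list(offset = as.integer(offset), codon = codon))
}

#' @rdname splice_event
#' @export
deletion_event <- function(branch, exon_number)
  planted_event(branch, "EXON_DELETION", exon_number, list())

#' @rdname splice_event
#' @param intron_length Length (nt, multiple of 3) of the retained intron;
#'   99 nt contributes 33 residues to the fused protein.
#' @param seed Seed for the generated intron interior.
#' @export
fusion_event <- function(model, branch, exon_number, dinucleotide = "AT",
                         intron_length = 99L, seed = 1L) {
  stopifnot(intron_length %% 3L == 0L, intron_length >= 9L)
  idx <- which(vapply(model$exons, `[[`, 1L, "exon_number") == exon_number)
  if (length(idx) != 1L || idx >= length(model$exons))
    stop("fusion requires an internal exon present in the model")
  # an A-initial donor can complete a STOP with a TA/TG exon tail in
  # phase 2; fall back to other non-functional dinucleotides when needed
  for (dn in unique(c(dinucleotide, "CT", "CA"))) {
    intron <- tryCatch(
      with_seed(seed, make_fusion_intron(model, idx, intron_length, dn)),
      error = function(e) NULL)
    if (!is.null(intron))
      return(planted_event(branch, "EXON_FUSION", exon_number,
                           list(dinucleotide = dn,
                                intron_sequence = intron)))
  }
  stop("cannot build a STOP-free fusion intron after exon ", exon_number)
}

# Construct a retained-intron sequence for a fusion of exon idx with
# idx + 1: mutated donor at its 5' end, AG at its 3' end, length a multiple
# of 3, and no STOP codon when read through in the running frame.
make_fusion_intron <- function(model, idx, intron_length, dinucleotide) {
  intron <- paste0(dinucleotide, random_dna(intron_length - 4L), "AG")
  p <- model$exons[[idx + 1L]]$phase  # codon offset entering the intron
  exk <- model$exons[[idx]]$sequence
  tail_ref <- if (p > 0L) substr(exk, nchar(exk) - p + 1L, nchar(exk)) else ""
  spill <- (3L - p) %% 3L
  ex_next <- model$exons[[idx + 1L]]$sequence
  head_ref <- if (spill > 0L) substr(ex_next, 1L, spill) else ""
  ctx <- paste0(tail_ref, intron, head_ref)
  chars <- strsplit(ctx, "")[[1L]]
  # mutable context positions: intron interior only
  mut_lo <- nchar(tail_ref) + 3L          # 1-based; keeps donor dinucleotide
  mut_hi <- nchar(tail_ref) + intron_length - 2L  # keeps the AG acceptor
  for (st in seq(1L, length(chars) - 2L, by = 3L)) {
    cod <- paste(chars[st:(st + 2L)], collapse = "")
    if (cod %in% STOP_CODONS) {
      fixable <- intersect(st:(st + 2L), mut_lo:mut_hi)
      if (length(fixable) == 0L)
        stop("cannot build STOP-free fusion intron in this frame")
      chars[fixable[1L]] <- "C"  # C occurs in no STOP codon
    }
  }
  paste(chars[(nchar(tail_ref) + 1L):(nchar(tail_ref) + intron_length)],
        collapse = "")
}

# ---- tree plumbing ----

# Accept a phylo object, a newick string, or a newick file path; ensure
# node labels exist so branches are addressable by child-node label.
resolve_tree <- function(tree) {
  if (inherits(tree, "phylo")) {
    t <- tree
  } else if (is.character(tree) && length(tree) == 1L) {
    t <- if (grepl("\\(", tree)) ape::read.tree(text = tree)
         else ape::read.tree(tree)
  } else stop("tree must be a phylo object, newick string, or file path")
  if (is.null(t)) stop("could not parse tree")
  if (is.null(t$node.label)) t$node.label <- rep("", t$Nnode)
  blank <- which(is.na(t$node.label) | t$node.label == "")
  if (length(blank) > 0L) {
    taken <- c(t$tip.label, t$node.label)
    cand <- setdiff(paste0("N", seq_len(t$Nnode + length(taken))), taken)
    t$node.label[blank] <- cand[seq_along(blank)]
  }
  if (anyDuplicated(c(t$tip.label, t$node.label)))
    stop("tree tip/node labels must be unique")
  if (is.null(t$edge.length)) t$edge.length <- rep(1, nrow(t$edge))
  t
}

node_label <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) tree$tip.label[node] else tree$node.label[node - n_tip]
}

# ---- branch processes ----

apply_substitutions <- function(segs, n_sub, model) {
  if (n_sub == 0L) return(list(segs = segs, realised = 0L))
  charsegs <- lapply(segs, function(s) strsplit(s$seq, "")[[1L]])
  lens <- vapply(charsegs, length, 1L)
  cum <- cumsum(lens)
  total <- cum[length(cum)]
  start_exnum <- model$exons[[model$start_exon]]$exon_number
  stop_exnum <- model$exons[[model$stop_exon]]$exon_number
  realised <- 0L
  for (k in seq_len(n_sub)) {
    pos <- sample.int(total, 1L)
    si <- which.max(cum >= pos)
    off <- pos - (if (si > 1L) cum[si - 1L] else 0L)  # 1-based in segment
    s <- segs[[si]]
    L <- lens[si]
    if (isTRUE(s$protected)) next  # e.g. retained fusion introns
    # windows adjoining a planted splice mutation stay frozen so that no
    # later substitution can fabricate a rescue site
    if (off <= (s$protect_head_n %||% 0L)) next
    if (off > L - (s$protect_tail_n %||% 0L)) next
    if (s$type == "intron" && (off <= 2L || off > L - 2L)) next  # splice mask
    if (s$type == "exon") {
      if (off <= 2L || off > L - 2L) next  # junction codons stay reference
      if (s$exon_number == start_exnum && off <= 3L) next        # start codon
      if (s$exon_number == stop_exnum && off > L - 3L) next      # terminal STOP
    }
    old <- charsegs[[si]][off]
    cands <- setdiff(DNA_BASES, old)
    if (s$type == "exon") {
      # refuse substitutions that create a STOP codon in any reading frame
      ok <- cands[vapply(cands, function(b) {
        v <- charsegs[[si]]
        v[off] <- b
        lo <- max(1L, off - 2L)
        hi <- min(L, off + 2L)
        w <- paste(v[lo:hi], collapse = "")
        !any(vapply(seq_len(max(0L, nchar(w) - 2L)), function(i)
          substr(w, i, i + 2L) %in% STOP_CODONS, TRUE))
      }, TRUE)]
      if (length(ok) == 0L) next
      cands <- ok
    }
    charsegs[[si]][off] <- if (length(cands) == 1L) cands else sample(cands, 1L)
    realised <- realised + 1L
  }
  for (i in seq_along(segs)) segs[[i]]$seq <- paste(charsegs[[i]], collapse = "")
  list(segs = segs, realised = realised)
}

apply_background_indels <- function(segs, n_indel) {
  if (n_indel == 0L) return(list(segs = segs, realised = 0L))
  realised <- 0L
  for (k in seq_len(n_indel)) {
    intron_idx <- which(vapply(segs, function(s)
      s$type == "intron" && nchar(s$seq) > 30L && !isTRUE(s$protected), TRUE))
    if (length(intron_idx) == 0L) break
    lens <- vapply(segs[intron_idx], function(s) nchar(s$seq), 1L)
    si <- intron_idx[sample.int(length(intron_idx), 1L, prob = lens)]
    s <- segs[[si]]
    L <- nchar(s$seq)
    g <- min(rgeom(1L, 0.5) + 1L, 10L)
    pos <- sample.int(L - g - 4L, 1L) + 2L  # interior, clear of splice sites
    if (runif(1L) < 0.5) {
      segs[[si]]$seq <- paste0(substr(s$seq, 1L, pos - 1L),
                               substr(s$seq, pos + g, L))
    } else {
      segs[[si]]$seq <- paste0(substr(s$seq, 1L, pos - 1L), random_dna(g),
                               substr(s$seq, pos, L))
    }
    realised <- realised + 1L
  }
  list(segs = segs, realised = realised)
}

# Remove rescue-mimicking canonical dinucleotides from the frame-preserving
# positions around a planted splice mutation, and make sure a mutated donor
# cannot satisfy the in-frame read-through conditions of a fusion call.
# This keeps planted splice lesions unambiguous in the truth log: without
# it, random intron sequence offers frame-preserving GT/AG sites (or, for
# introns whose length is a multiple of 3, a STOP-free read-through) often
# enough to blur the planted signal.
RESCUE_SCRUB_WINDOW <- 33L

scrub_rescue_sites <- function(segs, exon_idx, intron_idx, side) {
  ex <- strsplit(segs[[exon_idx]]$seq, "")[[1L]]
  it <- strsplit(segs[[intron_idx]]$seq, "")[[1L]]
  Le <- length(ex); Li <- length(it)
  for (d in seq.int(-RESCUE_SCRUB_WINDOW, RESCUE_SCRUB_WINDOW)) {
    if (d == 0L || d %% 3L != 0L) next
    if (side == "donor") {
      if (d > 0L) {  # dinucleotide at intron offset d (0-based)
        if (d + 2L <= Li - 2L && it[d + 1L] == "G" && it[d + 2L] == "T")
          it[d + 1L] <- "C"
      } else {       # within the exon tail
        p <- Le + d  # 0-based
        if (p >= 0L && p + 2L <= Le && ex[p + 1L] == "G" && ex[p + 2L] == "T")
          ex[p + 1L] <- "C"
      }
    } else {         # acceptor: dinucleotide ends 2 nt before the boundary
      if (d > 0L) {  # shifted into the exon
        p <- d - 2L  # 0-based exon offset of the dinucleotide start
        if (p >= 0L && p + 2L <= Le && ex[p + 1L] == "A" && ex[p + 2L] == "G")
          ex[p + 1L] <- "C"
      } else {       # within the intron
        p <- Li + d - 2L
        if (p >= 2L && p + 2L <= Li - 2L && it[p + 1L] == "A" &&
            it[p + 2L] == "G")
          it[p + 1L] <- "C"
      }
    }
  }
  segs[[exon_idx]]$seq <- paste(ex, collapse = "")
  segs[[intron_idx]]$seq <- paste(it, collapse = "")
  segs
}

# A block containing a STOP codon in every reading frame; written into the
# interior of the intron following a planted (non-fusion) donor mutation,
# so that intron read-through can never look like a clean exon fusion
# (whatever the intron length ends up being after background indels).
ALL_FRAME_STOP_BLOCK <- "TAACTAACTAA"

block_fusion_readthrough <- function(segs, intron_idx) {
  s <- segs[[intron_idx]]$seq
  off <- min(RESCUE_SCRUB_WINDOW + 3L,
             max(2L, nchar(s) - nchar(ALL_FRAME_STOP_BLOCK) - 2L))
  substr(segs[[intron_idx]]$seq, off + 1L,
         off + nchar(ALL_FRAME_STOP_BLOCK)) <- ALL_FRAME_STOP_BLOCK
  segs
}

seg_index_of_exon <- function(segs, exon_number, type = "exon") {
  which(vapply(segs, function(s)
    s$type == type && !is.na(s$exon_number) && s$exon_number == exon_number,
    TRUE))
}

apply_planted_event <- function(segs, ev) {
  ei <- seg_index_of_exon(segs, ev$exon_number)
  needs_exon <- ev$kind != "SPLICE_ACCEPTOR_MUT" || TRUE
  if (length(ei) == 0L && needs_exon)
    stop(sprintf("planted event %s on exon %d collides with a deleted exon",
                 ev$kind, ev$exon_number))
  ei <- ei[1L]
  s <- segs[[ei]]
  L <- nchar(s$seq)
  switch(ev$kind,
    SPLICE_DONOR_MUT = {
      ii <- seg_index_of_exon(segs, ev$exon_number, "intron")
      if (length(ii) == 0L) stop("no intron downstream of exon ", ev$exon_number)
      substr(segs[[ii[1L]]]$seq, 1L, 2L) <- ev$detail$dinucleotide
      segs <- scrub_rescue_sites(segs, ei, ii[1L], "donor")
      segs <- block_fusion_readthrough(segs, ii[1L])
      segs[[ei]]$protect_tail_n <-
        max(segs[[ei]]$protect_tail_n %||% 0L, RESCUE_SCRUB_WINDOW + 2L)
      segs[[ii[1L]]]$protect_head_n <-
        max(segs[[ii[1L]]]$protect_head_n %||% 0L, RESCUE_SCRUB_WINDOW + 2L)
    },
    SPLICE_ACCEPTOR_MUT = {
      # intron upstream of this exon: last intron segment before ei
      prev <- rev(which(vapply(seq_len(ei - 1L), function(i)
        segs[[i]]$type == "intron", TRUE)))
      if (length(prev) == 0L) stop("no intron upstream of exon ", ev$exon_number)
      ii <- prev[1L]
      iL <- nchar(segs[[ii]]$seq)
      substr(segs[[ii]]$seq, iL - 1L, iL) <- ev$detail$dinucleotide
      segs <- scrub_rescue_sites(segs, ei, ii, "acceptor")
      segs[[ei]]$protect_head_n <-
        max(segs[[ei]]$protect_head_n %||% 0L, RESCUE_SCRUB_WINDOW + 2L)
      segs[[ii]]$protect_tail_n <-
        max(segs[[ii]]$protect_tail_n %||% 0L, RESCUE_SCRUB_WINDOW + 2L)
    },
    FRAMESHIFT_INDEL = ,
    INFRAME_INDEL = {
      off <- ev$detail$offset  # 0-based
      if (identical(ev$detail$op, "ins")) {
        segs[[ei]]$seq <- paste0(substr(s$seq, 1L, off),
                                 ev$detail$sequence,
                                 substr(s$seq, off + 1L, L))
      } else {
        if (off + ev$detail$length > L)
          stop("planted deletion exceeds exon length")
        segs[[ei]]$seq <- paste0(substr(s$seq, 1L, off),
                                 substr(s$seq, off + ev$detail$length + 1L, L))
      }
    },
    PREMATURE_STOP = {
      off <- ev$detail$offset
      if (off + 3L > L) stop("planted STOP exceeds exon length")
      substr(segs[[ei]]$seq, off + 1L, off + 3L) <- ev$detail$codon
    },
    EXON_DELETION = {
      ii <- seg_index_of_exon(segs, ev$exon_number, "intron")
      drop <- c(ei, ii[1L])
      drop <- drop[!is.na(drop)]
      if (length(ii) == 0L) {  # terminal exon: drop the upstream intron
        prev <- rev(which(vapply(seq_len(ei - 1L), function(i)
          segs[[i]]$type == "intron", TRUE)))
        drop <- c(ei, prev[1L])
      }
      segs <- segs[-drop]
    },
    EXON_FUSION = {
      ii <- seg_index_of_exon(segs, ev$exon_number, "intron")
      if (length(ii) == 0L) stop("no intron to retain after exon ", ev$exon_number)
      segs[[ii[1L]]]$seq <- ev$detail$intron_sequence
      # the retained intron is now coding-like; background substitutions
      # could plant read-through STOPs there and blur the planted truth
      segs[[ii[1L]]]$protected <- TRUE
    })
  segs
}

#' Evolve a gene locus along a phylogeny with planted lesions
#'
#' Starting from the reference locus of `model`, applies Jukes-Cantor
#' background substitutions and background intronic indels independently on
#' every branch (Poisson numbers proportional to branch length), then any
#' planted events assigned to that branch; descendants inherit all changes,
#' so planted events are Dollo-consistent by construction. Splice
#' dinucleotides, the start codon and the terminal STOP are masked from
#' background substitution, exonic substitutions never create STOP codons,
#' and background indels fall only in intron interiors, so the truth log
#' lists every ORF-disrupting change.
#'
#' @param model Reference [gene_model()] with introns.
#' @param tree A phylo object, newick string, or newick file path; branch
#'   ids are child-node labels (internal nodes are auto-labelled
#'   `N1..Nk` when unlabelled).
#' @param sub_rate Substitutions per site per unit branch length.
#' @param indel_rate Background indels per site per unit branch length.
#' @param planted List of [planted_event()] objects.
#' @param seed Master seed; per-branch streams are derived from it so
#'   editing one branch's events leaves other branches' background
#'   unchanged.
#' @return `list(loci, truth)`: a list of [target_locus()] (one per tip) and
#'   a `sim_truth` object (planted-event log, per-species inherited events,
#'   realised exon intervals, background counts).
#' @export
evolve_along_tree <- function(model, tree, sub_rate = 0, indel_rate = 0,
                              planted = list(), seed = 1L) {
  stopifnot(sub_rate >= 0, indel_rate >= 0)
  tree <- resolve_tree(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  all_labels <- c(tree$tip.label, tree$node.label)
  root_label <- node_label(tree, root)
  for (ev in planted) {
    if (!ev$branch %in% all_labels)
      stop("planted event references unknown branch: ", ev$branch)
    if (ev$branch == root_label)
      stop("cannot plant an event on the root (it has no branch)")
    if (!ev$exon_number %in% vapply(model$exons, `[[`, 1L, "exon_number"))
      stop("planted event references unknown exon: ", ev$exon_number)
  }
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])

  loci <- list()
  truth_events <- list()
  per_species <- list()

  recurse <- function(node, segs, inherited, n_sub_acc, n_indel_acc) {
    if (node <= n_tip) {
      sp <- tree$tip.label[node]
      loci[[sp]] <<- target_locus(sp, model$gene_id, segments_sequence(segs))
      per_species[[sp]] <<- list(
        events = inherited,
        exon_intervals = segment_exon_intervals(segs),
        n_substitutions = n_sub_acc,
        n_background_indels = n_indel_acc)
      return(invisible(NULL))
    }
    for (e in children[[as.character(node)]]) {
      child <- tree$edge[e, 2L]
      bl <- tree$edge.length[e]
      key <- node_label(tree, child)
      ev_here <- Filter(function(ev) ev$branch == key, planted)
      res <- with_seed(derive_seed(seed, key), {
        L <- nchar(segments_sequence(segs))
        n_sub <- rpois(1L, sub_rate * L * bl)
        n_ind <- rpois(1L, indel_rate * L * bl)
        r1 <- apply_substitutions(segs, n_sub, model)
        r2 <- apply_background_indels(r1$segs, n_ind)
        list(segs = r2$segs, n_sub = r1$realised, n_ind = r2$realised)
      })
      segs_child <- res$segs
      for (ev in ev_here) {
        segs_child <- apply_planted_event(segs_child, ev)
        truth_events[[length(truth_events) + 1L]] <<- ev
      }
      recurse(child, segs_child,
              c(inherited, lapply(ev_here, identity)),
              n_sub_acc + res$n_sub, n_indel_acc + res$n_ind)
    }
  }
  recurse(root, model_segments(model), list(), 0L, 0L)

  truth <- structure(list(seed = as.integer(seed),
                          gene_id = model$gene_id,
                          tree = ape::write.tree(tree),
                          sub_rate = sub_rate, indel_rate = indel_rate,
                          events = planted,
                          per_species = per_species),
                     class = "sim_truth")
  list(loci = loci[tree$tip.label], truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d species, %d planted events, seed %d\n",
              length(x$per_species), length(x$events), x$seed))
  invisible(x)
}

event_to_list <- function(ev)
  list(branch = ev$branch, kind = ev$kind, exon_number = ev$exon_number,
       detail = ev$detail)

event_from_list <- function(l)
  planted_event(l$branch, l$kind, l$exon_number,
                lapply(l$detail, function(x) if (is.list(x)) unlist(x) else x))

#' Write / read a simulated fixture
#'
#' Writes one FASTA per species, the truth log as JSON, and (optionally)
#' the generating configuration as YAML. Re-running the simulation with the
#' stored configuration and seed reproduces the files byte-identically.
#'
#' @param loci Named list of [target_locus()] (as from
#'   [evolve_along_tree()]).
#' @param truth The matching `sim_truth`.
#' @param out_dir Output directory (created if needed).
#' @param config Optional list serialised alongside as `config.yaml`.
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(loci, truth, out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(loci)) {
    ss <- Biostrings::DNAStringSet(loci[[sp]]$sequence)
    names(ss) <- paste0(sp, "|", loci[[sp]]$locus_id)
    Biostrings::writeXStringSet(ss, file.path(out_dir, paste0(sp, ".fasta")))
  }
  tr <- list(seed = truth$seed, gene_id = truth$gene_id, tree = truth$tree,
             sub_rate = truth$sub_rate, indel_rate = truth$indel_rate,
             events = lapply(truth$events, event_to_list),
             per_species = lapply(truth$per_species, function(ps)
               list(events = lapply(ps$events, event_to_list),
                    exon_intervals = ps$exon_intervals,
                    n_substitutions = ps$n_substitutions,
                    n_background_indels = ps$n_background_indels)))
  jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(config))
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(out_dir) {
  tr <- jsonlite::read_json(file.path(out_dir, "truth.json"))
  per_species <- lapply(tr$per_species, function(ps)
    list(events = lapply(ps$events, event_from_list),
         exon_intervals = do.call(rbind, lapply(ps$exon_intervals, as.data.frame)),
         n_substitutions = ps$n_substitutions,
         n_background_indels = ps$n_background_indels))
  truth <- structure(list(seed = tr$seed, gene_id = tr$gene_id, tree = tr$tree,
                          sub_rate = tr$sub_rate, indel_rate = tr$indel_rate,
                          events = lapply(tr$events, event_from_list),
                          per_species = per_species),
                     class = "sim_truth")
  fas <- list.files(out_dir, pattern = "\\.fasta$", full.names = TRUE)
  loci <- list()
  for (f in fas) {
    ss <- Biostrings::readDNAStringSet(f)
    hdr <- strsplit(names(ss)[1L], "|", fixed = TRUE)[[1L]]
    loci[[hdr[1L]]] <- target_locus(hdr[1L], hdr[2L], as.character(ss[[1L]]))
  }
  list(loci = loci[names(per_species)], truth = truth)
}
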