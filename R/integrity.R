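# Lesion calling, exon-fusion detection, CDS assembly and gene verdicts.

LESION_KINDS <- c("SPLICE_DONOR_MUT", "SPLICE_ACCEPTOR_MUT",
                  "FRAMESHIFT_INDEL", "INFRAME_INDEL", "PREMATURE_STOP",
                  "EXON_MISSING")

lesion_row <- function(kind, exon_number, offset, observed, reference,
                       disrupting, note = "") {
  data.frame(kind = kind, exon_number = as.integer(exon_number),
             offset = as.integer(offset), observed = observed,
             reference = reference, disrupting = disrupting, note = note,
             stringsAsFactors = FALSE)
}

empty_lesions <- function()
  data.frame(kind = character(0), exon_number = integer(0),
             offset = integer(0), observed = character(0),
             reference = character(0), disrupting = logical(0),
             note = character(0), stringsAsFactors = FALSE)

#' Classify a splice-site dinucleotide
#'
#' Donor GT and acceptor AG are canonical; donor GC and acceptor AC are
#' rare but tolerated non-canonical motifs; anything else is a mutated
#' (presumed non-functional) site. A dinucleotide containing N is MUTATED
#' with a low-confidence attribute.
#'
#' @param dinucleotide 2-mer over A/C/G/T/N.
#' @param side `"donor"` or `"acceptor"`.
#' @return One of `"CANONICAL"`, `"NONCANONICAL_TOLERATED"`, `"MUTATED"`;
#'   attribute `low_confidence` is `TRUE` when an N was involved.
#' @examples
#' classify_splice_site("GT", "donor")   # CANONICAL
#' classify_splice_site("GC", "donor")   # NONCANONICAL_TOLERATED
#' classify_splice_site("AT", "donor")   # MUTATED
#' @export
classify_splice_site <- function(dinucleotide, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  if (is.na(dinucleotide) || nchar(dinucleotide) != 2L)
    stop("splice dinucleotide must be exactly 2 nt")
  dinucleotide <- toupper(dinucleotide)
  if (grepl("[^ACGTN]", dinucleotide))
    stop("splice dinucleotide outside {A,C,G,T,N}")
  if (grepl("N", dinucleotide, fixed = TRUE))
    return(structure("MUTATED", low_confidence = TRUE))
  canonical <- if (side == "donor") "GT" else "AG"
  tolerated <- if (side == "donor") "GC" else "AC"
  out <- if (dinucleotide == canonical) "CANONICAL"
         else if (dinucleotide == tolerated) "NONCANONICAL_TOLERATED"
         else "MUTATED"
  structure(out, low_confidence = FALSE)
}

# Walk an exon hit's gapped alignment: emit indel lesions and in-frame
# premature STOPs, tracking the observed reading frame through indels.
#
# upstream_frame_shift: net indel length (target minus reference) carried
# in from upstream exons.
call_exon_lesions_one <- function(hit, model, upstream_frame_shift = 0L,
                                  terminal_stop_grace = 30L) {
  stopifnot(isTRUE(hit$found))
  idx <- which(vapply(model$exons, `[[`, 1L, "exon_number") == hit$exon_number)
  ex <- model$exons[[idx]]
  lesions <- list()
  rc <- strsplit(hit$aligned_ref, "")[[1L]]
  tc <- strsplit(hit$aligned_target, "")[[1L]]
  n <- length(rc)
  # --- indels from gap runs ---
  runs <- list()
  i <- 1L
  ref_pos <- 0L  # 0-based position in reference exon
  while (i <= n) {
    if (rc[i] == "-" || tc[i] == "-") {
      j <- i
      ins <- character(); del <- character()
      while (j <= n && (rc[j] == "-" || tc[j] == "-")) {
        if (rc[j] == "-") ins <- c(ins, tc[j]) else del <- c(del, rc[j])
        j <- j + 1L
      }
      runs[[length(runs) + 1L]] <- list(
        ref_pos = ref_pos, ins = paste(ins, collapse = ""),
        del = paste(del, collapse = ""))
      ref_pos <- ref_pos + length(del)
      i <- j
    } else {
      ref_pos <- ref_pos + 1L
      i <- i + 1L
    }
  }
  # merge gap runs separated by few matched bases: local aligners often
  # split one event, or render a cluster of mismatches as offsetting
  # insertion/deletion pairs; the merged net length is what matters for
  # the reading frame
  merge_dist <- 10L
  merged <- list()
  for (r in runs) {
    if (length(merged) > 0L) {
      last <- merged[[length(merged)]]
      if (r$ref_pos - (last$ref_pos + nchar(last$del)) <= merge_dist) {
        last$ins <- paste0(last$ins, r$ins)
        last$del <- paste0(last$del, r$del)
        merged[[length(merged)]] <- last
        next
      }
    }
    merged[[length(merged) + 1L]] <- r
  }
  for (r in merged) {
    net <- nchar(r$ins) - nchar(r$del)
    if (net == 0L && nchar(r$ins) == nchar(r$del) &&
        nchar(r$ins) <= merge_dist) next  # offsetting pair: substitutions
    kind <- if (abs(net) %% 3L == 0L) "INFRAME_INDEL" else "FRAMESHIFT_INDEL"
    lesions[[length(lesions) + 1L]] <- lesion_row(
      kind, ex$exon_number, r$ref_pos, observed = r$ins,
      reference = r$del, disrupting = kind == "FRAMESHIFT_INDEL")
  }
  # --- in-frame premature STOPs in the observed sequence ---
  # codon offset of the first target base, given phase and upstream shift
  frame <- (ex$phase + (upstream_frame_shift %% 3L)) %% 3L
  is_stop_exon <- idx == model$stop_exon
  ref_len <- nchar(ex$sequence)
  codon <- character(3L)
  codon_start_t <- NA_integer_
  codon_start_r <- NA_integer_
  codon_shift <- upstream_frame_shift
  cur_shift <- upstream_frame_shift  # running net indel shift at this column
  t_pos <- 0L; r_pos <- 0L
  for (k in seq_len(n)) {
    if (rc[k] != "-") r_pos <- r_pos + 1L
    if (rc[k] == "-") cur_shift <- cur_shift + 1L
    if (tc[k] == "-") { cur_shift <- cur_shift - 1L; next }
    t_pos <- t_pos + 1L
    slot <- frame + 1L
    if (slot == 1L) {
      codon_start_t <- t_pos; codon_start_r <- r_pos
      codon_shift <- cur_shift
    }
    codon[slot] <- tc[k]
    frame <- (frame + 1L) %% 3L
    if (frame == 0L && slot == 3L) {
      cod <- paste(codon, collapse = "")
      if (cod %in% STOP_CODONS) {
        near_terminal <- is_stop_exon &&
          codon_start_r > ref_len - terminal_stop_grace
        if (!near_terminal)
          lesions[[length(lesions) + 1L]] <- lesion_row(
            "PREMATURE_STOP", ex$exon_number, codon_start_t - 1L,
            observed = cod, reference = "", disrupting = TRUE,
            note = if (cur_shift %% 3L != 0L ||
                       codon_shift %% 3L != 0L) "frameshift_consequence"
                   else "")
      }
    }
  }
  # --- splice flank classification ---
  if (idx < length(model$exons) && !is.na(hit$donor_dinucleotide)) {
    cls <- classify_splice_site(hit$donor_dinucleotide, "donor")
    if (cls == "MUTATED")
      lesions[[length(lesions) + 1L]] <- lesion_row(
        "SPLICE_DONOR_MUT", ex$exon_number, ref_len,
        observed = hit$donor_dinucleotide,
        reference = ex$expected_donor %||% "GT", disrupting = TRUE,
        note = if (isTRUE(attr(cls, "low_confidence"))) "low_confidence" else "")
  }
  if (idx > 1L && !is.na(hit$acceptor_dinucleotide)) {
    cls <- classify_splice_site(hit$acceptor_dinucleotide, "acceptor")
    if (cls == "MUTATED")
      lesions[[length(lesions) + 1L]] <- lesion_row(
        "SPLICE_ACCEPTOR_MUT", ex$exon_number, -1L,
        observed = hit$acceptor_dinucleotide,
        reference = ex$expected_acceptor %||% "AG", disrupting = TRUE,
        note = if (isTRUE(attr(cls, "low_confidence"))) "low_confidence" else "")
  }
  if (length(lesions) == 0L) return(empty_lesions())
  do.call(rbind, lesions)
}

#' Call lesions for one exon hit
#'
#' Emits every alignment gap as an indel lesion (frameshifting when its net
#' length is not a multiple of 3; otherwise an in-frame structural note
#' with `disrupting = FALSE`), every in-frame STOP codon in the observed
#' exon sequence as a premature-STOP lesion (frame tracked through indels;
#' a STOP within the final `terminal_stop_grace` nt of the terminal exon is
#' treated as the true STOP shifted), and MUTATED splice flanks as splice
#' lesions.
#'
#' @param hit An `exon_hit` with `found = TRUE`.
#' @param model The reference [gene_model()].
#' @param upstream_frame_shift Net indel length (nt) carried in from
#'   upstream exons.
#' @param terminal_stop_grace Window (nt) at the end of the terminal exon
#'   within which a STOP is taken as the true terminator.
#' @return Data frame of lesions (columns kind, exon_number, offset,
#'   observed, reference, disrupting, note). Offsets are 0-based within the
#'   reference exon; use the TSV writers for 1-based reporting.
#' @export
call_exon_lesions <- function(hit, model, upstream_frame_shift = 0L,
                              terminal_stop_grace = 30L)
  call_exon_lesions_one(hit, model, upstream_frame_shift, terminal_stop_grace)

#' Call lesions across a whole locus
#'
#' Iterates exons in order, carrying the observed frame shift from exon to
#' exon, and emits `EXON_MISSING` for exons that were not found (always
#' disrupting; when the locus has an assembly gap the unresolved exon is
#' instead flagged for an INCOMPLETE verdict by [classify_gene()]).
#'
#' @param hits List of `exon_hit` (one per model exon, in order).
#' @param model The reference [gene_model()].
#' @param terminal_stop_grace See [call_exon_lesions()].
#' @return Data frame of lesions for the locus.
#' @export
call_locus_lesions <- function(hits, model, terminal_stop_grace = 30L) {
  out <- list()
  shift <- 0L
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    if (!h$found) {
      ex <- model$exons[[i]]
      out[[length(out) + 1L]] <- lesion_row(
        "EXON_MISSING", ex$exon_number, 0L, observed = "",
        reference = ex$sequence, disrupting = TRUE)
      shift <- shift - nchar(ex$sequence)
      next
    }
    les <- call_exon_lesions_one(h, model, shift, terminal_stop_grace)
    out[[length(out) + 1L]] <- les
    if (nrow(les) > 0L) {
      ind <- les$kind %in% c("FRAMESHIFT_INDEL", "INFRAME_INDEL")
      shift <- shift + sum(nchar(les$observed[ind]) - nchar(les$reference[ind]))
    }
  }
  res <- do.call(rbind, c(list(empty_lesions()), out))
  rownames(res) <- NULL
  res
}

#' Detect an in-frame fusion of two adjacent exons
#'
#' A "super exon" call: the donor following the upstream exon is mutated,
#' the intervening intron length is a multiple of 3, and reading through
#' the intron in the running frame meets no STOP codon — so the intron is
#' retained in the mRNA without disrupting the ORF, adding
#' `intron_length / 3` residues to the protein.
#'
#' @param locus Oriented [target_locus()].
#' @param hit_k,hit_k1 Hits for the upstream and downstream exons (both
#'   found and adjacent in the model).
#' @param model The reference [gene_model()].
#' @param frame_shift Net observed indel shift upstream of the intron.
#' @return A list of class `fusion_call` (fields `upstream_exon`,
#'   `downstream_exon`, `intron_length`, `incorporated_residues`,
#'   `in_frame`) or `NULL` when the criteria are not met.
#' @export
detect_exon_fusion <- function(locus, hit_k, hit_k1, model,
                               frame_shift = 0L) {
  if (!isTRUE(hit_k$found) || !isTRUE(hit_k1$found)) return(NULL)
  if (is.na(hit_k$donor_dinucleotide)) return(NULL)
  if (classify_splice_site(hit_k$donor_dinucleotide, "donor") != "MUTATED")
    return(NULL)
  i_start <- hit_k$target_interval[2L]
  i_end <- hit_k1$target_interval[1L]
  intron_len <- i_end - i_start
  if (intron_len <= 0L || intron_len %% 3L != 0L) return(NULL)
  idx1 <- which(vapply(model$exons, `[[`, 1L, "exon_number") ==
                  hit_k1$exon_number)
  p <- (model$exons[[idx1]]$phase + (frame_shift %% 3L)) %% 3L
  # read-through context: p bases completing the running codon, the intron,
  # and the spill into the next exon
  exk_seq <- substr(locus$sequence, hit_k$target_interval[1L] + 1L, i_start)
  tail_p <- if (p > 0L) substr(exk_seq, nchar(exk_seq) - p + 1L,
                               nchar(exk_seq)) else ""
  spill <- (3L - p) %% 3L
  head_next <- if (spill > 0L) substr(locus$sequence, i_end + 1L,
                                      i_end + spill) else ""
  ctx <- paste0(tail_p, substr(locus$sequence, i_start + 1L, i_end), head_next)
  aa <- translate_cds(ctx)
  if (grepl("*", aa, fixed = TRUE)) return(NULL)
  structure(list(upstream_exon = hit_k$exon_number,
                 downstream_exon = hit_k1$exon_number,
                 intron_length = intron_len,
                 incorporated_residues = intron_len %/% 3L,
                 in_frame = TRUE),
            class = "fusion_call")
}

#' Scan for a rescuing alternative splice site
#'
#' When a splice flank is mutated, searches within `window` nt of the
#' original boundary for the nearest canonical dinucleotide (GT for a
#' donor, AG for an acceptor) whose use would shift the exon's contribution
#' by a multiple of 3 and introduce no new in-frame STOP. A replacement for
#' full splice-model prediction: proximity, frame and STOP constraints
#' only.
#'
#' @param locus Oriented [target_locus()].
#' @param hit The `exon_hit` whose flank is mutated.
#' @param side `"donor"` or `"acceptor"`.
#' @param window Search half-width in nt (default 30).
#' @param model The reference [gene_model()] (for frame bookkeeping).
#' @param frame_shift Net observed indel shift upstream of the exon.
#' @return The signed offset (nt) of the rescue boundary relative to the
#'   original, or `NULL` when none qualifies.
#' @export
scan_rescue_splice_site <- function(locus, hit, side = c("donor", "acceptor"),
                                    window = 30L, model = NULL,
                                    frame_shift = 0L) {
  side <- match.arg(side)
  L <- nchar(locus$sequence)
  boundary <- if (side == "donor") hit$target_interval[2L]
              else hit$target_interval[1L]
  want <- if (side == "donor") "GT" else "AG"
  cand <- integer(0)
  for (d in setdiff(seq.int(-window, window), 0L)) {
    if (d %% 3L != 0L) next  # frame must be preserved
    pos <- boundary + d  # 0-based position of the shifted boundary
    dinuc_start <- if (side == "donor") pos else pos - 2L
    if (dinuc_start < 0L || dinuc_start + 2L > L) next
    if (substr(locus$sequence, dinuc_start + 1L, dinuc_start + 2L) != want)
      next
    # an extension pulls intronic bases into the exon; check for new STOPs
    if ((side == "donor" && d > 0L) || (side == "acceptor" && d < 0L)) {
      if (!is.null(model)) {
        idx <- which(vapply(model$exons, `[[`, 1L, "exon_number") ==
                       hit$exon_number)
        if (side == "donor") {
          exon_seq <- substr(locus$sequence, hit$target_interval[1L] + 1L,
                             boundary + d)
          f0 <- (model$exons[[idx]]$phase + (frame_shift %% 3L)) %% 3L
          aa <- translate_cds(exon_seq, phase = (3L - f0) %% 3L)
        } else {
          exon_seq <- substr(locus$sequence, boundary + d + 1L,
                             hit$target_interval[2L])
          f0 <- (model$exons[[idx]]$phase + (frame_shift %% 3L) + d) %% 3L
          aa <- translate_cds(exon_seq, phase = (3L - f0) %% 3L)
        }
        if (grepl("*", aa, fixed = TRUE)) next
      }
    }
    cand <- c(cand, d)
  }
  if (length(cand) == 0L) return(NULL)
  cand[order(abs(cand), cand)][1L]
}

#' Assemble the predicted coding sequence
#'
#' Concatenates the observed exon slices in order, splicing in the retained
#' intron for every fusion call, translates from the start exon and reports
#' whether the ORF is continuous (exactly one STOP, at the final codon).
#'
#' @param hits List of `exon_hit`.
#' @param lesions Lesion data frame (unused for assembly itself; retained
#'   so reporting stays traceable to one call).
#' @param fusions List of `fusion_call`.
#' @param model The reference [gene_model()].
#' @param locus Oriented [target_locus()].
#' @return List `cds`, `orf_continuous`, `first_premature_stop` (1-based nt
#'   position of the first premature STOP codon in the assembled CDS, or
#'   `NA`).
#' @export
assemble_cds <- function(hits, lesions = NULL, fusions = list(), model,
                         locus) {
  if (!any(vapply(hits, `[[`, TRUE, "found")))
    stop("no assembly possible: no exon of the model was found in the locus")
  fused_after <- vapply(fusions, `[[`, 1L, "upstream_exon")
  parts <- character(0)
  for (i in model$start_exon:model$stop_exon) {
    h <- hits[[i]]
    if (!h$found) next
    parts <- c(parts, substr(locus$sequence, h$target_interval[1L] + 1L,
                             h$target_interval[2L]))
    if (h$exon_number %in% fused_after && i < length(hits) &&
        hits[[i + 1L]]$found) {
      parts <- c(parts, substr(locus$sequence, h$target_interval[2L] + 1L,
                               hits[[i + 1L]]$target_interval[1L]))
    }
  }
  cds <- paste(parts, collapse = "")
  aa <- translate_cds(cds)
  stops <- gregexpr("*", aa, fixed = TRUE)[[1L]]
  has_stop <- !identical(as.integer(stops), -1L)
  orf_continuous <- has_stop && length(stops) == 1L && stops[1L] == nchar(aa)
  first_premature <- if (has_stop && stops[1L] < nchar(aa))
    (stops[1L] - 1L) * 3L + 1L else NA_integer_
  list(cds = cds, orf_continuous = orf_continuous,
       first_premature_stop = first_premature)
}

#' Per-gene verdict for one species
#'
#' Applies the verdict logic of a comparative integrity matrix:
#' `INCOMPLETE` when an exon is unresolved because of assembly gaps or
#' locus truncation; otherwise `PSEUDOGENE` when a disrupting lesion
#' survives fusion/rescue reconciliation or the assembled ORF is not
#' continuous; otherwise `INTACT_FUSION` when a fusion call is present;
#' otherwise `INTACT`. A pseudogene called on splice evidence alone carries
#' the confidence flag `"splice_only"`.
#'
#' @param hits List of `exon_hit`.
#' @param lesions Lesion data frame (post reconciliation).
#' @param fusions List of `fusion_call`.
#' @param quality [locus_quality()] result.
#' @param assembly [assemble_cds()] result, or `NULL` when nothing
#'   assembled.
#' @param species_id,gene_id Labels for the verdict.
#' @return A list of class `gene_verdict` with fields `species_id`,
#'   `gene_id`, `status`, `confidence`, `lesions`, `fusions`, `cds`.
#' @export
classify_gene <- function(hits, lesions, fusions = list(),
                          quality = list(has_gap = FALSE), assembly = NULL,
                          species_id = "", gene_id = "") {
  missing_exons <- !vapply(hits, `[[`, TRUE, "found")
  status <- NULL
  confidence <- ""
  if (any(missing_exons) && isTRUE(quality$has_gap)) {
    status <- "INCOMPLETE"
  } else {
    disrupting <- lesions[lesions$disrupting, , drop = FALSE]
    orf_ok <- is.null(assembly) || isTRUE(assembly$orf_continuous)
    if (nrow(disrupting) > 0L || !orf_ok) {
      status <- "PSEUDOGENE"
      if (nrow(disrupting) > 0L &&
          all(disrupting$kind %in% c("SPLICE_DONOR_MUT",
                                     "SPLICE_ACCEPTOR_MUT")) && orf_ok)
        confidence <- "splice_only"
    } else if (length(fusions) > 0L) {
      status <- "INTACT_FUSION"
    } else {
      status <- "INTACT"
    }
  }
  structure(list(species_id = species_id, gene_id = gene_id,
                 status = status, confidence = confidence,
                 lesions = lesions, fusions = fusions,
                 cds = if (status %in% c("INTACT", "INTACT_FUSION") &&
                           !is.null(assembly)) assembly$cds else NA_character_),
            class = "gene_verdict")
}

#' @export
print.gene_verdict <- function(x, ...) {
  cat(sprintf("<gene_verdict> %s / %s: %s%s — %d lesion(s), %d fusion(s)\n",
              x$species_id, x$gene_id, x$status,
              if (nzchar(x$confidence)) paste0(" [", x$confidence, "]") else "",
              nrow(x$lesions), length(x$fusions)))
  invisible(x)
}

#' Evaluate one locus end to end
#'
#' Orientation, exon location, lesion calling, fusion detection,
#' rescue-site reconciliation, CDS assembly and verdict in one call — the
#' per-species unit of the comparative screen.
#'
#' A splice lesion whose boundary participates in a fusion call, or for
#' which a rescue site is found, is downgraded to non-disrupting but kept
#' in the report.
#'
#' @param model Reference [gene_model()].
#' @param locus A [target_locus()].
#' @param min_identity Minimum exon-hit identity.
#' @param params [score_params()].
#' @param rescue_window Half-width (nt) of the rescue-site scan.
#' @param orient Resolve orientation first (set `FALSE` for loci known to
#'   be on the gene strand).
#' @param terminal_stop_grace See [call_exon_lesions()].
#' @return A `gene_verdict`; `status = "INCOMPLETE"` with no hits when no
#'   gene is found but the locus contains assembly gaps.
#' @export
evaluate_locus <- function(model, locus, min_identity = 0.6,
                           params = score_params(), rescue_window = 30L,
                           orient = TRUE, terminal_stop_grace = 30L) {
  if (orient) locus <- orient_locus(locus, model, params, min_identity)
  quality <- locus_quality(locus)
  hits <- locate_exons(model, locus, min_identity, params)
  lesions <- call_locus_lesions(hits, model, terminal_stop_grace)

  # fusion detection for each mutated donor between adjacent found exons
  fusions <- list()
  shift <- 0L
  shifts_before <- integer(length(hits))
  for (i in seq_along(hits)) {
    shifts_before[i] <- shift
    h <- hits[[i]]
    if (!h$found) { shift <- shift - nchar(model$exons[[i]]$sequence); next }
    les_i <- lesions[lesions$exon_number == h$exon_number &
                     lesions$kind %in% c("FRAMESHIFT_INDEL", "INFRAME_INDEL"), ,
                     drop = FALSE]
    shift <- shift + sum(nchar(les_i$observed) - nchar(les_i$reference))
    if (i < length(hits) && h$found && hits[[i + 1L]]$found) {
      fc <- detect_exon_fusion(locus, h, hits[[i + 1L]], model,
                               frame_shift = shift)
      if (!is.null(fc)) fusions[[length(fusions) + 1L]] <- fc
    }
  }

  # reconcile splice lesions with fusions and rescue sites
  if (nrow(lesions) > 0L) {
    fused_after <- vapply(fusions, `[[`, 1L, "upstream_exon")
    for (r in seq_len(nrow(lesions))) {
      les <- lesions[r, ]
      if (!les$kind %in% c("SPLICE_DONOR_MUT", "SPLICE_ACCEPTOR_MUT")) next
      if (les$kind == "SPLICE_DONOR_MUT" && les$exon_number %in% fused_after) {
        lesions$disrupting[r] <- FALSE
        lesions$note[r] <- "rescued_by_fusion"
        next
      }
      i <- which(vapply(hits, `[[`, 1L, "exon_number") == les$exon_number)
      side <- if (les$kind == "SPLICE_DONOR_MUT") "donor" else "acceptor"
      resc <- scan_rescue_splice_site(locus, hits[[i]], side,
                                      window = rescue_window, model = model,
                                      frame_shift = shifts_before[i])
      if (!is.null(resc)) {
        lesions$disrupting[r] <- FALSE
        lesions$note[r] <- sprintf("rescue_site_%+d", resc)
      }
    }
  }

  assembly <- if (any(vapply(hits, `[[`, TRUE, "found")))
    assemble_cds(hits, lesions, fusions, model, locus) else NULL
  classify_gene(hits, lesions, fusions, quality, assembly,
                species_id = locus$species_id, gene_id = model$gene_id)
}
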