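# Scoring detected lesions and verdicts against simulator truth.

# Expected detectable lesion set for one species, derived from its
# inherited planted events with frame bookkeeping: a planted premature
# STOP, or a fusion, is only detectable in its planted form when the
# reading frame at its exon is unshifted by upstream planted events.
expected_detections <- function(events, model) {
  exnums <- vapply(model$exons, `[[`, 1L, "exon_number")
  ord <- order(vapply(events, `[[`, 1L, "exon_number"))
  events <- events[ord]
  shift <- 0L
  rows <- list()
  fusion_exons <- integer(0)
  for (ev in events) {
    kind <- ev$kind
    inframe_here <- shift %% 3L == 0L
    if (kind == "PREMATURE_STOP") {
      if (inframe_here)
        rows[[length(rows) + 1L]] <- list(kind = kind, exon = ev$exon_number)
    } else if (kind == "EXON_FUSION") {
      if (inframe_here)
        fusion_exons <- c(fusion_exons, ev$exon_number)
      else
        rows[[length(rows) + 1L]] <- list(kind = "SPLICE_DONOR_MUT",
                                          exon = ev$exon_number)
    } else if (kind == "EXON_DELETION") {
      rows[[length(rows) + 1L]] <- list(kind = "EXON_MISSING",
                                        exon = ev$exon_number)
      shift <- shift - nchar(model$exons[[which(exnums == ev$exon_number)]]$sequence)
    } else {
      rows[[length(rows) + 1L]] <- list(kind = kind, exon = ev$exon_number)
      if (kind %in% c("FRAMESHIFT_INDEL", "INFRAME_INDEL")) {
        net <- if (identical(ev$detail$op, "ins")) nchar(ev$detail$sequence)
               else -ev$detail$length
        shift <- shift + net
      }
    }
  }
  list(lesions = rows, fusion_exons = fusion_exons)
}

# Truth verdict for one species from its inherited planted events.
truth_status <- function(events) {
  kinds <- vapply(events, `[[`, "", "kind")
  disrupting <- c("SPLICE_DONOR_MUT", "SPLICE_ACCEPTOR_MUT",
                  "FRAMESHIFT_INDEL", "PREMATURE_STOP", "EXON_DELETION")
  if (any(kinds %in% disrupting)) "PSEUDOGENE"
  else if (any(kinds == "EXON_FUSION")) "INTACT_FUSION"
  else "INTACT"
}

#' Score lesion and verdict recovery against simulator truth
#'
#' Matches detected lesions (and fusion calls) to the planted events each
#' species inherited, at the (kind, exon) level. Premature-STOP lesions
#' tagged as frameshift consequences are attributed to their upstream
#' frameshift and excluded from the precision denominator, as are
#' splice lesions downgraded by fusion; everything else detected must
#' correspond to a planted event to count as a true positive.
#'
#' @param verdicts Named list of `gene_verdict` (one per species).
#' @param truth The matching `sim_truth`.
#' @param model The reference [gene_model()].
#' @return List with `lesion_sensitivity`, `lesion_precision`,
#'   `verdict_accuracy`, `n_expected`, `n_detected`, and a per-species
#'   data frame `details`.
#' @export
score_recovery <- function(verdicts, truth, model) {
  tp <- 0L; fn <- 0L; fp <- 0L
  verdict_ok <- logical(0)
  details <- list()
  for (sp in names(truth$per_species)) {
    v <- verdicts[[sp]]
    exp <- expected_detections(truth$per_species[[sp]]$events, model)
    want <- vapply(exp$lesions, function(x) paste(x$kind, x$exon), "")
    got_lesions <- v$lesions
    got_keep <- got_lesions[!(got_lesions$note %in%
                                c("frameshift_consequence",
                                  "rescued_by_fusion")), , drop = FALSE]
    got <- paste(got_keep$kind, got_keep$exon_number)
    got_fusions <- vapply(v$fusions, `[[`, 1L, "upstream_exon")
    tp_sp <- sum(want %in% got) +
      sum(exp$fusion_exons %in% got_fusions)
    fn_sp <- sum(!want %in% got) +
      sum(!exp$fusion_exons %in% got_fusions)
    fp_sp <- sum(!got %in% want) +
      sum(!got_fusions %in% exp$fusion_exons)
    tp <- tp + tp_sp; fn <- fn + fn_sp; fp <- fp + fp_sp
    ok <- identical(v$status, truth_status(truth$per_species[[sp]]$events))
    verdict_ok <- c(verdict_ok, ok)
    details[[length(details) + 1L]] <- data.frame(
      species = sp, expected = length(want) + length(exp$fusion_exons),
      tp = tp_sp, fn = fn_sp, fp = fp_sp,
      status = v$status, status_ok = ok)
  }
  list(lesion_sensitivity = if (tp + fn > 0L) tp / (tp + fn) else 1,
       lesion_precision = if (tp + fp > 0L) tp / (tp + fp) else 1,
       verdict_accuracy = mean(verdict_ok),
       n_expected = tp + fn, n_detected = tp + fp,
       details = do.call(rbind, details))
}

#' Random validation scenario with planted events
#'
#' Draws a random ultrametric-ish tree and plants events of the requested
#' kinds on distinct branches and well-separated exons, the configuration
#' used to validate planted-event recovery. Exons are chosen at least two
#' apart so events never collide (a deleted exon is never re-edited, a
#' fusion intron is never touched by a neighbouring acceptor mutation).
#'
#' @param model Reference [gene_model()].
#' @param seed Integer seed.
#' @param n_tips Number of species.
#' @param kinds Event kinds to plant (one each, in order).
#' @return List with `tree` (newick string) and `planted`.
#' @export
random_recovery_scenario <- function(model, seed, n_tips = 8L,
                                     kinds = c("SPLICE_DONOR_MUT",
                                               "SPLICE_ACCEPTOR_MUT",
                                               "FRAMESHIFT_INDEL",
                                               "PREMATURE_STOP")) {
  exnums <- vapply(model$exons, `[[`, 1L, "exon_number")
  n_ex <- length(exnums)
  with_seed(seed, {
    tree <- ape::rtree(n_tips, tip.label = paste0("sp", seq_len(n_tips)),
                       br = function(n) stats::runif(n, 0.5, 1.5))
    tree$node.label <- paste0("N", seq_len(tree$Nnode))
    branches <- c(tree$tip.label, tree$node.label[-1L])  # root has no edge
    picks <- sample(branches, length(kinds))
    # internal exons on an every-other grid, so events are >= 2 exons apart
    pool <- exnums[seq(3L, n_ex - 1L, by = 2L)]
    exons <- sample(pool, length(kinds))
    planted <- vector("list", length(kinds))
    for (k in seq_along(kinds)) {
      planted[[k]] <- switch(kinds[k],
        SPLICE_DONOR_MUT = splice_event(picks[k], exons[k], "donor", "AT"),
        SPLICE_ACCEPTOR_MUT = splice_event(picks[k], exons[k], "acceptor",
                                           "GG"),
        FRAMESHIFT_INDEL = indel_event(picks[k], exons[k],
                                       offset = 20L, "del", length = 1L),
        INFRAME_INDEL = indel_event(picks[k], exons[k], offset = 20L,
                                    "del", length = 3L),
        PREMATURE_STOP = stop_event(model, picks[k], exons[k]),
        EXON_DELETION = deletion_event(picks[k], exons[k]),
        EXON_FUSION = fusion_event(model, picks[k], exons[k],
                                   intron_length = 99L,
                                   seed = derive_seed(seed, picks[k])))
    }
    list(tree = ape::write.tree(tree), planted = planted)
  })
}

#' Planted-event recovery benchmark
#'
#' Simulates loci over repeated random scenarios until `n_loci` species
#' loci have been evaluated, cycling the event kinds so that all seven are
#' represented, then scores lesion- and verdict-level recovery against the
#' truth logs. Every fourth locus is reverse-complemented before
#' evaluation so strand resolution is exercised too.
#'
#' @param n_loci Total number of species loci to evaluate.
#' @param sub_rate Background substitution rate.
#' @param indel_rate Background (intronic) indel rate.
#' @param seed Integer seed.
#' @param model Optional [gene_model()]; one is generated from `seed` when
#'   absent.
#' @param n_tips Species per scenario.
#' @return Aggregate list: `lesion_sensitivity`, `lesion_precision`,
#'   `verdict_accuracy`, `n_expected`, `n_loci`, `kinds_covered`.
#' @export
run_recovery_benchmark <- function(n_loci = 200L, sub_rate = 0,
                                   indel_rate = 0, seed = 1L, model = NULL,
                                   n_tips = 8L) {
  if (is.null(model))
    model <- build_reference_model(seed = derive_seed(seed, "refmodel"))
  kind_sets <- list(
    c("SPLICE_DONOR_MUT", "SPLICE_ACCEPTOR_MUT", "FRAMESHIFT_INDEL",
      "PREMATURE_STOP"),
    c("INFRAME_INDEL", "EXON_DELETION", "EXON_FUSION", "SPLICE_DONOR_MUT"))
  tp <- 0L; fn <- 0L; fp <- 0L; n_ok <- 0L; n_done <- 0L
  covered <- character(0)
  rep_i <- 0L
  while (n_done < n_loci) {
    rep_i <- rep_i + 1L
    kinds <- kind_sets[[(rep_i - 1L) %% 2L + 1L]]
    sc <- random_recovery_scenario(model, derive_seed(seed, paste0("scn", rep_i)),
                                   n_tips = n_tips, kinds = kinds)
    sim <- evolve_along_tree(model, sc$tree, sub_rate, indel_rate,
                             planted = sc$planted,
                             seed = derive_seed(seed, paste0("sim", rep_i)))
    loci <- sim$loci
    flip <- seq_along(loci) %% 4L == 0L
    for (i in which(flip)) loci[[i]]$sequence <- revcomp(loci[[i]]$sequence)
    verdicts <- lapply(loci, function(l) evaluate_locus(model, l))
    sc_res <- score_recovery(verdicts, sim$truth, model)
    d <- sc_res$details
    tp <- tp + sum(d$tp); fn <- fn + sum(d$fn); fp <- fp + sum(d$fp)
    n_ok <- n_ok + sum(d$status_ok)
    n_done <- n_done + nrow(d)
    covered <- union(covered, vapply(sc$planted, `[[`, "", "kind"))
  }
  list(lesion_sensitivity = tp / (tp + fn),
       lesion_precision = tp / (tp + fp),
       verdict_accuracy = n_ok / n_done,
       n_expected = tp + fn, n_detected = tp + fp, n_loci = n_done,
       kinds_covered = sort(covered))
}
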