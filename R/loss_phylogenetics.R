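# Shared-lesion signatures and Dollo-parsimony mapping of gene loss.

#' Canonical lesion signature
#'
#' Two lesions in different species are evidence for a single ancestral
#' event exactly when their canonical signatures are equal: same gene,
#' exon, kind, observed sequence, and offset bucket. Offsets are bucketed
#' by `offset_tolerance` (0 for splice-site lesions, whose position is the
#' exon boundary itself; 3 nt by default for indels, absorbing
#' assembly-specific wobble in gap placement).
#'
#' @param lesion One lesion row (as produced by [call_locus_lesions()]).
#' @param gene_id Gene label.
#' @param offset_tolerance Bucket width (nt) for indel/STOP offsets.
#' @return A single string, the canonical signature.
#' @export
lesion_signature <- function(lesion, gene_id = "",
                             offset_tolerance = 3L) {
  splice <- lesion$kind %in% c("SPLICE_DONOR_MUT", "SPLICE_ACCEPTOR_MUT")
  tol <- if (splice) 0L else as.integer(offset_tolerance)
  bucket <- if (splice) "boundary"
            else if (tol > 0L) as.character(lesion$offset %/% tol)
            else as.character(lesion$offset)
  sprintf("%s|exon%d|%s|%s|%s", gene_id, lesion$exon_number, lesion$kind,
          bucket, lesion$observed)
}

#' Signatures of all disrupting lesions of a verdict
#'
#' @param verdict A `gene_verdict`.
#' @param offset_tolerance See [lesion_signature()].
#' @return Character vector of signatures (disrupting lesions only).
#' @export
verdict_signatures <- function(verdict, offset_tolerance = 3L) {
  les <- verdict$lesions
  # primary disrupting lesions only: STOPs that merely ride on an upstream
  # frameshift are derived consequences, not shareable evidence
  les <- les[les$disrupting & les$note != "frameshift_consequence", ,
             drop = FALSE]
  if (nrow(les) == 0L) return(character(0))
  vapply(seq_len(nrow(les)), function(r)
    lesion_signature(les[r, ], verdict$gene_id, offset_tolerance), "")
}

# Count the minimum number of gain-only (Dollo) events explaining the
# carrier tips: the number of maximal subtrees whose (non-excluded) tips
# are all carriers and contain at least one carrier. Excluded tips
# (e.g. INCOMPLETE genomes) are compatible with either state.
dollo_gain_count <- function(tree, carriers, excluded = character(0)) {
  n_tip <- length(tree$tip.label)
  unknown_tips <- match(excluded, tree$tip.label)
  carrier_tips <- match(carriers, tree$tip.label)
  if (anyNA(carrier_tips))
    stop("carrier species absent from tree: ",
         paste(carriers[is.na(carrier_tips)], collapse = ", "))
  n_node <- n_tip + tree$Nnode
  pure <- logical(n_node)      # all informative tips below are carriers
  has_carrier <- logical(n_node)
  pure[seq_len(n_tip)] <- seq_len(n_tip) %in% c(carrier_tips, unknown_tips)
  has_carrier[seq_len(n_tip)] <- seq_len(n_tip) %in% carrier_tips
  pure[(n_tip + 1L):n_node] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    pure[p] <- pure[p] && pure[ch]
    has_carrier[p] <- has_carrier[p] || has_carrier[ch]
  }
  # gain points: pure subtrees with >= 1 carrier, maximal (parent impure)
  parent <- integer(n_node)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- n_tip + 1L
  gain_nodes <- integer(0)
  for (v in seq_len(n_node)) {
    if (!pure[v] || !has_carrier[v]) next
    if (v == root || !pure[parent[v]]) gain_nodes <- c(gain_nodes, v)
  }
  list(n_events = length(gain_nodes), gain_nodes = gain_nodes)
}

#' Map shared lesion signatures onto a species tree
#'
#' For every distinct signature, finds the carriers' most recent common
#' ancestor and the minimum number of independent origins under Dollo
#' parsimony (the derived state can be gained but never reverted): if the
#' carriers are monophyletic the signature is explained by a single event
#' at their MRCA, otherwise by one event per maximal carrier-only clade.
#'
#' @param signatures_by_species Named list: per species, a character vector
#'   of lesion signatures (see [verdict_signatures()]).
#' @param tree A phylo object / newick string / file.
#' @return Data frame with one row per signature: `signature`, `carriers`
#'   (comma-separated), `n_carriers`, `placement_node` (MRCA label),
#'   `n_events`, `monophyletic`.
#' @export
map_events_on_tree <- function(signatures_by_species, tree) {
  tree <- resolve_tree(tree)
  missing <- setdiff(names(signatures_by_species), tree$tip.label)
  if (length(missing) > 0L)
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  sigs <- unique(unlist(signatures_by_species))
  if (length(sigs) == 0L)
    return(data.frame(signature = character(0), carriers = character(0),
                      n_carriers = integer(0), placement_node = character(0),
                      n_events = integer(0), monophyletic = logical(0)))
  rows <- lapply(sigs, function(sg) {
    carriers <- names(signatures_by_species)[vapply(signatures_by_species,
                                                    function(v) sg %in% v,
                                                    TRUE)]
    tipn <- match(carriers, tree$tip.label)
    mrca <- if (length(tipn) == 1L) tipn else ape::getMRCA(tree, tipn)
    dc <- dollo_gain_count(tree, carriers)
    data.frame(signature = sg,
               carriers = paste(sort(carriers), collapse = ","),
               n_carriers = length(carriers),
               placement_node = node_label(tree, mrca),
               n_events = dc$n_events,
               monophyletic = dc$n_events == 1L)
  })
  do.call(rbind, rows)
}

#' Minimum independent gene-loss events on a tree
#'
#' Treats "pseudogene" as an irreversibly gained character (Dollo: a lost
#' gene is never regained) and counts the minimum number of loss events
#' explaining the observed per-species statuses. INCOMPLETE tips are
#' compatible with either state and never force an extra event.
#'
#' @param statuses Named character vector of per-species statuses
#'   (`INTACT`, `INTACT_FUSION`, `PSEUDOGENE`, `INCOMPLETE`, or the codes
#'   I/F/P/U).
#' @param tree A phylo object / newick string / file.
#' @return List with `n_events`, `stem_branches` (labels of the nodes
#'   subtending each inferred loss), and `carriers`.
#' @export
min_loss_events <- function(statuses, tree) {
  tree <- resolve_tree(tree)
  if (length(tree$tip.label) == 0L) stop("empty tree")
  st <- toupper(statuses)
  st[st == "P"] <- "PSEUDOGENE"; st[st == "U"] <- "INCOMPLETE"
  st[st == "I"] <- "INTACT"; st[st == "F"] <- "INTACT_FUSION"
  carriers <- names(st)[st == "PSEUDOGENE"]
  excluded <- names(st)[st == "INCOMPLETE"]
  if (length(carriers) == 0L)
    return(list(n_events = 0L, stem_branches = character(0),
                carriers = character(0)))
  dc <- dollo_gain_count(tree, carriers, excluded)
  list(n_events = dc$n_events,
       stem_branches = vapply(dc$gain_nodes, function(v)
         node_label(tree, v), ""),
       carriers = carriers)
}

#' Annotate a tree with event placements
#'
#' Writes a newick string whose node labels carry `#loss` marks at the stem
#' of every inferred loss event.
#'
#' @param tree A phylo object / newick string / file.
#' @param stem_branches Labels of loss stems (from [min_loss_events()]).
#' @return Newick string.
#' @export
annotate_loss_tree <- function(tree, stem_branches) {
  tree <- resolve_tree(tree)
  n_tip <- length(tree$tip.label)
  tree$tip.label <- ifelse(tree$tip.label %in% stem_branches,
                           paste0(tree$tip.label, "#loss"), tree$tip.label)
  tree$node.label <- ifelse(tree$node.label %in% stem_branches,
                            paste0(tree$node.label, "#loss"),
                            tree$node.label)
  ape::write.tree(tree)
}
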