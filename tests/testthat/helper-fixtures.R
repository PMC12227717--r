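# Shared fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

fixture_model <- function() {
  if (is.null(.fix$model)) .fix$model <- build_reference_model(seed = 3L)
  .fix$model
}

# Four-clade scenario exercising splice mutation, fusion, premature STOP
# and exon deletion, at zero background rates.
fixture_sim0 <- function() {
  if (is.null(.fix$sim0)) {
    m <- fixture_model()
    tree <- "((A:1,B:1)AB:1,((C:1,D:1)CD:1,(E:1,F:1)EF:1)N2:1)R;"
    planted <- list(
      splice_event("AB", 5, "donor", "AT"),
      stop_event(m, "D", 8),
      fusion_event(m, "EF", 11, intron_length = 99L, seed = 5L),
      indel_event("B", 9, offset = 40L, "del", length = 1L))
    .fix$sim0 <- c(evolve_along_tree(m, tree, 0, 0, planted, seed = 11L),
                   list(tree = tree, planted = planted))
  }
  .fix$sim0
}

random_codon <- function() {
  repeat {
    cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                 collapse = "")
    if (!cod %in% c("TAA", "TAG", "TGA")) return(cod)
  }
}

# Independent brute-force NG86 oracle: recursive pathway enumeration over
# orderings of differing positions, STOP-blocked paths dropped.
oracle_codon_diffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  diff <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diff) == 0) return(c(nd = 0, sd = 0))
  paths <- list()
  recurse <- function(cur, remaining, nd, sd) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- c(nd, sd)
      return(NULL)
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% stops) next
      step_syn <- code[[nxt]] == code[[cur]]
      recurse(nxt, setdiff(remaining, p), nd + !step_syn, sd + step_syn)
    }
  }
  recurse(c1, diff, 0, 0)
  if (length(paths) == 0) return(c(nd = NA_real_, sd = NA_real_))
  m <- do.call(rbind, paths)
  c(nd = mean(m[, 1]), sd = mean(m[, 2]))
}

oracle_site_counts <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  s <- 0
  for (pos in 1:3) {
    syn <- 0; tot <- 0
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (mut %in% stops) next
      tot <- tot + 1
      if (code[[mut]] == code[[codon]]) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  c(n = 3 - s, s = s)
}

# Brute-force minimum Dollo gain count: smallest set of edges (root
# allowed as a pseudo-edge) whose covered tips include every carrier and
# no intact tip; excluded tips are free.
oracle_dollo_min <- function(tree, carriers, excluded = character(0)) {
  n_tip <- length(tree$tip.label)
  tipmask <- function(tips) sum(bitwShiftL(1L, tips - 1L))
  edge_sets <- vapply(seq_len(nrow(tree$edge)), function(e) {
    below <- genloss:::tip_descendants(tree, tree$edge[e, 2])
    tipmask(below)
  }, 1L)
  edge_sets <- c(edge_sets, tipmask(seq_len(n_tip)))
  carrier_mask <- tipmask(match(carriers, tree$tip.label))
  intact <- setdiff(seq_len(n_tip),
                    match(c(carriers, excluded), tree$tip.label))
  intact_mask <- tipmask(intact)
  if (carrier_mask == 0L) return(0L)
  k <- length(edge_sets)
  best <- Inf
  union_of <- integer(2^k)
  pop <- integer(2^k)
  for (m in seq_len(2^k - 1)) {
    low <- bitwAnd(m, -m)
    idx <- as.integer(log2(low)) + 1L
    rest <- bitwAnd(m, m - 1L)
    union_of[m + 1L] <- bitwOr(union_of[rest + 1L], edge_sets[idx])
    pop[m + 1L] <- pop[rest + 1L] + 1L
    u <- union_of[m + 1L]
    if (pop[m + 1L] < best &&
        bitwAnd(u, carrier_mask) == carrier_mask &&
        bitwAnd(u, intact_mask) == 0L)
      best <- pop[m + 1L]
  }
  best
}
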