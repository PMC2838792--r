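#' Parsimony score of a tree over individuals
#'
#' Sums, over behavioral characters, the minimum number of state changes the
#' tree requires. Dichotomous traits are scored as unordered characters
#' (Fitch); ordinal severity traits as ordered characters with step cost
#' `|i - j|` (Wagner), unless `ordered_ordinal = FALSE`. Missing states are
#' free: they are assigned whatever state minimizes tree length. The score is
#' invariant to rooting.
#'
#' @param tree an ape `phylo` whose tip labels are individual keys
#'   (`"family/id"`) present in `traits`.
#' @param traits a [trait_matrix()].
#' @param ordered_ordinal score ordinal traits as ordered (default).
#' @param per_character return the per-character change counts instead of the
#'   total.
#' @return total number of changes (or a named per-character vector).
#' @export
parsimony_score <- function(tree, traits, ordered_ordinal = TRUE,
                            per_character = FALSE) {
  ct <- phylo_to_ct(tree)
  dat <- prepare_chars(traits, ct$labels, ordered_ordinal)
  if (per_character)
    setNames(ct_score_per_char(ct, dat), colnames(traits))
  else
    ct_score(ct, dat)
}

new_pheno_treeset <- function(cts, score, labels) {
  trees <- lapply(cts, ct_to_phylo)
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, score = score, labels = labels),
            class = "pheno_treeset")
}

#' @export
print.pheno_treeset <- function(x, ...) {
  cat("Equally parsimonious tree set:", length(x$trees), "tree(s) over",
      length(x$labels), "leaves; score", x$score, "\n")
  invisible(x)
}

# collapse identical symptom profiles to one representative leaf;
# returns representative labels and the member groups
profile_groups <- function(traits, labels) {
  st <- unclass(traits)[labels, , drop = FALSE]
  key <- apply(st, 1, function(r) paste(ifelse(is.na(r), "?", r),
                                        collapse = ""))
  split(labels, factor(key, levels = unique(key)))
}

# re-expand a searched tree over representatives to the full leaf set:
# a representative with k > 1 identical members becomes a fan of k leaves
ct_expand <- function(ct, groups, all_labels) {
  n_full <- length(all_labels)
  old_max <- max(ct$edge)
  remap_internal <- function(v) n_full + (v - ct$n_leaf)
  next_id <- n_full + (old_max - ct$n_leaf) + 1L
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(ct$edge))) {
    a <- ct$edge[i, 1]; b <- ct$edge[i, 2]
    a2 <- remap_internal(a)           # parents are always internal
    if (b > ct$n_leaf) {
      edges <- rbind(edges, c(a2, remap_internal(b)))
    } else {
      members <- groups[[b]]
      ids <- match(members, all_labels)
      if (length(ids) == 1) {
        edges <- rbind(edges, c(a2, ids))
      } else {
        fan <- next_id; next_id <- next_id + 1L
        edges <- rbind(edges, c(a2, fan), cbind(fan, ids))
      }
    }
  }
  ct_new(edges, n_full, all_labels)
}

star_ct <- function(labels) {
  n <- length(labels)
  root <- n + 1L
  ct_new(cbind(root, seq_len(n)), n, labels)
}

#' Heuristic ratchet search for most-parsimonious trees
#'
#' Implements the parsimony ratchet: iterations alternate a hill-climbing
#' search on a randomly up-weighted subset of characters with a search on the
#' original weights, escaping local optima while retaining all distinct
#' minimal-length trees encountered. Identical symptom profiles are collapsed
#' to a single leaf during the search and re-expanded afterwards (this cannot
#' change the score).
#'
#' @param traits a [trait_matrix()]; all rows become leaves.
#' @param n_iterations ratchet iterations (default 200).
#' @param reweight_fraction fraction of characters up-weighted (x2) in the
#'   perturbed phase (default 0.25).
#' @param seed integer seed; fixed seeds give identical results.
#' @param move rearrangement scheme for the hill climbs, `"spr"` (default) or
#'   the cheaper `"nni"` for large leaf sets.
#' @param max_trees cap on retained equally parsimonious trees (default 1000).
#' @param ordered_ordinal score ordinal traits as ordered (default).
#' @return a `pheno_treeset`: distinct minimal-length trees and their score.
#' @export
ratchet_search <- function(traits, n_iterations = 200,
                           reweight_fraction = 0.25, seed = NULL,
                           move = c("spr", "nni"), max_trees = 1000,
                           ordered_ordinal = TRUE) {
  move <- match.arg(move)
  all_labels <- rownames(traits)
  with_seed(seed, {
    groups <- profile_groups(traits, all_labels)
    reps <- vapply(groups, `[`, "", 1)
    names(groups) <- NULL
    dat_full <- prepare_chars(traits, all_labels, ordered_ordinal)
    if (length(reps) < 4) {
      ct <- if (length(all_labels) < 2) {
        # single individual: a lone leaf hanging off a root
        ct_new(cbind(2L, 1L), 1L, all_labels)
      } else {
        st <- star_ct(reps)
        ct_expand(st, groups, all_labels)
      }
      return(new_pheno_treeset(list(ct), ct_score(ct, dat_full), all_labels))
    }
    dat <- prepare_chars(traits, reps, ordered_ordinal)
    n_char <- ncol(dat$states)
    w0 <- rep(1, n_char)

    pool <- list()
    pool_keys <- character(0)
    best <- Inf
    add_pool <- function(ct, s) {
      if (s < best - 1e-9) {
        best <<- s; pool <<- list(); pool_keys <<- character(0)
      }
      if (abs(s - best) < 1e-9 && length(pool) < max_trees) {
        k <- ct_key(ct)
        if (!(k %in% pool_keys)) {
          pool[[length(pool) + 1L]] <<- ct
          pool_keys <<- c(pool_keys, k)
        }
      }
    }

    cur <- ct_stepwise(reps, dat, ord = sample.int(length(reps)))
    res <- ct_hillclimb(cur, dat, move = move)
    add_pool(res$tree, res$score)
    for (t in res$ties) add_pool(t, res$score)
    cur <- res$tree

    n_up <- max(1L, floor(reweight_fraction * n_char))
    for (it in seq_len(n_iterations)) {
      w <- w0
      w[sample.int(n_char, n_up)] <- 2
      pert <- ct_hillclimb(cur, dat, weights = w, move = move)
      res <- ct_hillclimb(pert$tree, dat, move = move)
      add_pool(res$tree, res$score)
      for (t in res$ties) add_pool(t, res$score)
      cur <- res$tree
    }
    expanded <- lapply(pool, ct_expand, groups = groups,
                       all_labels = all_labels)
    new_pheno_treeset(expanded, ct_score(expanded[[1]], dat_full), all_labels)
  })
}

#' Refine a tree set by SPR branch swapping
#'
#' Subtree-prune-regraft hill climbing from each input tree, typically used
#' to improve resolution within a clade of the network. If `traits` covers
#' only a subset of the trees' leaves, trees are first restricted to that
#' subset.
#'
#' @param tree_set a `pheno_treeset` (or list of `phylo`).
#' @param traits a [trait_matrix()] restricted to the members of interest.
#' @param ordered_ordinal score ordinal traits as ordered (default).
#' @return a `pheno_treeset` with score no greater than the input's.
#' @export
spr_refine <- function(tree_set, traits, ordered_ordinal = TRUE) {
  trees <- if (inherits(tree_set, "pheno_treeset")) tree_set$trees
           else tree_set
  keep <- rownames(traits)
  pool <- list(); pool_keys <- character(0); best <- Inf
  for (phy in trees) {
    if (!all(keep %in% phy$tip.label))
      stop("trait matrix contains individuals absent from the trees")
    if (length(setdiff(phy$tip.label, keep)))
      phy <- ape::keep.tip(phy, keep)
    ct <- phylo_to_ct(phy)
    dat <- prepare_chars(traits, ct$labels, ordered_ordinal)
    res <- ct_hillclimb(ct, dat, move = "spr")
    cand <- c(list(res$tree), res$ties)
    for (t in cand) {
      s <- ct_score(t, dat)
      if (s < best - 1e-9) { best <- s; pool <- list(); pool_keys <- character(0) }
      if (abs(s - best) < 1e-9) {
        k <- ct_key(t)
        if (!(k %in% pool_keys)) {
          pool[[length(pool) + 1L]] <- t
          pool_keys <- c(pool_keys, k)
        }
      }
    }
  }
  new_pheno_treeset(pool, best, keep)
}

#' Majority-rule consensus of equally parsimonious trees
#'
#' Returns the tree containing exactly those bipartitions present in strictly
#' more than `threshold` of the input trees (51% minimum support by default),
#' with multifurcations where the input set is unresolved.
#'
#' @param tree_set a `pheno_treeset` or list of `phylo` with identical leaf
#'   sets.
#' @param threshold minimum support fraction (strict), default 0.51.
#' @return an ape `phylo`.
#' @export
majority_consensus <- function(tree_set, threshold = 0.51) {
  trees <- if (inherits(tree_set, "pheno_treeset")) tree_set$trees
           else tree_set
  stopifnot(length(trees) >= 1)
  labels <- sort(trees[[1]]$tip.label)
  ref <- labels[1]
  counts <- new.env(parent = emptyenv())
  for (phy in trees) {
    if (!setequal(phy$tip.label, labels))
      stop("trees have incompatible leaf sets")
    ct <- phylo_to_ct(phy)
    sets <- ct_leafsets(ct)
    internal <- setdiff(unique(ct$edge[, 2]), seq_len(ct$n_leaf))
    seen <- character(0)
    for (v in internal) {
      members <- ct$labels[sets[[v]]]
      if (ref %in% members) members <- setdiff(labels, members)
      if (length(members) < 2 || length(members) > length(labels) - 2) next
      k <- paste(sort(members), collapse = "\r")
      if (k %in% seen) next
      seen <- c(seen, k)
      counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
    }
  }
  n <- length(trees)
  keys <- ls(counts)
  kept <- keys[vapply(keys, function(k) counts[[k]] / n > threshold, TRUE)]
  clusters <- lapply(kept, function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  build_from_clusters(labels, clusters)
}

# assemble a tree from a laminar set of clusters (each excluding the
# reference leaf); root children are the maximal clusters plus stray leaves
build_from_clusters <- function(labels, clusters) {
  n <- length(labels)
  root <- n + 1L
  if (length(clusters)) {
    ord <- order(-lengths(clusters))
    clusters <- clusters[ord]
  }
  cl_id <- if (length(clusters)) n + 1L + seq_along(clusters) else integer(0)
  parent_cluster <- function(i) {
    ci <- clusters[[i]]
    cand <- which(vapply(seq_along(clusters), function(j)
      j != i && length(clusters[[j]]) > length(ci) &&
        all(ci %in% clusters[[j]]), TRUE))
    if (!length(cand)) return(root)
    cl_id[cand[which.min(lengths(clusters)[cand])]]
  }
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_along(clusters))
    edges <- rbind(edges, c(parent_cluster(i), cl_id[i]))
  for (l in seq_len(n)) {
    lab <- labels[l]
    cand <- which(vapply(clusters, function(cl) lab %in% cl, TRUE))
    p <- if (!length(cand)) root
         else cl_id[cand[which.min(lengths(clusters)[cand])]]
    edges <- rbind(edges, c(p, l))
  }
  # collapse a degree-2 root (unrooted semantics forbids it)
  rkids <- edges[edges[, 1] == root, 2]
  if (length(rkids) == 2 && any(rkids > n)) {
    newroot <- rkids[rkids > n][1]
    other <- setdiff(rkids, newroot)
    edges <- edges[edges[, 1] != root, , drop = FALSE]
    if (length(other)) edges <- rbind(edges, c(newroot, other))
  }
  ct_to_phylo(ct_new(edges, n, labels))
}

#' Map parsimony trait changes onto a tree
#'
#' Computes one minimal-change assignment of ancestral states (ties broken
#' toward the smallest state) and lists every edge on which a character
#' changes. The total number of changes equals [parsimony_score()].
#'
#' @inheritParams parsimony_score
#' @return data frame: trait, parent and child node, from/to states, and
#'   direction (`gain` = state increase, `loss` = decrease).
#' @export
map_trait_changes <- function(tree, traits, ordered_ordinal = TRUE) {
  ct <- phylo_to_ct(tree)
  dat <- prepare_chars(traits, ct$labels, ordered_ordinal)
  kids <- ct_children(ct)
  root <- ct_root(ct)
  post <- ct_postorder(ct)
  n_char <- ncol(dat$states)
  out <- list()
  for (k in seq_len(n_char)) {
    S <- dat$n_states[k]
    stepc <- if (dat$ordered[k]) function(i, j) abs(i - j)
             else function(i, j) as.numeric(i != j)
    cost <- matrix(0, max(ct$edge), S)
    for (v in post) {
      if (v <= ct$n_leaf) {
        s <- dat$states[v, k]
        cost[v, ] <- if (is.na(s)) 0 else ifelse(seq_len(S) - 1L == s, 0, Inf)
      } else {
        acc <- numeric(S)
        for (c in kids[[v]]) {
          for (i in seq_len(S))
            acc[i] <- acc[i] + min(cost[c, ] +
                                     stepc(i - 1L, seq_len(S) - 1L))
          cost[v, ] <- acc
        }
        cost[v, ] <- acc
      }
    }
    assign_state <- integer(max(ct$edge))
    assign_state[root] <- which.min(cost[root, ]) - 1L
    # preorder backtrace
    rec <- function(v) {
      sv <- assign_state[v]
      for (c in kids[[v]]) {
        sc <- which.min(cost[c, ] + stepc(sv, seq_len(S) - 1L)) - 1L
        assign_state[c] <<- sc
        if (sc != sv)
          out[[length(out) + 1L]] <<- data.frame(
            trait = colnames(traits)[k], parent = v, child = c,
            from = sv, to = sc,
            direction = if (sc > sv) "gain" else "loss",
            stringsAsFactors = FALSE)
        if (c > ct$n_leaf) rec(c)
      }
    }
    rec(root)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(trait = character(), parent = integer(), child = integer(),
                  from = integer(), to = integer(), direction = character(),
                  stringsAsFactors = FALSE)
}

#' Enumerate all unrooted binary topologies
#'
#' Generates every unrooted binary tree over the given leaves
#' ((2n-5)!! topologies) by sequential edge insertion; feasible up to
#' about 8 leaves. Used as the exhaustive-search oracle for the heuristic
#' searches.
#'
#' @param labels leaf labels (individual keys), length 3 or more.
#' @return list of `phylo` trees.
#' @export
enumerate_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3)
  root0 <- n + 1L
  base <- cbind(root0, 1:3)
  grow <- function(edge, next_leaf, next_id) {
    if (next_leaf > n) return(list(edge))
    out <- list()
    for (e in seq_len(nrow(edge))) {
      m <- edge
      a <- m[e, 1]; b <- m[e, 2]
      m[e, ] <- c(a, next_id)
      m <- rbind(m, c(next_id, b), c(next_id, next_leaf))
      out <- c(out, grow(m, next_leaf + 1L, next_id + 1L))
    }
    out
  }
  lapply(grow(base, 4L, n + 2L), function(e)
    ct_to_phylo(ct_new(e, n, labels)))
}

#' Add an artificial asymptomatic outgroup to a trait matrix
#'
#' Appends a pseudo-individual with every symptom absent. Rooting the
#' consensus network at this leaf orients the nesting so that symptom-free
#' individuals sit at the base; the pseudo-leaf is removed again during
#' nesting.
#'
#' @param traits a [trait_matrix()].
#' @param family_id,individual_id key of the pseudo-individual.
#' @return a [trait_matrix()] with one extra all-zero row.
#' @export
add_outgroup <- function(traits, family_id = ".outgroup",
                         individual_id = "0") {
  st <- rbind(unclass(traits), 0L)
  trait_matrix(st,
               c(attr(traits, "family_id"), family_id),
               c(attr(traits, "individual_id"), individual_id),
               trait_kind = trait_kinds(traits))
}
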