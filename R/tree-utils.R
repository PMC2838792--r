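# Internal rooted-tree representation used during search: a bare edge list
# (parent, child) with leaves numbered 1..n_leaf and internal nodes any ids
# above that. Kept deliberately minimal so topology surgery is cheap; trees
# are converted to ape "phylo" objects at module boundaries.

ct_new <- function(edge, n_leaf, labels) {
  storage.mode(edge) <- "integer"
  list(edge = edge, n_leaf = as.integer(n_leaf), labels = labels)
}

ct_root <- function(ct) {
  setdiff(unique(ct$edge[, 1]), ct$edge[, 2])
}

# Character data prepared for the C scorer, aligned to a label order.
# ordinal4 columns are scored ordered (Wagner, cost |i-j|) unless
# ordered_ordinal = FALSE, in which case they are unordered (Fitch-like).
prepare_chars <- function(traits, labels, ordered_ordinal = TRUE) {
  miss <- setdiff(labels, rownames(traits))
  if (length(miss))
    stop("no trait row for individual '", miss[1], "'")
  st <- unclass(traits)[labels, , drop = FALSE]
  kind <- trait_kinds(traits)
  list(states = st,
       n_states = ifelse(kind == "ordinal4", 4L, 2L),
       ordered = (kind == "ordinal4") & ordered_ordinal)
}

ct_score <- function(ct, dat, weights = NULL) {
  if (is.null(weights))
    weights <- rep(1, ncol(dat$states))
  cpp_parsimony_score(ct$edge, ct$n_leaf, dat$states,
                      dat$n_states, dat$ordered, weights)
}

ct_score_per_char <- function(ct, dat) {
  cpp_parsimony_per_char(ct$edge, ct$n_leaf, dat$states,
                         dat$n_states, dat$ordered)
}

# children lists as an environment-free list indexed by node id
ct_children <- function(ct) {
  n_max <- max(ct$edge)
  kids <- vector("list", n_max)
  for (i in seq_len(nrow(ct$edge))) {
    p <- ct$edge[i, 1]
    kids[[p]] <- c(kids[[p]], ct$edge[i, 2])
  }
  kids
}

# logical leaf-membership mask (over 1..n_leaf) for every node, as a list
ct_leafsets <- function(ct) {
  kids <- ct_children(ct)
  n_max <- max(ct$edge)
  sets <- vector("list", n_max)
  ord <- ct_postorder(ct)
  for (v in ord) {
    if (v <= ct$n_leaf) {
      m <- logical(ct$n_leaf); m[v] <- TRUE
      sets[[v]] <- m
    } else {
      m <- logical(ct$n_leaf)
      for (c in kids[[v]]) m <- m | sets[[c]]
      sets[[v]] <- m
    }
  }
  sets
}

ct_postorder <- function(ct) {
  kids <- ct_children(ct)
  root <- ct_root(ct)
  out <- integer(0)
  rec <- function(v) {
    for (c in kids[[v]]) rec(c)
    out[[length(out) + 1L]] <<- v
  }
  rec(root)
  unlist(out)
}

# Random rooted binary tree by sequential random attachment (used for
# restarts); deterministic under the caller's RNG state.
ct_random <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 2)
  next_id <- n + 1L
  edge <- matrix(c(next_id, next_id, 1L, 2L), 2, 2)
  root <- next_id
  next_id <- next_id + 1L
  if (n >= 3) for (x in 3:n) {
    e <- sample.int(nrow(edge), 1)
    q <- next_id; next_id <- next_id + 1L
    a <- edge[e, 1]; b <- edge[e, 2]
    edge[e, ] <- c(a, q)
    edge <- rbind(edge, c(q, b), c(q, x))
  }
  ct_new(edge, n, labels)
}

# Greedy stepwise-addition start tree: leaves added in `ord`, each at the
# placement minimizing the (weighted) parsimony score.
ct_stepwise <- function(labels, dat, weights = NULL, ord = seq_along(labels)) {
  n <- length(labels)
  if (n < 3) return(ct_random(labels))
  next_id <- n + 1L
  edge <- matrix(c(next_id, next_id, ord[1], ord[2]), 2, 2)
  root <- next_id
  next_id <- next_id + 1L
  for (i in 3:n) {
    x <- ord[i]
    q <- next_id
    best <- NULL; best_s <- Inf
    for (e in seq_len(nrow(edge))) {
      a <- edge[e, 1]; b <- edge[e, 2]
      cand <- edge
      cand[e, ] <- c(a, q)
      cand <- rbind(cand, c(q, b), c(q, x))
      s <- cpp_parsimony_score(cand, n, dat$states, dat$n_states,
                               dat$ordered,
                               if (is.null(weights)) rep(1, ncol(dat$states)) else weights)
      if (s < best_s) { best_s <- s; best <- cand }
    }
    edge <- best
    next_id <- next_id + 1L
  }
  ct_new(edge, n, labels)
}

# All NNI rearrangements of a rooted binary tree.
ct_nni_moves <- function(ct) {
  edge <- ct$edge
  parent_of <- function(v) edge[match(v, edge[, 2]), 1]
  internal <- setdiff(unique(edge[, 1]), seq_len(ct$n_leaf))
  moves <- list()
  for (e in seq_len(nrow(edge))) {
    u <- edge[e, 1]; v <- edge[e, 2]
    if (v <= ct$n_leaf) next        # v must be internal
    vkids <- which(edge[, 1] == v)
    if (length(vkids) != 2) next
    us <- which(edge[, 1] == u & edge[, 2] != v)
    if (length(us) != 1) next
    for (ck in vkids) {
      m <- edge
      s <- m[us, 2]
      m[us, 2] <- m[ck, 2]
      m[ck, 2] <- s
      moves[[length(moves) + 1L]] <- m
    }
  }
  moves
}

# All SPR rearrangements (prune any non-root subtree, regraft on any edge
# outside it, plus regrafting above the current root).
ct_spr_moves <- function(ct) {
  edge <- ct$edge
  n_leaf <- ct$n_leaf
  root <- ct_root(ct)
  sets <- ct_leafsets(ct)
  moves <- list()
  nodes <- setdiff(unique(as.vector(edge)), root)
  for (v in nodes) {
    e_pv <- match(v, edge[, 2])
    p <- edge[e_pv, 1]
    # an edge row belongs to the pruned subtree iff its parent's leafset is
    # a subset of v's leafset
    inside <- vapply(seq_len(nrow(edge)), function(i) {
      w <- edge[i, 1]
      all(!(sets[[w]] & !sets[[v]]))
    }, logical(1))
    sub_rows <- which(inside)
    if (p == root) {
      rkids <- edge[edge[, 1] == root, 2]
      if (length(rkids) != 2) next
      w <- setdiff(rkids, v)
      e_pw <- which(edge[, 1] == root & edge[, 2] == w)
      keep <- setdiff(seq_len(nrow(edge)), c(e_pv, e_pw, sub_rows))
      rem <- edge[keep, , drop = FALSE]
      sub <- edge[sub_rows, , drop = FALSE]
      spare <- p
      skip_ab <- c(NA, NA)              # original is root attachment at w
      new_root_skip <- w
    } else {
      e_gp <- match(p, edge[, 2])
      g <- edge[e_gp, 1]
      e_pw <- which(edge[, 1] == p & edge[, 2] != v)
      if (length(e_pw) != 1) next
      w <- edge[e_pw, 2]
      keep <- setdiff(seq_len(nrow(edge)), c(e_pv, e_gp, e_pw, sub_rows))
      rem <- rbind(edge[keep, , drop = FALSE], c(g, w))
      sub <- edge[sub_rows, , drop = FALSE]
      spare <- p
      skip_ab <- c(g, w)                # regrafting here recreates the input
      new_root_skip <- NA
    }
    if (!nrow(rem)) next
    for (t in seq_len(nrow(rem))) {
      a <- rem[t, 1]; b <- rem[t, 2]
      if (!is.na(skip_ab[1]) && a == skip_ab[1] && b == skip_ab[2]) next
      m <- rem
      m[t, ] <- c(a, spare)
      m <- rbind(m, c(spare, b), c(spare, v), sub)
      moves[[length(moves) + 1L]] <- m
    }
    # regraft above the remaining root
    rem_root <- setdiff(unique(rem[, 1]), rem[, 2])
    if (length(rem_root) == 1 &&
        (is.na(new_root_skip) || rem_root != new_root_skip)) {
      m <- rbind(rem, c(spare, rem_root), c(spare, v), sub)
      moves[[length(moves) + 1L]] <- m
    }
  }
  moves
}

# Best-improvement hill climb under a move scheme; deterministic given input.
ct_hillclimb <- function(ct, dat, weights = NULL,
                         move = c("spr", "nni")) {
  move <- match.arg(move)
  w <- if (is.null(weights)) rep(1, ncol(dat$states)) else weights
  cur <- ct
  cur_s <- ct_score(cur, dat, w)
  ties <- list()
  repeat {
    cands <- if (move == "spr") ct_spr_moves(cur) else ct_nni_moves(cur)
    if (!length(cands)) break
    scores <- vapply(cands, function(m)
      cpp_parsimony_score(m, cur$n_leaf, dat$states, dat$n_states,
                          dat$ordered, w), 0)
    b <- which.min(scores)
    if (scores[b] < cur_s - 1e-9) {
      cur <- ct_new(cands[[b]], cur$n_leaf, cur$labels)
      cur_s <- scores[b]
    } else {
      # local optimum: remember equal-score neighbors (co-optimal trees)
      ties <- lapply(which(abs(scores - cur_s) < 1e-9),
                     function(i) ct_new(cands[[i]], cur$n_leaf, cur$labels))
      break
    }
  }
  list(tree = cur, score = cur_s, ties = ties)
}

# Canonical unrooted-split key of a tree: sorted bit-strings of all
# non-trivial bipartitions, each normalized to the side excluding leaf 1.
ct_splits <- function(ct) {
  sets <- ct_leafsets(ct)
  root <- ct_root(ct)
  internal <- setdiff(unique(ct$edge[, 2]), seq_len(ct$n_leaf))
  out <- character(0)
  for (v in internal) {
    m <- sets[[v]]
    if (m[1]) m <- !m
    k <- sum(m)
    if (k < 2 || k > ct$n_leaf - 2) next
    out <- c(out, paste(as.integer(m), collapse = ""))
  }
  unique(out)
}

ct_key <- function(ct) paste(sort(ct_splits(ct)), collapse = "|")

# Convert to an ape phylo (tips keep ids 1..n in label order; internals
# renumbered n+1.. in preorder).
ct_to_phylo <- function(ct) {
  kids <- ct_children(ct)
  root <- ct_root(ct)
  n <- ct$n_leaf
  n_int <- length(setdiff(unique(ct$edge[, 1]), seq_len(n)))
  newid <- integer(max(ct$edge))
  newid[seq_len(n)] <- seq_len(n)
  counter <- n
  edges <- matrix(0L, nrow(ct$edge), 2)
  k <- 0L
  rec <- function(v) {
    counter <<- counter + 1L
    newid[v] <<- counter
    for (c in kids[[v]]) {
      if (c > n) rec(c) else newid[c] <<- c
    }
  }
  # preorder numbering of internals
  assign_ids <- function(v) {
    counter <<- counter + 1L
    newid[v] <<- counter
    for (c in kids[[v]]) if (c > n) assign_ids(c)
  }
  assign_ids(root)
  emit <- function(v) {
    for (c in kids[[v]]) {
      k <<- k + 1L
      edges[k, ] <<- c(newid[v], newid[c])
      if (c > n) emit(c)
    }
  }
  emit(root)
  phy <- list(edge = edges, tip.label = ct$labels, Nnode = n_int)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

phylo_to_ct <- function(phy) {
  ct_new(phy$edge, length(phy$tip.label), phy$tip.label)
}
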