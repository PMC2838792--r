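#' Nest a consensus network into clades
#'
#' Roots the consensus tree (by default at an artificial asymptomatic
#' outgroup leaf, which is then removed) and converts every internal node
#' into a clade of its descendant leaves. Levels count from the leaves
#' upwards so that the most inclusive split below the root carries the
#' largest level number; clades are labeled `level_index` with indices
#' assigned in preorder within each level. Single-leaf (trivial) clades are
#' excluded.
#'
#' @param consensus an ape `phylo` (e.g. from [majority_consensus()]).
#' @param root_policy either `list(outgroup = "<leafkey>")` to root at (and
#'   then drop) an outgroup leaf, or `"asis"` to treat the stored tree as
#'   already rooted.
#' @return an object of class `clade_set`: a table of clades, their member
#'   keys, and the rooted tree.
#' @export
nest_tree <- function(consensus,
                      root_policy = list(outgroup = ".outgroup/0")) {
  phy <- consensus
  if (is.list(root_policy) && !is.null(root_policy$outgroup)) {
    og <- root_policy$outgroup
    if (!og %in% phy$tip.label)
      stop("outgroup leaf '", og, "' not in the tree")
    phy <- ape::root(phy, outgroup = og, resolve.root = TRUE)
    phy <- ape::drop.tip(phy, og)
  } else if (!identical(root_policy, "asis")) {
    stop("root_policy must be list(outgroup=) or \"asis\"")
  }
  if (length(phy$tip.label) < 2) stop("consensus needs at least 2 leaves")
  ct <- phylo_to_ct(phy)
  kids <- ct_children(ct)
  root <- ct_root(ct)
  sets <- ct_leafsets(ct)
  # preorder rank and depth of every internal node
  rank <- integer(0); depth <- integer(0); nodes <- integer(0)
  cnt <- 0L
  rec <- function(v, d) {
    cnt <<- cnt + 1L
    if (v != root) {
      nodes <<- c(nodes, v); rank <<- c(rank, cnt); depth <<- c(depth, d)
    }
    for (c in kids[[v]]) if (c > ct$n_leaf) rec(c, d + 1L)
  }
  rec(root, 0L)
  keep <- vapply(nodes, function(v) sum(sets[[v]]) >= 2, TRUE)
  nodes <- nodes[keep]; rank <- rank[keep]; depth <- depth[keep]
  if (!length(nodes)) {
    return(structure(list(
      table = data.frame(label = character(), level = integer(),
                         index = integer(), node = integer(),
                         n_members = integer(), n_families = integer(),
                         stringsAsFactors = FALSE),
      members = list(), tree = phy), class = "clade_set"))
  }
  d_max <- max(depth)
  level <- d_max + 1L - depth
  members <- lapply(nodes, function(v) ct$labels[sets[[v]]])
  index <- integer(length(nodes))
  for (l in unique(level)) {
    sel <- which(level == l)
    index[sel][order(rank[sel])] <- seq_along(sel) - 1L
  }
  label <- paste(level, index, sep = "_")
  fams <- vapply(members, function(m)
    length(unique(sub("/.*$", "", m))), 0L)
  ord <- order(-level, index)
  tab <- data.frame(label = label, level = level, index = index,
                    node = nodes, n_members = lengths(members),
                    n_families = fams, stringsAsFactors = FALSE)[ord, ]
  rownames(tab) <- NULL
  structure(list(table = tab, members = setNames(members, label)[tab$label],
                 tree = phy),
            class = "clade_set")
}

#' @export
print.clade_set <- function(x, ...) {
  cat("Clade set:", nrow(x$table), "nested clades over",
      length(x$tree$tip.label), "individuals\n")
  if (nrow(x$table)) print(head(x$table, 10))
  invisible(x)
}

#' @export
summary.clade_set <- function(object, ...) object$table

#' Member keys of one clade
#'
#' @param clades a `clade_set`; @param label clade label (`"level_index"`).
#' @return character vector of individual keys.
#' @export
clade_members <- function(clades, label) {
  m <- clades$members[[label]]
  if (is.null(m)) stop("no clade labeled '", label, "'")
  m
}

#' Filter clades by family count
#'
#' Keeps clades whose members span at least `min_families` distinct
#' families. This constraint is applied a priori, before any linkage test,
#' to avoid testing small samples with little power.
#'
#' @param clades a `clade_set`.
#' @param pedigree optional [pedigree()] used to validate that member keys
#'   exist.
#' @param min_families minimum distinct families (default 40).
#' @return a `clade_set` restricted to qualifying clades.
#' @export
filter_clades <- function(clades, pedigree = NULL, min_families = 40) {
  if (!is.null(pedigree)) {
    keys <- ped_keys(pedigree)
    for (m in clades$members) {
      bad <- setdiff(m, keys)
      if (length(bad)) stop("clade member '", bad[1], "' not in pedigree")
    }
  }
  fams <- vapply(clades$members, function(m)
    length(unique(sub("/.*$", "", m))), 0L)
  keep <- fams >= min_families
  out <- clades
  out$table <- clades$table[clades$table$label %in% names(fams)[keep], ,
                            drop = FALSE]
  rownames(out$table) <- NULL
  out$members <- clades$members[keep]
  out
}

#' Derive an affection coding from a clade
#'
#' Clade members are designated affected; their family members who do not
#' share the defining symptoms (i.e. are not in the clade) are designated
#' unaffected; family members without trait data are coded unknown.
#' Families with no clade member are excluded from that clade's analysis.
#'
#' @param clade character vector of member keys (see [clade_members()]).
#' @param ped a [pedigree()].
#' @param traits optional [trait_matrix()]; individuals absent from it are
#'   coded `"unknown"` rather than `"unaffected"` (unscored is not
#'   asymptomatic).
#' @return named character vector (`affected`/`unaffected`/`unknown`) over
#'   all individuals in analyzed families, with attribute `families`.
#' @export
affection_coding <- function(clade, ped, traits = NULL) {
  keys <- ped_keys(ped)
  bad <- setdiff(clade, keys)
  if (length(bad)) stop("clade member '", bad[1], "' not in pedigree")
  fams <- unique(ped$family_id[keys %in% clade])
  sel <- ped$family_id %in% fams
  code <- rep("unaffected", sum(sel))
  names(code) <- keys[sel]
  if (!is.null(traits))
    code[!(names(code) %in% rownames(traits))] <- "unknown"
  code[names(code) %in% clade] <- "affected"
  attr(code, "families") <- fams
  code
}
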