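#' Construct a validated pedigree
#'
#' A pedigree is a data frame of individuals with family structure. Founders
#' have both parent ids missing (`NA`); non-founders must have both parents
#' present in the same family. Each family must form a single connected,
#' acyclic graph.
#'
#' @param family_id,id,father_id,mother_id character vectors; parent ids are
#'   `NA` for founders.
#' @param sex one of `"male"`, `"female"`, `"unknown"` per individual.
#' @param affection affection status coded 0 (unknown), 1 (unaffected),
#'   2 (affected); retained as the file's default phenotype.
#' @param diagnosis optional diagnostic-category label per individual (`NA`
#'   when unassigned).
#' @return an object of class `pedigree` (a data frame).
#' @export
pedigree <- function(family_id, id, father_id = NA, mother_id = NA,
                     sex = "unknown", affection = 0L, diagnosis = NA) {
  n <- length(id)
  ped <- data.frame(
    family_id = as.character(family_id),
    id = as.character(id),
    father_id = as.character(rep_len(father_id, n)),
    mother_id = as.character(rep_len(mother_id, n)),
    sex = rep_len(as.character(sex), n),
    affection = rep_len(as.integer(affection), n),
    diagnosis = rep_len(as.character(diagnosis), n),
    stringsAsFactors = FALSE
  )
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  keys <- ind_key(ped$family_id, ped$id)
  if (anyDuplicated(keys))
    stop("duplicate individual ids: ", keys[duplicated(keys)][1])
  if (!all(ped$sex %in% c("male", "female", "unknown")))
    stop("sex must be male/female/unknown")
  if (!all(ped$affection %in% 0:2))
    stop("affection must be coded 0/1/2")
  has_f <- !is.na(ped$father_id)
  has_m <- !is.na(ped$mother_id)
  if (any(has_f != has_m))
    stop("individual ", ped$id[which(has_f != has_m)[1]],
         ": father and mother must both be present or both absent")
  for (fam in unique(ped$family_id)) {
    p <- ped[ped$family_id == fam, , drop = FALSE]
    for (col in c("father_id", "mother_id")) {
      par <- p[[col]][!is.na(p[[col]])]
      bad <- setdiff(par, p$id)
      if (length(bad))
        stop("family ", fam, ": unknown parent id '", bad[1], "'")
    }
    sx <- p$sex[match(p$father_id[!is.na(p$father_id)], p$id)]
    if (any(sx == "female"))
      stop("family ", fam, ": father '",
           p$father_id[!is.na(p$father_id)][which(sx == "female")[1]],
           "' has sex female")
    sx <- p$sex[match(p$mother_id[!is.na(p$mother_id)], p$id)]
    if (any(sx == "male"))
      stop("family ", fam, ": mother listed with sex male")
    # acyclicity: repeatedly strip individuals whose parents are all stripped
    done <- is.na(p$father_id)
    repeat {
      newly <- !done & p$father_id %in% p$id[done] & p$mother_id %in% p$id[done]
      if (!any(newly)) break
      done <- done | newly
    }
    if (!all(done))
      stop("family ", fam, ": cyclic pedigree involving individual '",
           p$id[!done][1], "'")
    # connectivity over parent-child edges
    if (nrow(p) > 1) {
      adj <- rbind(
        cbind(p$id[!is.na(p$father_id)], p$father_id[!is.na(p$father_id)]),
        cbind(p$id[!is.na(p$mother_id)], p$mother_id[!is.na(p$mother_id)])
      )
      comp <- p$id[1]
      repeat {
        hit <- adj[, 1] %in% comp | adj[, 2] %in% comp
        grow <- union(comp, c(adj[hit, 1], adj[hit, 2]))
        if (length(grow) == length(comp)) break
        comp <- grow
      }
      if (length(comp) < nrow(p))
        stop("family ", fam, ": not connected (individual '",
             setdiff(p$id, comp)[1], "' is isolated)")
    }
  }
  invisible(ped)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals in",
      length(unique(x$family_id)), "families;",
      sum(is.na(x$father_id)), "founders\n")
  invisible(x)
}

ped_keys <- function(ped) ind_key(ped$family_id, ped$id)

founder_mask <- function(ped) is.na(ped$father_id)

#' Construct a trait matrix of behavioral symptoms
#'
#' Rows are individuals (keyed by family and individual id), columns are
#' behavioral symptoms. Dichotomous traits take values \{0, 1\}; ordinal
#' severity traits take \{0, 1, 2, 3\} (absent, minimal, moderate, severe).
#' `NA` marks an unscored state and is treated as unknown throughout: free in
#' parsimony scoring, excluded from prevalence and likelihood-ratio counts.
#'
#' @param states integer matrix of symptom states (individuals x traits).
#' @param family_id,individual_id row keys.
#' @param trait_kind optional character vector `"dichotomous"`/`"ordinal4"`
#'   per column; inferred from the observed state set when `NULL` (any state
#'   above 1 makes a column ordinal).
#' @return an object of class `trait_matrix`.
#' @export
trait_matrix <- function(states, family_id, individual_id, trait_kind = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(colnames(states)))
    colnames(states) <- paste0("t", seq_len(ncol(states)))
  bad <- which(!(states %in% c(0:3, NA)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(states))
    stop("trait state outside {0..3} at row ", rc[1],
         ", column ", colnames(states)[rc[2]])
  }
  if (is.null(trait_kind)) {
    trait_kind <- unname(ifelse(
      apply(states, 2, function(v) any(v > 1, na.rm = TRUE)),
      "ordinal4", "dichotomous"))
  }
  stopifnot(all(trait_kind %in% c("dichotomous", "ordinal4")),
            length(trait_kind) == ncol(states))
  for (j in seq_len(ncol(states)))
    if (trait_kind[j] == "dichotomous" && any(states[, j] > 1, na.rm = TRUE))
      stop("dichotomous column ", colnames(states)[j], " contains states > 1")
  rownames(states) <- ind_key(family_id, individual_id)
  if (anyDuplicated(rownames(states)))
    stop("duplicate individuals in trait matrix")
  structure(states,
            family_id = as.character(family_id),
            individual_id = as.character(individual_id),
            trait_kind = trait_kind,
            class = c("trait_matrix", "matrix"))
}

#' @export
print.trait_matrix <- function(x, ...) {
  k <- attr(x, "trait_kind")
  cat("Trait matrix:", nrow(x), "individuals x", ncol(x), "traits (",
      sum(k == "dichotomous"), "dichotomous,", sum(k == "ordinal4"),
      "ordinal ),", sum(is.na(x)), "missing states\n")
  invisible(x)
}

trait_kinds <- function(x) attr(x, "trait_kind")

#' Construct a genetic map
#'
#' @param chrom,marker,pos_cM per-marker chromosome label, marker name, and
#'   map position in centimorgans (strictly increasing within chromosome).
#' @param freqs named list (by marker) of named numeric allele-frequency
#'   vectors; allele labels are the names. Each vector must sum to 1.
#' @return an object of class `genetic_map`.
#' @export
genetic_map <- function(chrom, marker, pos_cM, freqs) {
  tab <- data.frame(chrom = as.character(chrom), marker = as.character(marker),
                    pos_cM = as.numeric(pos_cM), stringsAsFactors = FALSE)
  if (anyDuplicated(tab$marker)) stop("duplicate marker names")
  for (ch in unique(tab$chrom)) {
    p <- tab$pos_cM[tab$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on ", ch)
  }
  stopifnot(setequal(names(freqs), tab$marker))
  for (m in tab$marker) {
    f <- freqs[[m]]
    if (is.null(names(f))) stop("allele frequencies for ", m, " are unnamed")
    if (abs(sum(f) - 1) > 1e-9)
      stop("allele frequencies for ", m, " sum to ", sum(f))
  }
  structure(list(table = tab, freqs = freqs[tab$marker]),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", nrow(x$table), "markers on",
      length(unique(x$table$chrom)), "chromosomes\n")
  invisible(x)
}

#' Marker names of a genetic map, in map order
#' @param map a [genetic_map()].
#' @return character vector.
#' @export
map_markers <- function(map) map$table$marker

#' Construct a genotype table
#'
#' Stores one unordered allele pair per individual per marker; `NA` = untyped.
#'
#' @param alleles integer matrix with two columns per marker
#'   (`<marker>.1`, `<marker>.2`), rows keyed like the pedigree.
#' @param markers character vector of marker names, in map order.
#' @param keys individual keys (`"family/id"`).
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(alleles, markers, keys) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  stopifnot(ncol(alleles) == 2L * length(markers))
  colnames(alleles) <- paste(rep(markers, each = 2), 1:2, sep = ".")
  rownames(alleles) <- keys
  structure(alleles, markers = markers,
            class = c("genotype_table", "matrix"))
}

geno_markers <- function(g) attr(g, "markers")

# two-column allele matrix for one marker, rows aligned to `keys`
geno_pair <- function(g, marker, keys = rownames(g)) {
  j <- 2L * (match(marker, geno_markers(g)) - 1L)
  out <- g[match(keys, rownames(g)), c(j + 1L, j + 2L), drop = FALSE]
  rownames(out) <- keys
  out
}

#' Read a LINKAGE-style (pre-makeped) pedigree file
#'
#' Whitespace-delimited columns: family, individual, father, mother, sex,
#' affection, then two allele columns per marker in map order. `0` codes a
#' missing parent, unknown sex, unknown affection, or an untyped allele.
#' Mendelian consistency is checked per trio; violations are reported via a
#' warning and attached as attribute `"mendel"` on the genotype table.
#'
#' @param path file path.
#' @param map a [genetic_map()]; defines marker order and legal allele labels.
#' @return `list(pedigree = , genotypes = )`.
#' @export
read_ped <- function(path, map) {
  if (!file.exists(path)) stop("file not found: ", path)
  tok <- read.table(path, header = FALSE, colClasses = "character")
  markers <- map_markers(map)
  need <- 6L + 2L * length(markers)
  if (ncol(tok) != need)
    stop("expected ", need, " columns (6 + 2 per marker), found ", ncol(tok))
  sex <- c("0" = "unknown", "1" = "male", "2" = "female")[tok[[5]]]
  if (any(is.na(sex))) stop("sex column must be 0/1/2")
  ped <- pedigree(
    family_id = tok[[1]], id = tok[[2]],
    father_id = ifelse(tok[[3]] == "0", NA, tok[[3]]),
    mother_id = ifelse(tok[[4]] == "0", NA, tok[[4]]),
    sex = sex, affection = as.integer(tok[[6]])
  )
  al <- as.matrix(tok[, -(1:6), drop = FALSE])
  al <- matrix(as.integer(al), nrow = nrow(al))
  al[al == 0L] <- NA_integer_
  # one allele typed and the other not is not representable in this dialect
  for (j in seq_along(markers)) {
    a1 <- al[, 2 * j - 1]; a2 <- al[, 2 * j]
    if (any(xor(is.na(a1), is.na(a2))))
      stop("marker ", markers[j], ": half-typed genotype")
    legal <- as.integer(names(map$freqs[[markers[j]]]))
    bad <- setdiff(c(a1, a2), c(legal, NA))
    if (length(bad))
      stop("marker ", markers[j], ": allele ", bad[1], " not in map")
  }
  geno <- genotype_table(al, markers, ped_keys(ped))
  viol <- mendel_check(ped, geno)
  if (nrow(viol))
    warning(nrow(viol), " Mendelian inconsistencies (see attr(geno,'mendel'))")
  attr(geno, "mendel") <- viol
  list(pedigree = ped, genotypes = geno)
}

#' Write a LINKAGE-style (pre-makeped) pedigree file
#'
#' @param ped a [pedigree()].
#' @param geno a [genotype_table()] aligned with `ped` (or `NULL` for a
#'   phenotype-only file with no marker columns).
#' @param path output path.
#' @export
write_ped <- function(ped, geno, path) {
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  out <- cbind(ped$family_id, ped$id,
               ifelse(is.na(ped$father_id), "0", ped$father_id),
               ifelse(is.na(ped$mother_id), "0", ped$mother_id),
               sex, as.character(ped$affection))
  if (!is.null(geno)) {
    al <- geno[match(ped_keys(ped), rownames(geno)), , drop = FALSE]
    al[is.na(al)] <- 0L
    out <- cbind(out, matrix(as.character(al), nrow = nrow(out)))
  }
  write.table(out, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Report Mendelian inconsistencies per trio
#'
#' A child is flagged at a marker when no assignment of its two alleles to
#' paternal and maternal gametes is compatible with the (typed) parental
#' genotypes. Untyped individuals are compatible with anything.
#'
#' @param ped a [pedigree()]; @param geno a [genotype_table()].
#' @return data frame with columns family, marker, child.
#' @export
mendel_check <- function(ped, geno) {
  markers <- geno_markers(geno)
  keys <- ped_keys(ped)
  out <- list()
  kid <- which(!is.na(ped$father_id))
  for (i in kid) {
    fk <- ind_key(ped$family_id[i], ped$father_id[i])
    mk <- ind_key(ped$family_id[i], ped$mother_id[i])
    ck <- keys[i]
    for (m in markers) {
      c2 <- geno_pair(geno, m, ck)[1, ]
      if (any(is.na(c2))) next
      fa <- geno_pair(geno, m, fk)[1, ]
      mo <- geno_pair(geno, m, mk)[1, ]
      fromF <- function(a) any(is.na(fa)) || a %in% fa
      fromM <- function(a) any(is.na(mo)) || a %in% mo
      ok <- (fromF(c2[1]) && fromM(c2[2])) || (fromF(c2[2]) && fromM(c2[1]))
      if (!ok)
        out[[length(out) + 1L]] <- data.frame(
          family = ped$family_id[i], marker = m, child = ped$id[i],
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(family = character(), marker = character(),
                  child = character(), stringsAsFactors = FALSE)
}

#' Read / write a genetic map file
#'
#' Whitespace-delimited columns: chromosome, marker name, position (cM), and
#' a comma-separated `allele:frequency` list.
#'
#' @param path file path.
#' @return a [genetic_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tok <- read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tok) != 4) stop("map file needs 4 columns")
  freqs <- lapply(tok[[4]], function(s) {
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    f <- vapply(parts, function(p) as.numeric(p[2]), 0)
    names(f) <- vapply(parts, `[`, "", 1)
    f
  })
  names(freqs) <- tok[[2]]
  genetic_map(tok[[1]], tok[[2]], as.numeric(tok[[3]]), freqs)
}

#' @rdname read_map
#' @param map a [genetic_map()] to write.
#' @export
write_map <- function(map, path) {
  fr <- vapply(map$freqs, function(f)
    paste(names(f), format(f, trim = TRUE, digits = 15), sep = ":",
          collapse = ","), "")
  out <- cbind(map$table$chrom, map$table$marker,
               format(map$table$pos_cM, trim = TRUE, digits = 15), fr)
  write.table(out, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a trait matrix file
#'
#' Tab-separated, header row of trait names; first two columns are
#' `family_id` and `individual_id`. Missing states are written as `NA`.
#'
#' @param path file path.
#' @return a [trait_matrix()].
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = c("NA", ".", "-", ""))
  if (ncol(tab) < 3) stop("trait file needs family_id, individual_id + traits")
  st <- as.matrix(tab[, -(1:2), drop = FALSE])
  num <- suppressWarnings(matrix(as.integer(st), nrow = nrow(st)))
  bad <- which(is.na(num) & !is.na(st), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)))
    stop("non-numeric trait state at row ", bad[1, 1], ", column ",
         colnames(st)[bad[1, 2]])
  colnames(num) <- colnames(st)
  trait_matrix(num, tab[[1]], tab[[2]])
}

#' @rdname read_traits
#' @param traits a [trait_matrix()] to write.
#' @export
write_traits <- function(traits, path) {
  tab <- data.frame(family_id = attr(traits, "family_id"),
                    individual_id = attr(traits, "individual_id"),
                    unclass(traits), check.names = FALSE)
  write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a diagnostic-category label file
#'
#' Tab-separated with header `family_id individual_id diagnosis`.
#'
#' @param path file path.
#' @return data frame with an added `key` column.
#' @export
read_diagnoses <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  stopifnot(all(c("family_id", "individual_id", "diagnosis") %in% names(tab)))
  tab$key <- ind_key(tab$family_id, tab$individual_id)
  tab
}

#' Estimate marker allele frequencies from typed founders
#'
#' Allele counts are taken over founders only (so that each population
#' chromosome is counted once) and normalized.
#'
#' @param ped a [pedigree()]; @param geno a [genotype_table()].
#' @param marker marker name.
#' @return named numeric frequency vector summing to 1.
#' @export
estimate_founder_allele_freqs <- function(ped, geno, marker) {
  fk <- ped_keys(ped)[founder_mask(ped)]
  al <- geno_pair(geno, marker, fk)
  al <- al[!is.na(al)]
  if (!length(al))
    stop("no typed founders at ", marker,
         "; supply allele frequencies via the map")
  tab <- table(al)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}
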