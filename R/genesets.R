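#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (member genes); names are
#'   set names and must be unique.
#' @param universe optional character vector of gene identifiers the
#'   collection is defined over; defaults to the union of all members.
#' @param category optional character vector of category labels, one per
#'   set (recycled if length 1).
#' @return Object of class `geneset_collection`: list with `sets`
#'   (list of unique character vectors), `universe`, `category`,
#'   `original_size` (set sizes before any universe binding) and
#'   `clusters` (NULL until [cluster_representatives()] is run).
#' @export
geneset_collection <- function(sets, universe = NULL, category = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) stop("empty gene set(s) not allowed")
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  if (is.null(category)) category <- rep("", length(sets))
  if (length(category) == 1L) category <- rep(category, length(sets))
  structure(
    list(sets = sets, universe = as.character(universe),
         category = stats::setNames(category, names(sets)),
         original_size = stats::setNames(lengths(sets), names(sets)),
         clusters = NULL),
    class = "geneset_collection"
  )
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x$sets), "sets over",
      length(x$universe), "genes\n")
  if (!is.null(x$clusters))
    cat("  representatives of", length(unique(x$clusters)), "clusters\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated interchange format for gene sets: one set per
#' line as `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate
#' members within a line are deduplicated; a line without members is a
#' parse error.
#'
#' @param path GMT file.
#' @return A [geneset_collection()]; the description field is kept as the
#'   category label.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop("malformed GMT line ", i, ": no members")
    nm[i] <- f[[1L]]
    desc[i] <- f[[2L]]
    sets[[i]] <- members
  }
  names(sets) <- nm
  geneset_collection(sets, category = desc)
}

#' Write a collection to GMT
#'
#' @param coll a [geneset_collection()].
#' @param path output file.
#' @return `coll`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  lines <- vapply(names(coll$sets), function(nm) {
    paste(c(nm, if (nzchar(coll$category[[nm]])) coll$category[[nm]] else "na",
            coll$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(coll)
}

#' Restrict a collection to a gene universe
#'
#' Intersects every set with `universe` (typically the genes of the
#' expression study); sets left empty are removed with a message. The
#' original (pre-binding) sizes are retained for reporting.
#'
#' @param coll a [geneset_collection()].
#' @param universe character vector of gene identifiers.
#' @return The bound collection.
#' @export
bind_universe <- function(coll, universe) {
  universe <- as.character(universe)
  sets <- lapply(coll$sets, intersect, universe)
  empty <- lengths(sets) == 0L
  if (any(empty))
    message(sum(empty), " gene set(s) empty after universe binding, removed")
  keep <- !empty
  out <- coll
  out$sets <- sets[keep]
  out$universe <- universe
  out$category <- coll$category[keep]
  out$original_size <- coll$original_size[keep]
  out
}

#' Cohen's kappa between two gene sets
#'
#' Chance-corrected agreement of the two binary membership vectors over a
#' common gene universe:
#' \deqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' \eqn{p_o = (|A \cap B| + |A^c \cap B^c|)/U} and
#' \eqn{p_e = (|A||B| + (U-|A|)(U-|B|))/U^2}.
#'
#' The degenerate case \eqn{p_e = 1} (both sets equal the universe, or
#' both empty) is defined as 1 for identical sets and 0 otherwise.
#'
#' @param a,b character vectors of member genes (subsets of `universe`).
#' @param universe character vector, the gene universe.
#' @return Kappa in \[-1, 1\].
#' @export
kappa_stat <- function(a, b, universe) {
  U <- length(universe)
  if (U == 0L) stop("empty universe")
  a <- unique(a); b <- unique(b)
  nA <- length(a); nB <- length(b)
  nAB <- length(intersect(a, b))
  po <- (nAB + (U - nA - nB + nAB)) / U
  pe <- (nA * nB + (U - nA) * (U - nB)) / U^2
  if (pe >= 1) {
    message("degenerate kappa (p_e = 1)")
    return(if (nA == nB && nAB == nA) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Reduce a collection to representative gene sets
#'
#' Builds the graph whose edges connect set pairs with kappa at or above
#' `threshold`, takes single-linkage clusters (connected components), and
#' keeps one representative per cluster: the largest set, ties broken by
#' lexicographically smallest name. The result is independent of input
#' order.
#'
#' @param coll a [geneset_collection()]; kappa uses `coll$universe`.
#' @param threshold kappa cutoff in (0, 1].
#' @param selection representative rule; only `"largest"` is implemented.
#' @return The collection restricted to representatives, with a
#'   `clusters` element mapping every original set name to its cluster id
#'   (the representative's name).
#' @export
cluster_representatives <- function(coll, threshold = 0.5,
                                    selection = "largest") {
  stopifnot(inherits(coll, "geneset_collection"),
            threshold > 0, threshold <= 1,
            identical(selection, "largest"))
  nms <- names(coll$sets)
  n <- length(nms)
  # union-find over the kappa >= threshold graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    memb <- lapply(coll$sets, unique)
    sizes <- lengths(memb)
    U <- length(coll$universe)
    for (i in seq_len(n - 1L)) {
      mi <- memb[[i]]
      for (j in (i + 1L):n) {
        nAB <- length(intersect(mi, memb[[j]]))
        po <- (nAB + (U - sizes[i] - sizes[j] + nAB)) / U
        pe <- (sizes[i] * sizes[j] + (U - sizes[i]) * (U - sizes[j])) / U^2
        k <- if (pe >= 1) (if (sizes[i] == sizes[j] && nAB == sizes[i]) 1 else 0)
             else (po - pe) / (1 - pe)
        if (k >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))

  reps <- character(0)
  cluster_of <- character(n)
  for (cid in unique(comp)) {
    members <- nms[comp == cid]
    sz <- lengths(coll$sets[members])
    best <- members[order(-sz, members)][1L]
    reps <- c(reps, best)
    cluster_of[comp == cid] <- best
  }
  reps <- sort(reps)
  out <- coll
  out$sets <- coll$sets[reps]
  out$category <- coll$category[reps]
  out$original_size <- coll$original_size[reps]
  out$clusters <- stats::setNames(cluster_of, nms)
  out
}

#' Write a cluster map as a two-column TSV
#'
#' @param coll a clustered [cluster_representatives()] result.
#' @param path output TSV (`set_name`, `cluster_id`).
#' @return `coll`, invisibly.
#' @export
write_cluster_map <- function(coll, path) {
  if (is.null(coll$clusters)) stop("collection has no cluster map")
  utils::write.table(
    data.frame(set_name = names(coll$clusters),
               cluster_id = unname(coll$clusters)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(coll)
}
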