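#' Drug signature
#'
#' Per-treatment summary feeding the pair scores: the set of genes with
#' significant delta z-scores and the set of enriched gene sets (adjusted
#' p below the FDR threshold and informative).
#'
#' @param profile a [gene_significance()]-annotated [delta_z()] profile.
#' @param enrichment the profile's [enrich_profile()] table.
#' @return Object of class `drug_signature`: list with `drug`,
#'   `concentration`, `significant_genes` (character),
#'   `enriched_sets` (character).
#' @export
drug_signature <- function(profile, enrichment) {
  stopifnot(inherits(profile, "delta_z_profile"))
  if (anyNA(profile$significant))
    stop("run gene_significance() on the profile first")
  structure(
    list(drug = profile$drug,
         concentration = profile$concentration,
         significant_genes = names(profile$z)[profile$significant],
         enriched_sets = enrichment$set_name[enrichment$enriched]),
    class = "drug_signature"
  )
}

#' Co-gene score
#'
#' Fraction of the gene universe that is significantly regulated by both
#' drugs: \eqn{g_{d_1,d_2}/G}.
#'
#' @param a,b [drug_signature()] objects.
#' @param G gene universe size.
#' @return Score in \[0, 1\].
#' @export
co_gene_score <- function(a, b, G) {
  stopifnot(G >= 1)
  length(intersect(a$significant_genes, b$significant_genes)) / G
}

#' Co-GS score
#'
#' Fraction of the gene-set collection enriched in both drugs:
#' \eqn{n_{d_1,d_2}/L}.
#'
#' @param a,b [drug_signature()] objects.
#' @param L collection size (number of representative gene sets).
#' @return Score in \[0, 1\].
#' @export
co_gs_score <- function(a, b, L) {
  stopifnot(L >= 1)
  length(intersect(a$enriched_sets, b$enriched_sets)) / L
}

#' Co-gene/GS score
#'
#' Average, over the co-enriched gene sets, of the fraction of each set's
#' members significantly regulated by both drugs:
#' \deqn{\frac{1}{n}\sum_l N^l_{d_1,d_2} / N^l}
#' where \eqn{N^l} is the set size bound to the study universe. With no
#' co-enriched sets the score is defined as 0.
#'
#' @param a,b [drug_signature()] objects.
#' @param coll a [geneset_collection()] bound to the study universe.
#' @return Score in \[0, 1\].
#' @export
co_gene_gs_score <- function(a, b, coll) {
  co <- intersect(a$enriched_sets, b$enriched_sets)
  if (length(co) == 0L) return(0)
  cosig <- intersect(a$significant_genes, b$significant_genes)
  mean(vapply(coll$sets[co], function(m)
    length(intersect(m, cosig)) / length(m), numeric(1)))
}

#' Collapse per-concentration scores to the drug-pair level
#'
#' A drug profiled at several concentrations contributes one instance per
#' concentration; all instance-by-instance score combinations for a drug
#' pair are collapsed to a single value, by default the maximum ("the
#' most synergistic one").
#'
#' @param scores numeric vector of instance-pair scores.
#' @param rule `"max"` (default) or `"mean"`.
#' @return One collapsed score.
#' @export
collapse_concentrations <- function(scores, rule = c("max", "mean")) {
  rule <- match.arg(rule)
  stopifnot(length(scores) >= 1)
  if (rule == "max") max(scores) else mean(scores)
}

#' Score all unordered drug pairs
#'
#' Computes the three similarity scores for every unordered pair of drugs
#' from their signatures, collapsing multiple concentration instances per
#' drug with [collapse_concentrations()]. The co-enriched gene-set list
#' reported for a pair comes from the instance pair attaining the
#' collapsed co-gene/GS score (first in instance order on ties).
#'
#' @param signatures list of [drug_signature()] objects (one per
#'   drug-concentration instance).
#' @param coll the bound representative [geneset_collection()].
#' @param G gene universe size; defaults to `length(coll$universe)`.
#' @param rule concentration collapse rule, see
#'   [collapse_concentrations()].
#' @return data.frame of class `pair_score_table` with one row per
#'   unordered drug pair: `drug_a`, `drug_b`, `co_gene`, `co_gs`,
#'   `co_gene_gs`, rank columns per score, and attribute
#'   `co_enriched` (named list of character vectors).
#' @export
pair_scores <- function(signatures, coll, G = length(coll$universe),
                        rule = "max") {
  drugs <- sort(unique(vapply(signatures, `[[`, character(1), "drug")))
  if (length(drugs) < 2L) stop("need at least two drugs")
  L <- length(coll$sets)
  by_drug <- split(signatures,
                   vapply(signatures, `[[`, character(1), "drug"))

  pairs <- utils::combn(drugs, 2L)
  n_pairs <- ncol(pairs)
  co_gene <- co_gs <- co_gg <- numeric(n_pairs)
  co_enriched <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    sa <- by_drug[[pairs[1L, k]]]
    sb <- by_drug[[pairs[2L, k]]]
    grid <- expand.grid(i = seq_along(sa), j = seq_along(sb))
    v_gene <- v_gs <- v_gg <- numeric(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      a <- sa[[grid$i[r]]]; b <- sb[[grid$j[r]]]
      v_gene[r] <- co_gene_score(a, b, G)
      v_gs[r] <- co_gs_score(a, b, L)
      v_gg[r] <- co_gene_gs_score(a, b, coll)
    }
    co_gene[k] <- collapse_concentrations(v_gene, rule)
    co_gs[k] <- collapse_concentrations(v_gs, rule)
    co_gg[k] <- collapse_concentrations(v_gg, rule)
    best <- which(v_gg == co_gg[k])[1L]
    co_enriched[[k]] <- intersect(
      sa[[grid$i[best]]]$enriched_sets, sb[[grid$j[best]]]$enriched_sets)
  }
  tab <- data.frame(drug_a = pairs[1L, ], drug_b = pairs[2L, ],
                    co_gene = co_gene, co_gs = co_gs, co_gene_gs = co_gg,
                    stringsAsFactors = FALSE)
  names(co_enriched) <- paste(tab$drug_a, tab$drug_b, sep = "|")
  for (col in c("co_gene", "co_gs", "co_gene_gs"))
    tab[[paste0("rank_", col)]] <- rank_pairs(tab, col)
  attr(tab, "co_enriched") <- co_enriched
  class(tab) <- c("pair_score_table", "data.frame")
  tab
}

#' Rank drug pairs by a score column
#'
#' Rank 1 is the highest score (most synergistic). Ties are broken
#' deterministically by `(drug_a, drug_b)` lexicographic order, so the
#' ranks are always a permutation of `1..n`.
#'
#' @param table a [pair_scores()] table (or any data.frame with
#'   `drug_a`, `drug_b` and the score column).
#' @param score_column name of the score column to rank on.
#' @return Integer vector of ranks aligned with the table's rows.
#' @export
rank_pairs <- function(table, score_column) {
  if (!score_column %in% names(table))
    stop("no such score column: ", score_column)
  s <- table[[score_column]]
  ord <- order(-s, table$drug_a, table$drug_b)
  rk <- integer(length(s))
  rk[ord] <- seq_along(s)
  rk
}

#' Write a pair score table and its co-enriched set lists
#'
#' @param table a [pair_scores()] result.
#' @param path output TSV for the score/rank table.
#' @param sets_path optional long-format TSV
#'   (`drug_a`, `drug_b`, `set_name`) of co-enriched gene sets.
#' @return `table`, invisibly.
#' @export
write_pair_scores <- function(table, path, sets_path = NULL) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sets_path)) {
    co <- attr(table, "co_enriched")
    long <- do.call(rbind, lapply(names(co), function(key) {
      if (length(co[[key]]) == 0L) return(NULL)
      ab <- strsplit(key, "|", fixed = TRUE)[[1L]]
      data.frame(drug_a = ab[1L], drug_b = ab[2L], set_name = co[[key]],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(long))
      long <- data.frame(drug_a = character(0), drug_b = character(0),
                         set_name = character(0))
    utils::write.table(long, sets_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(table)
}
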