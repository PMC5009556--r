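#' Gene-set enrichment score
#'
#' The set-level statistic is the plain mean of the delta z-scores over
#' the set's members bound to the profile's gene universe:
#' \deqn{S_l = \frac{1}{N^l}\sum_{j \in l} Z_{i,j}.}
#'
#' @param profile a [delta_z()] profile.
#' @param members character vector of member genes.
#' @return The mean delta z-score over the bound members, or `NA` when no
#'   member is present in the profile.
#' @export
enrichment_score <- function(profile, members) {
  z <- profile$z[names(profile$z) %in% members]
  if (length(z) == 0L) return(NA_real_)
  mean(z)
}

#' Informativeness filter for enrichment scores
#'
#' A set-level score inside the \eqn{L_{0.05} = \pm 1.96/\sqrt{N}} band is
#' deemed non-informative: its magnitude is no larger than what 5% of
#' random sets of the same size would reach under unit-variance noise.
#'
#' @param score enrichment score(s).
#' @param n bound set size(s), same length as `score` or length 1.
#' @return Logical: `TRUE` when `|score| > 1.96/sqrt(n)`.
#' @export
informative_filter <- function(score, n) {
  stopifnot(all(n >= 1))
  abs(score) > 1.96 / sqrt(n)
}

#' Permutation enrichment analysis of one profile
#'
#' Scores every gene set of the collection against the profile and
#' attaches a two-sided empirical p-value from `B` gene-label
#' permutations: for each bound size N the null scores are means of N
#' genes drawn without replacement from the profile, and
#' \eqn{p = (\#\{|S^*| \ge |S_{obs}|\} + 1)/(B + 1)}. Draws are shared
#' across sets of equal bound size; the result does not depend on that
#' optimization. Benjamini-Hochberg adjustment is applied across all sets
#' of the profile, and sets are flagged `enriched` when the adjusted
#' p-value is below `alpha` and the score passes the informativeness
#' band.
#'
#' @param profile a [delta_z()] profile.
#' @param coll a [geneset_collection()] (bound or unbound; binding to the
#'   profile's genes happens internally).
#' @param B number of permutations (the reference analysis used 1000).
#' @param alpha FDR threshold for the enriched call.
#' @param seed integer seed for the permutation draws (mandatory for
#'   reproducibility).
#' @return data.frame of class `enrichment_table` with columns `drug`,
#'   `concentration`, `set_name`, `n_bound`, `score`, `p_raw`, `p_adj`,
#'   `informative`, `enriched`.
#' @export
enrich_profile <- function(profile, coll, B = 1000, alpha = 0.05, seed) {
  stopifnot(inherits(profile, "delta_z_profile"),
            inherits(coll, "geneset_collection"),
            B >= 1)
  if (missing(seed)) stop("`seed` is required")
  genes <- names(profile$z)
  bound <- lapply(coll$sets, intersect, genes)
  keep <- lengths(bound) > 0L
  if (!all(keep))
    warning(sum(!keep), " set(s) with no genes in the profile skipped")
  bound <- bound[keep]
  if (length(bound) == 0L)
    return(empty_enrichment_table())
  nb <- lengths(bound)
  z <- profile$z
  G <- length(z)
  obs <- vapply(bound, function(m) mean(z[m]), numeric(1))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  # shared null per bound size: B draws of n genes without replacement
  p_raw <- numeric(length(bound))
  for (n in sort(unique(nb))) {
    null_scores <- vapply(seq_len(B), function(b)
      mean(z[sample.int(G, n)]), numeric(1))
    idx <- which(nb == n)
    for (i in idx)
      p_raw[i] <- (sum(abs(null_scores) >= abs(obs[i])) + 1) / (B + 1)
  }
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  informative <- informative_filter(obs, nb)

  out <- data.frame(
    drug = profile$drug,
    concentration = profile$concentration,
    set_name = names(bound),
    n_bound = unname(nb),
    score = unname(obs),
    p_raw = p_raw,
    p_adj = p_adj,
    informative = unname(informative),
    enriched = p_adj < alpha & informative,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

empty_enrichment_table <- function() {
  out <- data.frame(drug = character(0), concentration = character(0),
                    set_name = character(0), n_bound = integer(0),
                    score = numeric(0), p_raw = numeric(0),
                    p_adj = numeric(0), informative = logical(0),
                    enriched = logical(0), stringsAsFactors = FALSE)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as a
#' named operation of the pipeline.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}
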