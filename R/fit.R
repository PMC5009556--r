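#' Fit the gene set-based synergy prediction model
#'
#' Runs the whole pipeline on an expression study: delta z-score profiles
#' versus the vehicle control for every treated sample, per-gene
#' significance calls, permutation gene-set enrichment per profile, drug
#' signatures, and the three pairwise similarity scores (co-gene, co-GS,
#' co-gene/GS) with deterministic rankings over all unordered drug pairs.
#'
#' @param study an [expression_study()].
#' @param collection a [geneset_collection()]; bound to the study's genes
#'   internally.
#' @param alpha_gene gene-level significance level for delta z-scores.
#' @param alpha_set FDR threshold for the set-level enriched call.
#' @param B permutations per enrichment analysis.
#' @param kappa_threshold if non-NULL, the collection is first reduced to
#'   representative sets by kappa clustering at this cutoff (after
#'   universe binding).
#' @param std_mode,null_variance see [delta_z()] and
#'   [gene_significance()].
#' @param rule concentration collapse rule, see
#'   [collapse_concentrations()].
#' @param seed master integer seed; per-profile permutation seeds are
#'   derived from it deterministically.
#' @return Object of class `drugsyn_fit`: list with `pairs` (the
#'   [pair_scores()] table), `enrichment` (row-bound per-profile
#'   tables), `signatures`, `profiles`, `collection` (as used for
#'   scoring), `config`.
#' @seealso [evaluate()] to score the fit against a gold standard.
#' @export
synergy_fit <- function(study, collection,
                        alpha_gene = 0.05, alpha_set = 0.05,
                        B = 1000, kappa_threshold = NULL,
                        std_mode = "sample", null_variance = 1,
                        rule = "max", seed) {
  stopifnot(inherits(study, "expression_study"),
            inherits(collection, "geneset_collection"))
  if (missing(seed)) stop("`seed` is required")
  seed <- as.integer(seed)

  coll <- bind_universe(collection, study$genes)
  if (!is.null(kappa_threshold))
    coll <- cluster_representatives(coll, threshold = kappa_threshold)

  profiles <- study_profiles(study, std_mode = std_mode,
                             alpha = alpha_gene,
                             null_variance = null_variance)
  enr <- vector("list", length(profiles))
  sigs <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    enr[[i]] <- enrich_profile(profiles[[i]], coll, B = B,
                               alpha = alpha_set,
                               seed = seed + 131L * i)
    sigs[[i]] <- drug_signature(profiles[[i]], enr[[i]])
  }
  pairs <- pair_scores(sigs, coll, G = length(coll$universe), rule = rule)

  structure(
    list(pairs = pairs,
         enrichment = do.call(rbind, enr),
         signatures = sigs,
         profiles = profiles,
         collection = coll,
         config = list(alpha_gene = alpha_gene, alpha_set = alpha_set,
                       B = B, kappa_threshold = kappa_threshold,
                       std_mode = std_mode, null_variance = null_variance,
                       rule = rule, seed = seed)),
    class = "drugsyn_fit"
  )
}

#' @export
print.drugsyn_fit <- function(x, ...) {
  drugs <- sort(unique(c(x$pairs$drug_a, x$pairs$drug_b)))
  cat("Gene set-based synergy fit\n")
  cat("  drugs:", length(drugs), " pairs:", nrow(x$pairs),
      " gene sets:", length(x$collection$sets),
      " universe:", length(x$collection$universe), "\n")
  cat("  top pairs by co-gene/GS score:\n")
  top <- x$pairs[order(x$pairs$rank_co_gene_gs), ][seq_len(min(3, nrow(x$pairs))), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %s & %s  (%.4g)\n", top$drug_a[i], top$drug_b[i],
                top$co_gene_gs[i]))
  invisible(x)
}

#' @export
summary.drugsyn_fit <- function(object, ...) {
  sig_counts <- vapply(object$signatures, function(s)
    length(s$significant_genes), integer(1))
  enr_counts <- vapply(object$signatures, function(s)
    length(s$enriched_sets), integer(1))
  out <- list(
    n_drugs = length(unique(c(object$pairs$drug_a, object$pairs$drug_b))),
    n_pairs = nrow(object$pairs),
    n_sets = length(object$collection$sets),
    universe = length(object$collection$universe),
    significant_genes = summary(sig_counts),
    enriched_sets = summary(enr_counts),
    score_summary = vapply(c("co_gene", "co_gs", "co_gene_gs"),
                           function(cn) range(object$pairs[[cn]]),
                           numeric(2)),
    config = object$config)
  class(out) <- "summary.drugsyn_fit"
  out
}

#' @export
print.summary.drugsyn_fit <- function(x, ...) {
  cat("Gene set-based synergy fit:", x$n_drugs, "drugs,",
      x$n_pairs, "pairs,", x$n_sets, "sets over",
      x$universe, "genes\n")
  cat("significant genes per profile:\n"); print(x$significant_genes)
  cat("enriched sets per profile:\n"); print(x$enriched_sets)
  cat("score ranges (min, max):\n"); print(t(x$score_summary))
  invisible(x)
}

#' Extract the pair scores of a fit
#'
#' @param object a [synergy_fit()].
#' @param ... unused.
#' @return Numeric matrix, pairs by the three scores, with
#'   `"drug_a|drug_b"` row names.
#' @export
coef.drugsyn_fit <- function(object, ...) {
  m <- as.matrix(object$pairs[, c("co_gene", "co_gs", "co_gene_gs")])
  rownames(m) <- paste(object$pairs$drug_a, object$pairs$drug_b, sep = "|")
  m
}

#' Predicted synergy ranking
#'
#' @param object a [synergy_fit()].
#' @param score score column to rank on (default `"co_gene_gs"`, the
#'   best-performing score).
#' @param ... unused.
#' @return The pair table ordered from most to least synergistic under
#'   the chosen score.
#' @export
predict.drugsyn_fit <- function(object, score = "co_gene_gs", ...) {
  rk <- object$pairs[[paste0("rank_", score)]]
  if (is.null(rk)) rk <- rank_pairs(object$pairs, score)
  out <- as.data.frame(object$pairs)[order(rk), ]
  rownames(out) <- NULL
  out
}

#' Plot a synergy fit against a gold standard
#'
#' Scatter of the chosen prediction score versus the measured excess over
#' Bliss, one point per drug pair; without a gold standard, the sorted
#' score profile of all pairs.
#'
#' @param x a [synergy_fit()].
#' @param gold optional [gold_standard()].
#' @param score score column to show.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.drugsyn_fit <- function(x, gold = NULL, score = "co_gene_gs", ...) {
  s <- x$pairs[[score]]
  if (is.null(gold)) {
    plot(sort(s, decreasing = TRUE), type = "h",
         xlab = "drug pair (ranked)", ylab = score, ...)
  } else {
    key_p <- paste(pmin(x$pairs$drug_a, x$pairs$drug_b),
                   pmax(x$pairs$drug_a, x$pairs$drug_b))
    key_g <- paste(pmin(gold$drug_a, gold$drug_b),
                   pmax(gold$drug_a, gold$drug_b))
    eob <- gold$eob_mean[match(key_p, key_g)]
    plot(s, eob, xlab = score, ylab = "excess over Bliss (EOB)", ...)
  }
  invisible(x)
}

#' Plot the ROC curves of an evaluation
#'
#' @param x a [evaluate()] report.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.synergy_eval <- function(x, ...) {
  plot(c(0, 1), c(0, 1), type = "n", xlab = "FPR", ylab = "TPR", ...)
  abline(0, 1, lty = 3)
  if (!is.null(x$roc_synergy))
    lines(x$roc_synergy$fpr, x$roc_synergy$tpr, type = "s", col = 2)
  if (!is.null(x$roc_antagonism))
    lines(x$roc_antagonism$fpr, x$roc_antagonism$tpr, type = "s", col = 4)
  legend("bottomright", lty = 1, col = c(2, 4), bty = "n",
         legend = c(sprintf("synergy (AUC %.2f)", x$auc_synergy),
                    sprintf("antagonism (AUC %.2f)", x$auc_antagonism)))
  invisible(x)
}
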