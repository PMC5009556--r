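erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Concordance index between two rankings
#'
#' Fraction of the \eqn{C(n,2)} item pairs ranked in the same relative
#' order by `u` (reference) and `v` (prediction). A pair tied in either
#' ranking contributes 0.5.
#'
#' @param u reference ranks (rank 1 = most synergistic).
#' @param v predicted ranks, same length.
#' @return Index in \[0, 1\].
#' @export
c_index <- function(u, v) {
  n <- length(u)
  if (length(v) != n) stop("rank vectors differ in length")
  if (n < 2L) stop("need at least two items")
  total <- 0
  for (q in seq_len(n - 1L)) {
    du <- u[q] - u[(q + 1L):n]
    dv <- v[q] - v[(q + 1L):n]
    s <- sign(du) * sign(dv)
    total <- total + sum(ifelse(s == 0, 0.5, (s + 1) / 2))
  }
  total / choose(n, 2)
}

#' Read a gold standard of measured drug-pair synergy
#'
#' @param path TSV with columns `drug_a`, `drug_b`, `eob_mean`,
#'   `eob_sem` (excess over Bliss and its standard error).
#' @return A `gold_standard` data.frame with derived columns `gold_rank`
#'   (1 = highest EOB) and `class`
#'   (synergistic/antagonistic/additive from [snr_classify()]).
#' @export
read_gold_standard <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  gold_standard(tab)
}

#' Construct a gold standard from a data.frame
#'
#' @param tab data.frame with `drug_a`, `drug_b`, `eob_mean`, `eob_sem`.
#' @return A `gold_standard` data.frame (see [read_gold_standard()]).
#' @export
gold_standard <- function(tab) {
  req <- c("drug_a", "drug_b", "eob_mean", "eob_sem")
  if (!all(req %in% names(tab)))
    stop("gold standard needs columns: ", paste(req, collapse = ", "))
  key <- paste(pmin(tab$drug_a, tab$drug_b), pmax(tab$drug_a, tab$drug_b))
  if (anyDuplicated(key)) stop("duplicated drug pair(s) in gold standard")
  if (any(tab$eob_sem < 0)) stop("negative eob_sem")
  ord <- order(-tab$eob_mean, tab$drug_a, tab$drug_b)
  tab$gold_rank <- integer(nrow(tab))
  tab$gold_rank[ord] <- seq_len(nrow(tab))
  tab$class <- snr_classify(tab$eob_mean, tab$eob_sem)
  class(tab) <- c("gold_standard", "data.frame")
  tab
}

#' SNR-based synergy classification
#'
#' The signal-to-noise ratio of a drug pair is its mean excess over Bliss
#' divided by the standard error of that mean. A pair is synergistic when
#' SNR > 2 with positive EOB, antagonistic when |SNR| > 2 with negative
#' EOB, and additive otherwise.
#'
#' @param eob_mean mean EOB value(s).
#' @param eob_sem standard error(s) of the mean EOB, positive.
#' @return Character vector of class labels.
#' @export
snr_classify <- function(eob_mean, eob_sem) {
  stopifnot(all(eob_sem > 0))
  snr <- eob_mean / eob_sem
  ifelse(snr > 2 & eob_mean > 0, "synergistic",
         ifelse(abs(snr) > 2 & eob_mean < 0, "antagonistic", "additive"))
}

#' Probabilistic concordance index
#'
#' Soft concordance between a predicted ranking and measured synergy,
#' weighting each pair comparison by how distinguishable the two EOB
#' measurements are:
#' \deqn{t'_{q,r} = \tfrac12 \pm \tfrac12\,
#'   \mathrm{erf}\!\left(\frac{EOB_q - EOB_r}
#'   {\sqrt{sem_q^2 + sem_r^2}}\right)}
#' with the plus branch when the prediction ranks pair q better than pair
#' r. Predicted ties contribute 0.5 (the two branches averaged). The
#' PC-index is the mean of \eqn{t'_{q,r}} over all unordered pairs.
#'
#' @param gold a [gold_standard()] (uses `eob_mean`, `eob_sem`).
#' @param v predicted ranks aligned with the gold standard rows
#'   (rank 1 = most synergistic).
#' @return PC-index in \[0, 1\].
#' @export
pc_index <- function(gold, v) {
  eob <- gold$eob_mean
  sem <- gold$eob_sem
  n <- length(eob)
  if (length(v) != n) stop("rank vector length mismatch")
  if (n < 2L) stop("need at least two pairs")
  total <- 0
  for (q in seq_len(n - 1L)) {
    r <- (q + 1L):n
    denom <- sqrt(sem[q]^2 + sem[r]^2)
    num <- eob[q] - eob[r]
    e <- ifelse(denom == 0, ifelse(num == 0, 0, sign(num)), erf(num / denom))
    dir <- sign(v[r] - v[q])   # +1 when q predicted better (smaller rank)
    total <- total + sum(0.5 + 0.5 * dir * e)
  }
  total / choose(n, 2)
}

#' Attainable PC-index extremes of a gold standard
#'
#' The maximum PC-index is attained by ranking pairs by EOB descending,
#' the minimum by the reverse; measurement noise keeps them away from 1
#' and 0.
#'
#' @param gold a [gold_standard()].
#' @return Named numeric `c(pc_max = , pc_min = )`.
#' @export
pc_extremes <- function(gold) {
  n <- nrow(gold)
  ord <- order(-gold$eob_mean, gold$drug_a, gold$drug_b)
  v_best <- integer(n); v_best[ord] <- seq_len(n)
  c(pc_max = pc_index(gold, v_best),
    pc_min = pc_index(gold, (n + 1L) - v_best))
}

#' Normalize a PC-index to its attainable range
#'
#' @param pc observed PC-index.
#' @param pc_max,pc_min attainable extremes from [pc_extremes()].
#' @return `(pc - pc_min)/(pc_max - pc_min)`.
#' @export
normalize_pc <- function(pc, pc_max, pc_min) {
  if (pc_max <= pc_min) stop("degenerate gold standard: pc_max <= pc_min")
  (pc - pc_min) / (pc_max - pc_min)
}

#' Permutation p-value for a PC-index
#'
#' Upper-tail empirical p-value of the observed PC-index against `B`
#' random permutations of the predicted ranking, with the +1 correction.
#'
#' @param gold a [gold_standard()].
#' @param v predicted ranks.
#' @param B number of permutations.
#' @param seed integer seed.
#' @return List with `p` and the null `pc_null` vector.
#' @export
pc_permutation_p <- function(gold, v, B = 10000, seed) {
  if (missing(seed)) stop("`seed` is required")
  obs <- pc_index(gold, v)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  null <- vapply(seq_len(B), function(b)
    pc_index(gold, sample(v)), numeric(1))
  list(p = (sum(null >= obs) + 1) / (B + 1), pc = obs, pc_null = null)
}

#' ROC curve for synergy or antagonism prediction
#'
#' Sweeps the number of top-ranked pairs called positive from 0 to n and
#' reports the (FPR, TPR) staircase with its trapezoidal AUC. For synergy
#' the ranking is swept from the most synergistic end (rank 1 first); for
#' antagonism from the least synergistic end.
#'
#' @param labels class labels (from [snr_classify()]).
#' @param v predicted ranks (1 = most synergistic).
#' @param direction `"synergy"` or `"antagonism"`; sets both the sweep
#'   order and which label counts as positive.
#' @return List with `points` (data.frame `i`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(labels, v, direction = c("synergy", "antagonism")) {
  direction <- match.arg(direction)
  positive <- if (direction == "synergy") "synergistic" else "antagonistic"
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("need at least one positive and one negative label")
  ord <- if (direction == "synergy") order(v) else order(-v)
  n <- length(v)
  P <- sum(pos); N <- n - P
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(i = 0:n, fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision of the top-k calls
#'
#' Fraction of the k best-ranked pairs (direction as in [roc_curve()])
#' carrying the positive class label. The reference analysis used k equal
#' to the number of gold-standard positives (16 synergistic, 36
#' antagonistic of 91 pairs).
#'
#' @inheritParams roc_curve
#' @param k number of top calls, in 1..n.
#' @return Precision in \[0, 1\].
#' @export
precision_at_k <- function(labels, v, k, direction = c("synergy", "antagonism")) {
  direction <- match.arg(direction)
  n <- length(v)
  stopifnot(k >= 1, k <= n)
  positive <- if (direction == "synergy") "synergistic" else "antagonistic"
  ord <- if (direction == "synergy") order(v) else order(-v)
  sum(labels[ord][seq_len(k)] == positive) / k
}

#' Evaluate a predicted ranking against a gold standard
#'
#' Computes the full evaluation report: c-index, PC-index with permutation
#' p-value, attainable extremes and normalized PC-index, ROC/AUC and
#' precision for synergy and antagonism, and the SNR class counts.
#'
#' @param object a [pair_scores()] table.
#' @param gold a [gold_standard()]; must contain exactly the same
#'   unordered drug pairs.
#' @param score which score column to evaluate (default `co_gene_gs`).
#' @param B permutations for the PC-index p-value.
#' @param seed integer seed for the permutation p-value.
#' @param ... unused.
#' @return Object of class `synergy_eval` (a list of the quantities
#'   above) with print method.
#' @export
evaluate <- function(object, ...) UseMethod("evaluate")

#' @rdname evaluate
#' @export
evaluate.pair_score_table <- function(object, gold,
                                      score = "co_gene_gs",
                                      B = 10000, seed = 1L, ...) {
  stopifnot(inherits(gold, "gold_standard"))
  key_pred <- paste(pmin(object$drug_a, object$drug_b),
                    pmax(object$drug_a, object$drug_b))
  key_gold <- paste(pmin(gold$drug_a, gold$drug_b),
                    pmax(gold$drug_a, gold$drug_b))
  unmatched <- c(setdiff(key_pred, key_gold), setdiff(key_gold, key_pred))
  if (length(unmatched) > 0)
    stop("drug pairs not shared between prediction and gold standard: ",
         paste(unmatched, collapse = "; "))
  gold <- gold[match(key_pred, key_gold), , drop = FALSE]

  v <- object[[paste0("rank_", score)]]
  if (is.null(v)) v <- rank_pairs(object, score)
  u <- gold$gold_rank

  perm <- pc_permutation_p(gold, v, B = B, seed = seed)
  ext <- pc_extremes(gold)

  labels <- gold$class
  two_class <- function(dir, positive, k) {
    if (any(labels == positive) && !all(labels == positive)) {
      roc <- roc_curve(labels, v, dir)
      list(auc = roc$auc, roc = roc$points,
           precision = precision_at_k(labels, v, k, dir))
    } else list(auc = NA_real_, roc = NULL, precision = NA_real_)
  }
  n_syn <- sum(labels == "synergistic")
  n_ant <- sum(labels == "antagonistic")
  syn <- two_class("synergy", "synergistic", max(n_syn, 1L))
  ant <- two_class("antagonism", "antagonistic", max(n_ant, 1L))

  structure(
    list(score = score,
         n_pairs = nrow(gold),
         c_index = c_index(u, v),
         pc_index = perm$pc,
         pc_p = perm$p,
         pc_B = B, seed = seed,
         pc_max = unname(ext["pc_max"]),
         pc_min = unname(ext["pc_min"]),
         pc_index_norm = unname(
           normalize_pc(perm$pc, ext["pc_max"], ext["pc_min"])),
         auc_synergy = syn$auc, auc_antagonism = ant$auc,
         roc_synergy = syn$roc, roc_antagonism = ant$roc,
         precision_synergy = syn$precision,
         precision_antagonism = ant$precision,
         class_counts = table(factor(labels, levels = c(
           "synergistic", "antagonistic", "additive")))),
    class = "synergy_eval"
  )
}

#' @export
print.synergy_eval <- function(x, ...) {
  cat("Synergy ranking evaluation (", x$score, ", ", x$n_pairs,
      " pairs)\n", sep = "")
  cat(sprintf("  c-index        %.4f\n", x$c_index))
  cat(sprintf("  PC-index       %.4f  (perm. p = %.4g, B = %d)\n",
              x$pc_index, x$pc_p, x$pc_B))
  cat(sprintf("  PC range       [%.4f, %.4f]  normalized PC = %.4f\n",
              x$pc_min, x$pc_max, x$pc_index_norm))
  cat(sprintf("  AUC            synergy %.3f | antagonism %.3f\n",
              x$auc_synergy, x$auc_antagonism))
  cat(sprintf("  Precision      synergy %.1f%% | antagonism %.1f%%\n",
              100 * x$precision_synergy, 100 * x$precision_antagonism))
  cat("  classes       ",
      paste(names(x$class_counts), as.integer(x$class_counts),
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Write an evaluation report
#'
#' @param report a [evaluate()] result.
#' @param path flat key-value TSV for the scalar metrics.
#' @param roc_path optional TSV of the ROC staircase points for both
#'   directions.
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, path, roc_path = NULL) {
  kv <- data.frame(
    key = c("score", "n_pairs", "c_index", "pc_index", "pc_p", "pc_B",
            "seed", "pc_max", "pc_min", "pc_index_norm", "auc_synergy",
            "auc_antagonism", "precision_synergy", "precision_antagonism",
            paste0("n_", names(report$class_counts))),
    value = c(report$score, report$n_pairs, report$c_index,
              report$pc_index, report$pc_p, report$pc_B, report$seed,
              report$pc_max, report$pc_min, report$pc_index_norm,
              report$auc_synergy, report$auc_antagonism,
              report$precision_synergy, report$precision_antagonism,
              as.integer(report$class_counts)))
  utils::write.table(kv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(roc_path)) {
    rocs <- rbind(
      if (!is.null(report$roc_synergy))
        cbind(direction = "synergy", report$roc_synergy),
      if (!is.null(report$roc_antagonism))
        cbind(direction = "antagonism", report$roc_antagonism))
    utils::write.table(rocs, roc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
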