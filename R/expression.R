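#' Construct an expression study
#'
#' An expression study bundles a normalized genes-by-samples expression
#' matrix with per-sample annotations identifying the drug, the
#' concentration label and the vehicle (DMSO) control columns.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row
#'   names are gene identifiers, column names are sample identifiers.
#' @param samples data.frame with columns `sample_id`, `drug`,
#'   `concentration`, `is_control` (logical), one row per column of
#'   `values`, in any order.
#'
#' @details Rows containing missing values are dropped with a warning;
#'   duplicated gene identifiers are collapsed by their mean. At least one
#'   control sample is required and every non-control sample must carry a
#'   non-empty drug name.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `values` (matrix), `genes` (character), `samples` (data.frame).
#' @export
expression_study <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  req <- c("sample_id", "drug", "concentration", "is_control")
  if (!all(req %in% names(samples)))
    stop("`samples` must have columns: ", paste(req, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$drug <- as.character(samples$drug)
  samples$concentration <- as.character(samples$concentration)
  samples$is_control <- as.logical(samples$is_control)

  missing_meta <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_meta) > 0)
    stop("sample column(s) without metadata: ",
         paste(missing_meta, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  if (!any(samples$is_control))
    stop("no control (vehicle) sample in metadata")
  bad_drug <- !samples$is_control & (is.na(samples$drug) | samples$drug == "")
  if (any(bad_drug))
    stop("non-control sample(s) without a drug name: ",
         paste(samples$sample_id[bad_drug], collapse = ", "))

  has_na <- apply(values, 1L, function(r) any(!is.finite(r)))
  if (any(has_na)) {
    warning(sum(has_na), " gene row(s) with missing values dropped")
    values <- values[!has_na, , drop = FALSE]
  }
  dup <- duplicated(rownames(values))
  if (any(dup)) {
    warning(sum(dup), " duplicated gene row(s) collapsed by mean")
    values <- rowsum(values, group = rownames(values), reorder = FALSE) /
      as.vector(table(rownames(values))[unique(rownames(values))])
  }
  if (nrow(values) == 0L) stop("no genes left after validation")

  structure(
    list(values = values, genes = rownames(values), samples = samples),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat("Expression study:", length(x$genes), "genes x",
      nrow(x$samples), "samples\n")
  cat("  controls:", sum(x$samples$is_control),
      " drugs:", length(unique(x$samples$drug[!x$samples$is_control])), "\n")
  invisible(x)
}

#' Read an expression matrix with sample metadata
#'
#' Reads a tab-separated genes-by-samples matrix (plain TSV with a header
#' row of sample identifiers, or the GCT 1.2 dialect with its two-line
#' header and NAME/Description columns) together with a 4-column metadata
#' TSV (`sample_id`, `drug`, `concentration`, `is_control`).
#'
#' @param path expression matrix file (TSV or GCT 1.2).
#' @param metadata path to the sample metadata TSV.
#' @return An [expression_study()].
#' @export
read_expression <- function(path, metadata) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (!file.exists(metadata)) stop("metadata file not found: ", metadata)

  first <- readLines(path, n = 1L)
  if (identical(trimws(first), "#1.2")) {
    tab <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -(1:2), drop = FALSE])   # drop NAME, Description
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- genes

  meta <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  if (is.character(meta$is_control))
    meta$is_control <- tolower(meta$is_control) %in% c("true", "1", "yes")
  expression_study(vals, meta)
}

#' Write an expression study to TSV
#'
#' @param study an [expression_study()].
#' @param path output matrix TSV (gene identifiers in column 1).
#' @param metadata optional path for the sample metadata TSV.
#' @return `study`, invisibly.
#' @export
write_expression <- function(study, path, metadata = NULL) {
  tab <- data.frame(gene = study$genes, study$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata))
    utils::write.table(study$samples, metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(study)
}

#' Delta z-score profile of a treated sample versus the vehicle control
#'
#' Each gene is z-transformed across all samples of the study
#' (\eqn{(X_{i,j} - \mu_j)/\sigma_j}) and the z-transformed control value
#' is subtracted, yielding the delta z-score
#' \deqn{Z_{i,j} = \frac{X_{i,j}-\mu_j}{\sigma_j} -
#'   \frac{X_{ctrl,j}-\mu_j}{\sigma_j}.}
#' Genes with zero variance across samples have no defined z-score and are
#' dropped with a message.
#'
#' @param study an [expression_study()].
#' @param sample_id treated sample identifier.
#' @param control_id control sample identifier(s); defaults to all samples
#'   flagged `is_control`. With several controls their z-transformed
#'   values are averaged before subtraction.
#' @param std_mode `"sample"` (n-1 denominator, default) or
#'   `"population"` (n) for \eqn{\sigma_j}.
#' @return An object of class `delta_z_profile`: list with `drug`,
#'   `concentration`, `z` (named numeric over retained genes),
#'   `significant` (logical, NA until [gene_significance()] is applied).
#' @export
delta_z <- function(study, sample_id,
                    control_id = NULL,
                    std_mode = c("sample", "population")) {
  std_mode <- match.arg(std_mode)
  stopifnot(inherits(study, "expression_study"))
  if (is.null(control_id))
    control_id <- study$samples$sample_id[study$samples$is_control]
  ids <- colnames(study$values)
  unknown <- setdiff(c(sample_id, control_id), ids)
  if (length(unknown) > 0)
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  if (length(sample_id) != 1L) stop("`sample_id` must be a single id")
  if (length(control_id) < 1L) stop("no control sample given")

  X <- study$values
  n <- ncol(X)
  mu <- rowMeans(X)
  if (std_mode == "sample") {
    sigma <- sqrt(rowSums((X - mu)^2) / (n - 1L))
  } else {
    sigma <- sqrt(rowSums((X - mu)^2) / n)
  }
  keep <- sigma > 0
  if (!all(keep))
    message(sum(!keep), " zero-variance gene(s) dropped from profile")

  zt <- (X[keep, sample_id] - mu[keep]) / sigma[keep]
  zc <- (X[keep, control_id, drop = FALSE] - mu[keep]) / sigma[keep]
  z <- zt - rowMeans(zc)
  names(z) <- study$genes[keep]

  i <- match(sample_id, study$samples$sample_id)
  structure(
    list(drug = study$samples$drug[i],
         concentration = study$samples$concentration[i],
         sample_id = sample_id,
         z = z,
         significant = rep(NA, length(z))),
    class = "delta_z_profile"
  )
}

#' @export
print.delta_z_profile <- function(x, ...) {
  cat("Delta z-profile:", x$drug, "@", x$concentration,
      "(", length(x$z), "genes )\n")
  if (!anyNA(x$significant))
    cat("  significant genes:", sum(x$significant), "\n")
  invisible(x)
}

#' Flag genes with significant delta z-scores
#'
#' A gene is called significant when the two-tailed standard-normal tail
#' probability of its delta z-score is below `alpha` (strict inequality).
#' The default null variance 1 gives the familiar |z| > 1.96 call at
#' `alpha = 0.05`; `null_variance = 2` treats the delta z-score as the
#' difference of two independent standard normals.
#'
#' @param profile a [delta_z()] profile.
#' @param alpha gene-level significance level in (0, 1).
#' @param null_variance variance of the null normal for the delta z-score.
#' @return The profile with its `significant` vector filled in.
#' @export
gene_significance <- function(profile, alpha = 0.05, null_variance = 1) {
  stopifnot(inherits(profile, "delta_z_profile"),
            alpha > 0, alpha <= 1, null_variance > 0)
  p <- 2 * stats::pnorm(-abs(profile$z) / sqrt(null_variance))
  profile$significant <- p < alpha
  profile
}

#' All treatment profiles of a study
#'
#' Convenience wrapper running [delta_z()] and [gene_significance()] for
#' every non-control sample.
#'
#' @inheritParams delta_z
#' @inheritParams gene_significance
#' @return A list of `delta_z_profile` objects, one per treated sample.
#' @export
study_profiles <- function(study, std_mode = "sample",
                           alpha = 0.05, null_variance = 1) {
  treated <- study$samples$sample_id[!study$samples$is_control]
  lapply(treated, function(s)
    gene_significance(delta_z(study, s, std_mode = std_mode),
                      alpha = alpha, null_variance = null_variance))
}
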