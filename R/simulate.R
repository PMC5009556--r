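#' Simulation configuration
#'
#' Parameters of the planted-perturbation generator. The defaults mirror
#' the screening design the method was built for: a drug panel profiled
#' at two concentrations plus a vehicle control on a genome-scale array,
#' with each drug perturbing a block of pathways from a druggable pool.
#'
#' @param n_genes genes on the array.
#' @param n_sets gene sets in the collection.
#' @param set_size_range inclusive range of set sizes. The default floor
#'   of 20 keeps the permutation null of the mean-z set statistic narrow
#'   enough that truly perturbed sets reliably reach the empirical
#'   p-value floor.
#' @param n_drugs drugs in the panel.
#' @param sets_per_drug pathways perturbed by each drug. Kept large
#'   enough (default 12) that a treatment's truly enriched sets can
#'   clear Benjamini-Hochberg at FDR 0.05 given the empirical p-value
#'   floor of 1/(B+1): with B = 200 and 100 sets, at least 10 sets must
#'   reach the floor before any discovery is possible.
#' @param pool_size size of the "druggable" pathway pool drugs draw
#'   their perturbed sets from; the remaining sets are never perturbed.
#' @param overlap how perturbed sets are assigned: `"window"` (default)
#'   places each drug on a circular window over the pool so that pair
#'   overlap decays gradually with panel distance, from near-identical
#'   neighbours to disjoint distant drugs; `"random"` samples each
#'   drug's sets independently from the pool.
#' @param n_concentrations profiles per drug; concentration labels are
#'   `c1` (full effect), `c2` (half), and so on.
#' @param effect effect size, in units of `noise_sd`, added to member
#'   genes of a drug's perturbed sets at the highest concentration.
#' @param noise_sd standard deviation of the Gaussian measurement noise.
#' @param eob_scale scale mapping planted overlap (Jaccard in \[0,1\]) to
#'   EOB units in the planted gold standard.
#' @param eob_noise_sd Gaussian noise on the planted EOB; also reported
#'   as the sem (single-draw convention).
#' @param B permutations for downstream enrichment analysis.
#' @param seed integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_sets = 100,
                       set_size_range = c(20, 50),
                       n_drugs = 8, sets_per_drug = 12, pool_size = 32,
                       overlap = c("window", "random"),
                       n_concentrations = 2,
                       effect = 2, noise_sd = 1,
                       eob_scale = 10, eob_noise_sd = 0.5,
                       B = 200, seed) {
  if (missing(seed)) stop("`seed` is required")
  overlap <- match.arg(overlap)
  stopifnot(n_genes > 0, n_sets > 0, n_drugs > 1,
            sets_per_drug > 0, pool_size >= sets_per_drug,
            pool_size <= n_sets, n_concentrations >= 1,
            is.finite(effect), noise_sd > 0, eob_noise_sd > 0,
            set_size_range[1] >= 1, set_size_range[2] >= set_size_range[1])
  if (set_size_range[2] > n_genes) stop("set size exceeds n_genes")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an expression study with planted pathway perturbations
#'
#' Generates a normalized expression matrix (log2-intensity scale,
#' baseline ~ N(8, 1)), a gene-set collection of random sets, and treated
#' samples in which the member genes of each drug's assigned sets are
#' shifted by `effect * noise_sd` (scaled by 1, 1/2, ... per
#' concentration index) on top of N(0, `noise_sd`) measurement noise.
#' The planted truth records each drug's perturbed sets and genes, and
#' the pairwise Jaccard overlap of perturbed genes that defines
#' ground-truth synergy.
#'
#' @param cfg a [sim_config()].
#' @return List with `study` ([expression_study()]), `collection`
#'   ([geneset_collection()]), and `truth` (list: `drug_sets`,
#'   `drug_genes`, `overlap` data.frame of all unordered drug pairs with
#'   their Jaccard overlap).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  sizes <- sample(cfg$set_size_range[1]:cfg$set_size_range[2],
                  cfg$n_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(genes, k))
  names(sets) <- sprintf("SET%03d", seq_len(cfg$n_sets))
  coll <- geneset_collection(sets, universe = genes)

  drugs <- sprintf("drug%02d", seq_len(cfg$n_drugs))
  pool <- names(sets)[seq_len(cfg$pool_size)]
  if (cfg$overlap == "window") {
    step <- max(1L, cfg$pool_size %/% cfg$n_drugs)
    drug_sets <- lapply(seq_len(cfg$n_drugs), function(k) {
      idx <- ((k - 1L) * step + seq_len(cfg$sets_per_drug) - 1L) %%
        cfg$pool_size + 1L
      pool[idx]
    })
  } else {
    drug_sets <- lapply(seq_len(cfg$n_drugs), function(k)
      sample(pool, cfg$sets_per_drug))
  }
  names(drug_sets) <- drugs
  drug_genes <- lapply(drug_sets, function(s) unique(unlist(sets[s])))

  conc_labels <- paste0("c", seq_len(cfg$n_concentrations))
  conc_mult <- 1 / seq_len(cfg$n_concentrations)  # c1 full, c2 half, ...

  sample_ids <- c("DMSO",
                  as.vector(t(outer(drugs, conc_labels, paste, sep = "_"))))
  baseline <- stats::rnorm(cfg$n_genes, mean = 8, sd = 1)
  X <- matrix(stats::rnorm(cfg$n_genes * length(sample_ids),
                           sd = cfg$noise_sd),
              nrow = cfg$n_genes) + baseline
  colnames(X) <- sample_ids
  rownames(X) <- genes

  meta <- data.frame(sample_id = sample_ids,
                     drug = c("", rep(drugs, each = cfg$n_concentrations)),
                     concentration = c("", rep(conc_labels, cfg$n_drugs)),
                     is_control = c(TRUE, rep(FALSE, length(sample_ids) - 1L)),
                     stringsAsFactors = FALSE)
  for (d in drugs) {
    gidx <- match(drug_genes[[d]], genes)
    for (ci in seq_len(cfg$n_concentrations)) {
      col <- paste(d, conc_labels[ci], sep = "_")
      X[gidx, col] <- X[gidx, col] +
        cfg$effect * cfg$noise_sd * conc_mult[ci]
    }
  }
  study <- expression_study(X, meta)

  pairs <- utils::combn(drugs, 2L)
  jac <- apply(pairs, 2L, function(p) {
    a <- drug_genes[[p[1L]]]; b <- drug_genes[[p[2L]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  overlap <- data.frame(drug_a = pairs[1L, ], drug_b = pairs[2L, ],
                        jaccard = jac, stringsAsFactors = FALSE)

  list(study = study, collection = coll,
       truth = list(drug_sets = drug_sets, drug_genes = drug_genes,
                    overlap = overlap))
}

#' Planted gold standard from simulation truth
#'
#' Maps the planted pairwise overlap to an EOB-style gold standard:
#' `eob_mean = eob_scale * jaccard + N(0, eob_noise_sd)`, with
#' `eob_sem = eob_noise_sd` for every pair; ranks and SNR classes are
#' derived as for a measured gold standard.
#'
#' @param truth the `truth` element of [simulate_study()].
#' @param cfg the same [sim_config()] (uses `eob_scale`, `eob_noise_sd`,
#'   `seed`).
#' @return A [gold_standard()] data.frame.
#' @export
planted_gold_standard <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(cfg$seed + 1L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  ov <- truth$overlap
  gold_standard(data.frame(
    drug_a = ov$drug_a, drug_b = ov$drug_b,
    eob_mean = cfg$eob_scale * ov$jaccard +
      stats::rnorm(nrow(ov), sd = cfg$eob_noise_sd),
    eob_sem = cfg$eob_noise_sd,
    stringsAsFactors = FALSE))
}
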