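# Small in-code fixtures shared across test files.

# A tiny study: `n_genes` genes, one DMSO control plus one sample per drug.
toy_study <- function(n_genes = 6, drugs = c("A", "B"), seed = 42,
                      shift = NULL) {
  set.seed(seed)
  ids <- c("ctrl", drugs)
  X <- matrix(rnorm(n_genes * length(ids), mean = 8),
              nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)), ids))
  if (!is.null(shift))
    for (d in names(shift)) X[shift[[d]], d] <- X[shift[[d]], d] + 5
  meta <- data.frame(sample_id = ids,
                     drug = c("", drugs),
                     concentration = c("", rep("c1", length(drugs))),
                     is_control = c(TRUE, rep(FALSE, length(drugs))))
  expression_study(X, meta)
}

# A delta-z profile with prescribed z values, bypassing the matrix.
toy_profile <- function(z, drug = "A", concentration = "c1") {
  structure(list(drug = drug, concentration = concentration,
                 sample_id = drug, z = z,
                 significant = rep(NA, length(z))),
            class = "delta_z_profile")
}

# A drug signature with prescribed components.
toy_signature <- function(drug, sig_genes, enr_sets, concentration = "c1") {
  structure(list(drug = drug, concentration = concentration,
                 significant_genes = sig_genes, enriched_sets = enr_sets),
            class = "drug_signature")
}

# Independent concordance oracle: brute-force double loop over item pairs.
brute_c_index <- function(u, v) {
  n <- length(u)
  tot <- 0
  for (q in 1:(n - 1)) for (r in (q + 1):n) {
    if (u[q] == u[r] || v[q] == v[r]) tot <- tot + 0.5
    else if ((u[q] < u[r]) == (v[q] < v[r])) tot <- tot + 1
  }
  tot / choose(n, 2)
}

# Independent BH step-up oracle.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
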