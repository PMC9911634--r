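# Small in-code fixtures shared across test files.

# Tiny deterministic expression matrix with named genes/samples.
toy_expr <- function(genes = 5L, samples = 4L, seed = 42L) {
  set.seed(seed)
  m <- matrix(round(runif(genes * samples, 0, 8), 3), nrow = genes,
              dimnames = list(sprintf("G%d", seq_len(genes)),
                              sprintf("S%d", seq_len(samples))))
  m
}

# Annotation for 2 patients x 2 regions matching toy_expr(samples = 4).
toy_annot <- function() {
  tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S4"),
    patient_id = c("P1", "P1", "P2", "P2"),
    region_id = c("R1", "R2", "R1", "R2")
  )
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Brute-force one-way ANOVA ICC oracle: explicit loops, no shared code
# with icc_oneway().
icc_bruteforce <- function(values, group) {
  groups <- unique(group)
  P <- length(groups)
  N <- length(values)
  m <- 0
  for (v in values) m <- m + v / N
  msb <- 0
  ssw <- 0
  sum_np2 <- 0
  for (g in groups) {
    x <- values[group == g]
    n_g <- length(x)
    m_g <- 0
    for (v in x) m_g <- m_g + v / n_g
    msb <- msb + n_g * (m_g - m)^2
    for (v in x) ssw <- ssw + (v - m_g)^2
    sum_np2 <- sum_np2 + n_g^2
  }
  msb <- msb / (P - 1)
  msw <- ssw / (N - P)
  k0 <- (N - sum_np2 / N) / (P - 1)
  if (msb == 0 && msw == 0) return(1)
  min(max((msb - msw) / (msb + (k0 - 1) * msw), 0), 1)
}
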