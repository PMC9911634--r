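#' Simulate a multi-region tumor expression cohort with known structure
#'
#' Generates a gene-by-sample log2-scale expression matrix for `n_patients`
#' tumors sampled at several intra-tumor regions each, with four planted
#' gene categories:
#'
#' * `clonal_immune`: driven by a patient-level immune infiltration level
#'   \eqn{\theta_p} with only small region-to-region jitter — the genes an
#'   ITH-robust inflamed signature should recover;
#' * `subclonal_immune`: driven by a region-level immune level that
#'   deviates strongly from the patient level — immune-correlated but
#'   heterogeneous, the genes an IHS filter should remove;
#' * `subclonal_background`: immune-independent genes with large
#'   region-level expression deviations;
#' * `stable_background`: the remainder, with small region-level noise.
#'
#' The generative model for gene g in patient p, region r is
#' \deqn{x_{g,pr} = \mu_0 + a_{g,p} + \mathrm{effect}_{g,pr} + \varepsilon_{g,pr}}
#' with gene-by-patient baseline \eqn{a_{g,p} \sim N(0, \sigma_a^2)},
#' measurement noise \eqn{\varepsilon \sim N(0, \sigma_e^2)}, and an effect
#' of \eqn{\beta\,\theta^{clonal}_{pr}} (clonal immune),
#' \eqn{\beta\,\theta^{subclonal}_{pr}} (subclonal immune),
#' \eqn{N(0,\sigma_s^2)} per gene and region (subclonal background) or
#' \eqn{N(0,\sigma_r^2)} (stable background). Immune drivers are
#' \eqn{\theta_p \sim U(0,1)},
#' \eqn{\theta^{clonal}_{pr} = \mathrm{clip}_{[0,1]}(\theta_p + N(0,0.05))},
#' \eqn{\theta^{subclonal}_{pr} = \mathrm{clip}_{[0,1]}(\theta_p + N(0,0.35))}.
#' Values are clipped at 0 after generation, mimicking the log2(x+1) floor.
#'
#' @param n_patients Number of patients (>= 2).
#' @param regions_per_patient Regions sampled per patient: a single integer
#'   or one integer per patient (each >= 2).
#' @param n_genes Total genes simulated.
#' @param n_clonal_immune,n_subclonal_immune,n_subclonal_background Sizes
#'   of the planted categories (the remainder is stable background).
#' @param baseline_mean Grand mean expression, log2 units.
#' @param patient_sd SD of the gene-by-patient baseline \eqn{a_{g,p}}.
#' @param region_sd_clonal Region-level SD of stable background genes.
#' @param region_sd_subclonal Region-level SD of subclonal background genes.
#' @param immune_effect Effect size \eqn{\beta} (log2 units) of the immune
#'   driver on immune-category genes.
#' @param noise_sd Measurement noise SD.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A list with elements `expr` (matrix, genes x samples), `annot`
#'   (tibble: sample_id, patient_id, region_id) and `truth` (list:
#'   `gene_category` named per-gene factor, `patient_theta`, `region_theta`
#'   tibble with clonal and subclonal drivers per sample, `true_class`
#'   named logical — patients whose \eqn{\theta_p} reaches the cohort's
#'   upper tertile).
#' @export
simulate_cohort <- function(n_patients = 20L,
                            regions_per_patient = 4L,
                            n_genes = 3000L,
                            n_clonal_immune = 150L,
                            n_subclonal_immune = 150L,
                            n_subclonal_background = 300L,
                            baseline_mean = 3.0,
                            patient_sd = 0.8,
                            region_sd_clonal = 0.15,
                            region_sd_subclonal = 1.2,
                            immune_effect = 2.0,
                            noise_sd = 0.3,
                            seed = 1L) {
  P <- as.integer(n_patients)
  if (P < 2L) abort("need at least 2 patients")
  np <- as.integer(regions_per_patient)
  if (length(np) == 1L) np <- rep(np, P)
  if (length(np) != P) abort("regions_per_patient must be length 1 or n_patients")
  if (any(np < 2L)) abort("every patient needs at least 2 regions")
  G <- as.integer(n_genes)
  n_ci <- as.integer(n_clonal_immune)
  n_si <- as.integer(n_subclonal_immune)
  n_sb <- as.integer(n_subclonal_background)
  if (n_ci + n_si + n_sb > G) abort("gene category counts exceed n_genes")
  stopifnot(patient_sd >= 0, region_sd_clonal >= 0, region_sd_subclonal >= 0,
            noise_sd >= 0)

  set.seed(as.integer(seed))

  N <- sum(np)
  patient_ids <- sprintf("P%02d", seq_len(P))
  patient_of <- rep(seq_len(P), np)
  region_of <- unlist(lapply(np, seq_len))
  sample_ids <- sprintf("%s_R%d", patient_ids[patient_of], region_of)
  annot <- tibble(
    sample_id = sample_ids,
    patient_id = patient_ids[patient_of],
    region_id = sprintf("R%d", region_of)
  )

  gene_ids <- sprintf("G%05d", seq_len(G))
  category <- rep("stable_background", G)
  category[seq_len(n_ci)] <- "clonal_immune"
  if (n_si > 0L) category[n_ci + seq_len(n_si)] <- "subclonal_immune"
  if (n_sb > 0L) category[n_ci + n_si + seq_len(n_sb)] <- "subclonal_background"
  names(category) <- gene_ids

  theta_p <- runif(P)
  names(theta_p) <- patient_ids
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  theta_clonal <- clip01(theta_p[patient_of] + rnorm(N, 0, 0.05))
  theta_subclonal <- clip01(theta_p[patient_of] + rnorm(N, 0, 0.35))

  # gene-by-patient baseline, expanded to samples
  a_gp <- matrix(rnorm(G * P, 0, patient_sd), nrow = G)
  expr <- baseline_mean + a_gp[, patient_of, drop = FALSE]

  is_ci <- category == "clonal_immune"
  is_si <- category == "subclonal_immune"
  is_sb <- category == "subclonal_background"
  is_st <- category == "stable_background"
  if (any(is_ci)) {
    expr[is_ci, ] <- expr[is_ci, , drop = FALSE] +
      rep(immune_effect * theta_clonal, each = sum(is_ci))
  }
  if (any(is_si)) {
    expr[is_si, ] <- expr[is_si, , drop = FALSE] +
      rep(immune_effect * theta_subclonal, each = sum(is_si))
  }
  if (any(is_sb)) {
    expr[is_sb, ] <- expr[is_sb, , drop = FALSE] +
      matrix(rnorm(sum(is_sb) * N, 0, region_sd_subclonal), ncol = N)
  }
  if (any(is_st)) {
    expr[is_st, ] <- expr[is_st, , drop = FALSE] +
      matrix(rnorm(sum(is_st) * N, 0, region_sd_clonal), ncol = N)
  }
  expr <- expr + matrix(rnorm(G * N, 0, noise_sd), ncol = N)
  expr <- pmax(expr, 0)
  dimnames(expr) <- list(gene_ids, sample_ids)

  cut <- unname(quantile(theta_p, 2 / 3, type = 7))
  truth <- list(
    gene_category = category,
    patient_theta = theta_p,
    region_theta = tibble(
      sample_id = sample_ids,
      patient_id = patient_ids[patient_of],
      region_id = sprintf("R%d", region_of),
      theta_clonal = unname(theta_clonal),
      theta_subclonal = unname(theta_subclonal)
    ),
    true_class = stats::setNames(theta_p >= cut, patient_ids)
  )
  list(expr = expr, annot = annot, truth = truth)
}

#' Precision and recall of planted clonal-immune genes in a signature
#'
#' The simulator's clonal-immune genes are the ground-truth targets of an
#' ITH-robust signature; this reports how well a derived signature
#' recovered them.
#'
#' @param truth `truth` element of [simulate_cohort()] output.
#' @param signature A [gene_set()] whose genes are simulated gene ids.
#' @return One-row tibble: `precision`, `recall`, `n_signature`,
#'   `n_clonal_immune`.
#' @export
truth_recovery_report <- function(truth, signature) {
  if (!inherits(signature, "gene_set")) abort("signature must be a gene_set")
  genes <- signature$genes
  if (length(genes) == 0L) abort("signature is empty")
  unknown <- setdiff(genes, names(truth$gene_category))
  if (length(unknown) > 0L) {
    abort(paste0("signature gene(s) not in simulated cohort: ",
                 paste(head(unknown, 5L), collapse = ", ")))
  }
  clonal <- names(truth$gene_category)[truth$gene_category == "clonal_immune"]
  hits <- length(intersect(genes, clonal))
  tibble(
    precision = hits / length(genes),
    recall = if (length(clonal) > 0L) hits / length(clonal) else NA_real_,
    n_signature = length(genes),
    n_clonal_immune = length(clonal)
  )
}
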