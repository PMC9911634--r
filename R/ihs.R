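#' One-way random-effects intraclass correlation
#'
#' ANOVA estimator of the ICC for a single gene's expression grouped by
#' patient: with P groups of sizes \eqn{n_p}, \eqn{N = \sum n_p}, group
#' means \eqn{m_p} and grand mean \eqn{m},
#' \deqn{MSB = \sum_p n_p (m_p - m)^2 / (P - 1), \quad
#'       MSW = \sum_p \sum_r (x_{pr} - m_p)^2 / (N - P),}
#' \deqn{k_0 = (N - \sum_p n_p^2 / N) / (P - 1), \quad
#'       ICC = \frac{MSB - MSW}{MSB + (k_0 - 1) MSW},}
#' clipped to \[0, 1\]. A constant gene (MSB = MSW = 0) returns ICC = 1
#' with `flagged_constant = TRUE`: a gene identical everywhere is maximally
#' clonal.
#'
#' @param values Numeric vector of expression values.
#' @param group Grouping vector (patient ids), same length as `values`;
#'   at least 2 groups, each with at least 2 values.
#' @return A list: `icc`, `msb`, `msw`, `k0`, `n_groups`,
#'   `flagged_constant`.
#' @export
icc_oneway <- function(values, group) {
  if (length(values) != length(group)) abort("values and group lengths differ")
  if (anyNA(values)) abort("missing values are not supported")
  group <- as.character(group)
  n_p <- table(group)
  if (length(n_p) < 2L) abort("need at least 2 groups")
  if (any(n_p < 2L)) abort("every group needs at least 2 values")
  P <- length(n_p)
  N <- length(values)
  m_p <- tapply(values, group, mean)
  m <- mean(values)
  msb <- sum(n_p * (m_p[names(n_p)] - m)^2) / (P - 1)
  msw <- sum((values - m_p[group])^2) / (N - P)
  k0 <- (N - sum(n_p^2) / N) / (P - 1)
  if (msb == 0 && msw == 0) {
    return(list(icc = 1, msb = 0, msw = 0, k0 = k0, n_groups = P,
                flagged_constant = TRUE))
  }
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  list(icc = min(max(icc, 0), 1), msb = msb, msw = msw, k0 = k0,
       n_groups = P, flagged_constant = FALSE)
}

#' Subclonal expression-event frequency
#'
#' Fraction of patients in which a gene's within-tumor expression range
#' (max over regions minus min over regions) exceeds `tau` log2 units —
#' i.e. in how many tumors the gene shows a subclonal expression event.
#'
#' @inheritParams icc_oneway
#' @param tau Positive range threshold in log2 units.
#' @return Event frequency in \[0, 1\].
#' @export
event_frequency <- function(values, group, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) abort("tau must be a positive number")
  if (length(values) != length(group)) abort("values and group lengths differ")
  group <- as.character(group)
  n_p <- table(group)
  if (length(n_p) < 2L) abort("need at least 2 groups")
  if (any(n_p < 2L)) abort("every group needs at least 2 values")
  ranges <- tapply(values, group, function(x) max(x) - min(x))
  mean(ranges > tau)
}

#' Gene-wise integrated heterogeneity score (IHS)
#'
#' Quantifies per-gene intra-tumor heterogeneity from multi-region
#' expression by integrating two complementary components over patients:
#'
#' 1. `h1` = 1 - ICC (one-way random-effects, [icc_oneway()]): the share
#'    of a gene's variance that lies *within* tumors rather than between
#'    patients;
#' 2. `event_freq` ([event_frequency()]): the fraction of tumors with a
#'    subclonal expression event (within-tumor range > `tau`).
#'
#' Each component is converted to an ascending percentile rank across
#' retained genes (average ties, scaled to (0, 1\] as rank/G) and the IHS
#' is the mean of the two ranks. Low IHS marks genes with a clonal,
#' representative expression pattern; high IHS marks heterogeneous genes.
#'
#' Patients with a single region are excluded (warning); genes with mean
#' expression below `min_mean` are excluded before ranking (message).
#'
#' @param expr Expression matrix (genes x samples, log2 scale).
#' @param annot Annotation tibble with `sample_id`, `patient_id`.
#' @param tau Subclonal-event range threshold, log2 units.
#' @param min_mean Expression filter: genes with mean < `min_mean` are
#'   dropped before scoring.
#' @return An `ihs_tbl` tibble, one row per retained gene: `gene_id`,
#'   `h1`, `event_freq`, `rank_h1`, `rank_e`, `ihs`, `n_patients_used`,
#'   `flagged_constant`; sorted as the input gene order.
#' @export
compute_ihs <- function(expr, annot, tau = 1.0, min_mean = 1.0) {
  validate_expression(expr, require_nonnegative = FALSE)
  annot <- validate_annotation(annot)
  if (!is.numeric(tau) || tau <= 0) abort("tau must be a positive number")
  annot <- annot |> filter(.data$sample_id %in% colnames(expr))
  counts <- table(annot$patient_id)
  single <- names(counts)[counts < 2L]
  if (length(single) > 0L) {
    warn(paste0("excluding ", length(single),
                " patient(s) with a single region: ",
                paste(head(single, 5L), collapse = ", ")))
    annot <- annot |> filter(!.data$patient_id %in% single)
  }
  if (length(unique(annot$patient_id)) < 2L) {
    abort("need at least 2 patients with >= 2 regions each")
  }
  expr <- expr[, annot$sample_id, drop = FALSE]
  patient <- factor(annot$patient_id)

  keep <- rowMeans(expr) >= min_mean
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    inform(paste0("expression filter (mean >= ", min_mean, ") dropped ",
                  n_dropped, " gene(s)"))
  }
  if (!any(keep)) abort("no genes pass the expression filter")
  expr <- expr[keep, , drop = FALSE]

  # vectorized one-way ANOVA across all genes at once
  n_p <- as.vector(table(patient))
  P <- length(n_p)
  N <- ncol(expr)
  group_sums <- t(rowsum(t(expr), patient))          # genes x patients
  m_p <- sweep(group_sums, 2, n_p, "/")
  m <- rowMeans(expr)
  msb <- rowSums(sweep((m_p - m)^2, 2, n_p, "*")) / (P - 1)
  ssw <- rowSums((expr - m_p[, as.integer(patient), drop = FALSE])^2)
  msw <- ssw / (N - P)
  k0 <- (N - sum(n_p^2) / N) / (P - 1)
  constant <- msb == 0 & msw == 0
  icc <- ifelse(constant, 1, (msb - msw) / (msb + (k0 - 1) * msw))
  icc <- pmin(pmax(icc, 0), 1)
  h1 <- 1 - icc

  # per-patient within-tumor range, by patient loop (P is small)
  idx_by_patient <- split(seq_len(N), patient)
  exceeds <- vapply(idx_by_patient, function(idx) {
    sub <- expr[, idx, drop = FALSE]
    (apply(sub, 1L, max) - apply(sub, 1L, min)) > tau
  }, logical(nrow(expr)))
  event_freq <- rowMeans(exceeds)

  G <- nrow(expr)
  rank_h1 <- rank(h1, ties.method = "average") / G
  rank_e <- rank(event_freq, ties.method = "average") / G

  structure(
    tibble(
      gene_id = rownames(expr),
      h1 = unname(h1),
      event_freq = unname(event_freq),
      rank_h1 = unname(rank_h1),
      rank_e = unname(rank_e),
      ihs = unname((rank_h1 + rank_e) / 2),
      n_patients_used = P,
      flagged_constant = unname(constant)
    ),
    class = c("ihs_tbl", "tbl_df", "tbl", "data.frame")
  )
}

#' Select the most clonal (lowest-IHS) genes
#'
#' Returns the `n` genes with smallest IHS. Ties at the boundary are
#' broken by smaller `h1`, then lexicographic gene id, so selection is
#' fully deterministic.
#'
#' @param ihs An `ihs_tbl` from [compute_ihs()].
#' @param n Number of genes to select (at most the retained gene count).
#' @return A [gene_set()] named `low_ihs`, with per-gene `ihs` and its
#'   rank recorded in `provenance`.
#' @export
select_low_ihs <- function(ihs, n) {
  n <- as.integer(n)
  if (n < 1L) abort("n must be >= 1")
  if (n > nrow(ihs)) {
    abort(sprintf("requested %d low-IHS genes but only %d genes retained", n, nrow(ihs)))
  }
  ordered <- ihs |> arrange(.data$ihs, .data$h1, .data$gene_id)
  sel <- ordered[seq_len(n), ]
  gene_set(
    "low_ihs", sel$gene_id,
    description = sprintf("%d lowest-IHS genes", n),
    provenance = tibble(gene_id = sel$gene_id, ihs = sel$ihs,
                        ihs_rank = seq_len(n))
  )
}

#' @export
autoplot.ihs_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$h1, y = .data$event_freq,
                                       colour = .data$ihs)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "IHS") +
    ggplot2::labs(x = "within-tumor variance share (1 - ICC)",
                  y = "subclonal event frequency",
                  title = "Gene-wise intra-tumor heterogeneity") +
    ggplot2::theme_minimal()
}
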