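#' Derive an ITH-robust inflamed signature by intersection
#'
#' Intersects the immune-module gene set (top NMF loadings) with the
#' low-IHS (most clonal) gene set. Genes in both sets are immune-related
#' *and* clonally expressed within tumors, so a signature built from them
#' scores single-region samples consistently across a tumor's regions.
#'
#' An empty intersection is returned as an empty signature with a
#' prominent warning rather than an error; downstream scoring then fails
#' fast.
#'
#' @param top_loading [gene_set()] of immune-module genes, typically from
#'   [top_loading_genes()] (its `provenance` carries loading ranks).
#' @param low_ihs [gene_set()] of low-IHS genes, typically from
#'   [select_low_ihs()] (its `provenance` carries IHS ranks).
#' @return A [gene_set()] named `inflamed_signature` whose `provenance`
#'   joins per-gene loading and IHS ranks.
#' @export
derive_signature <- function(top_loading, low_ihs) {
  if (!inherits(top_loading, "gene_set") || !inherits(low_ihs, "gene_set")) {
    abort("both inputs must be gene_set objects")
  }
  common <- intersect(top_loading$genes, low_ihs$genes)
  if (length(common) == 0L) {
    warn(paste0("immune-module and low-IHS gene sets are disjoint: ",
                "the derived signature is EMPTY and cannot score samples"))
    return(structure(
      list(name = "inflamed_signature",
           description = "empty intersection of immune-module and low-IHS genes",
           genes = character(0), provenance = NULL),
      class = "gene_set"
    ))
  }
  prov <- tibble(gene_id = common)
  if (!is.null(top_loading$provenance)) {
    prov <- left_join(prov, top_loading$provenance, by = "gene_id")
  }
  if (!is.null(low_ihs$provenance)) {
    prov <- left_join(prov, low_ihs$provenance, by = "gene_id")
  }
  gene_set(
    "inflamed_signature", common,
    description = sprintf("intersection of %d immune-module and %d low-IHS genes",
                          length(top_loading$genes), length(low_ihs$genes)),
    provenance = prov
  )
}

#' Score samples by a gene signature
#'
#' Per-sample signature score = mean cohort z-score over the signature's
#' genes: each gene is standardized across samples ((x - mean)/sd) and a
#' sample's score is the mean over usable genes. Scores are
#' cohort-relative by construction.
#'
#' At least half of the signature's genes must be present in the matrix;
#' zero-variance genes are dropped with a warning.
#'
#' @param expr Expression matrix, genes x samples.
#' @param signature A [gene_set()].
#' @return A tibble: `sample_id`, `score`, in matrix column order.
#' @export
score_samples <- function(expr, signature) {
  validate_expression(expr, require_nonnegative = FALSE)
  if (!inherits(signature, "gene_set")) abort("signature must be a gene_set")
  if (length(signature$genes) == 0L) abort("signature is empty; cannot score")
  present <- intersect(signature$genes, rownames(expr))
  missing <- setdiff(signature$genes, rownames(expr))
  if (length(present) < length(signature$genes) / 2) {
    abort(paste0("fewer than 50% of signature genes present; missing: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(missing) > 0L) {
    inform(paste0(length(missing), " signature gene(s) absent from matrix: ",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1L, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping ", sum(sds == 0), " zero-variance signature gene(s)"))
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(sub) == 0L) abort("all usable signature genes have zero variance")
  z <- (sub - rowMeans(sub)) / sds
  tibble(sample_id = colnames(expr), score = unname(colMeans(z)))
}

#' Classify samples into inflamed and non-inflamed by score tertile
#'
#' The cutpoint is the empirical quantile of the scores at
#' `class_quantile` (linear interpolation between order statistics, R
#' type 7); a sample is `inflamed` iff its score is >= the cutpoint. With
#' the default quantile of 2/3 the top third of the cohort is inflamed.
#'
#' If all scores are equal the cutpoint equals the common score and every
#' sample is labelled inflamed, with a degenerate-distribution warning.
#'
#' @param scores Tibble with `sample_id` and `score` (as returned by
#'   [score_samples()]), or a named numeric vector.
#' @param class_quantile Quantile in (0, 1) splitting the classes.
#' @return A `class_tbl` tibble: `sample_id`, `score`, `label`
#'   (`"inflamed"`/`"non_inflamed"`), with attributes `cutpoint` and
#'   `class_quantile`.
#' @export
classify_tertile <- function(scores, class_quantile = 2 / 3) {
  if (is.numeric(scores)) {
    scores <- tibble(sample_id = names(scores) %||% as.character(seq_along(scores)),
                     score = unname(scores))
  }
  if (!all(c("sample_id", "score") %in% names(scores))) {
    abort("scores must have sample_id and score columns")
  }
  if (nrow(scores) < 3L) abort("need at least 3 samples to classify by tertile")
  if (!(class_quantile > 0 && class_quantile < 1)) {
    abort("class_quantile must be strictly between 0 and 1")
  }
  cut <- unname(quantile(scores$score, class_quantile, type = 7))
  if (sd(scores$score) == 0) {
    warn("all signature scores identical; every sample labelled inflamed")
  }
  out <- scores |>
    mutate(label = ifelse(.data$score >= cut, "inflamed", "non_inflamed"))
  structure(out, class = c("class_tbl", class(tibble())),
            cutpoint = cut, class_quantile = class_quantile)
}

#' @describeIn classify_tertile One-row summary: cutpoint, quantile,
#'   class sizes.
#' @param x,object A `class_tbl`.
#' @param ... Unused.
#' @export
glance.class_tbl <- function(x, ...) {
  tibble(
    cutpoint = attr(x, "cutpoint"),
    class_quantile = attr(x, "class_quantile"),
    n_samples = nrow(x),
    n_inflamed = sum(x$label == "inflamed"),
    n_non_inflamed = sum(x$label == "non_inflamed")
  )
}

#' @describeIn classify_tertile Score distribution with the cutpoint and
#'   class labels.
#' @export
autoplot.class_tbl <- function(object, ...) {
  cut <- attr(object, "cutpoint")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8, position = "identity") +
    ggplot2::geom_vline(xintercept = cut, linetype = "dashed") +
    ggplot2::labs(x = "signature score (mean z)", y = "samples",
                  title = "Inflamed / non-inflamed classification") +
    ggplot2::theme_minimal()
}

#' Correlate two signatures' sample scores
#'
#' Pearson and Spearman correlation (two-sided tests) between matched
#' per-sample scores of two signatures, e.g. a heterogeneity-filtered
#' signature against the unfiltered one it replaces.
#'
#' @param scores_a,scores_b Score tibbles (`sample_id`, `score`) over the
#'   same samples, or numeric vectors of equal length >= 3.
#' @return A tibble with one row per method: `method`, `estimate`,
#'   `p_value`, `n`.
#' @export
signature_correlation <- function(scores_a, scores_b) {
  to_tbl <- function(s) {
    if (is.data.frame(s)) return(as_tibble(s))
    tibble(sample_id = names(s) %||% as.character(seq_along(s)), score = unname(s))
  }
  a <- to_tbl(scores_a); b <- to_tbl(scores_b)
  if (!setequal(a$sample_id, b$sample_id) || nrow(a) != nrow(b)) {
    abort("score tables cover different sample sets")
  }
  b <- b[match(a$sample_id, b$sample_id), ]
  if (nrow(a) < 3L) abort("need at least 3 matched samples")
  if (sd(a$score) == 0 || sd(b$score) == 0) {
    abort("zero variance in a score vector; correlation undefined")
  }
  pear <- cor.test(a$score, b$score, method = "pearson")
  spear <- suppressWarnings(cor.test(a$score, b$score, method = "spearman"))
  tibble(
    method = c("pearson", "spearman"),
    estimate = c(unname(pear$estimate), unname(spear$estimate)),
    p_value = c(pear$p.value, spear$p.value),
    n = nrow(a)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
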