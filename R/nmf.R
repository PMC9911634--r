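#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative expression matrix V (genes x samples) as
#' V ~ WH, minimizing the Frobenius reconstruction error with the classic
#' multiplicative updates
#' \deqn{W \leftarrow W \odot \frac{V H^\top}{W H H^\top + \delta}, \quad
#'       H \leftarrow H \odot \frac{W^\top V}{W^\top W H + \delta}}
#' (\eqn{\delta = 10^{-12}}), which keep both factors non-negative and
#' never increase the loss. Each restart draws its initial entries from
#' Uniform(0, sqrt(mean(V)/k)) on its own seeded stream; the restart with
#' the smallest final loss is returned. Deterministic given `seed`.
#'
#' Iteration stops when the relative loss decrease falls below `tol` or at
#' `max_iter`.
#'
#' @param expr Non-negative numeric matrix, genes x samples.
#' @param k Factorization rank, `k < min(dim(expr))`.
#' @param restarts Number of random restarts.
#' @param max_iter Maximum iterations per restart.
#' @param tol Relative-decrease stopping tolerance on the Frobenius loss.
#' @param seed Integer seed; each restart runs on its own stream derived
#'   from it.
#' @return An `nmf_fit`: `W` (genes x k), `H` (k x samples), `loss`
#'   (final Frobenius error per restart), `chosen_restart`,
#'   `loss_trajectory` (per-iteration loss of the chosen restart), `k`,
#'   `seed`.
#' @export
nmf_factorize <- function(expr, k, restarts = 5L, max_iter = 500L,
                          tol = 1e-5, seed = 1L) {
  validate_expression(expr, require_nonnegative = FALSE)
  if (any(expr < 0)) abort("NMF requires a non-negative matrix")
  k <- as.integer(k)
  if (k < 1L || k >= min(dim(expr))) {
    abort(sprintf("rank k = %d must satisfy 1 <= k < min(genes, samples) = %d",
                  k, min(dim(expr))))
  }
  delta <- 1e-12
  init_scale <- sqrt(mean(expr) / k)
  G <- nrow(expr); S <- ncol(expr)

  norm_v2 <- sum(expr^2)
  # independent seeded stream per restart, derived once from the master seed
  set.seed(as.integer(seed))
  restart_seeds <- sample.int(.Machine$integer.max, as.integer(restarts))
  run_one <- function(r) {
    set.seed(restart_seeds[r])
    W <- matrix(runif(G * k, 0, init_scale), nrow = G)
    H <- matrix(runif(k * S, 0, init_scale), nrow = k)
    loss <- numeric(max_iter)
    prev <- Inf
    n_it <- 0L
    for (it in seq_len(max_iter)) {
      W <- W * tcrossprod(expr, H) / (W %*% tcrossprod(H) + delta)
      wtv <- crossprod(W, expr)
      wtw <- crossprod(W)
      H <- H * wtv / (wtw %*% H + delta)
      # ||V - WH||^2 = ||V||^2 - 2<WtV, H> + <WtW, HHt>
      cur <- sqrt(max(norm_v2 - 2 * sum(wtv * H) + sum(wtw * tcrossprod(H)), 0))
      n_it <- it
      loss[it] <- cur
      if (is.finite(prev) && prev > 0 && (prev - cur) / prev < tol) break
      prev <- cur
    }
    list(W = W, H = H, trajectory = loss[seq_len(n_it)], final = loss[n_it])
  }

  runs <- lapply(seq_len(as.integer(restarts)), run_one)
  finals <- vapply(runs, `[[`, numeric(1), "final")
  best <- which.min(finals)
  W <- runs[[best]]$W
  H <- runs[[best]]$H
  dimnames(W) <- list(rownames(expr), paste0("factor", seq_len(k)))
  dimnames(H) <- list(paste0("factor", seq_len(k)), colnames(expr))
  structure(
    list(W = W, H = H, loss = finals, chosen_restart = best,
         loss_trajectory = runs[[best]]$trajectory, k = k,
         seed = as.integer(seed)),
    class = "nmf_fit"
  )
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat("<nmf_fit> rank", x$k, "on", nrow(x$W), "genes x", ncol(x$H), "samples\n")
  cat("  restart", x$chosen_restart, "of", length(x$loss),
      "| final Frobenius loss", format(min(x$loss), digits = 6),
      "|", length(x$loss_trajectory), "iterations\n")
  invisible(x)
}

#' @describeIn nmf_factorize Long tibble of gene loadings: `gene_id`,
#'   `factor`, `loading`.
#' @param x,object An `nmf_fit`.
#' @param ... Unused.
#' @export
tidy.nmf_fit <- function(x, ...) {
  as_tibble(x$W, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "factor", values_to = "loading")
}

#' @describeIn nmf_factorize One-row fit summary: rank, restarts, chosen
#'   restart, final loss, iterations.
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble(
    k = x$k, restarts = length(x$loss), chosen_restart = x$chosen_restart,
    loss = min(x$loss), n_iter = length(x$loss_trajectory), seed = x$seed
  )
}

#' @describeIn nmf_factorize Loss trajectory of the chosen restart.
#' @export
autoplot.nmf_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$loss_trajectory),
               loss = object$loss_trajectory)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "Frobenius reconstruction error",
                  title = sprintf("NMF convergence (rank %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' Per-sample immune marker score
#'
#' Mean cohort z-score of a marker gene panel: each present marker is
#' standardized across samples ((x - mean) / sd), and samples are scored
#' by the mean over markers. Used to pick out the immune NMF factor.
#'
#' @param expr Expression matrix, genes x samples.
#' @param markers Character vector of marker gene ids; absent markers are
#'   reported, zero-variance markers skipped with a warning.
#' @return Named numeric vector, one score per sample.
#' @export
marker_score <- function(expr, markers) {
  validate_expression(expr, require_nonnegative = FALSE)
  present <- intersect(markers, rownames(expr))
  absent <- setdiff(markers, rownames(expr))
  if (length(absent) > 0L) {
    inform(paste0(length(absent), " marker(s) absent from matrix: ",
                  paste(head(absent, 5L), collapse = ", ")))
  }
  if (length(present) == 0L) abort("no marker gene present in the expression matrix")
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1L, sd)
  if (any(sds == 0)) {
    warn(paste0("skipping ", sum(sds == 0), " zero-variance marker(s)"))
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(sub) == 0L) abort("all present markers have zero variance")
  }
  z <- (sub - rowMeans(sub)) / sds
  colMeans(z)
}

#' Identify the immune-related NMF factor
#'
#' Correlates each factor's sample weights (rows of H) with a per-sample
#' immune marker score and selects the factor with the largest Pearson
#' correlation; ties break toward the lower factor index. Zero-variance H
#' rows can never be selected.
#'
#' @param fit An `nmf_fit` from [nmf_factorize()].
#' @param score Per-sample numeric score, length `ncol(fit$H)` (e.g. from
#'   [marker_score()]).
#' @return An `immune_factor_selection`: `factor_index`,
#'   `correlation_per_factor`, `marker_score`.
#' @export
select_immune_factor <- function(fit, score) {
  if (!inherits(fit, "nmf_fit")) abort("fit must be an nmf_fit")
  if (length(score) != ncol(fit$H)) {
    abort(sprintf("score length %d != sample count %d", length(score), ncol(fit$H)))
  }
  cors <- apply(fit$H, 1L, function(h) {
    if (sd(h) == 0) -Inf else cor(h, score)
  })
  if (all(!is.finite(cors))) abort("every H row has zero variance")
  degenerate <- sum(!is.finite(cors))
  if (degenerate > 0L) {
    inform(paste0(degenerate, " zero-variance factor(s) excluded from immune-factor selection"))
  }
  structure(
    list(factor_index = unname(which.max(cors)),
         correlation_per_factor = unname(cors),
         marker_score = score),
    class = "immune_factor_selection"
  )
}

#' @export
print.immune_factor_selection <- function(x, ...) {
  cat("<immune_factor_selection> factor", x$factor_index,
      "| r =", format(max(x$correlation_per_factor), digits = 4), "\n")
  invisible(x)
}

#' Top-loading genes of an NMF factor
#'
#' The `n` genes with largest loading in column `factor` of W; ties break
#' lexicographically by gene id.
#'
#' @param fit An `nmf_fit`.
#' @param factor Factor (column of W) index.
#' @param n Number of genes, at most `nrow(fit$W)`.
#' @return A [gene_set()] with per-gene `loading` and `loading_rank`
#'   provenance.
#' @export
top_loading_genes <- function(fit, factor, n) {
  if (!inherits(fit, "nmf_fit")) abort("fit must be an nmf_fit")
  factor <- as.integer(factor)
  if (factor < 1L || factor > fit$k) abort("factor index out of range")
  n <- as.integer(n)
  if (n < 1L || n > nrow(fit$W)) {
    abort(sprintf("requested %d genes but matrix has %d", n, nrow(fit$W)))
  }
  loading <- fit$W[, factor]
  ord <- order(-loading, names(loading))
  sel <- ord[seq_len(n)]
  gene_set(
    "immune_module", names(loading)[sel],
    description = sprintf("top %d genes by loading on NMF factor %d", n, factor),
    provenance = tibble(gene_id = names(loading)[sel],
                        loading = unname(loading[sel]),
                        loading_rank = seq_len(n))
  )
}
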