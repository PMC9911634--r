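#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample identifiers, a first column of gene
#' identifiers (header `gene_id`), and a numeric body on the log2(x+1)
#' scale. The scale is a contract with the caller: the package never
#' re-transforms expression values.
#'
#' Duplicate gene rows are collapsed by their mean with a warning;
#' duplicate sample columns are an error.
#'
#' @param path Path to a tab-separated file.
#' @param require_nonnegative If `TRUE` (default), any negative value is an
#'   error. Non-negativity is required by the NMF stage; set to `FALSE`
#'   only for analyses that never factorize the matrix.
#' @return A numeric matrix (genes in rows, samples in columns) with gene
#'   and sample identifiers as dimnames.
#' @export
read_expression_tsv <- function(path, require_nonnegative = TRUE) {
  if (!file.exists(path)) abort(paste0("expression file not found: ", path))
  header <- strsplit(readr::read_lines(path, n_max = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) abort("expression TSV needs a gene_id column and at least one sample column")
  sample_ids <- header[-1L]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate sample id(s) in expression header: ", paste(dup, collapse = ", ")))
  }
  # readr's parse warning is redundant: problems() is turned into an
  # explicit error just below
  body <- suppressWarnings(
    readr::read_tsv(path, skip = 1L,
                    col_names = c("gene_id", sample_ids),
                    col_types = readr::cols(
                      gene_id = readr::col_character(),
                      .default = readr::col_double()
                    ),
                    progress = FALSE)
  )
  prob <- readr::problems(body)
  if (nrow(prob) > 0L) {
    p1 <- prob[1L, ]
    abort(sprintf("non-numeric value in expression body at row %d, column '%s'",
                  p1$row, sample_ids[p1$col - 1L]))
  }
  if (anyNA(body)) abort("missing values in expression matrix are not supported")
  dup_genes <- unique(body$gene_id[duplicated(body$gene_id)])
  if (length(dup_genes) > 0L) {
    warn(paste0("collapsing ", length(dup_genes),
                " duplicated gene id(s) by mean: ",
                paste(head(dup_genes, 5L), collapse = ", ")))
    first_order <- unique(body$gene_id)
    body <- body |>
      group_by(.data$gene_id) |>
      summarise(across(dplyr::everything(), mean), .groups = "drop")
    body <- body[match(first_order, body$gene_id), ]
  }
  m <- as.matrix(body[, -1L, drop = FALSE])
  rownames(m) <- body$gene_id
  validate_expression(m, require_nonnegative = require_nonnegative)
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]: round-trips gene/sample identifiers
#' and values exactly (up to decimal printing at full precision).
#'
#' @param expr Numeric matrix with gene and sample dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expression(expr, require_nonnegative = FALSE)
  df <- tibble(gene_id = rownames(expr)) |>
    dplyr::bind_cols(as_tibble(expr))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

validate_expression <- function(expr, require_nonnegative = TRUE) {
  if (!is.matrix(expr) || !is.numeric(expr)) abort("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr))) abort("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(expr))) abort("duplicate sample ids in expression matrix")
  if (!all(is.finite(expr))) abort("expression matrix contains non-finite values")
  if (require_nonnegative && any(expr < 0)) {
    abort("negative expression values; expected log2(x+1)-scale non-negative matrix")
  }
  invisible(expr)
}

#' Read a multi-region sample annotation table
#'
#' A TSV with columns `sample_id`, `patient_id`, `region_id` mapping each
#' expression column to its patient and intra-tumor region. Extra columns
#' are preserved untouched.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with at least the three required columns.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  ann <- as_tibble(ann)
  required <- c("sample_id", "patient_id", "region_id")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0L) {
    abort(paste0("annotation is missing required column(s): ", paste(missing, collapse = ", ")))
  }
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate sample_id(s) in annotation: ", paste(dup, collapse = ", ")))
  }
  pr <- paste(ann$patient_id, ann$region_id, sep = "\r")
  if (anyDuplicated(pr)) {
    abort("duplicate (patient_id, region_id) pair(s) in annotation")
  }
  ann
}

#' Write a sample annotation table to TSV
#' @param annot Annotation tibble (see [read_annotation_tsv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annot, path) {
  readr::write_tsv(validate_annotation(annot), path, progress = FALSE)
  invisible(path)
}

#' Construct a gene set
#'
#' A named list of unique gene identifiers with an optional free-text
#' description and an optional per-gene provenance table (e.g. loading and
#' IHS ranks recorded when a signature is derived).
#'
#' @param name Set name.
#' @param genes Character vector of unique gene ids (non-empty).
#' @param description Free-text description (second GMT field).
#' @param provenance Optional tibble of per-gene metadata, one row per gene.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, genes, description = "", provenance = NULL) {
  if (!is.character(genes) || length(genes) == 0L) abort("gene set must contain at least one gene")
  if (anyDuplicated(genes)) abort("gene set contains duplicate gene ids")
  structure(
    list(name = as.character(name), description = as.character(description),
         genes = genes, provenance = provenance),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  cat("  ", paste(head(x$genes, 8L), collapse = ", "),
      if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB gene ...`.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  sets <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      abort(sprintf("GMT line %d has %d field(s); need name, description and at least one gene",
                    i, length(fields)))
    }
    gene_set(fields[1L], fields[-(1:2)], description = fields[2L])
  })
  stats::setNames(sets, purrr::map_chr(sets, "name"))
}

#' Write gene sets to a GMT file
#'
#' Round-trips exactly with [read_gmt()] (provenance tables are not
#' serialized; GMT carries names, descriptions and gene lists only).
#'
#' @param sets A `gene_set` or list of `gene_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- purrr::map_chr(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Analysis configuration with package defaults
#'
#' Collects the tunable parameters of the signature pipeline. Defaults:
#' 500 top-loading immune genes, 2000 low-IHS genes, NMF rank 6 with
#' 5 restarts, subclonal-event threshold 1 log2 unit, expression filter
#' mean >= 1, inflamed class above the 2/3 score quantile.
#'
#' @param n_top_loading Number of top-loading genes taken from the immune
#'   NMF factor.
#' @param n_low_ihs Number of lowest-IHS (most clonal) genes intersected
#'   with the immune genes.
#' @param nmf_rank,nmf_restarts,nmf_max_iter,nmf_tol NMF parameters, see
#'   [nmf_factorize()].
#' @param event_threshold_tau Within-patient expression range (log2 units)
#'   above which a gene counts as a subclonal event in that patient.
#' @param expression_filter_min_mean Genes with mean expression below this
#'   are excluded before IHS and NMF.
#' @param class_quantile Score quantile splitting inflamed from
#'   non-inflamed samples; default 2/3 labels the top tertile inflamed.
#' @param marker_genes Immune marker genes used to identify the immune NMF
#'   factor; defaults to canonical human cytotoxic/exhaustion markers.
#' @param seed Integer seed fanned out to all stochastic stages.
#' @return A validated `analysis_config` list.
#' @export
analysis_config <- function(n_top_loading = 500L,
                            n_low_ihs = 2000L,
                            nmf_rank = 6L,
                            nmf_restarts = 5L,
                            nmf_max_iter = 500L,
                            nmf_tol = 1e-5,
                            event_threshold_tau = 1.0,
                            expression_filter_min_mean = 1.0,
                            class_quantile = 2 / 3,
                            marker_genes = c("CD8A", "CD8B", "GZMA", "GZMB", "PRF1",
                                             "IFNG", "CXCL9", "CXCL10", "CD274", "CTLA4"),
                            seed = 1L) {
  cfg <- list(
    n_top_loading = as.integer(n_top_loading),
    n_low_ihs = as.integer(n_low_ihs),
    nmf_rank = as.integer(nmf_rank),
    nmf_restarts = as.integer(nmf_restarts),
    nmf_max_iter = as.integer(nmf_max_iter),
    nmf_tol = as.numeric(nmf_tol),
    event_threshold_tau = as.numeric(event_threshold_tau),
    expression_filter_min_mean = as.numeric(expression_filter_min_mean),
    class_quantile = as.numeric(class_quantile),
    marker_genes = as.character(marker_genes),
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_top_loading >= 1L, cfg$n_low_ihs >= 1L,
            cfg$nmf_rank >= 1L, cfg$nmf_restarts >= 1L,
            cfg$nmf_max_iter >= 1L, cfg$nmf_tol > 0,
            cfg$event_threshold_tau > 0)
  if (!(cfg$class_quantile > 0 && cfg$class_quantile < 1)) {
    abort("class_quantile must be strictly between 0 and 1")
  }
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are an error; absent keys take package defaults.
#'
#' @param path Path to a YAML file whose keys match [analysis_config()]
#'   arguments.
#' @return An `analysis_config` list.
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(analysis_config, vals)
}
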