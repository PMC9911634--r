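#' Per-patient classification concordance across intra-tumor regions
#'
#' A multi-region tumor is *concordant* when all of its regional samples
#' receive the same class (all inflamed or all non-inflamed) and
#' *discordant* when its regions split across both classes. The cohort
#' discordance rate is the fraction of eligible patients (>= 2 classified
#' samples) that are discordant, with a percentile bootstrap confidence
#' interval over patients.
#'
#' @param classes A `class_tbl` from [classify_tertile()] (or any tibble
#'   with `sample_id` and `label`).
#' @param annot Annotation tibble mapping `sample_id` to `patient_id`.
#' @param n_boot Bootstrap replicates for the CI.
#' @param seed Seed for the bootstrap resampling.
#' @param conf_level CI level.
#' @return A `concordance_report`: `patients` tibble (`patient_id`,
#'   `n_regions`, `n_inflamed`, `concordant`), `n_eligible`,
#'   `n_discordant`, `discordance_rate`, `ci_lower`, `ci_upper`,
#'   `conf_level`, `n_boot`, `seed`.
#' @export
evaluate_concordance <- function(classes, annot, n_boot = 1000L, seed = 1L,
                                 conf_level = 0.95) {
  if (!all(c("sample_id", "label") %in% names(classes))) {
    abort("classes must have sample_id and label columns")
  }
  annot <- validate_annotation(annot)
  joined <- as_tibble(classes)[, c("sample_id", "label")] |>
    left_join(annot[, c("sample_id", "patient_id")], by = "sample_id")
  if (anyNA(joined$patient_id)) {
    abort("some classified samples are missing from the annotation")
  }
  patients <- joined |>
    group_by(.data$patient_id) |>
    summarise(
      n_regions = n(),
      n_inflamed = sum(.data$label == "inflamed"),
      concordant = dplyr::n_distinct(.data$label) == 1L,
      .groups = "drop"
    ) |>
    filter(.data$n_regions >= 2L) |>
    arrange(.data$patient_id)
  if (nrow(patients) == 0L) {
    abort("no eligible patient: none has >= 2 classified samples")
  }
  disc <- !patients$concordant
  rate <- mean(disc)
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(as.integer(n_boot)), function(i) {
    mean(disc[sample.int(length(disc), replace = TRUE)])
  }, numeric(1))
  alpha <- 1 - conf_level
  ci <- unname(quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 7))
  structure(
    list(patients = patients,
         n_eligible = nrow(patients),
         n_discordant = sum(disc),
         discordance_rate = rate,
         ci_lower = ci[1], ci_upper = ci[2],
         conf_level = conf_level,
         n_boot = as.integer(n_boot), seed = as.integer(seed)),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> ", x$n_discordant, "/", x$n_eligible,
      " patients discordant (rate ", format(x$discordance_rate, digits = 3),
      ", ", round(100 * x$conf_level), "% CI [",
      format(x$ci_lower, digits = 3), ", ", format(x$ci_upper, digits = 3),
      "])\n", sep = "")
  invisible(x)
}

#' @describeIn evaluate_concordance Per-patient tibble with concordance
#'   flags.
#' @param x,object A `concordance_report`.
#' @param ... Unused.
#' @export
tidy.concordance_report <- function(x, ...) x$patients

#' @describeIn evaluate_concordance One-row cohort summary.
#' @export
glance.concordance_report <- function(x, ...) {
  tibble(
    n_eligible = x$n_eligible, n_discordant = x$n_discordant,
    discordance_rate = x$discordance_rate,
    ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    conf_level = x$conf_level, n_boot = x$n_boot
  )
}

#' @describeIn evaluate_concordance Per-patient inflamed-region fractions
#'   coloured by concordance.
#' @export
autoplot.concordance_report <- function(object, ...) {
  df <- object$patients |>
    mutate(frac_inflamed = .data$n_inflamed / .data$n_regions,
           status = ifelse(.data$concordant, "concordant", "discordant"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$patient_id,
                                   y = .data$frac_inflamed,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(concordant = "grey40",
                                            discordant = "red3")) +
    ggplot2::labs(x = NULL, y = "fraction of regions inflamed",
                  title = "Multi-region classification concordance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Compare two signatures' discordance rates on the same cohort
#'
#' Paired comparison of two concordance reports over the identical
#' eligible patient set: the rate difference (a - b) with a paired
#' patient-level bootstrap CI, and an exact sign test (binomial, p = 0.5)
#' restricted to patients whose concordance flags disagree between the
#' signatures.
#'
#' @param report_a,report_b `concordance_report`s over the same patients.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for resampling.
#' @param conf_level CI level.
#' @return One-row tibble: `rate_a`, `rate_b`, `delta`, `ci_lower`,
#'   `ci_upper`, `n_disagree`, `n_favor_a` (patients discordant under b
#'   only), `sign_test_p`.
#' @export
compare_discordance <- function(report_a, report_b, n_boot = 1000L, seed = 1L,
                                conf_level = 0.95) {
  pa <- report_a$patients; pb <- report_b$patients
  if (!setequal(pa$patient_id, pb$patient_id)) {
    only_a <- setdiff(pa$patient_id, pb$patient_id)
    only_b <- setdiff(pb$patient_id, pa$patient_id)
    abort(paste0("eligible patient sets differ; only in a: ",
                 paste(only_a, collapse = ", "), "; only in b: ",
                 paste(only_b, collapse = ", ")))
  }
  pb <- pb[match(pa$patient_id, pb$patient_id), ]
  da <- !pa$concordant
  db <- !pb$concordant
  delta <- mean(da) - mean(db)
  set.seed(as.integer(seed))
  n <- length(da)
  boot <- vapply(seq_len(as.integer(n_boot)), function(i) {
    idx <- sample.int(n, replace = TRUE)
    mean(da[idx]) - mean(db[idx])
  }, numeric(1))
  alpha <- 1 - conf_level
  ci <- unname(quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 7))
  disagree <- da != db
  n_favor_a <- sum(disagree & db)  # b discordant where a concordant
  sign_p <- if (sum(disagree) == 0L) 1 else {
    binom.test(n_favor_a, sum(disagree), p = 0.5)$p.value
  }
  tibble(
    rate_a = mean(da), rate_b = mean(db), delta = delta,
    ci_lower = ci[1], ci_upper = ci[2],
    n_disagree = sum(disagree), n_favor_a = n_favor_a,
    sign_test_p = sign_p
  )
}
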