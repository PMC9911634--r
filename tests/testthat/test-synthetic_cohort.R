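test_that("simulated cohort has the requested shape and grouping", {
  sim <- simulate_cohort(n_patients = 10, regions_per_patient = 3,
                         n_genes = 1000, n_clonal_immune = 50,
                         n_subclonal_immune = 50, n_subclonal_background = 100,
                         seed = 1)
  expect_identical(dim(sim$expr), c(1000L, 30L))
  expect_identical(nrow(sim$annot), 30L)
  expect_identical(length(unique(sim$annot$patient_id)), 10L)
  expect_true(all(table(sim$annot$patient_id) == 3L))
  expect_identical(colnames(sim$expr), sim$annot$sample_id)
  expect_identical(sort(unique(unname(sim$truth$gene_category))),
                   c("clonal_immune", "stable_background",
                     "subclonal_background", "subclonal_immune"))
  expect_identical(sum(sim$truth$gene_category == "clonal_immune"), 50L)
})

test_that("simulated values are finite, non-negative, and seed-reproducible", {
  sim1 <- simulate_cohort(n_patients = 4, n_genes = 200, n_clonal_immune = 20,
                          n_subclonal_immune = 20, n_subclonal_background = 40,
                          seed = 5)
  sim2 <- simulate_cohort(n_patients = 4, n_genes = 200, n_clonal_immune = 20,
                          n_subclonal_immune = 20, n_subclonal_background = 40,
                          seed = 5)
  sim3 <- simulate_cohort(n_patients = 4, n_genes = 200, n_clonal_immune = 20,
                          n_subclonal_immune = 20, n_subclonal_background = 40,
                          seed = 6)
  expect_true(all(is.finite(sim1$expr)))
  expect_true(all(sim1$expr >= 0))
  expect_identical(sim1$expr, sim2$expr)
  expect_identical(sim1$truth$patient_theta, sim2$truth$patient_theta)
  expect_false(identical(sim1$expr, sim3$expr))
})

test_that("degenerate noise parameters give exactly zero within-patient variance", {
  sim <- simulate_cohort(n_patients = 4, regions_per_patient = 3, n_genes = 100,
                         n_clonal_immune = 0, n_subclonal_immune = 0,
                         n_subclonal_background = 0, region_sd_clonal = 0,
                         region_sd_subclonal = 0, noise_sd = 0,
                         immune_effect = 0, seed = 2)
  for (p in unique(sim$annot$patient_id)) {
    cols <- sim$annot$sample_id[sim$annot$patient_id == p]
    vars <- apply(sim$expr[, cols], 1L, stats::var)
    expect_true(all(vars == 0))
  }
})

test_that("within-patient variance of stable background genes converges to region_sd^2 + noise_sd^2", {
  sim <- simulate_cohort(n_patients = 50, regions_per_patient = 4,
                         n_genes = 400, n_clonal_immune = 0,
                         n_subclonal_immune = 0, n_subclonal_background = 0,
                         baseline_mean = 8,  # keep clipping at 0 inactive
                         seed = 3)
  patient <- factor(sim$annot$patient_id)
  within_var <- vapply(seq_len(nrow(sim$expr)), function(g) {
    mean(tapply(sim$expr[g, ], patient, stats::var))
  }, numeric(1))
  expected <- 0.15^2 + 0.3^2
  expect_lt(abs(mean(within_var) - expected) / expected, 0.15)
})

test_that("subclonal genes have larger within-patient variance than stable genes across seeds", {
  for (s in 1:10) {
    sim <- simulate_cohort(n_patients = 6, regions_per_patient = 3,
                           n_genes = 300, n_clonal_immune = 30,
                           n_subclonal_immune = 30, n_subclonal_background = 60,
                           seed = s)
    patient <- factor(sim$annot$patient_id)
    wv <- vapply(seq_len(nrow(sim$expr)), function(g) {
      mean(tapply(sim$expr[g, ], patient, stats::var))
    }, numeric(1))
    cat_of <- sim$truth$gene_category
    expect_gt(mean(wv[cat_of == "subclonal_background"]),
              mean(wv[cat_of == "stable_background"]))
    expect_gt(mean(wv[cat_of == "subclonal_immune"]),
              mean(wv[cat_of == "stable_background"]))
  }
})

test_that("true inflamed class marks patients at or above the upper theta tertile", {
  sim <- simulate_cohort(n_patients = 9, n_genes = 100, n_clonal_immune = 10,
                         n_subclonal_immune = 10, n_subclonal_background = 10,
                         seed = 4)
  cut <- unname(quantile(sim$truth$patient_theta, 2 / 3, type = 7))
  expect_identical(unname(sim$truth$true_class),
                   unname(sim$truth$patient_theta >= cut))
})

test_that("truth recovery report counts precision and recall directly", {
  sim <- simulate_cohort(n_patients = 3, n_genes = 50, n_clonal_immune = 20,
                         n_subclonal_immune = 5, n_subclonal_background = 5,
                         seed = 1)
  clonal <- names(sim$truth$gene_category)[sim$truth$gene_category == "clonal_immune"]
  other <- names(sim$truth$gene_category)[sim$truth$gene_category != "clonal_immune"]

  r1 <- truth_recovery_report(sim$truth, gene_set("s", clonal))
  expect_equal(r1$precision, 1)
  expect_equal(r1$recall, 1)

  r2 <- truth_recovery_report(sim$truth, gene_set("s", other[1:8]))
  expect_equal(r2$precision, 0)

  mixed <- gene_set("s", c(clonal[1:7], other[1:3]))
  r3 <- truth_recovery_report(sim$truth, mixed)
  expect_equal(r3$precision, 0.7)
  expect_equal(r3$recall, 7 / 20)

  expect_error(truth_recovery_report(sim$truth, gene_set("s", "NOT_A_GENE")),
               "not in simulated cohort")
})

test_that("category counts exceeding the gene total are rejected", {
  expect_error(
    simulate_cohort(n_patients = 3, n_genes = 10, n_clonal_immune = 5,
                    n_subclonal_immune = 5, n_subclonal_background = 5),
    "exceed"
  )
})
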