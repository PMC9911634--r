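test_that("one-way ICC matches explicit hand cases", {
  # zero within-group variance => ICC 1
  r <- icc_oneway(c(2, 2, 5, 5), c("A", "A", "B", "B"))
  expect_equal(r$icc, 1)
  expect_false(r$flagged_constant)

  # all values equal => ICC 1 by convention, flagged constant
  r2 <- icc_oneway(rep(3, 6), rep(c("A", "B", "C"), each = 2))
  expect_equal(r2$icc, 1)
  expect_true(r2$flagged_constant)

  # unbalanced example against the brute-force oracle
  vals <- c(1, 2, 4, 6, 3, 3)
  grp <- c("A", "A", "B", "B", "C", "C")
  expect_equal(icc_oneway(vals, grp)$icc, icc_bruteforce(vals, grp),
               tolerance = 1e-12)

  expect_error(icc_oneway(c(1, 2), c("A", "A")), "2 groups")
  expect_error(icc_oneway(c(1, 2, 3), c("A", "A", "B")), "2 values")
})

test_that("one-way ICC equals the brute-force ANOVA oracle on random unbalanced instances", {
  set.seed(101)
  for (i in 1:300) {
    P <- sample(2:8, 1)
    sizes <- sample(2:6, P, replace = TRUE)
    grp <- rep(paste0("P", seq_len(P)), sizes)
    vals <- rnorm(sum(sizes), sample(0:5, 1), runif(1, 0.1, 3))
    expect_equal(icc_oneway(vals, grp)$icc, icc_bruteforce(vals, grp),
                 tolerance = 1e-10)
  }
})

test_that("event frequency counts patients whose range exceeds tau", {
  # ranges per patient: 1.5, 0.2, 0.8
  vals <- c(0, 1.5, 1, 1.2, 2, 2.8)
  grp <- rep(c("A", "B", "C"), each = 2)
  expect_equal(event_frequency(vals, grp, tau = 1.0), 1 / 3)
  expect_equal(event_frequency(vals, grp, tau = 0.1), 1)
  expect_equal(event_frequency(rep(c(1, 5), each = 2), rep(c("A", "B"), each = 2), 1.0), 0)
  expect_error(event_frequency(vals, grp, tau = 0), "positive")
})

test_that("clonal extreme gene gets H1 = 0, E = 0 and the minimal IHS", {
  set.seed(3)
  ann <- tibble::tibble(
    sample_id = paste0("S", 1:8),
    patient_id = rep(paste0("P", 1:4), each = 2),
    region_id = rep(c("R1", "R2"), 4)
  )
  m <- matrix(runif(10 * 8, 2, 6), nrow = 10,
              dimnames = list(paste0("G", 1:10), ann$sample_id))
  # G1: identical within every patient, different between patients
  m[1, ] <- rep(c(2, 4, 6, 8), each = 2)
  ihs <- compute_ihs(m, ann, min_mean = 0)
  g1 <- ihs[ihs$gene_id == "G1", ]
  expect_equal(g1$h1, 0)
  expect_equal(g1$event_freq, 0)
  expect_equal(g1$ihs, min(ihs$ihs))

  # constant gene also lands at H1 = 0, E = 0, flagged
  m[2, ] <- 3
  ihs2 <- compute_ihs(m, ann, min_mean = 0)
  g2 <- ihs2[ihs2$gene_id == "G2", ]
  expect_equal(g2$h1, 0)
  expect_equal(g2$event_freq, 0)
  expect_true(g2$flagged_constant)
})

test_that("IHS is invariant to gene-wise location shifts", {
  set.seed(9)
  ann <- tibble::tibble(
    sample_id = paste0("S", 1:12),
    patient_id = rep(paste0("P", 1:4), each = 3),
    region_id = rep(paste0("R", 1:3), 4)
  )
  m <- matrix(rnorm(20 * 12, 4, 1.5), nrow = 20,
              dimnames = list(paste0("G", 1:20), ann$sample_id))
  base <- compute_ihs(m, ann, min_mean = -Inf)
  shifted <- m
  shifted[5, ] <- shifted[5, ] + 5.0
  after <- compute_ihs(shifted, ann, min_mean = -Inf)
  expect_equal(after$h1, base$h1, tolerance = 1e-9)
  expect_equal(after$event_freq, base$event_freq)
  expect_equal(after$ihs, base$ihs, tolerance = 1e-9)
})

test_that("IHS is invariant to joint sample permutation", {
  set.seed(13)
  ann <- tibble::tibble(
    sample_id = paste0("S", 1:10),
    patient_id = rep(paste0("P", 1:5), each = 2),
    region_id = rep(c("R1", "R2"), 5)
  )
  m <- matrix(rnorm(15 * 10, 4, 1), nrow = 15,
              dimnames = list(paste0("G", 1:15), ann$sample_id))
  perm <- sample(10)
  base <- compute_ihs(m, ann, min_mean = -Inf)
  permuted <- compute_ihs(m[, perm], ann[perm, ], min_mean = -Inf)
  expect_equal(permuted, base)
})

test_that("an outlier region never makes a gene look more clonal", {
  # A +10 log2 outlier drives h1 toward its contaminated asymptote, so a
  # clonal gene (low h1) always moves up, and the event frequency can
  # only grow. (For genes already near h1 = 1 the ANOVA ICC estimator can
  # pull h1 slightly back toward the asymptote, so monotonicity is only
  # guaranteed from the clonal side.)
  set.seed(21)
  ann <- tibble::tibble(
    sample_id = paste0("S", 1:12),
    patient_id = rep(paste0("P", 1:4), each = 3),
    region_id = rep(paste0("R", 1:3), 4)
  )
  for (i in 1:20) {
    # between-patient structure keeps baseline h1 in the clonal range
    m <- matrix(rep(rnorm(10 * 4, 4, 2), each = 3) + rnorm(10 * 12, 0, 0.3),
                nrow = 10, byrow = TRUE,
                dimnames = list(paste0("G", 1:10), ann$sample_id))
    base <- compute_ihs(m, ann, min_mean = -Inf)
    g <- sample(10, 1); s <- sample(12, 1)
    m[g, s] <- m[g, s] + 10
    after <- compute_ihs(m, ann, min_mean = -Inf)
    if (base$h1[g] < 0.5) expect_gte(after$h1[g] - base$h1[g], -1e-12)
    expect_gte(after$event_freq[g] - base$event_freq[g], 0)
  }
})

test_that("percentile ranks average to (G+1)/(2G) and IHS lies in (0, 1]", {
  set.seed(31)
  ann <- tibble::tibble(
    sample_id = paste0("S", 1:8),
    patient_id = rep(paste0("P", 1:4), each = 2),
    region_id = rep(c("R1", "R2"), 4)
  )
  m <- matrix(rnorm(40 * 8, 4, 1), nrow = 40,
              dimnames = list(paste0("G", 1:40), ann$sample_id))
  ihs <- compute_ihs(m, ann, min_mean = -Inf)
  G <- nrow(ihs)
  expect_equal(mean(ihs$rank_h1), (G + 1) / (2 * G))
  expect_equal(mean(ihs$rank_e), (G + 1) / (2 * G))
  expect_true(all(ihs$ihs > 0 & ihs$ihs <= 1))
  expect_true(all(ihs$h1 >= 0 & ihs$h1 <= 1))
  expect_true(all(ihs$event_freq >= 0 & ihs$event_freq <= 1))
})

test_that("single-region patients are excluded with a warning and filters log drops", {
  set.seed(41)
  ann <- tibble::tibble(
    sample_id = paste0("S", 1:5),
    patient_id = c("P1", "P1", "P2", "P2", "P3"),
    region_id = c("R1", "R2", "R1", "R2", "R1")
  )
  m <- matrix(runif(6 * 5, 2, 6), nrow = 6,
              dimnames = list(paste0("G", 1:6), ann$sample_id))
  expect_warning(ihs <- compute_ihs(m, ann, min_mean = 0), "P3")
  expect_true(all(ihs$n_patients_used == 2L))

  m[1, ] <- 0.1  # below default expression filter
  expect_message(
    ihs2 <- suppressWarnings(compute_ihs(m, ann, min_mean = 1)),
    "dropped"
  )
  expect_false("G1" %in% ihs2$gene_id)

  ann_single <- ann[c(1, 3, 5), ]
  expect_error(suppressWarnings(compute_ihs(m, ann_single)), "2 patients")
})

test_that("subclonal genes score higher IHS than stable genes on simulated truth", {
  for (s in 1:10) {
    sim <- simulate_cohort(n_patients = 8, regions_per_patient = 3,
                           n_genes = 400, n_clonal_immune = 40,
                           n_subclonal_immune = 40, n_subclonal_background = 80,
                           seed = s)
    ihs <- suppressMessages(compute_ihs(sim$expr, sim$annot))
    cat_of <- sim$truth$gene_category[ihs$gene_id]
    expect_gt(mean(ihs$ihs[cat_of == "subclonal_background"]),
              mean(ihs$ihs[cat_of == "stable_background"]))
  }
})

test_that("low-IHS selection is deterministic with documented tie-breaks", {
  ihs <- structure(
    tibble::tibble(
      gene_id = c("GB", "GA", "GC", "GD"),
      h1 = c(0.3, 0.1, 0.2, 0.9),
      event_freq = c(0.1, 0.1, 0.2, 0.8),
      rank_h1 = c(0.5, 0.25, 0.375, 1),
      rank_e = c(0.25, 0.25, 0.625, 1),
      ihs = c(0.375, 0.25, 0.5, 1),
      n_patients_used = 4L,
      flagged_constant = FALSE
    ),
    class = c("ihs_tbl", class(tibble::tibble()))
  )
  expect_identical(select_low_ihs(ihs, 1)$genes, "GA")
  expect_identical(select_low_ihs(ihs, 4)$genes, c("GA", "GB", "GC", "GD"))

  # tie on ihs at the boundary: smaller h1 wins
  ihs$ihs[c(1, 3)] <- 0.4
  sel <- select_low_ihs(ihs, 2)
  expect_identical(sel$genes, c("GA", "GC"))  # GC h1=0.2 < GB h1=0.3

  expect_error(select_low_ihs(ihs, 5), "4")
})
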