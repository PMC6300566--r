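test_that("combine_pvalues implements the floored geometric mean", {
  expect_equal(combine_pvalues(c(0.3, 0.3, 0.3)), 0.3, tolerance = 1e-12)
  expect_equal(combine_pvalues(c(0.01, 0.0001)), 0.001, tolerance = 1e-12)
  # zeros are floored to 1e-4 before combining
  expect_equal(combine_pvalues(c(0, 0.01)), 0.001, tolerance = 1e-12)
  expect_equal(combine_pvalues(rep(0, 4)), 1e-4, tolerance = 1e-12)
  expect_error(combine_pvalues(numeric(0)), "non-empty")
  expect_error(combine_pvalues(c(0.2, 1.5)), "\\[0, 1\\]")
})

test_that("combine_pvalues is permutation-invariant, bounded and monotone", {
  withr::with_seed(14, {
    for (i in 1:20) {
      p <- stats::runif(sample(2:12, 1))
      pm <- combine_pvalues(p)
      expect_equal(combine_pvalues(sample(p)), pm, tolerance = 1e-12)
      expect_gte(pm, 1e-4)
      expect_lte(pm, max(p) + 1e-15)
      # decreasing one above-floor value strictly decreases the mean
      j <- which.max(p)
      p2 <- p; p2[j] <- p2[j] / 2
      if (p2[j] > 1e-4) expect_lt(combine_pvalues(p2), pm)
      # reciprocal identity to 12 significant digits
      expect_equal(sensitivity_index(pm) * pm, 1, tolerance = 1e-12)
    }
  })
})

test_that("sensitivity_index is the reciprocal of p_mean", {
  expect_equal(sensitivity_index(1), 1)
  expect_equal(sensitivity_index(1e-4), 1e4)
  # printed reference pair: index 75.82609324 <-> p_mean 0.0132 at 4 decimals
  expect_equal(round(1 / 75.82609324, 4), 0.0132)
  expect_error(sensitivity_index(0), "\\(0, 1\\]")
})

test_that("default zero floor tracks the null-set resolution", {
  expect_equal(default_zero_floor(1000), 1e-4)
  expect_equal(default_zero_floor(200), 5e-4)
})

make_matrix <- function(emp) {
  structure(list(empirical_p = emp, uncorrected_p = emp,
                 overlap = emp * 0, null_p = NULL,
                 n_null = 1000L, seed = 1L),
            class = "enrichment_matrix")
}

toy_catalog <- function() {
  pc <- pathway_collection(list(P1 = "a", P2 = "b", P3 = "c"))
  disease_catalog(list(D1 = c("P1", "P2", "P3"), D2 = "P1"),
                  c(D1 = "nervous", D2 = "null"), pc)
}

test_that("score_disease gathers the full interactome x pathway block", {
  emp <- matrix(stats::runif(30), nrow = 10,
                dimnames = list(sprintf("I%02d", 1:10), c("P1", "P2", "P3")))
  m <- make_matrix(emp)
  cat <- toy_catalog()
  s <- score_disease(m, "D1", cat)
  expect_equal(s$n, 30L)
  expect_equal(s$p_mean, combine_pvalues(as.vector(emp)), tolerance = 1e-12)
  expect_equal(s$sensitivity_index * s$p_mean, 1, tolerance = 1e-12)

  s2 <- score_disease(m, "D2", cat)
  expect_equal(s2$n, 10L)

  # single cell: index is the plain reciprocal
  m1 <- make_matrix(matrix(0.0042, 1, 1, dimnames = list("I", "P1")))
  s3 <- score_disease(m1, "D2", cat)
  expect_equal(s3$sensitivity_index, 1 / 0.0042, tolerance = 1e-12)

  # no-enrichment baseline
  mall1 <- make_matrix(matrix(1, 2, 3, dimnames = list(c("I1", "I2"),
                                                       c("P1", "P2", "P3"))))
  s4 <- score_disease(mall1, "D1", cat)
  expect_equal(s4$p_mean, 1)
  expect_equal(s4$sensitivity_index, 1)

  expect_error(score_disease(m, "D9", cat), "unknown disease")
  cat2 <- toy_catalog()
  m_small <- make_matrix(emp[, 1:2])
  expect_error(score_disease(m_small, "D1", cat2), "missing from matrix")
})

test_that("rank_diseases orders by index with lexicographic tie-break", {
  cat <- toy_catalog()
  mk <- function(d, pm) structure(list(disease = d, category = "null",
                                       p_values = pm, n = 1L, p_mean = pm,
                                       sensitivity_index = 1 / pm,
                                       zero_floor = 1e-4),
                                  class = "combined_score")
  r <- rank_diseases(list(mk("D2", 1 / 75.83), mk("D1", 1 / 239.29)), cat)
  expect_identical(r$disease, c("D1", "D2"))
  expect_identical(r$rank, 1:2)

  tied <- rank_diseases(list(mk("D2", 0.5), mk("D1", 0.5)), cat)
  expect_identical(tied$disease, c("D1", "D2"))

  expect_error(rank_diseases(list(mk("D1", 0.5), mk("D1", 0.5)), cat),
               "duplicate")
  single <- rank_diseases(list(mk("D1", 0.2)), cat)
  expect_identical(single$rank, 1L)
})

test_that("category_summary reports log10-index quantiles per category", {
  cat <- toy_catalog()
  mk <- function(d, pm, cc) structure(list(disease = d, category = cc,
                                           p_values = pm, n = 1L, p_mean = pm,
                                           sensitivity_index = 1 / pm,
                                           zero_floor = 1e-4),
                                      class = "combined_score")
  s <- list(mk("D1", 0.01, "nervous"), mk("D2", 0.5, "null"))
  cs <- category_summary(s, cat)
  expect_identical(cs$category, c("nervous", "null"))
  nerv <- cs[cs$category == "nervous", ]
  expect_equal(nerv$median, 2)        # index 100 -> log10 = 2
  expect_equal(nerv$min, nerv$max)    # single score: all quantiles equal
  expect_equal(nerv$q1, nerv$q3)
})

test_that("planted diseases outrank unplanted ones end to end", {
  hits <- 0L
  for (s in 1:3) {
    b <- generate_study(small_config(master_seed = 100L + s,
                                     planted_fraction = 0.8))
    ints <- lapply(b$seed_genes, function(g) {
      extract_interactome(b$network, interactome_spec(g, 0.4, 1L))
    })
    m <- enrich_matrix(ints, b$pathways, b$network$nodes, n_null = 100,
                       master_seed = 100L + s)
    ranking <- rank_diseases(score_all_diseases(m, b$catalog), b$catalog)
    truth <- unique(b$truth$disease)
    top <- ranking$disease[seq_along(truth)]
    if (setequal(top, truth)) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})
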