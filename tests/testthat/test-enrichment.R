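test_that("overlap_pvalue reproduces exact enumeration values", {
  # 210 4-subsets of a 10-gene universe; 5 of them contain all 4 set genes
  expect_equal(overlap_pvalue(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(overlap_pvalue(4, 5, 4, 10), hyper_tail_enum(10, 5, 4, 4),
               tolerance = 1e-12)
  # tail sum C(6,3)C(14,2) + C(6,4)C(14,1) + C(6,5) over C(20,5)
  expect_equal(overlap_pvalue(5, 6, 3, 20), 2036 / 15504, tolerance = 1e-12)
  expect_equal(overlap_pvalue(5, 6, 3, 20), hyper_tail_enum(20, 6, 5, 3),
               tolerance = 1e-12)
  expect_equal(overlap_pvalue(300, 40, 0, 2000), 1)
  expect_error(overlap_pvalue(4, 5, 6, 10), "overlap")
  expect_error(overlap_pvalue(4, 11, 2, 10), "universe_size")
})

test_that("overlap_pvalue is stable for large universes", {
  p <- overlap_pvalue(500, 200, 50, 1e6)
  expect_true(is.finite(log(p)))
  expect_gt(p, 0)
  expect_lt(p, 1e-100)
})

test_that("sample_null_sets draws uniform size-matched sets", {
  uni <- generate_universe(2000)
  nulls <- sample_null_sets(uni, 300, n_sets = 1000, seed = 21)
  expect_length(nulls, 1000L)
  expect_true(all(lengths(nulls) == 300L))
  expect_true(all(vapply(nulls, anyDuplicated, 0L) == 0L))

  # binomial oracle on inclusion frequency: p = 300/2000 = 0.15
  freq <- table(factor(unlist(nulls), levels = uni)) / 1000
  se <- sqrt(0.15 * 0.85 / 1000)
  expect_true(all(abs(freq - 0.15) < 4 * se + 1e-9))

  expect_identical(sample_null_sets(uni, 10, 5, seed = 3),
                   sample_null_sets(uni, 10, 5, seed = 3))
  expect_identical(sample_null_sets(letters, 26, 2, seed = 1)[[1]][order(
    sample_null_sets(letters, 26, 2, seed = 1)[[1]])], letters)
  expect_error(sample_null_sets(letters, 27, 1), "exceeds")
})

test_that("empirical_pvalue counts the <= fraction", {
  expect_equal(empirical_pvalue(0.2, c(0.1, 0.2, 0.3, 0.4)), 0.5)
  expect_equal(empirical_pvalue(0.9, c(0.1, 0.2)), 1)
  expect_equal(empirical_pvalue(0.05, c(0.1, 0.2)), 0)
  expect_equal(empirical_pvalue(0.05, c(0.1, 0.2), pseudo_count = TRUE), 1 / 3)
  expect_error(empirical_pvalue(0.5, numeric(0)), "non-empty")
})

test_that("empirical_pvalue is monotone in the observed p", {
  withr::with_seed(8, {
    nulls <- stats::runif(200)
    obs <- sort(stats::runif(50))
    emp <- vapply(obs, empirical_pvalue, 0, null_p = nulls)
    expect_true(all(diff(emp) >= 0))
  })
})

test_that("enrich_matrix flags extreme and null overlaps correctly", {
  uni <- generate_universe(1000)
  pw_genes <- uni[1:50]
  pc <- pathway_collection(list(PW1 = pw_genes))

  # interactome identical to the pathway: no random 50-set matches it
  ia <- new_interactome_for_test("hit", pw_genes)
  m <- enrich_matrix(list(ia), pc, uni, n_null = 1000, master_seed = 2)
  expect_equal(m$empirical_p["hit", "PW1"], 0)
  expect_lt(m$uncorrected_p["hit", "PW1"], 1e-80)

  # disjoint interactome: uncorrected p = 1, empirical p = 1
  ia2 <- new_interactome_for_test("miss", uni[501:550])
  m2 <- enrich_matrix(list(ia2), pc, uni, n_null = 100, master_seed = 2)
  expect_equal(m2$uncorrected_p["miss", "PW1"], 1)
  expect_equal(m2$empirical_p["miss", "PW1"], 1)
})

test_that("enrich_matrix is deterministic and respects the 1/n_null bound", {
  b <- generate_study(small_config())
  ints <- lapply(b$seed_genes[1:3], function(g) {
    extract_interactome(b$network, interactome_spec(g, 0.4, 2L))
  })
  m1 <- enrich_matrix(ints, b$pathways, b$network$nodes, n_null = 50,
                      master_seed = 77)
  m2 <- enrich_matrix(ints, b$pathways, b$network$nodes, n_null = 50,
                      master_seed = 77)
  expect_identical(m1, m2)
  expect_false(anyNA(m1$empirical_p))
  nz <- m1$empirical_p[m1$empirical_p > 0]
  expect_true(all(nz >= 1 / 50 - 1e-12))
  # empirical p must equal the fraction of that pathway's nulls <= observed
  expect_equal(m1$empirical_p[2, 5],
               mean(m1$null_p[[2]][, 5] <= m1$uncorrected_p[2, 5]))
})

test_that("enrich_matrix drops out-of-universe genes and errors when empty", {
  uni <- generate_universe(100)
  pc <- pathway_collection(list(PW1 = c(uni[1:10], "ALIEN")))
  ia <- new_interactome_for_test("I1", c(uni[5:20], "GHOST"))
  expect_message(m <- enrich_matrix(list(ia), pc, uni, n_null = 10,
                                    master_seed = 1),
                 "dropped")
  expect_equal(m$overlap["I1", "PW1"], 6)

  bad <- new_interactome_for_test("I2", c("GHOST", "PHANTOM"))
  expect_error(suppressMessages(
    enrich_matrix(list(bad), pc, uni, n_null = 10, master_seed = 1)),
    "empty after universe restriction")
})

test_that("null empirical p-values are approximately Uniform[0,1]", {
  # unplanted bundle: random test sets against random pathways
  b <- generate_study(small_config(master_seed = 5L, planted_fraction = 0))
  uni <- b$network$nodes
  sets <- withr::with_seed(31, lapply(1:5, function(i) {
    new_interactome_for_test(paste0("R", i), sample(uni, 150))
  }))
  m <- enrich_matrix(sets, b$pathways, uni, n_null = 100, master_seed = 9)
  emp <- as.vector(m$empirical_p)
  expect_gte(length(emp), 50)
  ks <- suppressWarnings(stats::ks.test(emp, "punif"))
  expect_gt(ks$p.value, 0.01)
})
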