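test_that("extract_interactome walks thresholded paths on the 3-node fixture", {
  net <- path3_network()
  cases <- list(
    list(spec = interactome_spec("A", 0.7, 1L), want = c("A", "B")),
    list(spec = interactome_spec("A", 0.7, 2L), want = c("A", "B", "C")),
    # threshold prunes the first hop, blocking the second
    list(spec = interactome_spec("A", 0.9, 2L), want = "A"),
    list(spec = interactome_spec("B", 0.7, 1L), want = c("A", "B", "C")))
  for (cs in cases) {
    expect_identical(extract_interactome(net, cs$spec)$members, cs$want)
  }
  expect_error(extract_interactome(net, interactome_spec("Z", 0.5, 1L)), "Z")
})

test_that("an isolated seed yields the singleton interactome", {
  net <- interaction_network(data.frame(gene_a = "A", gene_b = "B",
                                        confidence = 0.5),
                             nodes = c("A", "B", "L"))
  expect_identical(extract_interactome(net, interactome_spec("L", 0.1, 2L))$members,
                   "L")
  # no qualifying edge at threshold 1 on sub-1 confidences
  expect_identical(extract_interactome(net, interactome_spec("A", 1, 2L))$members,
                   "A")
})

test_that("extraction is monotone in threshold and order, and matches igraph", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    net <- random_network(50, p = 0.1, seed = s)
    seed_gene <- net$nodes[1 + (s %% 50)]
    for (thr in c(0.2, 0.5, 0.8)) {
      m1 <- extract_interactome(net, interactome_spec(seed_gene, thr, 1L))$members
      m2 <- extract_interactome(net, interactome_spec(seed_gene, thr, 2L))$members
      lo <- extract_interactome(net, interactome_spec(seed_gene, thr - 0.1, 1L))$members
      expect_true(all(m1 %in% m2))
      expect_true(all(m1 %in% lo))
      expect_identical(m1, ego_oracle(net, seed_gene, thr, 1L))
      expect_identical(m2, ego_oracle(net, seed_gene, thr, 2L))
    }
  }
})

test_that("order-2 equals one BFS layer applied to each order-1 member", {
  for (s in 6:9) {
    net <- random_network(50, p = 0.08, seed = s)
    seed_gene <- net$nodes[3]
    thr <- 0.4
    m1 <- extract_interactome(net, interactome_spec(seed_gene, thr, 1L))$members
    layered <- unique(unlist(lapply(m1, function(g) {
      extract_interactome(net, interactome_spec(g, thr, 1L))$members
    })))
    m2 <- extract_interactome(net, interactome_spec(seed_gene, thr, 2L))$members
    expect_setequal(m2, layered)
  }
})

test_that("tune_interactome honors the preference order", {
  # seed with 300 direct neighbors at >= 0.4: order 1 satisfies the window
  hub <- interaction_network(data.frame(
    gene_a = "HUB", gene_b = sprintf("X%03d", 1:300), confidence = 0.45))
  got <- tune_interactome(hub, "HUB", size_window = c(100, 600),
                          thresholds = c(0.4), orders = c(1L, 2L))
  expect_equal(got$spec$order, 1L)
  expect_true(got$in_window)

  # isolated seed: flagged singleton
  iso <- interaction_network(data.frame(gene_a = "A", gene_b = "B",
                                        confidence = 0.9),
                             nodes = c("A", "B", "L"))
  got <- tune_interactome(iso, "L")
  expect_false(got$in_window)
  expect_length(got$interactome$members, 1L)

  # order 1 too small (12), order 2 in window (250): order 2 chosen
  spokes <- sprintf("S%02d", 1:12)
  leaves <- data.frame(
    gene_a = rep(spokes, each = 20),
    gene_b = sprintf("L%03d", 1:240), confidence = 0.8)
  star <- interaction_network(rbind(
    data.frame(gene_a = "SEED", gene_b = spokes, confidence = 0.8), leaves))
  got <- tune_interactome(star, "SEED", size_window = c(100, 600),
                          thresholds = c(0.4, 0.6), orders = c(1L, 2L))
  expect_equal(got$spec$order, 2L)
  expect_true(got$in_window)
  # exhaustive scan oracle: the returned size must be the best order-2 size
  expect_equal(length(got$interactome$members), 253L)

  # higher threshold preferred when both land in the window
  both <- interaction_network(data.frame(
    gene_a = "H", gene_b = sprintf("Y%03d", 1:200),
    confidence = rep(c(0.45, 0.95), each = 100)))
  got <- tune_interactome(both, "H", size_window = c(50, 600),
                          thresholds = c(0.4, 0.9), orders = c(1L))
  expect_equal(got$spec$confidence_threshold, 0.9)
})

test_that("merge_similar groups by Jaccard with single linkage", {
  mk <- function(nm, members) new_interactome_for_test(nm, members)
  a <- mk("A", c("x", "y", "z"))
  b <- mk("B", c("x", "y", "w"))
  d <- mk("D", c("q", "r"))

  # Jaccard(a, b) = 2/4 = 0.5: merged at threshold 0.5, not above
  merged <- merge_similar(list(a, b, d), 0.5)
  expect_length(merged, 2L)
  expect_identical(merged[[1]]$name, "A+B")
  expect_setequal(merged[[1]]$members, c("x", "y", "z", "w"))
  expect_identical(merged[[1]]$spec, "merged")
  expect_length(merged[[1]]$provenance, 2L)

  kept <- merge_similar(list(a, b, d), 0.51)
  expect_length(kept, 3L)

  # identical sets always merge; disjoint never do
  expect_length(merge_similar(list(mk("P", c("u", "v")), mk("Q", c("u", "v"))),
                              0.99), 1L)
  expect_length(merge_similar(list(a, d), 0.01), 2L)
  expect_identical(merge_similar(list(), 0.8), list())
})

test_that("merge_similar is idempotent", {
  ints <- lapply(1:6, function(i) {
    withr::with_seed(i, new_interactome_for_test(
      paste0("I", i), sample(letters, 8)))
  })
  once <- merge_similar(ints, 0.4)
  twice <- merge_similar(once, 0.4)
  expect_identical(vapply(twice, `[[`, "", "name"),
                   vapply(once, `[[`, "", "name"))
  expect_identical(lapply(twice, `[[`, "members"),
                   lapply(once, `[[`, "members"))
})
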