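test_that("gene aggregation deduplicates events idempotently", {
  ev <- data.frame(gene_id = c("G1", "G1", "G2"))
  expect_setequal(genes_with_switches(ev), c("G1", "G2"))
  expect_equal(genes_with_switches(data.frame(gene_id = character(0))),
               character(0))
  twice <- genes_with_switches(ev)
  expect_identical(genes_with_switches(data.frame(gene_id = twice)), twice)
})

test_that("Venn partitions cover the union exactly once", {
  sets <- list(L1 = c("A", "B", "C"), L2 = c("B", "C"), L3 = "C")
  part <- intersect_gene_sets(sets)
  common <- part$members[[which(part$region == "L1&L2&L3")]]
  expect_equal(common, "C")
  expect_equal(sum(part$n), length(unique(unlist(sets))))

  same <- intersect_gene_sets(list(a = c("X", "Y"), b = c("X", "Y")))
  expect_equal(same$region, "a&b")
  expect_equal(same$n, 2)

  disj <- intersect_gene_sets(list(a = "X", b = "Y"))
  expect_false(any(disj$region == "a&b"))
  expect_equal(sum(disj$n), 2)

  expect_error(intersect_gene_sets(list(a = "X")), "at least 2")
})

test_that("hypergeometric upper tail matches closed forms and enumeration", {
  expect_equal(hypergeom_upper(0, 5, 5, 20), 1.0)
  expect_equal(hypergeom_upper(5, 5, 5, 20), 1 / choose(20, 5))
  expect_error(hypergeom_upper(6, 5, 5, 20), "inconsistent")

  # brute-force oracle: enumerate every draw of n from N
  enum_upper <- function(k, K, n, N) {
    draws <- utils::combn(N, n)
    annotated <- seq_len(K)
    mean(apply(draws, 2, function(d) sum(d %in% annotated) >= k))
  }
  for (N in c(5, 8, 12)) {
    for (K in 1:(N - 1)) {
      for (n in 1:(N - 1)) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_upper(k, K, n, N), enum_upper(k, K, n, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH adjustment is step-up with monotonicity, capped at 1", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ORA ranks a planted enriched set first and respects cutoffs", {
  universe <- sprintf("g%02d", 1:40)
  coll <- list(
    sets = list(S1 = universe[1:10], S2 = universe[11:20],
                S3 = universe[21:30], S4 = universe[31:40]),
    descriptions = c(S1 = "", S2 = "", S3 = "", S4 = ""),
    universe = NULL)

  expect_equal(nrow(run_ora("not_a_gene", coll)), 0)

  set.seed(7)
  query <- c(universe[1:8], sample(universe[11:40], 2))
  res <- run_ora(query, coll)
  expect_equal(res$set_id[1], "S1")
  expect_equal(res$k[1], 8)
  expect_true(all(res$p_adj >= res$p))

  # more passing sets than `top` returns exactly `top`
  many <- list(sets = stats::setNames(rep(list(universe[1:10]), 15),
                                      sprintf("R%02d", 1:15)),
               descriptions = character(0), universe = NULL)
  res2 <- run_ora(universe[1:10], many, universe = universe, top = 10)
  expect_equal(nrow(res2), 10)
})

test_that("null queries are calibrated near the nominal level", {
  # discrete test: P(p <= 0.05) equals the largest achievable level below
  # 0.05, which this universe/set/query geometry places at 0.0498
  universe <- sprintf("g%02d", 1:40)
  sets <- list(S1 = universe[1:10], S2 = universe[11:20],
               S3 = universe[21:30], S4 = universe[31:40])
  set.seed(123)
  hits <- 0; trials <- 0
  for (rep in 1:400) {
    query <- sample(universe, 10)
    for (s in sets) {
      k <- length(intersect(query, s))
      p <- hypergeom_upper(k, 10, 10, 40)
      hits <- hits + (p <= 0.05)
      trials <- trials + 1
    }
  }
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(hits / trials - 0.05), 3 * se)
})
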