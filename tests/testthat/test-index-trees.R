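fig_trie_umis <- c("AAAA", "ATAA", "CTGA", "AAAT", "ATTA")
fig_bk_umis <- c("ATAA", "AAAA", "CCGG", "AAAT", "ATTA")

test_that("trie query collects the k-ball and removal sticks", {
  tab <- as_umi_table(data.frame(umi = fig_trie_umis, count = rep(2L, 5)))
  idx <- umi_index(tab, k = 1, backend = "trie")
  # AAAG is not itself one of the five UMIs: query its neighborhood
  expect_setequal(umi_remove_near(idx, "AAAG", strict = FALSE),
                  c("AAAA", "AAAT"))
  expect_false(umi_contains(idx, "AAAA"))
  expect_setequal(umi_alive(idx), c("ATAA", "CTGA", "ATTA"))
  # identical second query finds nothing
  idx2 <- umi_index(tab, k = 1, backend = "trie")
  umi_remove_near(idx2, "AAAG", strict = FALSE)
  expect_length(umi_remove_near(idx2, "AAAG", strict = FALSE), 0L)
})

test_that("BK insertion attaches each UMI at its parent's distance slot", {
  tr <- cpp_bk_build_trace(fig_bk_umis)
  tr <- tr[match(fig_bk_umis, tr$umi), ]
  expect_equal(tr$parent[tr$umi == "ATAA"], "")        # first insert = root
  expect_equal(tr$parent[tr$umi == "AAAA"], "ATAA")
  expect_equal(tr$dist[tr$umi == "AAAA"], 1L)
  expect_equal(tr$parent[tr$umi == "CCGG"], "ATAA")
  expect_equal(tr$dist[tr$umi == "CCGG"], 4L)
  # d(ATAA, AAAT) = 2 and the root's slot 2 is free, so AAAT hangs off the
  # root; ATTA then recurses through the occupied slot 1 into AAAA
  expect_equal(tr$parent[tr$umi == "AAAT"], "ATAA")
  expect_equal(tr$dist[tr$umi == "AAAT"], 2L)
  expect_equal(tr$parent[tr$umi == "ATTA"], "AAAA")
  expect_equal(tr$dist[tr$umi == "ATTA"], 2L)
  # every edge distance equals the recomputed pairwise distance
  inner <- tr[tr$parent != "", ]
  expect_equal(inner$dist, unname(umi_hamming(inner$umi, inner$parent)))
  expect_error(cpp_bk_build_trace(c("AAAA", "AAAA")), "duplicate")
})

test_that("BK query prunes by triangle inequality without losing results", {
  tab <- as_umi_table(data.frame(umi = fig_bk_umis, count = c(1:5)))
  idx <- umi_index(tab, k = 1, backend = "bktree")
  expect_setequal(umi_remove_near(idx, "AAAG", strict = FALSE),
                  c("AAAA", "AAAT"))
  # F = 0 admits nothing by frequency, but the queried UMI always returns
  idx2 <- umi_index(tab, k = 1, backend = "bktree")
  expect_equal(umi_remove_near(idx2, "ATAA", f_max = 0), "ATAA")
  # random replay against the oracle
  set.seed(50)
  tab2 <- umi_count(random_umis(500, 7))
  ora <- oracle_index(tab2, 2)
  idx3 <- umi_index(tab2, k = 2, backend = "bktree")
  for (u in sample(tab2$umi, 120)) {
    expect_equal(sort(umi_remove_near(idx3, u)), oracle_remove_near(ora, u))
  }
})

test_that("BK child indices and pruning flags stay sound under removal", {
  set.seed(51)
  for (backend in c("bktree", "trie", "fenwickbk", "ngrambk")) {
    tab <- umi_count(random_umis(300, 8))
    idx <- umi_index(tab, k = 1, backend = backend)
    for (u in sample(tab$umi, 60)) umi_remove_near(idx, u)
    audit <- umidedup:::cpp_index_audit(idx$ptr)
    expect_true(audit$supported)
    if (backend != "trie") expect_true(audit$child_distances_ok)
    expect_true(audit$flags_ok, label = backend)
  }
})

test_that("membership counts match each structure's design", {
  set.seed(52)
  tab <- umi_count(random_umis(200, 9))
  n <- nrow(tab)
  # plain BK-tree and trie hold every UMI exactly once
  for (backend in c("bktree", "trie")) {
    audit <- umidedup:::cpp_index_audit(
      umi_index(tab, 1, backend = backend)$ptr)
    expect_equal(audit$membership, rep(1L, n))
  }
  # n-grams BK-trees: each UMI sits in exactly k + 1 bins
  for (k in 1:2) {
    audit <- umidedup:::cpp_index_audit(
      umi_index(tab, k, backend = "ngrambk")$ptr)
    expect_equal(audit$membership, rep(k + 1L, n))
  }
  # Fenwick: each UMI appears once per Fenwick node covering its rank
  audit <- umidedup:::cpp_index_audit(umi_index(tab, 1,
                                                backend = "fenwickbk")$ptr)
  vals <- sort(unique(tab$count))
  R <- length(vals)
  path_len <- function(r) {
    t <- r; cnt <- 0L
    while (t <= R) { cnt <- cnt + 1L; t <- t + bitwAnd(t, -t) }
    cnt
  }
  expected <- vapply(match(tab$count, vals), path_len, integer(1))
  expect_equal(audit$membership, expected)
})

test_that("Fenwick prefix decomposition tiles [1, rank(F)] disjointly", {
  dec <- fenwick_prefix_decompose(1:7, 5)
  expect_equal(dec$node, c(5L, 4L))
  expect_equal(dec$rank_lo, c(5L, 1L))
  expect_equal(dec$rank_hi, c(5L, 4L))
  set.seed(53)
  vals <- sort(sample(1:500, 64))
  for (f in 1:64) {
    F <- vals[f]
    dec <- fenwick_prefix_decompose(vals, F)
    covered <- unlist(mapply(seq, dec$rank_lo, dec$rank_hi,
                             SIMPLIFY = FALSE))
    expect_equal(sort(covered), seq_len(f)) # disjoint cover of [1, rank(F)]
  }
  expect_equal(fenwick_prefix_decompose(c(5, 9), 2)$rank_of_f, 0L)
  dec_inf <- fenwick_prefix_decompose(vals, Inf)
  expect_equal(sum(dec_inf$rank_hi - dec_inf$rank_lo + 1L), 64L)
})

test_that("degenerate equal frequencies collapse the Fenwick index", {
  tab <- as_umi_table(data.frame(umi = c("AAAA", "AAAT", "GGGG", "GGGT"),
                                 count = rep(3L, 4)))
  st <- umi_index_stats(tab, 1, backend = "fenwickbk")
  expect_lte(st$n_populated_nodes, 2L)
  g_f <- umi_group(tab, 1, "directional", "fenwickbk")
  g_n <- umi_group(tab, 1, "directional", "naive")
  expect_equal(grouping_signature(g_f), grouping_signature(g_n))
})

test_that("tree backends replay scripted queries like the naive oracle", {
  sim <- simulate_umi_dataset(100, 10, 1, seed = 54)
  tab <- sim$table
  set.seed(54)
  queries <- sample(tab$umi, 500, replace = TRUE)
  fmaxes <- ifelse(runif(500) < 0.3, Inf, sample(1:80, 500, replace = TRUE))
  expected <- local({
    ora <- oracle_index(tab, 1)
    lapply(seq_along(queries), function(i)
      oracle_remove_near(ora, queries[i], fmaxes[i]))
  })
  for (backend in c("trie", "bktree", "fenwickbk", "ngrambk")) {
    idx <- umi_index(tab, k = 1, backend = backend)
    got <- lapply(seq_along(queries), function(i)
      sort(umi_remove_near(idx, queries[i], f_max = fmaxes[i])))
    expect_identical(got, expected, label = backend)
  }
})
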