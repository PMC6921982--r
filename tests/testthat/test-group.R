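bridge_tab <- function() as_umi_table(data.frame(
  umi = c("AAAA", "AAAT", "AATT"), count = c(10L, 5L, 3L)))

test_that("cluster merges across bridges, adjacency does not", {
  g_cc <- umi_group(bridge_tab(), 1, "cluster", "naive")
  expect_equal(n_groups(g_cc), 1L) # AAAT bridges AAAA and AATT (d = 2)
  expect_equal(g_cc$umi[g_cc$representative], "AAAA")

  g_adj <- umi_group(bridge_tab(), 1, "adjacency", "naive")
  expect_equal(n_groups(g_adj), 2L)
  expect_setequal(g_adj$umi[g_adj$representative], c("AAAA", "AATT"))
  expect_equal(sort(g_adj$umi[g_adj$group == g_adj$group[1]]),
               c("AAAA", "AAAT"))
})

test_that("directional admits neighbors through f(v) <= eps * (f(u) + 1)", {
  tab <- as_umi_table(data.frame(umi = c("AAAA", "AAAT", "AATT"),
                                 count = c(10L, 5L, 2L)))
  # 5 <= 0.5 * 11 admits AAAT; recursing from AAAT, 2 <= 0.5 * 6 admits AATT
  expect_equal(n_groups(umi_group(tab, 1, "directional", "naive")), 1L)
  tab2 <- as_umi_table(data.frame(umi = c("AAAA", "AAAT"),
                                  count = c(10L, 6L)))
  # 6 > 0.5 * 11: the boundary case splits
  expect_equal(n_groups(umi_group(tab2, 1, "directional", "naive")), 2L)
  expect_error(umi_group(tab2, 1, "directional", epsilon = 1.5), "epsilon")
})

test_that("degenerate inputs behave: empty table, k >= M, far-apart UMIs", {
  g0 <- umi_group(umi_count(character(0)), 1, "cluster")
  expect_equal(n_groups(g0), 0L)
  expect_equal(nrow(g0), 0L)
  tab <- umi_count(c("AAAA", "CCGG", "TTTT"))
  expect_equal(n_groups(umi_group(tab, 4, "cluster", "naive")), 1L)
  expect_equal(n_groups(umi_group(tab, 1, "adjacency", "naive")), 3L)
})

test_that("representative selection is max frequency, then lexicographic", {
  expect_equal(select_representative(c("AAAA", "AAAT"), c(10, 5)), "AAAA")
  expect_equal(select_representative(c("AAAT", "AAAA"), c(5, 5)), "AAAA")
  expect_equal(select_representative("TTTT", 1), "TTTT")
  expect_error(select_representative(character(0), integer(0)), "empty")
  # groupings agree with the standalone rule
  set.seed(60)
  tab <- umi_count(random_umis(300, 6))
  g <- umi_group(tab, 1, "adjacency", "naive")
  for (gid in unique(g$group)) {
    rows <- g[g$group == gid, ]
    expect_equal(rows$umi[rows$representative],
                 select_representative(rows$umi, rows$count))
  }
})

test_that("groupings partition the key set on every backend", {
  sim <- simulate_umi_dataset(50, 8, 1, seed = 61)
  for (backend in c("naive", "subseq", "ngrambk")) {
    for (method in c("cluster", "adjacency", "directional")) {
      g <- umi_group(sim$table, 1, method, backend)
      expect_equal(sort(g$umi), sort(sim$table$umi))
      expect_false(anyNA(g$group))
      expect_equal(length(unique(g$group)), n_groups(g))
      expect_equal(sum(g$representative), n_groups(g))
      # representative is a member of its own group, by construction
      expect_true(all(tapply(g$representative, g$group, sum) == 1L))
    }
  }
})

test_that("cluster never yields more groups than adjacency", {
  for (seed in 62:66) {
    tab <- simulate_umi_dataset(40, 8, 2, seed = seed)$table
    expect_lte(n_groups(umi_group(tab, 2, "cluster", "naive")),
               n_groups(umi_group(tab, 2, "adjacency", "naive")))
  }
})

test_that("grouping is deterministic and invariant to the backend", {
  sim <- simulate_umi_dataset(80, 10, 1, seed = 67)
  ref <- lapply(c("cluster", "adjacency", "directional"), function(m)
    grouping_signature(umi_group(sim$table, 1, m, "naive")))
  for (backend in UMI_BACKENDS) {
    got <- lapply(c("cluster", "adjacency", "directional"), function(m)
      grouping_signature(umi_group(sim$table, 1, m, backend)))
    expect_identical(got, ref, label = backend)
  }
  # repeated runs are byte-identical
  g1 <- umi_group(sim$table, 1, "directional", "ngrambk")
  g2 <- umi_group(sim$table, 1, "directional", "ngrambk")
  expect_identical(g1, g2)
})

test_that("a prebuilt index can be consumed once, then is rejected", {
  tab <- umi_count(c("AAAA", "AAAT", "TTTT"))
  idx <- umi_index(tab, 1, backend = "bktree")
  g <- umi_group(tab, 1, "adjacency", index = idx)
  expect_equal(n_groups(g), 2L)
  expect_error(umi_group(tab, 1, "adjacency", index = idx), "fresh")
  idx2 <- umi_index(tab, 1, backend = "bktree")
  umi_remove_near(idx2, "TTTT")
  expect_error(umi_group(tab, 1, "adjacency", index = idx2), "fresh")
  idx3 <- umi_index(tab, 2, backend = "naive")
  expect_error(umi_group(tab, 1, "adjacency", index = idx3), "k = 2")
})
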