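test_that("counting UMIs builds the frequency table", {
  tab <- umi_count(c("AA", "AA", "AT"))
  expect_equal(tab$umi, c("AA", "AT"))
  expect_equal(tab$count, c(2L, 1L))
  expect_equal(sum(tab$count), 3L)
  expect_equal(nrow(umi_count(character(0))), 0L)
  expect_error(umi_count(c("AA", "AAA")), "one length")
})

test_that("simulated read multisets collapse to the expected table size", {
  sim <- simulate_umi_dataset(1000, 10, 1, seed = 11)
  reads <- rep(sim$table$umi, sim$table$count)
  tab <- umi_count(reads)
  expect_equal(nrow(tab), nrow(sim$table))
  expect_gt(nrow(tab), 16000)  # about 16.9k uniques at C = 1000, M = 10
  expect_lt(nrow(tab), 17600)
  expect_equal(sum(tab$count), length(reads))
})

test_that("remove_near returns and deletes the k-ball under the F ceiling", {
  mk <- function() umi_index(as_umi_table(data.frame(
    umi = c("AAAA", "AAAT", "TTTT"), count = c(5L, 2L, 3L))),
    k = 1, backend = "naive")

  idx <- mk()
  expect_setequal(umi_remove_near(idx, "AAAA"), c("AAAA", "AAAT"))
  expect_false(umi_contains(idx, "AAAT"))
  expect_true(umi_contains(idx, "TTTT"))

  idx <- mk() # frequency ceiling excludes AAAT but never the query itself
  expect_setequal(umi_remove_near(idx, "AAAA", f_max = 1), "AAAA")

  idx0 <- umi_index(as_umi_table(data.frame(
    umi = c("AAAA", "AAAT", "TTTT"), count = c(5L, 2L, 3L))),
    k = 0, backend = "naive")
  expect_setequal(umi_remove_near(idx0, "AAAA", k = 0), "AAAA")
})

test_that("contains tracks the alive set and absent UMIs are FALSE", {
  tab <- umi_count(c("ACGT", "ACGA", "TTTT"))
  idx <- umi_index(tab, k = 1, backend = "naive")
  for (u in tab$umi) expect_true(umi_contains(idx, u))
  expect_false(umi_contains(idx, "GGGG"))
  S <- umi_remove_near(idx, "ACGT")
  for (u in tab$umi) expect_equal(umi_contains(idx, u), !(u %in% S))
})

test_that("querying with the wrong k or an unknown UMI is an error", {
  idx <- umi_index(umi_count(c("AAAA", "TTTT")), k = 1, backend = "naive")
  expect_error(umi_remove_near(idx, "AAAA", k = 2), "built with k = 1")
  expect_error(umi_remove_near(idx, "CCCC"), "never present")
  expect_silent(umi_remove_near(idx, "CCCC", strict = FALSE))
})

test_that("exhaustive removal partitions the key set (conservation)", {
  set.seed(20)
  tab <- umi_count(random_umis(400, 6))
  for (backend in c("naive", "ngrambk")) {
    idx <- umi_index(tab, k = 1, backend = backend)
    seen <- character(0)
    for (u in sample(tab$umi)) {
      if (!umi_contains(idx, u)) next
      S <- umi_remove_near(idx, u)
      expect_length(intersect(S, seen), 0)
      seen <- c(seen, S)
    }
    expect_setequal(seen, tab$umi)
    expect_length(umi_alive(idx), 0)
  }
})

test_that("all backends replay a scripted query sequence like the oracle", {
  set.seed(21)
  sim <- simulate_umi_dataset(60, 10, 1, seed = 21)
  tab <- sim$table
  queries <- sample(tab$umi, 100, replace = TRUE)
  fmaxes <- ifelse(runif(100) < 0.5, Inf, sample(1:60, 100, replace = TRUE))
  expected <- local({
    ora <- oracle_index(tab, 1)
    lapply(seq_along(queries), function(i)
      oracle_remove_near(ora, queries[i], fmaxes[i]))
  })
  for (backend in UMI_BACKENDS) {
    idx <- umi_index(tab, k = 1, backend = backend)
    got <- lapply(seq_along(queries), function(i)
      sort(umi_remove_near(idx, queries[i], f_max = fmaxes[i])))
    expect_identical(got, expected, label = backend)
  }
})
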