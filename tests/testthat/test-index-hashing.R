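test_that("n-gram splitting follows the floor(M/(k+1)) rule", {
  sp <- split_ngrams("ACGTACGTAC", 1)
  expect_equal(sp$length, c(5L, 5L))
  expect_equal(sp$gram, c("ACGTA", "CGTAC"))
  sp2 <- split_ngrams("ACGTACG", 2) # remainder goes to the last gram
  expect_equal(sp2$length, c(2L, 2L, 3L))
  sp0 <- split_ngrams("ACGTACGTA", 0)
  expect_equal(sp0$gram, "ACGTACGTA")
  expect_error(split_ngrams("AC", 2), "cannot be split")
  # spans are contiguous, non-overlapping, covering
  for (k in 0:3) {
    sp <- split_ngrams("ACGTACGTACG", k)
    expect_equal(sp$start, cumsum(c(1, head(sp$length, -1))))
    expect_equal(sum(sp$length), 11L)
  }
})

test_that("subsequence masks enumerate all choose(M, k) keys", {
  expect_setequal(mask_subsequences("ATCG", 1),
                  c("*TCG", "A*CG", "AT*G", "ATC*"))
  expect_equal(mask_subsequences("AT", 2), "**")
  set.seed(30)
  for (i in 1:10) {
    m <- sample(4:12, 1)
    k <- sample(0:3, 1)
    u <- random_umis(1, m)
    keys <- mask_subsequences(u, k)
    expect_length(keys, choose(m, k))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("generate_within enumerates the Hamming ball exactly once", {
  expect_length(generate_within("AA", 1, c("A", "C", "G", "T")), 7L)
  expect_equal(generate_within("ACG", 0), "ACG")
  expect_setequal(generate_within("A", 1), c("A", "C", "G", "T", "N"))
  set.seed(31)
  for (i in 1:8) {
    m <- sample(2:10, 1)
    k <- sample(0:3, 1)
    u <- random_umis(1, m, alphabet = c("A", "C", "G", "T"))
    ball <- generate_within(u, k, c("A", "C", "G", "T"))
    closed_form <- sum(choose(m, 0:k) * 3^(0:k))
    expect_length(ball, closed_form)
    expect_equal(anyDuplicated(ball), 0L)
    expect_true(all(vapply(ball, char_hamming, integer(1), a = u) <= k))
  }
})

test_that("n-gram filter is complete: pairs within k share a gram key", {
  # exhaustive over a 2-letter alphabet at small M
  for (k in 1:2) {
    m <- 6
    space <- do.call(paste0, expand.grid(rep(list(c("A", "C")), m)))
    keyset <- function(u) {
      sp <- split_ngrams(u, k)
      paste(sp$slot, sp$gram)
    }
    keys <- lapply(space, keyset)
    for (i in seq_along(space)) {
      d <- vapply(space, char_hamming, integer(1), a = space[i],
                  USE.NAMES = FALSE)
      near <- which(d <= k)
      shares <- vapply(near, function(j)
        length(intersect(keys[[i]], keys[[j]])) > 0, logical(1))
      expect_true(all(shares))
    }
  }
})

test_that("subsequence keys are sound and complete: shared key iff d <= k", {
  for (k in 1:2) {
    m <- 5
    space <- do.call(paste0, expand.grid(rep(list(c("A", "G")), m)))
    keys <- lapply(space, mask_subsequences, k = k)
    for (i in seq_along(space)) {
      d <- vapply(space, char_hamming, integer(1), a = space[i],
                  USE.NAMES = FALSE)
      shares <- vapply(seq_along(space), function(j)
        length(intersect(keys[[i]], keys[[j]])) > 0, logical(1))
      expect_equal(shares, d <= k)
    }
  }
})

test_that("hash backend bin statistics have the expected shape", {
  sim <- simulate_umi_dataset(300, 10, 1, seed = 33)
  st_ng <- umi_index_stats(sim$table, k = 1, backend = "ngram")
  # 2 slots x at most 5^5 grams; far from saturated at this size
  expect_lte(st_ng$n_bins, 2 * 5^5)
  expect_equal(st_ng$avg_bin_size * st_ng$n_bins, 2 * nrow(sim$table))
  st_ss <- umi_index_stats(sim$table, k = 1, backend = "subseq")
  expect_equal(st_ss$avg_bin_size * st_ss$n_bins, 10 * nrow(sim$table))
})
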