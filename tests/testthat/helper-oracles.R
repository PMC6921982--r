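# Independent oracles used across the suite.  These deliberately avoid the
# package's encoded/indexed code paths: distances are per-character, and
# remove_near is replayed against a plain data frame.

char_hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_umis <- function(n, m, alphabet = c("A", "C", "G", "T", "N")) {
  vapply(seq_len(n),
         function(i) paste(sample(alphabet, m, replace = TRUE),
                           collapse = ""),
         character(1))
}

# stateful brute-force reference for the remove_near/contains contract
oracle_index <- function(table, k) {
  env <- new.env(parent = emptyenv())
  env$umi <- table$umi
  env$count <- table$count
  env$alive <- rep(TRUE, nrow(table))
  env$k <- k
  env
}

oracle_remove_near <- function(ora, u, f_max = Inf) {
  stopifnot(u %in% ora$umi)
  d <- vapply(ora$umi, char_hamming, integer(1), a = u, USE.NAMES = FALSE)
  hit <- ora$alive & d <= ora$k & ora$count <= f_max
  hit[match(u, ora$umi)] <- ora$alive[match(u, ora$umi)] # u always included
  ora$alive[hit] <- FALSE
  sort(ora$umi[hit])
}

# canonical signature of a grouping: sorted members per group, sorted groups
grouping_signature <- function(g) {
  parts <- tapply(g$umi, g$group, function(u) paste(sort(u), collapse = ","))
  paste(sort(unname(parts)), collapse = ";")
}

# small simulated table without going through the simulator's frequency
# scheme (generic random table with duplicates possible among neighbors)
sim_table <- function(C, M, k = 1, seed = 1) {
  simulate_umi_dataset(C, M, k, seed = seed)$table
}
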