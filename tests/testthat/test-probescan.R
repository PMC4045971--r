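make_fixture <- function(n_probes = 12, n_tx = 20, probe_len = 25,
                         tx_len = 300, plant_frac = 0.5, seed = 101) {
  set.seed(seed)
  probes <- probe_set(sprintf("p%02d", seq_len(n_probes)),
                      vapply(rep(probe_len, n_probes), rand_dna, ""),
                      rep(list(character()), n_probes))
  txs <- vapply(rep(tx_len, n_tx), rand_dna, "")
  # plant shared substrings of varied length so hits actually occur
  for (i in seq_len(floor(n_probes * plant_frac))) {
    len <- sample(11:probe_len, 1)
    ps <- sample(probe_len - len + 1, 1)
    j <- sample(n_tx, 1)
    ts <- sample(tx_len - len + 1, 1)
    substr(txs[j], ts, ts + len - 1) <-
      substr(probes$sequence[i], ps, ps + len - 1)
  }
  transcripts <- transcript_set(sprintf("t%02d", seq_len(n_tx)), txs)
  list(probes = probes, transcripts = transcripts)
}

test_that("a planted probe is found verbatim at its coordinates", {
  set.seed(3)
  probe <- rand_dna(24)
  tx <- paste0(rand_dna(100), probe, rand_dna(80))
  tr <- transcript_set("t1", tx, "rRNA_target")
  pr <- probe_set("p1", probe, "t1")
  h <- scan_probes(pr, tr)
  full <- h[h$length == 24, ]
  expect_equal(nrow(full), 1)
  expect_equal(full$transcript_start, 100)
  expect_equal(full$probe_start, 0)
  expect_true(full$is_target)
  expect_equal(full$tm, melting_temperature(probe))
})

test_that("probes sharing no k-mer with any transcript yield no hits", {
  pr <- probe_set("p1", strrep("AC", 13), "t1")
  tr <- transcript_set("t1", strrep("GT", 100), "rRNA_target")
  expect_warning(h <- scan_probes(pr, tr), "full-length")
  expect_equal(nrow(h), 0)
})

test_that("a shared substring of exactly 10 nt is below the threshold", {
  set.seed(5)
  pp <- plant_pair(10)
  pr <- probe_set("p1", pp$probe, character())
  tr <- transcript_set("t1", pp$transcript)
  h <- suppressWarnings(scan_probes(pr, tr))
  expect_equal(nrow(h), 0)
  # one base more and the match is reported
  pp11 <- plant_pair(11)
  h11 <- suppressWarnings(scan_probes(probe_set("p1", pp11$probe,
                                                character()),
                                      transcript_set("t1", pp11$transcript)))
  expect_equal(nrow(h11), 1)
  expect_equal(h11$length, 11)
})

test_that("scan agrees with the quadratic DP oracle on random fixtures", {
  fx <- make_fixture(seed = 211)
  h <- suppressWarnings(scan_probes(fx$probes, fx$transcripts))
  oracle <- list()
  for (i in seq_len(nrow(fx$probes))) for (j in seq_len(nrow(fx$transcripts))) {
    m <- oracle_matches(fx$probes$sequence[i], fx$transcripts$sequence[j], 11)
    if (nrow(m)) {
      m$probe_id <- fx$probes$id[i]
      m$transcript_id <- fx$transcripts$id[j]
      oracle[[length(oracle) + 1L]] <- m
    }
  }
  oracle <- do.call(rbind, oracle)
  oracle <- oracle[order(oracle$probe_id, oracle$transcript_id,
                         oracle$transcript_start, oracle$probe_start), ]
  expect_gt(nrow(oracle), 0)
  got <- as.data.frame(h)[, c("probe_start", "transcript_start", "length",
                              "probe_id", "transcript_id")]
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got, oracle[, names(got)])
})

test_that("no reported hit can be extended by one base on either side", {
  fx <- make_fixture(seed = 212)
  h <- suppressWarnings(scan_probes(fx$probes, fx$transcripts))
  expect_gt(nrow(h), 0)
  for (r in seq_len(nrow(h))) {
    p <- fx$probes$sequence[fx$probes$id == h$probe_id[r]]
    t <- fx$transcripts$sequence[fx$transcripts$id == h$transcript_id[r]]
    ps <- h$probe_start[r]; ts <- h$transcript_start[r]; len <- h$length[r]
    expect_identical(substr(p, ps + 1, ps + len),
                     substr(t, ts + 1, ts + len))
    if (ps > 0 && ts > 0)
      expect_false(substr(p, ps, ps) == substr(t, ts, ts))
    if (ps + len < nchar(p) && ts + len < nchar(t))
      expect_false(substr(p, ps + len + 1, ps + len + 1) ==
                     substr(t, ts + len + 1, ts + len + 1))
  }
})

test_that("scan output is invariant under input reordering", {
  fx <- make_fixture(seed = 213)
  h1 <- suppressWarnings(scan_probes(fx$probes, fx$transcripts))
  set.seed(1)
  p2 <- fx$probes[sample(nrow(fx$probes)), ]
  t2 <- fx$transcripts[sample(nrow(fx$transcripts)), ]
  class(p2) <- class(fx$probes); class(t2) <- class(fx$transcripts)
  h2 <- suppressWarnings(scan_probes(p2, t2))
  attr(h1, "unmatched_probes") <- attr(h2, "unmatched_probes") <- NULL
  rownames(h1) <- rownames(h2) <- NULL
  expect_equal(h1, h2)
})

test_that("off-target summary matches a brute-force group-by", {
  set.seed(31)
  target <- rand_dna(400)
  p1 <- substr(target, 51, 75)    # full-length target match
  p2 <- substr(target, 201, 226)
  off_tx <- paste0(rand_dna(50), substr(p1, 3, 16), rand_dna(50),
                   substr(p2, 5, 17), rand_dna(50))
  tr <- transcript_set(c("rna", "offA"), c(target, off_tx),
                       c("rRNA_target", "mRNA"))
  pr <- probe_set(c("p1", "p2"), c(p1, p2), "rna")
  h <- scan_probes(pr, tr)
  s <- summarize_offtargets(h, pr)
  for (pid in pr$id) {
    hp <- h[h$probe_id == pid, ]
    off <- hp[!hp$is_target, ]
    expect_equal(s$best_offtarget_tm[s$probe_id == pid],
                 if (nrow(off)) max(off$tm) else NA_real_)
    expect_equal(s$target_tm[s$probe_id == pid],
                 max(hp$tm[hp$is_target &
                             hp$length == nchar(pr$sequence[pr$id == pid])]))
  }
  expect_false(any(s$failed))
  # a probe with no off-target hits carries NA, never 0
  clean <- probe_set("p3", substr(target, 301, 325), "rna")
  s3 <- summarize_offtargets(scan_probes(clean, tr), clean)
  expect_true(is.na(s3$best_offtarget_tm))
})

test_that("hybridization temperature recommendation brackets the panel", {
  s <- data.frame(probe_id = c("a", "b"), probe_length = 25,
                  target_tm = c(70, 70), best_offtarget_tm = c(30, NA),
                  n_offtarget = c(1L, 0L), failed = FALSE)
  rec <- recommend_hybridization_temperature(s, margin = 5)
  expect_true(rec$feasible)
  expect_equal(unname(rec$window), c(35, 65))
  expect_equal(rec$recommended, 50)
  # infeasible: off-target as hot as the target
  s2 <- transform(s, best_offtarget_tm = c(70, 68))
  rec2 <- recommend_hybridization_temperature(s2, margin = 5)
  expect_false(rec2$feasible)
  expect_true(all(c("a", "b") %in% rec2$offending))
  # a well-separated panel leaves 48 C inside the window
  s3 <- data.frame(probe_id = sprintf("p%d", 1:6), probe_length = 25,
                   target_tm = c(62, 65, 70, 58, 60, 66),
                   best_offtarget_tm = c(35, 40, NA, 30, 42, 38),
                   n_offtarget = 1L, failed = FALSE)
  rec3 <- recommend_hybridization_temperature(s3, margin = 3)
  expect_true(rec3$feasible)
  expect_gt(48, rec3$window[1])
  expect_lt(48, rec3$window[2])
})

test_that("duplicate probe ids and failed probes are surfaced", {
  expect_error(probe_set(c("p1", "p1"), c(strrep("A", 25), strrep("C", 25)),
                         character()), "duplicate")
  set.seed(77)
  tr <- transcript_set("t1", rand_dna(200), "rRNA_target")
  pr <- probe_set("p1", rand_dna(25), "t1")
  expect_warning(scan_probes(pr, tr), "full-length")
})
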