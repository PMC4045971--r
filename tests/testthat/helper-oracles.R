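# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the match oracle is a quadratic dynamic program
# over the full probe x transcript equality matrix (no k-mer seeding), the
# survival oracle enumerates every insert, and the duplicate expectation is
# the closed-form birthday formula.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# all maximal exact shared substrings of length >= k, by quadratic DP:
# M[i, j] = length of the common suffix of probe[1..i] and transcript[1..j]
oracle_matches <- function(pseq, tseq, k) {
  p <- strsplit(pseq, "")[[1]]
  t <- strsplit(tseq, "")[[1]]
  np <- length(p); nt <- length(t)
  acgt <- c("A", "C", "G", "T")
  eq <- outer(p, t, "==") & (p %in% acgt) & rep(t %in% acgt, each = np)
  M <- matrix(0L, np, nt)
  M[1, ] <- as.integer(eq[1, ])
  if (np > 1) for (i in 2:np)
    M[i, ] <- as.integer(eq[i, ]) * (c(0L, M[i - 1, -nt]) + 1L)
  cand <- which(M >= k, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(probe_start = integer(), transcript_start = integer(),
                      length = integer()))
  i <- cand[, 1]; j <- cand[, 2]
  ext <- i < np & j < nt
  ext[ext] <- eq[cbind(i[ext] + 1L, j[ext] + 1L)]
  i <- i[!ext]; j <- j[!ext]
  len <- M[cbind(i, j)]
  out <- unique(data.frame(probe_start = i - len,
                           transcript_start = j - len, length = len))
  out[order(out$transcript_start, out$probe_start), , drop = FALSE]
}

# expected survival by enumerating every insert at every 5' position
oracle_survival <- function(target_len, fps, lmin, lmax, d = 10, p_cut = 1) {
  num <- den <- numeric(target_len)
  for (s in 0:(target_len - 1)) for (L in lmin:lmax) {
    if (s + L > target_len) next
    cleav <- FALSE
    if (nrow(fps)) {
      ov <- pmin(s + L, fps$end) - pmax(s, fps$start)
      cleav <- any(ov >= d)
    }
    num[s + 1] <- num[s + 1] + if (cleav) 1 - p_cut else 1
    den[s + 1] <- den[s + 1] + 1
  }
  ifelse(den > 0, num / den, NA_real_)
}

# closed-form expected number of exact 5' duplicates when n reads are
# placed uniformly at random on P positions
birthday_expected_dup <- function(n, P) n - P * (1 - (1 - 1 / P)^n)

# probe/transcript pair sharing exactly one planted substring of length len
# along one diagonal; flanking bases are forced to mismatch and shared
# 11-mer sets are checked so no incidental long match can occur
plant_pair <- function(len, probe_len = NULL, tx_len = 300, at = 120) {
  if (is.null(probe_len)) probe_len <- max(30, len + 12)
  repeat {
    p <- strsplit(rand_dna(probe_len), "")[[1]]
    t <- strsplit(rand_dna(tx_len), "")[[1]]
    from <- 6  # plant an interior probe segment so both flanks exist
    t[at:(at + len - 1)] <- p[from:(from + len - 1)]
    t[at - 1] <- setdiff(c("A", "C", "G", "T"), p[from - 1])[1]
    t[at + len] <- setdiff(c("A", "C", "G", "T"), p[from + len])[1]
    pseq <- paste(p, collapse = ""); tseq <- paste(t, collapse = "")
    km <- function(s) {
      n <- nchar(s)
      if (n < 11) character() else substring(s, 1:(n - 10), 11:n)
    }
    shared <- intersect(km(pseq), km(tseq))
    planted <- if (len >= 11)
      substring(pseq, from:(from + len - 11), (from + 10):(from + len - 1))
    else character()
    if (setequal(shared, planted))
      return(list(probe = pseq, transcript = tseq,
                  probe_start0 = from - 1, transcript_start0 = at - 1))
  }
}
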