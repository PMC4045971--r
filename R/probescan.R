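#' Construct a depletion probe set
#'
#' A probe is an unmodified DNA oligonucleotide written as the sense strand
#' of its intended target RNA; it hybridizes to the antisense first-strand
#' cDNA. Probes of 22 nt or shorter are flagged (`short = TRUE`) because
#' short probes risk failing to deplete; designing probes longer than 22 nt
#' is recommended.
#'
#' @param id Character vector of unique probe ids.
#' @param sequence Character vector of probe sequences (A/C/G/T).
#' @param intended_targets List of character vectors (or a single character
#'   vector recycled) naming the transcript ids each probe is designed
#'   against.
#' @return A data.frame of class `pdd_probes` with columns `id`, `sequence`,
#'   `intended_targets` (list column) and `short`.
#' @export
probe_set <- function(id, sequence, intended_targets) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate probe ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != length(id)) stop("id and sequence lengths differ")
  if (!all(grepl("^[ACGT]+$", sequence)))
    stop("probe sequences must contain only A/C/G/T")
  if (!is.list(intended_targets))
    intended_targets <- rep(list(as.character(intended_targets)), length(id))
  stopifnot(length(intended_targets) == length(id))
  short <- nchar(sequence) <= 22
  if (any(short))
    warning(sum(short), " probe(s) of length <= 22 nt (",
            paste(id[short], collapse = ", "),
            "); probes longer than 22 nt are recommended")
  out <- data.frame(id = id, sequence = sequence, short = short,
                    stringsAsFactors = FALSE)
  out$intended_targets <- lapply(intended_targets, as.character)
  class(out) <- c("pdd_probes", "data.frame")
  out
}

#' Construct a transcript set with categories
#'
#' Transcripts are sense-strand sequences with a category used for
#' normalization and reporting: the depletion target class (`rRNA_target`),
#' other non-coding RNA, or mRNA. `abundance_weight` is only used by the
#' library simulator.
#'
#' @param id Unique transcript ids.
#' @param sequence DNA sequences (non-empty).
#' @param category One of `"rRNA_target"`, `"other_ncRNA"`, `"mRNA"`
#'   (recycled).
#' @param abundance_weight Non-negative sampling weights (recycled,
#'   default 1).
#' @return A data.frame of class `pdd_transcripts` with columns `id`,
#'   `sequence`, `category`, `abundance_weight`, `length`.
#' @export
transcript_set <- function(id, sequence,
                           category = "mRNA",
                           abundance_weight = 1) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate transcript ids")
  sequence <- toupper(as.character(sequence))
  if (any(nchar(sequence) == 0)) stop("empty transcript sequence")
  category <- rep_len(as.character(category), length(id))
  ok <- category %in% c("rRNA_target", "other_ncRNA", "mRNA")
  if (!all(ok)) stop("unknown category: ", paste(unique(category[!ok]), collapse = ", "))
  abundance_weight <- rep_len(as.numeric(abundance_weight), length(id))
  if (any(abundance_weight < 0)) stop("abundance_weight must be >= 0")
  out <- data.frame(id = id, sequence = sequence, category = category,
                    abundance_weight = abundance_weight,
                    length = nchar(sequence), stringsAsFactors = FALSE)
  class(out) <- c("pdd_transcripts", "data.frame")
  out
}

#' Scanner configuration
#'
#' @param min_match_len Minimum length of a reported exact match, default 11
#'   (i.e. matches longer than 10 nt are reported; a shared substring of
#'   exactly 10 nt is not a hit).
#' @param both_strands Also scan the reverse complement of each probe
#'   (exploratory; default `FALSE` because probes are sense-strand and only
#'   sense-orientation matches threaten the antisense cDNA).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(min_match_len = 11L, both_strands = FALSE) {
  min_match_len <- as.integer(min_match_len)
  stopifnot(min_match_len >= 2L, is.logical(both_strands))
  structure(list(min_match_len = min_match_len, both_strands = both_strands),
            class = "scan_config")
}

# k-mer index of transcript sequences: data.table(kmer, tid, tpos0).
# Ambiguous bases never occur in a key, so they can never seed a match.
.transcript_kmer_index <- function(transcripts, k) {
  pieces <- lapply(seq_len(nrow(transcripts)), function(i) {
    s <- transcripts$sequence[i]
    n <- nchar(s)
    if (n < k) return(NULL)
    pos <- seq_len(n - k + 1L)
    data.table::data.table(kmer = substring(s, pos, pos + k - 1L),
                           tid = transcripts$id[i], tpos0 = pos - 1L)
  })
  idx <- data.table::rbindlist(pieces)
  if (nrow(idx)) idx <- idx[!grepl("[^ACGT]", idx$kmer)]
  data.table::setkey(idx, kmer)
  idx
}

# maximal exact matches between one probe and one transcript along one
# diagonal (offset = tpos0 - ppos0), as runs of base equality >= k
.diagonal_matches <- function(pchars, tchars, offset, k) {
  np <- length(pchars); nt <- length(tchars)
  i_lo <- max(1L, 1L - offset); i_hi <- min(np, nt - offset)
  if (i_hi - i_lo + 1L < k) return(NULL)
  i <- i_lo:i_hi
  pc <- pchars[i]; tc <- tchars[i + offset]
  eq <- pc == tc & pc %in% c("A", "C", "G", "T")
  r <- rle(eq)
  len <- r$lengths
  ends <- cumsum(len)
  keep <- r$values & len >= k
  if (!any(keep)) return(NULL)
  starts <- ends - len + 1L
  data.frame(probe_start = i_lo + starts[keep] - 2L,      # 0-based
             length = len[keep])
}

#' Scan probes for exact matches across a transcriptome
#'
#' Finds every maximal same-orientation exact shared substring of length
#' >= `config$min_match_len` between any probe and any transcript, using a
#' k-mer seed index with bidirectional extension. Each hit is annotated with
#' the melting temperature of the matched segment (not the full probe) under
#' the given conditions and classified as target (`is_target`) when the
#' transcript is among the probe's intended targets. Hits are sorted by
#' probe id, transcript id, then transcript position. Probes that lack a
#' full-length exact match to at least one intended target cannot act as
#' designed; they are reported via a warning and in the
#' `"unmatched_probes"` attribute.
#'
#' @param probes A [probe_set()].
#' @param transcripts A [transcript_set()].
#' @param config A [scan_config()].
#' @param conditions A [hybridization_conditions()].
#' @param table An [nn_table()].
#' @return A data.frame of class `pdd_hits` with columns `probe_id`,
#'   `transcript_id`, `probe_start`, `transcript_start` (0-based), `length`,
#'   `strand`, `segment`, `tm`, `is_target`.
#' @export
scan_probes <- function(probes, transcripts, config = scan_config(),
                        conditions = hybridization_conditions(),
                        table = nn_table()) {
  stopifnot(nrow(probes) > 0, nrow(transcripts) > 0)
  idx <- .transcript_kmer_index(transcripts, config$min_match_len)
  hits <- .scan_with_index(probes, transcripts, idx, config, conditions, table)
  full <- hits[hits$is_target & hits$length == nchar(probes$sequence[
    match(hits$probe_id, probes$id)]) & hits$strand == "+", , drop = FALSE]
  unmatched <- setdiff(probes$id, unique(full$probe_id))
  if (length(unmatched))
    warning("probe(s) without a full-length match to any intended target: ",
            paste(unmatched, collapse = ", "))
  attr(hits, "unmatched_probes") <- unmatched
  class(hits) <- c("pdd_hits", "data.frame")
  hits
}

.scan_with_index <- function(probes, transcripts, idx, config,
                             conditions, table) {
  k <- config$min_match_len
  tchars <- lapply(transcripts$sequence, function(s) strsplit(s, "")[[1]])
  names(tchars) <- transcripts$id
  target_map <- probes$intended_targets
  names(target_map) <- probes$id

  scan_one_orientation <- function(pseqs, strand) {
    res <- list()
    for (j in seq_along(pseqs)) {
      ps <- pseqs[j]
      np <- nchar(ps)
      if (np < k) next
      pos <- seq_len(np - k + 1L)
      pk <- data.table::data.table(kmer = substring(ps, pos, pos + k - 1L),
                                   ppos0 = pos - 1L)
      pk <- pk[!grepl("[^ACGT]", pk$kmer)]
      if (!nrow(pk)) next
      cand <- idx[pk, on = "kmer", nomatch = NULL]
      if (!nrow(cand)) next
      cand[, "offset" := cand$tpos0 - cand$ppos0]
      cand <- unique(cand[, c("tid", "offset")])
      pchars <- strsplit(ps, "")[[1]]
      for (r in seq_len(nrow(cand))) {
        tid <- cand$tid[r]
        m <- .diagonal_matches(pchars, tchars[[tid]], cand$offset[r], k)
        if (is.null(m)) next
        m$probe_id <- probes$id[j]
        m$transcript_id <- tid
        m$transcript_start <- m$probe_start + cand$offset[r]
        m$strand <- strand
        m$segment <- substring(ps, m$probe_start + 1L,
                               m$probe_start + m$length)
        res[[length(res) + 1L]] <- m
      }
    }
    res
  }

  res <- scan_one_orientation(probes$sequence, "+")
  if (isTRUE(config$both_strands))
    res <- c(res, scan_one_orientation(reverse_complement(probes$sequence), "-"))

  if (!length(res)) {
    hits <- data.frame(probe_id = character(), transcript_id = character(),
                       probe_start = integer(), transcript_start = integer(),
                       length = integer(), strand = character(),
                       segment = character(), tm = numeric(),
                       is_target = logical(), stringsAsFactors = FALSE)
    return(hits)
  }
  hits <- do.call(rbind, res)
  hits$tm <- melting_temperature(hits$segment, conditions, table)
  hits$is_target <- mapply(function(p, t) t %in% target_map[[p]],
                           hits$probe_id, hits$transcript_id,
                           USE.NAMES = FALSE)
  hits <- hits[order(hits$probe_id, hits$transcript_id,
                     hits$transcript_start, hits$probe_start),
               c("probe_id", "transcript_id", "probe_start",
                 "transcript_start", "length", "strand", "segment", "tm",
                 "is_target")]
  rownames(hits) <- NULL
  hits
}

#' Per-probe target and off-target Tm summary
#'
#' Summarizes a hit set into one row per probe: the Tm of its full-length
#' intended-target match (`target_tm`; the maximum if matched at several
#' sites), the best (highest) off-target Tm (`best_offtarget_tm`, `NA` when
#' the probe has no off-target hit — never 0), the number of off-target
#' hits, and a `failed` flag for probes lacking any full-length target
#' match.
#'
#' @param hits Result of [scan_probes()].
#' @param probes The [probe_set()] that produced the hits.
#' @return A data.frame of class `pdd_probe_summary`.
#' @export
summarize_offtargets <- function(hits, probes) {
  out <- data.frame(probe_id = probes$id,
                    probe_length = nchar(probes$sequence),
                    target_tm = NA_real_,
                    best_offtarget_tm = NA_real_,
                    n_offtarget = 0L,
                    failed = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    h <- hits[hits$probe_id == out$probe_id[i], , drop = FALSE]
    full <- h[h$is_target & h$length == out$probe_length[i] &
                h$strand == "+", , drop = FALSE]
    if (nrow(full)) out$target_tm[i] <- max(full$tm)
    off <- h[!h$is_target, , drop = FALSE]
    out$n_offtarget[i] <- nrow(off)
    if (nrow(off)) out$best_offtarget_tm[i] <- max(off$tm)
  }
  out$failed <- is.na(out$target_tm)
  class(out) <- c("pdd_probe_summary", "data.frame")
  out
}

#' Recommend a hybridization temperature for a probe panel
#'
#' The usable window is bounded below by the highest off-target Tm plus a
#' safety margin (hybridizing above it keeps off-target duplexes unstable)
#' and above by the lowest intended-target Tm minus the margin (so every
#' probe still binds its target). The recommended temperature is the window
#' midpoint; when no probe has any off-target the window is open below and
#' the recommendation is the upper bound minus the margin.
#'
#' @param summary Result of [summarize_offtargets()]. All probes must have a
#'   `target_tm` (no `failed` rows).
#' @param margin Safety margin in degrees C (default 3).
#' @return A list with elements `feasible`, `window` (low, high),
#'   `recommended`, and `offending` (probe ids whose off-target Tm makes the
#'   window infeasible; empty when feasible).
#' @export
recommend_hybridization_temperature <- function(summary, margin = 3) {
  stopifnot(nrow(summary) > 0)
  if (any(summary$failed))
    stop("probes without a target Tm: ",
         paste(summary$probe_id[summary$failed], collapse = ", "))
  high <- min(summary$target_tm) - margin
  off <- summary$best_offtarget_tm
  low <- if (all(is.na(off))) -Inf else max(off, na.rm = TRUE) + margin
  feasible <- low < high
  offending <- character()
  if (!feasible)
    offending <- summary$probe_id[!is.na(off) & off + margin >= high]
  recommended <- if (!feasible) NA_real_
    else if (is.finite(low)) (low + high) / 2 else high - margin
  list(feasible = feasible, window = c(low = low, high = high),
       recommended = recommended, offending = offending)
}
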