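#' DSN cleavage model
#'
#' Duplex-specific nuclease (DSN) requires at least ten perfectly
#' complementary base pairs to cut, so an adapter-flanked single-stranded
#' cDNA insert is cleavable iff it overlaps a probe footprint by at least
#' `min_duplex` nucleotides. A single cut anywhere in a circularized library
#' molecule prevents its amplification, so cleavage geometry reduces to
#' interval overlap on the target. `p_cut` is the per-molecule probability
#' that a cleavable insert is actually cut (1 = ideal enzyme; the handle for
#' sub-complete wet-lab efficiency).
#'
#' @param min_duplex Minimum perfectly matched duplex length for cleavage,
#'   in nt (default 10).
#' @param p_cut Probability in (0, 1] that a cleavable insert is cut
#'   (default 1).
#' @return An object of class `cleavage_model`.
#' @export
cleavage_model <- function(min_duplex = 10L, p_cut = 1.0) {
  min_duplex <- as.integer(min_duplex)
  stopifnot(min_duplex >= 1L, p_cut > 0, p_cut <= 1)
  structure(list(min_duplex = min_duplex, p_cut = p_cut),
            class = "cleavage_model")
}

#' Probe spacing rule
#'
#' For continuous depletion from intact total RNA, adjacent probe footprints
#' should be spaced at most the minimum anticipated library insert size
#' minus `offset` nucleotides apart. The published recommendation fixes
#' `offset` at 20 nt.
#'
#' @param offset Spacing offset in nt (default and recommended value 20).
#' @return An object of class `spacing_rule`.
#' @export
spacing_rule <- function(offset = 20L) {
  offset <- as.integer(offset)
  stopifnot(offset >= 0L)
  if (offset != 20L)
    warning("spacing offset overridden to ", offset,
            " nt; the published recommendation is 20 nt")
  structure(list(offset = offset), class = "spacing_rule")
}

#' Inclusive insert-size range
#'
#' @param min_len,max_len Inclusive bounds in nt, `0 < min_len <= max_len`.
#'   The default 25-200 nt mirrors a typical gel size selection of
#'   ~170-350 bp library molecules.
#' @return An object of class `insert_size_range`.
#' @export
insert_size_range <- function(min_len = 25L, max_len = 200L) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  stopifnot(min_len > 0L, min_len <= max_len)
  structure(list(min_len = min_len, max_len = max_len),
            class = "insert_size_range")
}

#' Probe footprints on their targets
#'
#' A footprint is the interval on an intended target covered by a
#' full-length exact probe match; only full-length matches count (a probe
#' that matches its target partially is a design error, not a footprint).
#'
#' @param hits Result of [scan_probes()].
#' @param probes The corresponding [probe_set()].
#' @return A data.frame of class `pdd_footprints` with columns `probe_id`,
#'   `target_id`, `start`, `end` (0-based half-open).
#' @export
probe_footprints <- function(hits, probes) {
  plen <- nchar(probes$sequence)[match(hits$probe_id, probes$id)]
  full <- hits[hits$is_target & hits$strand == "+" & hits$length == plen, ,
               drop = FALSE]
  out <- data.frame(probe_id = full$probe_id,
                    target_id = full$transcript_id,
                    start = full$transcript_start,
                    end = full$transcript_start + full$length,
                    stringsAsFactors = FALSE)
  out <- out[order(out$target_id, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("pdd_footprints", "data.frame")
  out
}

#' Manually specified footprints
#'
#' @param probe_id,target_id Character vectors.
#' @param start,end 0-based half-open interval on the target.
#' @return A `pdd_footprints` data.frame.
#' @export
footprints <- function(probe_id, target_id, start, end) {
  stopifnot(all(end > start), all(start >= 0))
  out <- data.frame(probe_id = as.character(probe_id),
                    target_id = as.character(target_id),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  class(out) <- c("pdd_footprints", "data.frame")
  out
}

#' Can an insert be cleaved?
#'
#' An insert with 5' end `five_prime` and length `insert_len` (interval
#' `[five_prime, five_prime + insert_len)` on the target) is cleavable iff
#' it overlaps at least one footprint by `model$min_duplex` or more
#' nucleotides. This is the deterministic capability test; probabilistic
#' cutting is applied in [apply_pdd()].
#'
#' @param five_prime Integer vector of 0-based 5' positions.
#' @param insert_len Integer vector of insert lengths (recycled).
#' @param fps Footprints on the same target (data.frame with `start`,
#'   `end`).
#' @param model A [cleavage_model()].
#' @return Logical vector.
#' @export
is_cleavable <- function(five_prime, insert_len, fps,
                         model = cleavage_model()) {
  if (any(insert_len < 0) || any(five_prime < 0))
    stop("negative insert length or 5' position")
  n <- max(length(five_prime), length(insert_len))
  five_prime <- rep_len(five_prime, n)
  insert_len <- rep_len(insert_len, n)
  out <- rep(FALSE, n)
  for (i in seq_len(nrow(fps))) {
    ov <- pmin(five_prime + insert_len, fps$end[i]) -
      pmax(five_prime, fps$start[i])
    out <- out | ov >= model$min_duplex
  }
  out
}

#' Expected per-position survival of read 5' ends
#'
#' For every 5' position on a target, the expected fraction of inserts
#' (lengths drawn from `size_range`, uniformly unless `length_weights` is
#' given) that escape PDD: non-cleavable inserts survive with probability 1
#' and cleavable ones with probability `1 - p_cut`. With an ideal enzyme
#' (`p_cut = 1`) the zero-survival positions are the predicted depletion
#' zone of the probe set, which widens with insert length; its right edge
#' sits `min_duplex - 1` nt upstream of each footprint's 3' end.
#'
#' @param target_len Target transcript length in nt.
#' @param fps Footprints on the target.
#' @param size_range An [insert_size_range()]; lengths exceeding
#'   `target_len` are truncated away with a warning.
#' @param model A [cleavage_model()].
#' @param length_weights Optional data.frame (`length`, `weight`) giving a
#'   non-uniform insert-length distribution within the range.
#' @return A data.frame with columns `position` (0-based) and `survival`
#'   in `[0, 1]` (`NA` at positions where no insert in the range fits).
#' @export
survival_profile <- function(target_len, fps, size_range,
                             model = cleavage_model(),
                             length_weights = NULL) {
  stopifnot(target_len >= 1)
  if (nrow(fps) && (any(fps$start < 0) || any(fps$end > target_len)))
    stop("footprints outside [0, target_len)")
  lens <- size_range$min_len:size_range$max_len
  if (size_range$max_len > target_len) {
    warning("insert lengths truncated at transcript end (max_len ",
            size_range$max_len, " > target length ", target_len, ")")
    lens <- lens[lens <= target_len]
    if (!length(lens)) stop("no insert length in range fits the target")
  }
  w <- rep(1, length(lens))
  if (!is.null(length_weights)) {
    w <- length_weights$weight[match(lens, length_weights$length)]
    w[is.na(w)] <- 0
    if (all(w == 0)) stop("length_weights assign zero weight to the range")
  }
  s <- 0:(target_len - 1L)
  num <- numeric(target_len)
  den <- numeric(target_len)
  for (j in seq_along(lens)) {
    L <- lens[j]
    valid <- s + L <= target_len
    if (!any(valid)) next
    cleav <- if (nrow(fps)) is_cleavable(s, L, fps, model) else
      rep(FALSE, target_len)
    surv <- ifelse(cleav, 1 - model$p_cut, 1)
    num <- num + w[j] * surv * valid
    den <- den + w[j] * valid
  }
  data.frame(position = s,
             survival = ifelse(den > 0, num / den, NA_real_))
}

#' Maximum recommended inter-probe gap
#'
#' The published spacing rule: probes spaced at most the minimum
#' anticipated library insert size minus the rule offset (20 nt) achieve
#' continuous depletion, because every insert of at least the minimum size
#' then overlaps some probe by at least the cleavable duplex length.
#'
#' @param min_insert Minimum anticipated insert size, nt.
#' @param rule A [spacing_rule()].
#' @return Maximum allowed footprint-edge-to-edge gap, nt.
#' @export
max_recommended_gap <- function(min_insert, rule = spacing_rule()) {
  if (min_insert <= rule$offset)
    stop("minimum insert size (", min_insert, ") must exceed the spacing ",
         "offset (", rule$offset, "): the rule max gap = min insert - ",
         rule$offset, " would not be positive")
  as.integer(min_insert - rule$offset)
}

# merge overlapping/adjacent-overlap footprints into disjoint intervals
.merge_footprints <- function(fps) {
  fps <- fps[order(fps$start, fps$end), , drop = FALSE]
  if (nrow(fps) < 2) return(fps)
  out <- fps[1, , drop = FALSE]
  merged <- FALSE
  for (i in 2:nrow(fps)) {
    j <- nrow(out)
    if (fps$start[i] < out$end[j]) {
      out$end[j] <- max(out$end[j], fps$end[i])
      out$probe_id[j] <- paste(out$probe_id[j], fps$probe_id[i], sep = "+")
      merged <- TRUE
    } else out <- rbind(out, fps[i, ])
  }
  if (merged) warning("overlapping footprints collapsed")
  rownames(out) <- NULL
  out
}

# 5' positions (0-based) of inserts of length L that escape all footprints,
# restricted to s in [s_lo, s_hi]
.escaping_positions <- function(s_lo, s_hi, L, fps, model, target_len) {
  s <- seq.int(max(0L, s_lo), min(s_hi, target_len - L))
  if (!length(s) || s[1] > s[length(s)]) return(integer())
  s[!is_cleavable(s, L, fps, model)]
}

#' Validate probe spacing against a minimum insert size
#'
#' Checks every adjacent footprint gap on each target against the spacing
#' rule (gap <= min insert - 20 nt) and, independently, against the exact
#' cleavage model by enumerating inserts of the minimum size: an insert
#' escapes iff it overlaps no footprint by `min_duplex` nt, so the longest
#' escaping insert across a gap is `gap + 2 (min_duplex - 1)` nt. The rule
#' is 1 nt more conservative than this exact bound; gaps where the two
#' disagree are flagged rather than re-judged. Uncovered terminal regions
#' and probes of length <= 22 nt are reported too.
#'
#' @param fps Footprints (possibly on several targets).
#' @param target_len Named integer vector of target lengths (or a single
#'   length when all footprints share one target).
#' @param min_insert Minimum anticipated insert size, nt.
#' @param model A [cleavage_model()].
#' @param rule A [spacing_rule()].
#' @return A list of class `pdd_spacing_report`: `gaps` (per adjacent pair:
#'   distance, rule pass/fail, exact escape count, disagreement flag),
#'   `terminal` (uncovered end regions with escape counts), `short_probes`,
#'   `max_gap`, and `ok` (all gaps pass the rule).
#' @export
validate_spacing <- function(fps, target_len, min_insert,
                             model = cleavage_model(),
                             rule = spacing_rule()) {
  stopifnot(nrow(fps) > 0)
  maxgap <- max_recommended_gap(min_insert, rule)
  if (is.null(names(target_len)) && length(target_len) == 1)
    target_len <- structure(rep(target_len, length(unique(fps$target_id))),
                            names = unique(fps$target_id))
  short <- fps$probe_id[(fps$end - fps$start) <= 22]
  gaps <- list(); terms <- list()
  for (tid in unique(fps$target_id)) {
    tl <- target_len[[tid]]
    f <- .merge_footprints(fps[fps$target_id == tid, , drop = FALSE])
    n <- nrow(f)
    if (n >= 2) for (i in 1:(n - 1)) {
      gap <- f$start[i + 1] - f$end[i]
      esc <- .escaping_positions(f$end[i] - model$min_duplex + 1L,
                                 f$start[i + 1] + model$min_duplex - 1L,
                                 min_insert, f, model, tl)
      gaps[[length(gaps) + 1L]] <- data.frame(
        target_id = tid, left_probe = f$probe_id[i],
        right_probe = f$probe_id[i + 1], distance = gap,
        rule_pass = gap <= maxgap, n_escaping = length(esc),
        exact_pass = length(esc) == 0L,
        max_escaping_insert = gap + 2L * (model$min_duplex - 1L),
        stringsAsFactors = FALSE)
    }
    head_esc <- .escaping_positions(0L, f$start[1] + model$min_duplex - 1L,
                                    min_insert, f, model, tl)
    tail_esc <- .escaping_positions(f$end[n] - model$min_duplex + 1L,
                                    tl - min_insert, min_insert, f, model, tl)
    terms[[length(terms) + 1L]] <- data.frame(
      target_id = tid,
      head_uncovered = f$start[1], tail_uncovered = tl - f$end[n],
      head_escaping = length(head_esc), tail_escaping = length(tail_esc),
      stringsAsFactors = FALSE)
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(target_id = character(), left_probe = character(),
               right_probe = character(), distance = integer(),
               rule_pass = logical(), n_escaping = integer(),
               exact_pass = logical(), max_escaping_insert = integer())
  gaps$disagree <- gaps$rule_pass != gaps$exact_pass
  out <- list(gaps = gaps, terminal = do.call(rbind, terms),
              short_probes = unique(short), max_gap = maxgap,
              min_insert = as.integer(min_insert),
              ok = all(gaps$rule_pass))
  class(out) <- "pdd_spacing_report"
  out
}

#' @export
print.pdd_spacing_report <- function(x, ...) {
  cat("Probe spacing report: max recommended gap", x$max_gap,
      "nt (min insert", x$min_insert, "nt)\n")
  cat(sum(x$gaps$rule_pass), "of", nrow(x$gaps), "gaps pass the rule;",
      sum(!x$gaps$exact_pass), "allow escaping inserts (exact check)\n")
  if (length(x$short_probes))
    cat("probes of length <= 22 nt:", paste(x$short_probes, collapse = ", "),
        "\n")
  invisible(x)
}

#' Greedy probe-set design for a target transcript
#'
#' Tiles a target left to right: each successive probe window is placed as
#' far right as the spacing rule allows, and within a slack of a few nt the
#' window with the largest Tm differential (intended-target Tm minus best
#' off-target Tm against the rest of the transcriptome) is chosen. A window
#' is disqualified when its best off-target Tm comes within twice the
#' margin of its target Tm, because no hybridization temperature could then
#' separate the two. The returned set always passes [validate_spacing()]
#' with zero rule failures.
#'
#' @param target A single-row [transcript_set()] (the depletion target).
#' @param transcriptome A [transcript_set()] of potential off-target
#'   transcripts (the target itself is excluded from off-target scoring).
#' @param min_insert Minimum anticipated insert size, nt (> rule offset).
#' @param probe_len Probe length, nt (>= 23).
#' @param conditions,table Thermodynamic context, as in
#'   [melting_temperature()].
#' @param config A [scan_config()] for off-target scoring.
#' @param model,rule Cleavage model and spacing rule.
#' @param margin Safety margin in degrees C (default 3).
#' @param slack Placement slack in nt (default 5): candidate windows may sit
#'   up to `slack` nt left of the rightmost rule-compliant position.
#' @return A [probe_set()] whose probes tile the target.
#' @export
design_probe_set <- function(target, transcriptome, min_insert,
                             probe_len = 25L,
                             conditions = hybridization_conditions(),
                             table = nn_table(),
                             config = scan_config(),
                             model = cleavage_model(),
                             rule = spacing_rule(),
                             margin = 3, slack = 5L) {
  stopifnot(nrow(target) == 1)
  if (probe_len < 23)
    stop("probe_len must be >= 23 nt (probes of <= 22 nt risk failure)")
  tl <- nchar(target$sequence)
  if (tl < probe_len) stop("target (", tl, " nt) shorter than probe_len")
  maxgap <- max_recommended_gap(min_insert, rule)
  others <- transcriptome[transcriptome$id != target$id, , drop = FALSE]
  idx <- if (nrow(others)) .transcript_kmer_index(others, config$min_match_len)
         else NULL

  score_windows <- function(starts) {
    wins <- substring(target$sequence, starts + 1L, starts + probe_len)
    ttm <- melting_temperature(wins, conditions, table)
    off <- rep(-Inf, length(starts))
    if (!is.null(idx) && nrow(idx)) {
      cand <- probe_set(paste0("w", seq_along(starts)), wins,
                        rep(list(character()), length(starts)))
      h <- .scan_with_index(cand, others, idx, config, conditions, table)
      if (nrow(h)) {
        best <- tapply(h$tm, h$probe_id, max)
        m <- match(paste0("w", seq_along(starts)), names(best))
        off[!is.na(m)] <- best[m[!is.na(m)]]
      }
    }
    data.frame(start = starts, target_tm = ttm, off_tm = off,
               diff = ttm - off,
               ok = !(is.finite(off) & (off + margin >= ttm - margin)))
  }

  pick <- function(base) {
    starts <- seq.int(max(0L, base - slack), base)
    sc <- score_windows(starts)
    sc <- sc[sc$ok, , drop = FALSE]
    if (!nrow(sc))
      stop("no usable probe window in [", max(0L, base - slack), ", ",
           base + probe_len, "): every candidate has a disqualifying ",
           "off-target")
    # largest Tm differential; ties broken toward the rightmost window
    sc$start[order(-sc$diff, -sc$start)][1]
  }

  starts <- integer()
  s1 <- pick(min(slack, tl - probe_len))
  starts <- s1
  repeat {
    prev_end <- starts[length(starts)] + probe_len
    if (tl - prev_end <= maxgap) break
    base <- prev_end + maxgap
    if (base > tl - probe_len) base <- tl - probe_len
    s <- pick(base)
    if (s < prev_end) s <- prev_end  # never nest into the previous probe
    starts <- c(starts, s)
  }
  ids <- sprintf("%s_p%02d", target$id, seq_along(starts))
  probes <- probe_set(ids,
                      substring(target$sequence, starts + 1L,
                                starts + probe_len),
                      rep(list(target$id), length(starts)))
  fps <- footprints(ids, target$id, starts, starts + probe_len)
  rep_ <- validate_spacing(fps, structure(tl, names = target$id),
                           min_insert, model, rule)
  stopifnot(rep_$ok)
  probes
}
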