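#' Analysis configuration
#'
#' Defaults mirror the published processing constants: reads shorter than
#' 11 nt after trimming are discarded, 5' densities are smoothed with a
#' 9-nt centered moving average, probe-anchored pileups with a 7-nt window,
#' and inter-probe read counting extends 10 nt into each flanking probe.
#'
#' @param min_read_len Minimum retained read length after trimming, nt.
#' @param density_window Moving-average window for 5' densities, odd, nt.
#' @param pileup_window Moving-average window for probe pileups, odd, nt.
#' @param interprobe_extension Extension of inter-probe intervals into each
#'   probe footprint, nt.
#' @param untreated_floor Fraction of the untreated library's in-group read
#'   total below which the smoothed untreated density masks the ratio
#'   (default 1e-6).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(min_read_len = 11L, density_window = 9L,
                            pileup_window = 7L, interprobe_extension = 10L,
                            untreated_floor = 1e-6) {
  stopifnot(density_window >= 1, density_window %% 2 == 1,
            pileup_window >= 1, pileup_window %% 2 == 1,
            interprobe_extension >= 0, min_read_len >= 1)
  structure(list(min_read_len = as.integer(min_read_len),
                 density_window = as.integer(density_window),
                 pileup_window = as.integer(pileup_window),
                 interprobe_extension = as.integer(interprobe_extension),
                 untreated_floor = untreated_floor),
            class = "analysis_config")
}

#' Centered moving average with truncated edges
#'
#' Windows are truncated at the ends of the vector (the mean is taken over
#' the available positions), so profiles stay defined at transcript
#' termini. `NA` values are ignored; a window with no finite value yields
#' `NA`.
#'
#' @param x Numeric vector.
#' @param window Odd window size.
#' @return Numeric vector of the same length.
#' @export
moving_average <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(x)
  if (n == 0) return(x)
  h <- (window - 1L) / 2L
  fin <- !is.na(x)
  x0 <- ifelse(fin, x, 0)
  cs <- c(0, cumsum(x0))
  cn <- c(0, cumsum(fin))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  s <- cs[hi + 1L] - cs[lo]
  k <- cn[hi + 1L] - cn[lo]
  ifelse(k > 0, s / k, NA_real_)
}

#' Adapter/poly(A) clipping and length filtering
#'
#' Locates the 3' adapter by exact match of its first 8 nt (the whole
#' adapter when shorter) and removes everything from there on, then strips
#' a trailing poly(A) tract of 5 or more A's, and finally discards reads
#' shorter than `config$min_read_len`. Base-quality trimming is delegated
#' to external tools and deliberately not implemented here.
#'
#' @param reads Character vector of read sequences.
#' @param adapter Adapter sequence (3' adapter as read).
#' @param config An [analysis_config()].
#' @return Character vector of retained, clipped reads.
#' @export
clip_and_filter <- function(reads, adapter, config = analysis_config()) {
  if (!length(reads)) return(character())
  prefix <- substr(adapter, 1, min(8L, nchar(adapter)))
  if (nchar(prefix) > 0) {
    pos <- regexpr(prefix, reads, fixed = TRUE)
    hit <- pos > 0
    reads[hit] <- substr(reads[hit], 1L, pos[hit] - 1L)
  }
  reads <- sub("A{5,}$", "", reads)
  reads[nchar(reads) >= config$min_read_len]
}

# reads filtered to one transcript and inclusive size group
.group_reads <- function(reads, transcript_id = NULL, size_range = NULL) {
  keep <- rep(TRUE, nrow(reads))
  if (!is.null(transcript_id))
    keep <- keep & reads$transcript_id == transcript_id
  if (!is.null(size_range))
    keep <- keep & reads$insert_len >= size_range$min_len &
      reads$insert_len <= size_range$max_len
  reads[keep, , drop = FALSE]
}

# per-position 5' end counts over [0, transcript_len)
.density_5p <- function(reads, transcript_len) {
  tabulate(reads$five_prime + 1L, nbins = transcript_len)
}

# number of reads mapping to mRNA-category transcripts (library loading
# normalizer), within an optional size group
.mrna_count <- function(reads, transcripts, size_range = NULL) {
  r <- .group_reads(reads, size_range = size_range)
  mrna <- transcripts$id[transcripts$category == "mRNA"]
  sum(r$transcript_id %in% mrna)
}

#' Treated/untreated 5' end-density ratio profile
#'
#' Per-position 5' end counts on one transcript, restricted to one
#' insert-size group, are smoothed with a centered moving average
#' (`density_window`, default 9 nt), normalized for library loading by each
#' library's total mRNA-mapped read count within the size group, and
#' expressed as treated density as a percentage of untreated. Positions
#' where the smoothed untreated density falls below the floor are masked
#' (`ratio = NA`), since a ratio over near-zero coverage is meaningless.
#'
#' @param treated,untreated `pdd_reads` data.frames (whole libraries; the
#'   size-group and transcript filters are applied internally, the mRNA
#'   normalizer over the whole size group).
#' @param transcript_id Transcript to profile.
#' @param transcripts The [transcript_set()] (for lengths and categories).
#' @param size_range An [insert_size_range()] defining the size group.
#' @param config An [analysis_config()].
#' @return A data.frame of class `pdd_ratio_profile` with columns
#'   `transcript_id`, `position` (0-based), `treated_density`,
#'   `untreated_density` (smoothed, normalized), `ratio` (percent, `NA`
#'   where masked), `masked`, `size_min`, `size_max`.
#' @export
ratio_profile <- function(treated, untreated, transcript_id, transcripts,
                          size_range, config = analysis_config()) {
  tl <- transcripts$length[match(transcript_id, transcripts$id)]
  if (is.na(tl)) stop("unknown transcript: ", transcript_id)
  n_t <- .mrna_count(treated, transcripts, size_range)
  n_u <- .mrna_count(untreated, transcripts, size_range)
  if (n_t == 0 || n_u == 0)
    stop("zero mRNA-mapped reads in size group [", size_range$min_len, ", ",
         size_range$max_len, "] (treated: ", n_t, ", untreated: ", n_u, ")")
  dt <- .density_5p(.group_reads(treated, transcript_id, size_range), tl)
  du <- .density_5p(.group_reads(untreated, transcript_id, size_range), tl)
  st <- moving_average(dt, config$density_window)
  su <- moving_average(du, config$density_window)
  u_total <- nrow(.group_reads(untreated, size_range = size_range))
  floor_abs <- config$untreated_floor * u_total
  masked <- su < floor_abs
  ratio <- ifelse(masked, NA_real_, (st / n_t) / (su / n_u) * 100)
  out <- data.frame(transcript_id = transcript_id, position = 0:(tl - 1L),
                    treated_density = st / n_t,
                    untreated_density = su / n_u,
                    ratio = ratio, masked = masked,
                    size_min = size_range$min_len,
                    size_max = size_range$max_len,
                    stringsAsFactors = FALSE)
  class(out) <- c("pdd_ratio_profile", "data.frame")
  out
}

#' Probe-anchored pileup of ratio profiles
#'
#' Re-indexes each probe's ratio profile to the probe's 3' end (x = 0 at
#' the footprint's last base), smooths each per-probe curve with a centered
#' moving average (`pileup_window`, default 7 nt), and averages across
#' probes at each x. Probes close to a transcript end contribute only their
#' defined positions.
#'
#' @param profiles A `pdd_ratio_profile`, or several row-bound together
#'   (e.g. covering both 18S- and 25S-like targets in the same size group).
#' @param fps Footprints of the probes to pile up.
#' @param config An [analysis_config()].
#' @param xlim Integer range of x (position minus footprint 3' end) to
#'   report; default `c(-250, 50)`.
#' @return A data.frame with columns `x`, `mean_ratio` and `n_probes`; the
#'   per-probe smoothed matrix is in the `"per_probe"` attribute.
#' @export
probe_pileup <- function(profiles, fps, config = analysis_config(),
                         xlim = c(-250L, 50L)) {
  stopifnot(nrow(fps) >= 1)
  x <- seq.int(xlim[1], xlim[2])
  mat <- matrix(NA_real_, nrow = length(x), ncol = nrow(fps),
                dimnames = list(NULL, fps$probe_id))
  for (i in seq_len(nrow(fps))) {
    prof <- profiles[profiles$transcript_id == fps$target_id[i], ,
                     drop = FALSE]
    if (!nrow(prof)) next
    anchor <- fps$end[i] - 1L  # 3' end position of the probe
    pos <- anchor + x
    m <- match(pos, prof$position)
    mat[, i] <- moving_average(prof$ratio[m], config$pileup_window)
  }
  mean_ratio <- rowMeans(mat, na.rm = TRUE)
  mean_ratio[!is.finite(mean_ratio)] <- NA_real_
  out <- data.frame(x = x, mean_ratio = mean_ratio,
                    n_probes = rowSums(!is.na(mat)))
  attr(out, "per_probe") <- mat
  out
}

#' Inter-probe read ratios versus gap distance
#'
#' For each pair of adjacent footprints on a target, counts reads whose 5'
#' end falls between the probes, extended `interprobe_extension` nt
#' (default 10) into each footprint, normalizes each library's count by its
#' mRNA-mapped total in the size group, and reports treated as a percentage
#' of untreated against the footprint-edge gap distance. Segments with no
#' untreated reads are masked.
#'
#' @inheritParams ratio_profile
#' @param fps Footprints (>= 2 on at least one target).
#' @return A data.frame with columns `target_id`, `left_probe`,
#'   `right_probe`, `distance`, `treated_count`, `untreated_count`,
#'   `ratio` (percent, `NA` when masked).
#' @export
interprobe_ratio <- function(treated, untreated, fps, transcripts,
                             size_range, config = analysis_config()) {
  n_t <- .mrna_count(treated, transcripts, size_range)
  n_u <- .mrna_count(untreated, transcripts, size_range)
  if (n_t == 0 || n_u == 0)
    stop("zero mRNA-mapped reads in the size group")
  tr <- .group_reads(treated, size_range = size_range)
  ur <- .group_reads(untreated, size_range = size_range)
  ext <- config$interprobe_extension
  rows <- list()
  for (tid in unique(fps$target_id)) {
    f <- .merge_footprints(fps[fps$target_id == tid, , drop = FALSE])
    if (nrow(f) < 2) next
    trt <- tr[tr$transcript_id == tid, , drop = FALSE]
    urt <- ur[ur$transcript_id == tid, , drop = FALSE]
    for (i in 1:(nrow(f) - 1)) {
      lo <- f$end[i] - ext          # inclusive, 0-based
      hi <- f$start[i + 1] + ext    # exclusive
      ct <- sum(trt$five_prime >= lo & trt$five_prime < hi)
      cu <- sum(urt$five_prime >= lo & urt$five_prime < hi)
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = tid, left_probe = f$probe_id[i],
        right_probe = f$probe_id[i + 1],
        distance = f$start[i + 1] - f$end[i],
        treated_count = ct, untreated_count = cu,
        ratio = if (cu > 0) (ct / n_t) / (cu / n_u) * 100 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("fewer than 2 footprints on every target")
  do.call(rbind, rows)
}

#' Depletion efficiency of a probe panel
#'
#' The per-probe ratio profiles are anchored at each functional probe's 3'
#' end, smoothed (7-nt window) and averaged across probes
#' ([probe_pileup()]); the efficiency is 100 minus the minimum of this mean
#' curve inside the core depletion zone — the x-range where every insert in
#' the size group is cleavable, from `min_duplex - min insert - probe
#' length + 1` up to `-(min_duplex - 1)` relative to the probe 3' end.
#' Probes may be excluded as non-functional via `exclude`; probes whose
#' zone is fully masked are dropped with a warning.
#'
#' @param profiles Ratio profile(s) for the probe targets in one size
#'   group.
#' @param fps Footprints of the probe panel.
#' @param size_range The size group the profiles were computed for.
#' @param model A [cleavage_model()].
#' @param config An [analysis_config()].
#' @param exclude Probe ids to treat as non-functional.
#' @return Efficiency as a percentage (scalar).
#' @export
depletion_efficiency <- function(profiles, fps, size_range,
                                 model = cleavage_model(),
                                 config = analysis_config(),
                                 exclude = character()) {
  f <- fps[!fps$probe_id %in% exclude, , drop = FALSE]
  if (!nrow(f)) stop("no functional probe left after exclusion")
  d <- model$min_duplex
  plen_min <- min(f$end - f$start)
  x_lo <- d - size_range$min_len - plen_min + 1L
  x_hi <- -(d - 1L)
  pp <- probe_pileup(profiles, f, config, xlim = c(x_lo, x_hi))
  per <- attr(pp, "per_probe")
  dead <- colSums(!is.na(per)) == 0
  if (any(dead)) {
    warning("probe(s) with fully masked depletion zone excluded: ",
            paste(colnames(per)[dead], collapse = ", "))
    if (all(dead)) stop("all probe zones are masked")
    pp$mean_ratio <- rowMeans(per[, !dead, drop = FALSE], na.rm = TRUE)
  }
  if (all(is.na(pp$mean_ratio))) stop("depletion zone entirely masked")
  100 - min(pp$mean_ratio, na.rm = TRUE)
}

#' Per-ORF read counts annotated with the best off-target Tm
#'
#' Raw read counts per ORF for the treated and untreated libraries, plus
#' the melting temperature of the best (highest-Tm) off-target probe match
#' within each ORF (`NA` when no probe matches the ORF), suitable for a
#' treated-vs-untreated scatter coloured by off-target potential.
#'
#' @param treated,untreated `pdd_reads` data.frames.
#' @param orf_ids Character vector of ORF (mRNA transcript) ids.
#' @param hits Result of [scan_probes()] (off-target hits are looked up per
#'   ORF).
#' @return A data.frame with columns `orf_id`, `count_treated`,
#'   `count_untreated`, `best_offtarget_tm`.
#' @export
orf_counts_with_offtarget_tm <- function(treated, untreated, orf_ids,
                                         hits) {
  count_in <- function(reads)
    as.integer(table(factor(reads$transcript_id, levels = orf_ids)))
  off <- hits[!hits$is_target & hits$transcript_id %in% orf_ids, ,
              drop = FALSE]
  best <- rep(NA_real_, length(orf_ids))
  if (nrow(off)) {
    agg <- tapply(off$tm, off$transcript_id, max)
    m <- match(orf_ids, names(agg))
    best[!is.na(m)] <- agg[m[!is.na(m)]]
  }
  data.frame(orf_id = orf_ids,
             count_treated = count_in(treated),
             count_untreated = count_in(untreated),
             best_offtarget_tm = best,
             stringsAsFactors = FALSE)
}

#' GC content of a set of reads
#'
#' @param reads Character vector of read sequences (typically the reads
#'   mapping to mRNA in one library).
#' @return G+C bases as a percentage of all bases.
#' @export
gc_content <- function(reads) {
  if (!length(reads)) stop("no reads supplied")
  x <- Biostrings::DNAStringSet(reads)
  gc <- sum(Biostrings::letterFrequency(x, "GC"))
  100 * gc / sum(Biostrings::width(x))
}

#' Reshuffling-based PCR duplicate analysis
#'
#' For each ORF, compares the observed number of exact 5'-end duplicates
#' (reads minus distinct 5' positions) with the expectation under random
#' placement: reads are repeatedly reshuffled uniformly over the ORF's
#' available positions (spliced ORF length minus the median read length)
#' and the duplicate count averaged. At least 100 reshuffles are used for
#' ORFs with more than 10 reads and at least 500 for ORFs with 2-10 reads;
#' ORFs with fewer than 2 reads, or with no available positions, are
#' skipped. Coverage is reads per available position.
#'
#' @param reads A `pdd_reads` data.frame (one library), restricted to
#'   ORF-mapped reads.
#' @param orf_len Named integer vector of ORF lengths.
#' @param median_read_len Median read length, nt.
#' @param seed Optional seed for the reshuffles.
#' @param n_sims_large,n_sims_small Reshuffle counts for ORFs with > 10 and
#'   2-10 reads (defaults 100 and 500).
#' @return A data.frame with columns `orf_id`, `n_reads`,
#'   `available_positions`, `coverage`, `observed_dup`, `expected_dup`,
#'   `n_sims`.
#' @export
duplication_analysis <- function(reads, orf_len, median_read_len,
                                 seed = NULL, n_sims_large = 100L,
                                 n_sims_small = 500L) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (orf in intersect(names(orf_len), unique(reads$transcript_id))) {
    p5 <- reads$five_prime[reads$transcript_id == orf]
    n <- length(p5)
    if (n < 2) next
    P <- orf_len[[orf]] - median_read_len
    if (P <= 0) {
      warning("ORF ", orf, " skipped: no available positions (length <= ",
              "median read length)")
      next
    }
    nsim <- if (n > 10) n_sims_large else n_sims_small
    sim <- vapply(seq_len(nsim), function(i)
      n - length(unique(sample.int(P, n, replace = TRUE))), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      orf_id = orf, n_reads = n, available_positions = P,
      coverage = n / P, observed_dup = n - length(unique(p5)),
      expected_dup = mean(sim), n_sims = nsim, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(orf_id = character(), n_reads = integer(),
                      available_positions = integer(), coverage = numeric(),
                      observed_dup = integer(), expected_dup = numeric(),
                      n_sims = integer()))
  do.call(rbind, rows)
}
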