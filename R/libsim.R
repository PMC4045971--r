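#' Simulated library configuration
#'
#' @param n_inserts Number of inserts to draw (>= 0).
#' @param size_range An [insert_size_range()] (default 25-200 nt, matching a
#'   typical ~170-350 bp gel size selection).
#' @param read_len Read length emitted in FASTQ output, nt (default 150).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param p_cut Cleavage probability handed to [cleavage_model()] when the
#'   pair simulator applies PDD (default 1).
#' @return An object of class `library_config`.
#' @export
library_config <- function(n_inserts, size_range = insert_size_range(),
                           read_len = 150L, seed = NULL, p_cut = 1.0) {
  n_inserts <- as.integer(n_inserts)
  stopifnot(n_inserts >= 0L, read_len >= 1L)
  structure(list(n_inserts = n_inserts, size_range = size_range,
                 read_len = as.integer(read_len), seed = seed,
                 p_cut = p_cut),
            class = "library_config")
}

#' Synthetic transcript pool with a dominant rRNA-like species
#'
#' Emulates the composition that motivates depletion: one highly abundant
#' rRNA-like transcript (default weight 200) and a background of mRNA-like
#' transcripts (weight 1 each). Sequences are uniform random DNA.
#'
#' @param n_mrna Number of mRNA-like transcripts (default 50).
#' @param rrna_len Length of the rRNA-like target, nt (default 1800,
#'   roughly a small-subunit rRNA).
#' @param mrna_len_range Length range for mRNA-like transcripts
#'   (default 500-2000 nt).
#' @param rrna_weight Abundance weight of the rRNA-like target
#'   (default 200).
#' @param seed Integer seed.
#' @return A [transcript_set()] with ids `rRNA1`, `mRNA_001`, ...
#' @export
synth_pool <- function(n_mrna = 50L, rrna_len = 1800L,
                       mrna_len_range = c(500L, 2000L),
                       rrna_weight = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  lens <- sample(mrna_len_range[1]:mrna_len_range[2], n_mrna, replace = TRUE)
  transcript_set(
    id = c("rRNA1", sprintf("mRNA_%03d", seq_len(n_mrna))),
    sequence = c(rand_dna(rrna_len), vapply(lens, rand_dna, "")),
    category = c("rRNA_target", rep("mRNA", n_mrna)),
    abundance_weight = c(rrna_weight, rep(1, n_mrna)))
}

#' Simulate random fragmentation of a transcript pool
#'
#' Draws inserts by choosing a transcript with probability proportional to
#' abundance weight times length, then sampling the insert length uniformly
#' over the size-selection range (truncated to what fits the transcript) and
#' the 5' position uniformly over the valid positions. This direct sampling
#' of the (5' position, length) joint distribution stands in for explicit
#' chemical fragmentation plus size selection.
#'
#' @param pool A [transcript_set()] with `abundance_weight`.
#' @param config A [library_config()]; `config$seed` (if non-NULL) seeds the
#'   draw.
#' @return A data.frame of class `pdd_inserts` with columns
#'   `transcript_id`, `start` (0-based), `length`.
#' @export
simulate_fragments <- function(pool, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  sr <- config$size_range
  usable <- pool$length >= sr$min_len & pool$abundance_weight > 0
  if (any(pool$length < sr$min_len))
    warning("transcript(s) shorter than the minimum insert excluded: ",
            paste(pool$id[pool$length < sr$min_len], collapse = ", "))
  pool <- pool[usable, , drop = FALSE]
  if (!nrow(pool) || sum(pool$abundance_weight) == 0)
    stop("no usable transcript with positive abundance weight")
  n <- config$n_inserts
  if (n == 0L)
    return(structure(data.frame(transcript_id = character(),
                                start = integer(), length = integer()),
                     class = c("pdd_inserts", "data.frame")))
  idx <- sample.int(nrow(pool), n, replace = TRUE,
                    prob = pool$abundance_weight * pool$length)
  tlen <- pool$length[idx]
  lmax <- pmin(sr$max_len, tlen)
  len <- sr$min_len + floor(stats::runif(n) * (lmax - sr$min_len + 1L))
  start <- floor(stats::runif(n) * (tlen - len + 1L))
  out <- data.frame(transcript_id = pool$id[idx],
                    start = as.integer(start), length = as.integer(len),
                    stringsAsFactors = FALSE)
  class(out) <- c("pdd_inserts", "data.frame")
  out
}

#' Apply probabilistic PDD cleavage to an insert set
#'
#' Each insert that is cleavable under the model (overlaps a footprint on
#' its transcript by at least `min_duplex` nt) is removed independently
#' with probability `model$p_cut`; non-cleavable inserts always survive.
#' `p_cut` of exactly 1 or 0 is applied deterministically.
#'
#' @param inserts Result of [simulate_fragments()].
#' @param fps Footprints (with `target_id`).
#' @param model A [cleavage_model()].
#' @param seed Optional integer seed for the removal draws.
#' @return The surviving subset of `inserts`.
#' @export
apply_pdd <- function(inserts, fps, model = cleavage_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(inserts)
  cleav <- rep(FALSE, n)
  for (tid in unique(fps$target_id)) {
    rows <- inserts$transcript_id == tid
    if (!any(rows)) next
    cleav[rows] <- is_cleavable(inserts$start[rows], inserts$length[rows],
                                fps[fps$target_id == tid, , drop = FALSE],
                                model)
  }
  removed <- if (model$p_cut >= 1) cleav
    else cleav & stats::runif(n) < model$p_cut
  inserts[!removed, , drop = FALSE]
}

#' Simulate a paired PDD-treated / untreated library
#'
#' Draws one insert set, splits it into two equal aliquots (emulating a
#' cDNA library intermediate split in half), leaves one untreated and
#' applies [apply_pdd()] to the other.
#'
#' @param pool A [transcript_set()].
#' @param fps Footprints of the probe panel.
#' @param config A [library_config()]; `config$p_cut` sets the cleavage
#'   probability and `config$seed` makes the whole pair reproducible.
#' @param model Optional [cleavage_model()]; its `p_cut` is overridden by
#'   `config$p_cut`.
#' @return A list with `treated` and `untreated` [aligned_reads()]
#'   data.frames and `pre_treatment` (the treated aliquot before cleavage).
#' @export
simulate_pdd_pair <- function(pool, fps, config,
                              model = cleavage_model()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  model$p_cut <- config$p_cut
  ins <- simulate_fragments(pool, within_seed(config))
  half <- sample.int(nrow(ins), floor(nrow(ins) / 2))
  treated_pre <- ins[half, , drop = FALSE]
  untreated <- ins[-half, , drop = FALSE]
  treated <- apply_pdd(treated_pre, fps, model)
  list(treated = aligned_reads("treated", treated),
       untreated = aligned_reads("untreated", untreated),
       pre_treatment = aligned_reads("treated", treated_pre))
}

# internal: strip the seed so nested calls don't re-seed
within_seed <- function(config) { config$seed <- NULL; config }

#' Aligned-read table from inserts
#'
#' The unit of all density analyses: one row per insert/read with its
#' library, transcript, 0-based 5' position and insert length.
#'
#' @param library_id Library label (recycled).
#' @param inserts A `pdd_inserts` data.frame (or columns `transcript_id`,
#'   `start`, `length`).
#' @return A data.frame of class `pdd_reads` with columns `library_id`,
#'   `transcript_id`, `five_prime`, `insert_len`.
#' @export
aligned_reads <- function(library_id, inserts) {
  out <- data.frame(library_id = rep_len(as.character(library_id),
                                         nrow(inserts)),
                    transcript_id = inserts$transcript_id,
                    five_prime = as.integer(inserts$start),
                    insert_len = as.integer(inserts$length),
                    stringsAsFactors = FALSE)
  class(out) <- c("pdd_reads", "data.frame")
  out
}
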