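#' Read probes from TSV
#'
#' Expected columns: `id`, `sequence`, `intended_targets`
#' (semicolon-separated transcript ids; may be empty).
#'
#' @param path Path to a tab-separated file with a header.
#' @return A [probe_set()].
#' @export
read_probes_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(c("id", "sequence", "intended_targets") %in% names(d)))
  targets <- strsplit(d$intended_targets, ";", fixed = TRUE)
  targets <- lapply(targets, function(x) x[nzchar(x)])
  probe_set(d$id, d$sequence, targets)
}

#' Read probes from FASTA
#'
#' Intended targets are taken from a `targets=a;b` token in the FASTA
#' description line, when present.
#'
#' @param path Path to a FASTA file.
#' @return A [probe_set()].
#' @export
read_probes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  tgt <- regmatches(nm, regexpr("targets=[^ ]+", nm))
  targets <- rep(list(character()), length(x))
  has <- grepl("targets=", nm)
  targets[has] <- strsplit(sub("^targets=", "", tgt), ";", fixed = TRUE)
  probe_set(id, as.character(x), targets)
}

#' Write probes to FASTA
#'
#' @param probes A [probe_set()].
#' @param path Output path.
#' @export
write_probes_fasta <- function(probes, path) {
  x <- Biostrings::DNAStringSet(probes$sequence)
  names(x) <- paste0(probes$id, " targets=",
                     vapply(probes$intended_targets, paste,
                            "", collapse = ";"))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a transcriptome from FASTA plus a category table
#'
#' @param fasta Path to transcript FASTA (ids are taken up to the first
#'   whitespace).
#' @param categories Path to a tab-separated table with columns `id`,
#'   `category` and optionally `abundance_weight`; transcripts absent from
#'   the table default to `mRNA`, weight 1.
#' @return A [transcript_set()].
#' @export
read_transcripts <- function(fasta, categories = NULL) {
  x <- Biostrings::readDNAStringSet(fasta)
  id <- sub("\\s.*$", "", names(x))
  cat_ <- rep("mRNA", length(x))
  w <- rep(1, length(x))
  if (!is.null(categories)) {
    d <- utils::read.delim(categories, stringsAsFactors = FALSE)
    m <- match(id, d$id)
    cat_[!is.na(m)] <- d$category[m[!is.na(m)]]
    if ("abundance_weight" %in% names(d))
      w[!is.na(m)] <- d$abundance_weight[m[!is.na(m)]]
  }
  transcript_set(id, as.character(x), cat_, w)
}

#' Write a transcript pool as FASTA plus categories TSV
#'
#' @param pool A [transcript_set()].
#' @param fasta,categories Output paths.
#' @export
write_transcripts <- function(pool, fasta, categories) {
  x <- Biostrings::DNAStringSet(pool$sequence)
  names(x) <- pool$id
  Biostrings::writeXStringSet(x, fasta)
  utils::write.table(pool[, c("id", "category", "abundance_weight")],
                     categories, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta)
}

#' Read/write aligned-read tables
#'
#' Plain TSV with columns `library_id`, `transcript_id`, `five_prime`
#' (0-based) and `insert_len`.
#'
#' @param path File path.
#' @return `read_alignments_tsv()` returns a `pdd_reads` data.frame.
#' @export
read_alignments_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("library_id", "transcript_id", "five_prime",
                  "insert_len") %in% names(d)))
  aligned_reads(d$library_id,
                data.frame(transcript_id = d$transcript_id,
                           start = d$five_prime, length = d$insert_len))
}

#' @rdname read_alignments_tsv
#' @param reads A `pdd_reads` data.frame.
#' @export
write_alignments_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read primary alignments from SAM/BAM
#'
#' Only primary, mapped alignments are kept (secondary and supplementary
#' records are dropped). The insert length is taken as the query length and
#' the 5' position as the 0-based leftmost mapping position on the
#' transcript.
#'
#' @param path Path to a BAM file, or a SAM text file (converted on the
#'   fly).
#' @param library_id Library label to attach.
#' @return A `pdd_reads` data.frame.
#' @export
read_alignments_bam <- function(path, library_id) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag,
                               what = c("rname", "pos", "qwidth"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  aligned_reads(library_id,
                data.frame(transcript_id = as.character(b$rname)[keep],
                           start = b$pos[keep] - 1L,
                           length = b$qwidth[keep]))
}

#' Write inserts as FASTQ
#'
#' Each record is the first `read_len` nt of the insert's sense sequence
#' with constant Phred quality `I` (Q40, Sanger encoding).
#'
#' @param inserts A `pdd_inserts` or `pdd_reads` data.frame.
#' @param pool The [transcript_set()] the inserts were drawn from.
#' @param path Output FASTQ path.
#' @param read_len Read length, nt.
#' @return `path`, invisibly.
#' @export
write_inserts_fastq <- function(inserts, pool, path, read_len = 150L) {
  start <- if ("start" %in% names(inserts)) inserts$start else
    inserts$five_prime
  len <- if ("length" %in% names(inserts)) inserts$length else
    inserts$insert_len
  seqs <- substring(pool$sequence[match(inserts$transcript_id, pool$id)],
                    start + 1L, start + pmin(len, read_len))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("read%06d %s:%d:%d", seq_along(seqs),
                      inserts$transcript_id, start, len)
  q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write a hit table with 1-based inclusive coordinates
#'
#' Internal coordinates are 0-based half-open; all TSV reports use 1-based
#' inclusive coordinates, as documented in their headers.
#'
#' @param hits Result of [scan_probes()].
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  d <- data.frame(probe_id = hits$probe_id,
                  transcript_id = hits$transcript_id,
                  probe_start1 = hits$probe_start + 1L,
                  probe_end1 = hits$probe_start + hits$length,
                  transcript_start1 = hits$transcript_start + 1L,
                  transcript_end1 = hits$transcript_start + hits$length,
                  length = hits$length, strand = hits$strand,
                  tm = round(hits$tm, 3), is_target = hits$is_target)
  con <- file(path, "w")
  writeLines("# coordinates are 1-based inclusive", con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
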