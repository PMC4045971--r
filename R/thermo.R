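#' Nearest-neighbor parameter table for DNA/DNA duplexes
#'
#' Loads a nearest-neighbor thermodynamic parameter set for perfectly matched
#' DNA/DNA duplexes: stacking enthalpies/entropies for the 16 dinucleotide
#' stacks (which collapse to 10 unique values by reverse-complement symmetry)
#' plus duplex-initiation terms per terminal A·T and G·C base pair. The
#' default table shipped with the package is the unified parameter set of the
#' Allawi & SantaLucia lineage, referenced to 1 M NaCl.
#'
#' @param path Path to a tab-separated parameter file with columns
#'   `key`, `dH` (kcal/mol) and `dS` (cal/(mol·K)). Keys are the 16
#'   dinucleotides plus `init_AT` and `init_GC`. Comment lines start with
#'   `#`; a leading `# source:` line is kept as the table's `source_label`.
#'   The default is the table installed with the package.
#' @return An object of class `nn_table`: a list with named numeric vectors
#'   `stack_dH` and `stack_dS` (16 entries each), scalars `init_dH_AT`,
#'   `init_dS_AT`, `init_dH_GC`, `init_dS_GC`, and a `source_label` string.
#' @examples
#' tab <- nn_table()
#' tab$stack_dH[["CG"]]
#' @export
nn_table <- function(path = system.file("extdata", "nn_unified_dna.tsv",
                                        package = "pddkit")) {
  lines <- readLines(path)
  src <- grep("^# source:", lines, value = TRUE)
  src <- if (length(src)) sub("^# source:\\s*", "", src[1]) else basename(path)
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  stacks <- .all_stacks()
  if (!all(stacks %in% tab$key))
    stop("parameter file is missing dinucleotide stacks: ",
         paste(setdiff(stacks, tab$key), collapse = ", "))
  if (!all(c("init_AT", "init_GC") %in% tab$key))
    stop("parameter file is missing initiation terms init_AT / init_GC")
  rownames(tab) <- tab$key
  out <- list(
    stack_dH = structure(tab[stacks, "dH"], names = stacks),
    stack_dS = structure(tab[stacks, "dS"], names = stacks),
    init_dH_AT = tab["init_AT", "dH"], init_dS_AT = tab["init_AT", "dS"],
    init_dH_GC = tab["init_GC", "dH"], init_dS_GC = tab["init_GC", "dS"],
    source_label = src
  )
  if (any(out$stack_dH >= 0))
    stop("Watson-Crick stack enthalpies must all be negative")
  class(out) <- "nn_table"
  out
}

.all_stacks <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(b, b, paste0))
}

#' Hybridization conditions for melting-temperature estimation
#'
#' Conditions under which probe/cDNA duplex melting temperatures are
#' predicted. The default probe concentration is 0.81 uM per probe, the
#' per-probe concentration used when hybridizing a 50-probe depletion panel,
#' with probe assumed in excess over its target. The symmetry factor is 4
#' for a non-self-complementary duplex formed from two distinct strands
#' (probe and cDNA), 1 for a self-complementary one.
#'
#' @param probe_concentration Total strand concentration C_T in mol/L
#'   (default `8.1e-7`).
#' @param monovalent_salt Monovalent cation concentration in mol/L
#'   (default `0.05`). Used in the entropic salt correction
#'   dS' = dS + 0.368 (N-1) ln(\[monovalent\]).
#' @param symmetry_factor Either 1 or 4 (default 4).
#' @return An object of class `hyb_conditions`.
#' @export
hybridization_conditions <- function(probe_concentration = 8.1e-7,
                                     monovalent_salt = 0.05,
                                     symmetry_factor = 4L) {
  stopifnot(is.numeric(probe_concentration), probe_concentration > 0,
            is.numeric(monovalent_salt), monovalent_salt > 0)
  if (!symmetry_factor %in% c(1L, 4L))
    stop("symmetry_factor must be 1 (self-complementary) or 4")
  structure(list(probe_concentration = probe_concentration,
                 monovalent_salt = monovalent_salt,
                 symmetry_factor = as.integer(symmetry_factor)),
            class = "hyb_conditions")
}

.check_duplex_seq <- function(sequence) {
  sequence <- toupper(sequence)
  bad <- !grepl("^[ACGT]+$", sequence)
  if (any(bad))
    stop("sequence contains bases outside {A,C,G,T}: ",
         paste(utils::head(sequence[bad], 3), collapse = ", "),
         " (ambiguous bases cannot be scored; matches are exact upstream)")
  short <- nchar(sequence) < 2
  if (any(short)) stop("duplex sequences must be at least 2 nt long")
  sequence
}

#' Nearest-neighbor duplex enthalpy and entropy
#'
#' Sums stacking parameters over consecutive dinucleotides of a perfectly
#' matched DNA/DNA duplex (given by its 5'->3' top strand) and adds the
#' initiation term for each terminal base pair. Both strands of the same
#' physical duplex give identical energies.
#'
#' @param sequence Character vector of DNA sequences (A/C/G/T only, length
#'   >= 2 each).
#' @param table An [nn_table()].
#' @return A data.frame with columns `sequence`, `dH` (kcal/mol) and `dS`
#'   (cal/(mol·K)), one row per input sequence.
#' @examples
#' duplex_energies("ACGTA")
#' @export
duplex_energies <- function(sequence, table = nn_table()) {
  sequence <- .check_duplex_seq(sequence)
  n <- nchar(sequence)
  init_for <- function(base) {
    at <- base %in% c("A", "T")
    cbind(dH = ifelse(at, table$init_dH_AT, table$init_dH_GC),
          dS = ifelse(at, table$init_dS_AT, table$init_dS_GC))
  }
  first <- init_for(substr(sequence, 1, 1))
  last <- init_for(substr(sequence, n, n))
  dH <- numeric(length(sequence))
  dS <- numeric(length(sequence))
  for (i in seq_along(sequence)) {
    st <- substring(sequence[i], 1:(n[i] - 1), 2:n[i])
    dH[i] <- sum(table$stack_dH[st])
    dS[i] <- sum(table$stack_dS[st])
  }
  data.frame(sequence = sequence,
             dH = dH + first[, "dH"] + last[, "dH"],
             dS = dS + first[, "dS"] + last[, "dS"],
             row.names = NULL)
}

#' Duplex melting temperature
#'
#' Two-state nearest-neighbor melting temperature of a perfectly matched
#' DNA/DNA duplex:
#' \deqn{T_m = \frac{1000\,\Delta H}{\Delta S' + R \ln(C_T/x)} - 273.15}
#' with R = 1.987 cal/(mol·K), C_T the total strand concentration, x the
#' symmetry factor, and the entropic salt correction
#' \eqn{\Delta S' = \Delta S + 0.368\,(N-1)\ln[\mathrm{monovalent}]}.
#'
#' @inheritParams duplex_energies
#' @param conditions A [hybridization_conditions()] object.
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' melting_temperature("AGCGTAAGCTGG")
#' @export
melting_temperature <- function(sequence,
                                conditions = hybridization_conditions(),
                                table = nn_table()) {
  en <- duplex_energies(sequence, table)
  n <- nchar(en$sequence)
  R <- 1.987  # cal/(mol K)
  dS_corr <- en$dS + 0.368 * (n - 1) * log(conditions$monovalent_salt)
  denom <- dS_corr +
    R * log(conditions$probe_concentration / conditions$symmetry_factor)
  if (any(denom >= 0))
    stop("non-negative Tm denominator for sequence(s) ",
         paste(utils::head(en$sequence[denom >= 0], 3), collapse = ", "),
         "; check concentrations and parameter table")
  1000 * en$dH / denom - 273.15
}

#' Duplex free energy at a given temperature
#'
#' Convenience helper: \eqn{\Delta G(T) = 1000\,\Delta H - T_K \Delta S'}
#' in cal/mol, with the same entropic salt correction as
#' [melting_temperature()]. Used to reason about duplex stability at the
#' hybridization temperature (48 degrees C by default).
#'
#' @inheritParams melting_temperature
#' @param celsius Temperature in degrees Celsius (default 48).
#' @return Numeric vector, cal/mol.
#' @export
duplex_dG <- function(sequence, celsius = 48,
                      conditions = hybridization_conditions(),
                      table = nn_table()) {
  en <- duplex_energies(sequence, table)
  n <- nchar(en$sequence)
  dS_corr <- en$dS + 0.368 * (n - 1) * log(conditions$monovalent_salt)
  1000 * en$dH - (celsius + 273.15) * dS_corr
}

#' Reverse complement of a DNA string
#'
#' @param sequence Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sequence)))
}
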