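# Reference genome container and FASTA I/O.
#
# Coordinates are 0-based, half-open everywhere inside the package; the SAM
# reader/writer converts at the boundary.

#' Construct a reference genome
#'
#' A reference genome is an ordered, named set of uppercase DNA sequences
#' (linkage groups plus any auxiliary sequences such as co-injected vectors).
#'
#' @param sequences Named character vector of DNA sequences. Names must be
#'   unique and non-empty; the alphabet is restricted to A, C, G, T, N.
#'   Lowercase input is uppercased.
#' @return An object of class `ReferenceGenome`: a list with elements
#'   `sequences` (named character vector) and `total_length` (total bases).
#' @export
reference_genome <- function(sequences) {
  if (length(sequences) == 0L) stop("a reference genome needs at least one sequence")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stop("all sequences must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate sequence name: ", nm[duplicated(nm)][1L])
  }
  sequences <- toupper(as.character(sequences))
  names(sequences) <- nm
  if (any(!nzchar(sequences))) {
    stop("empty sequence: ", nm[!nzchar(sequences)][1L])
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) stop("sequence '", nm[bad][1L], "' contains non-ACGTN characters")
  structure(
    list(sequences = sequences, total_length = sum(nchar(sequences))),
    class = "ReferenceGenome"
  )
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome:", length(x$sequences), "sequence(s),",
      x$total_length, "bp total\n")
  n <- nchar(x$sequences)
  for (i in seq_along(n)) cat("  ", names(n)[i], ": ", n[i], " bp\n", sep = "")
  invisible(x)
}

#' Read a reference genome from FASTA
#'
#' Records are kept in file order, sequences are uppercased, and duplicate
#' record names or empty records are rejected.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A [reference_genome()] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no FASTA records in '", path, "'")
  seqs <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(set))
  reference_genome(seqs)
}

#' Write sequences to FASTA
#'
#' @param sequences A `ReferenceGenome` or a named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  if (inherits(sequences, "ReferenceGenome")) sequences <- sequences$sequences
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

# Extract ref[start, end) (0-based half-open) from linkage group `lg`.
genome_sub <- function(ref, lg, start, end) {
  s <- ref$sequences[[lg]]
  if (is.null(s)) stop("unknown linkage group: ", lg)
  if (start < 0 || end > nchar(s) || start > end) {
    stop("interval [", start, ",", end, ") out of bounds for ", lg,
         " (length ", nchar(s), ")")
  }
  substr(s, start + 1L, end)
}

genome_length <- function(ref, lg) {
  s <- ref$sequences[[lg]]
  if (is.null(s)) stop("unknown linkage group: ", lg)
  nchar(s)
}
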