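# Algebra of IUPAC-degenerate nucleotide sequences: the 15-letter ambiguity
# alphabet, expansion semantics, complementation, pattern matching,
# translation and ORF arithmetic.

# symbol -> base set, the 15 canonical ambiguity codes
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# base-set key ("ACGT"-sorted, collapsed) -> symbol
.IUPAC_LOOKUP <- local({
  keys <- vapply(.IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(.IUPAC_SETS), keys)
})

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Base set of an IUPAC ambiguity code
#'
#' @param symbol single IUPAC nucleotide symbol (one of ACGTRYSWKMBDHVN,
#'   case-insensitive; `U` is treated as `T`).
#' @return character vector of concrete bases the symbol stands for.
#' @examples
#' iupac_bases("W")  # A T
#' iupac_bases("N")  # A C G T
#' @export
iupac_bases <- function(symbol) {
  s <- .normalize_nt(symbol)
  if (nchar(s) != 1L || is.na(match(s, names(.IUPAC_SETS))))
    stop("not an IUPAC nucleotide symbol: '", symbol, "'")
  .IUPAC_SETS[[s]]
}

#' IUPAC code for a set of bases
#'
#' Returns the unique ambiguity symbol whose base set equals `bases`
#' (e.g. `{A,T}` -> `W`, `{A,C,G,T}` -> `N`).
#'
#' @param bases non-empty subset of A, C, G, T (character vector).
#' @return single IUPAC symbol.
#' @export
iupac_union <- function(bases) {
  if (length(bases) == 0L) stop("no bases to encode")
  b <- unique(toupper(as.character(bases)))
  b[b == "U"] <- "T"
  if (!all(b %in% c("A", "C", "G", "T")))
    stop("not concrete nucleotides: ", paste(setdiff(b, c("A", "C", "G", "T")), collapse = ", "))
  unname(.IUPAC_LOOKUP[paste(sort(b), collapse = "")])
}

# upcase, U->T; no other normalization
.normalize_nt <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Degenerate nucleotide sequence
#'
#' Validates and normalizes a nucleotide string over the 15-letter IUPAC
#' alphabet. Lowercase is upcased, `U` becomes `T`. Gaps are not permitted:
#' primers are ungapped.
#'
#' @param x nucleotide string (or an existing `degenerate_seq`).
#' @return a `degenerate_seq` object (a validated character scalar).
#' @export
degenerate_seq <- function(x) {
  if (inherits(x, "degenerate_seq")) return(x)
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) < 1L)
    stop("a degenerate sequence must be a single non-empty string")
  s <- .normalize_nt(x)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(.IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC symbol '", chars[bad[1L]], "' at position ", bad[1L])
  structure(s, class = "degenerate_seq")
}

#' @export
print.degenerate_seq <- function(x, ...) {
  cat("Degenerate sequence (", nchar(x), " nt, degeneracy ",
      format(degeneracy(x), big.mark = ","), ")\n  ", unclass(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.degenerate_seq <- function(x, ...) unclass(x)

#' Reverse complement of a (possibly degenerate) sequence
#'
#' Position-wise Watson-Crick complementation over the full ambiguity
#' alphabet (R<->Y, K<->M, W and S self-complementary, ...) followed by
#' reversal. Degeneracy is preserved; the operation is an involution.
#'
#' @param seq nucleotide string or `degenerate_seq`.
#' @return `degenerate_seq` of the same length.
#' @examples
#' revcomp("GAR")  # YTC
#' @export
revcomp <- function(seq) {
  s <- degenerate_seq(seq)
  chars <- strsplit(unclass(s), "", fixed = TRUE)[[1L]]
  degenerate_seq(paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = ""))
}

#' Degeneracy of a sequence
#'
#' Number of concrete oligonucleotides the sequence stands for: the product
#' over positions of the ambiguity-set sizes.
#'
#' @param seq nucleotide string or `degenerate_seq`.
#' @return positive number (double, to avoid integer overflow on long
#'   highly degenerate sequences).
#' @export
degeneracy <- function(seq) {
  s <- degenerate_seq(seq)
  chars <- strsplit(unclass(s), "", fixed = TRUE)[[1L]]
  prod(vapply(chars, function(ch) length(.IUPAC_SETS[[ch]]), 1L))
}

#' Enumerate the concrete expansions of a degenerate sequence
#'
#' @param seq nucleotide string or `degenerate_seq`.
#' @param max_expansions guard against combinatorial blow-up; exceeded ->
#'   error.
#' @return character vector of all concrete sequences matching `seq`.
#' @export
expand_degenerate <- function(seq, max_expansions = 65536L) {
  s <- degenerate_seq(seq)
  if (degeneracy(s) > max_expansions)
    stop("degeneracy ", degeneracy(s), " exceeds max_expansions = ", max_expansions)
  chars <- strsplit(unclass(s), "", fixed = TRUE)[[1L]]
  sets <- lapply(chars, function(ch) .IUPAC_SETS[[ch]])
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

#' Does a concrete sequence match a degenerate pattern?
#'
#' TRUE iff sequences have equal length and at every position the concrete
#' base lies in the pattern's ambiguity set.
#'
#' @param concrete concrete nucleotide string (A/C/G/T only).
#' @param pattern nucleotide string or `degenerate_seq`.
#' @return logical scalar.
#' @export
matches_pattern <- function(concrete, pattern) {
  p <- degenerate_seq(pattern)
  c_ <- degenerate_seq(concrete)
  cc <- strsplit(unclass(c_), "", fixed = TRUE)[[1L]]
  if (!all(cc %in% c("A", "C", "G", "T")))
    stop("first argument must be a concrete A/C/G/T sequence")
  pc <- strsplit(unclass(p), "", fixed = TRUE)[[1L]]
  if (length(cc) != length(pc))
    stop("length mismatch: ", length(cc), " vs ", length(pc))
  all(mapply(function(b, sym) b %in% .IUPAC_SETS[[sym]], cc, pc))
}

#' Codon table (standard genetic codes)
#'
#' Thin wrapper around the NCBI genetic-code tables shipped with Biostrings,
#' returned as a named character vector codon -> amino acid (stop = `*`).
#'
#' @param table_id NCBI genetic-code table id (default `"1"`, the standard
#'   code, appropriate for Bacillus/Geobacillus chromosomal genes).
#' @return named character vector of length 64.
#' @export
codon_table <- function(table_id = "1") {
  Biostrings::getGeneticCode(as.character(table_id))
}

#' Translate a concrete nucleotide sequence
#'
#' Codon-wise translation. A terminal stop codon is dropped from the
#' protein; an internal stop is an error, as is any ambiguity code
#' (translation accepts concrete input only).
#'
#' @param nt concrete nucleotide string, length divisible by 3.
#' @param table codon table from [codon_table()].
#' @return protein string (one-letter code).
#' @export
translate_nt <- function(nt, table = codon_table()) {
  s <- unclass(degenerate_seq(nt))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  amb <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(amb))
    stop("ambiguous codon: symbol '", chars[amb[1L]], "' at position ", amb[1L])
  n <- nchar(s)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(table[codons])
  stops <- which(aa == "*")
  if (length(stops) && any(stops < length(aa)))
    stop("internal stop codon at codon ", stops[stops < length(aa)][1L])
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Protein length encoded by an ORF
#'
#' An open reading frame of `orf_bp` nucleotides (start codon through stop
#' codon inclusive) codes for `orf_bp / 3 - 1` residues: the stop codon is
#' excluded. A 1242 bp ORF therefore codes for a 413-residue protein.
#'
#' @param orf_bp ORF length in bp, divisible by 3 and at least 6.
#' @return integer residue count.
#' @export
orf_protein_length <- function(orf_bp) {
  if (!is.numeric(orf_bp) || length(orf_bp) != 1L || orf_bp < 6L)
    stop("orf_bp must be a single number >= 6")
  if (orf_bp %% 3L != 0L) stop("ORF length ", orf_bp, " is not divisible by 3")
  as.integer(orf_bp / 3L - 1L)
}

#' Read nucleotide sequences from FASTA
#'
#' Accepts concrete and degenerate sequences; each record is validated
#' against the IUPAC alphabet.
#'
#' @param path FASTA file.
#' @return named list of `degenerate_seq` objects.
#' @export
read_nt_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- lapply(as.character(x), degenerate_seq)
  names(out) <- names(x)
  out
}

#' Write nucleotide sequences to FASTA
#'
#' @param seqs named list or character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nt_fasta <- function(seqs, path) {
  s <- vapply(seqs, function(x) unclass(degenerate_seq(x)), "")
  if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
  Biostrings::writeXStringSet(Biostrings::BStringSet(s), path)
  invisible(path)
}
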