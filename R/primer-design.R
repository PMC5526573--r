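# Back-translation of conserved protein motifs into fully degenerate
# consensus primers, reverse-primer construction, restriction tails and
# design metrics.

#' Protein motif
#'
#' A short amino-acid block, optionally anchored to 1-based inclusive
#' alignment columns, used as a primer design anchor.
#'
#' @param residues one-letter amino-acid string (standard 20 residues).
#' @param span optional `c(start, end)` alignment columns, 1-based
#'   inclusive; must agree with the motif length.
#' @param cluster_tag free label, e.g. `"shared"` or `"long-cluster-flank"`.
#' @return a `protein_motif` object.
#' @export
protein_motif <- function(residues, span = NULL, cluster_tag = NA_character_) {
  if (inherits(residues, "protein_motif")) return(residues)
  if (!is.character(residues) || length(residues) != 1L || nchar(residues) < 1L)
    stop("motif residues must be a single non-empty string")
  r <- toupper(residues)
  chars <- strsplit(r, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]])
  if (length(bad))
    stop("non-standard amino acid '", chars[bad[1L]], "' at position ", bad[1L])
  if (!is.null(span)) {
    span <- as.integer(span)
    if (length(span) != 2L || span[2L] - span[1L] + 1L != nchar(r))
      stop("span must be c(start, end) with end - start + 1 == motif length")
  }
  structure(list(residues = r, span = span, cluster_tag = cluster_tag),
            class = "protein_motif")
}

#' @export
print.protein_motif <- function(x, ...) {
  cat("Protein motif ", x$residues,
      if (!is.null(x$span)) paste0(" [cols ", x$span[1L], "-", x$span[2L], "]"),
      if (!is.na(x$cluster_tag)) paste0(" (", x$cluster_tag, ")"), "\n", sep = "")
  invisible(x)
}

#' Fully degenerate codon for an amino acid
#'
#' Position-wise union rule: the 3-letter degenerate codon whose ambiguity
#' set at each position is the union, over all codons of the amino acid, of
#' the bases at that position. Every codon of the amino acid matches the
#' result. For residues whose codons split across boxes the union is
#' deliberately over-degenerate (serine: 6 codons, `WSN` covers 16
#' triplets); this single rule is what consensus-primer tables use.
#'
#' @param aa single amino acid (one-letter).
#' @param table codon table from [codon_table()].
#' @return `degenerate_seq` of length 3.
#' @examples
#' degenerate_codon("S")  # WSN
#' degenerate_codon("W")  # TGG
#' @export
degenerate_codon <- function(aa, table = codon_table()) {
  a <- toupper(as.character(aa))
  if (length(a) != 1L || nchar(a) != 1L) stop("aa must be one amino acid")
  codons <- names(table)[table == a & table != "*"]
  if (!length(codons)) stop("unknown amino acid: '", aa, "'")
  mat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  degenerate_seq(paste(vapply(1:3, function(j) iupac_union(mat[, j]), ""),
                       collapse = ""))
}

#' Back-translate a protein motif into a degenerate sequence
#'
#' Concatenates [degenerate_codon()] over the residues, giving the forward
#' (coding-strand, 5'->3') consensus primer core of length `3 * nchar(motif)`.
#'
#' @param motif `protein_motif` or plain amino-acid string.
#' @param table codon table.
#' @return `degenerate_seq`.
#' @examples
#' backtranslate("SSNWDRACE")  # WSNWSNAAYTGGGAYMGNGCNTGYGAR
#' @export
backtranslate <- function(motif, table = codon_table()) {
  m <- protein_motif(motif)
  aas <- strsplit(m$residues, "", fixed = TRUE)[[1L]]
  degenerate_seq(paste(vapply(aas, function(a)
    unclass(degenerate_codon(a, table)), ""), collapse = ""))
}

#' Reverse (bottom-strand) degenerate primer for a motif
#'
#' The reverse complement of the back-translated motif, reported 5'->3':
#' the oligo that anneals to the coding strand at the motif's position.
#'
#' @inheritParams backtranslate
#' @return `degenerate_seq`.
#' @examples
#' reverse_primer("YDFKLDQW")  # CCAYTGRTCNARYTTRAARTCRTA
#' @export
reverse_primer <- function(motif, table = codon_table()) {
  revcomp(backtranslate(motif, table))
}

#' Attach a concrete tail (e.g. restriction-site clamp) to a primer core
#'
#' Builds a full primer `tail + core` and, when a restriction recognition
#' sequence is supplied, verifies it occurs in the full oligo and records
#' its location. The tail must be concrete; degeneracy of the design is the
#' degeneracy of the core.
#'
#' @param core degenerate primer core (string or `degenerate_seq`).
#' @param tail concrete 5' extension; may be `""`.
#' @param site optional recognition sequence that must occur in the full
#'   primer (e.g. `"CCATGG"` for NcoI).
#' @param enzyme optional enzyme name for reporting.
#' @param direction `"forward"` or `"reverse"` (annotation only; pass an
#'   already reverse-complemented core for reverse primers).
#' @param name primer name for reports.
#' @return a `primer_design` object.
#' @export
tail_primer <- function(core, tail = "", site = NULL, enzyme = NA_character_,
                        direction = c("forward", "reverse"), name = NA_character_) {
  direction <- match.arg(direction)
  core <- degenerate_seq(core)
  if (nchar(tail) > 0L) {
    tl <- unclass(degenerate_seq(tail))
    if (!all(strsplit(tl, "", fixed = TRUE)[[1L]] %in% c("A", "C", "G", "T")))
      stop("tail must be concrete A/C/G/T")
  } else tl <- ""
  full <- degenerate_seq(paste0(tl, unclass(core)))
  site_pos <- NULL
  if (!is.null(site)) {
    st <- unclass(degenerate_seq(site))
    site_pos <- as.integer(regexpr(st, unclass(full), fixed = TRUE))
    if (site_pos < 1L)
      stop("restriction site ", st, " not present in primer ",
           if (!is.na(name)) name else unclass(full))
    site <- st
  }
  structure(list(name = name, core = core, tail = tl, full = full,
                 direction = direction, degeneracy = degeneracy(core),
                 restriction_site = site, restriction_enzyme = enzyme,
                 restriction_pos = site_pos),
            class = "primer_design")
}

#' @export
print.primer_design <- function(x, ...) {
  cat("Primer", if (!is.na(x$name)) x$name else "", "(", x$direction, ")\n",
      "  5'-", unclass(x$full), "-3'  (", nchar(x$full), " nt, degeneracy ",
      format(x$degeneracy, big.mark = ","), ")\n", sep = "")
  if (!is.null(x$restriction_site))
    cat("  ", x$restriction_enzyme, " site ", x$restriction_site,
        " at position ", x$restriction_pos, "\n", sep = "")
  invisible(x)
}

#' Design metrics for a primer
#'
#' Length, degeneracy, and GC-content / melting-temperature ranges over the
#' pool of concrete expansions. Tm uses the Wallace rule,
#' `Tm = 2 (A + T) + 4 (G + C)` degrees C, the convention for short
#' degenerate oligos; the minimum and maximum across the pool are reported.
#' For large pools the extremes are computed directly from per-position
#' ambiguity sets (GC-min/max per position), which is exact for both
#' metrics.
#'
#' @param p `primer_design`, `degenerate_seq`, or plain string.
#' @return data.frame with one row: name, direction, length, degeneracy,
#'   gc_min, gc_max, tm_min, tm_max.
#' @export
primer_report <- function(p) {
  if (!inherits(p, "primer_design"))
    p <- tail_primer(p, direction = "forward")
  chars <- strsplit(unclass(p$full), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  # per position: can the base be G/C, must it be?
  gc_possible <- vapply(chars, function(ch) any(.IUPAC_SETS[[ch]] %in% c("G", "C")), TRUE)
  gc_forced   <- vapply(chars, function(ch) all(.IUPAC_SETS[[ch]] %in% c("G", "C")), TRUE)
  gc_min <- sum(gc_forced); gc_max <- sum(gc_possible)
  data.frame(
    name = if (is.na(p$name)) unclass(p$full) else p$name,
    direction = p$direction,
    length = n,
    degeneracy = p$degeneracy,
    gc_min = gc_min / n, gc_max = gc_max / n,
    tm_min = 2 * (n - gc_min) + 4 * gc_min,
    tm_max = 2 * (n - gc_max) + 4 * gc_max,
    stringsAsFactors = FALSE
  )
}

#' Predicted amplicon size between two motif anchors
#'
#' For a forward motif and a reverse motif carrying spans on the same
#' (ungapped) alignment coordinate system, the predicted PCR product spans
#' the primer outer ends: `3 * (rev_end - fwd_start + 1)` bp. Gap columns
#' inside the span must be removed before conversion (codon coordinates are
#' ungapped).
#'
#' @param fwd,rev `protein_motif` objects with spans.
#' @return predicted product size in bp (integer).
#' @export
expected_amplicon <- function(fwd, rev) {
  fwd <- protein_motif(fwd); rev <- protein_motif(rev)
  if (is.null(fwd$span) || is.null(rev$span))
    stop("both motifs need alignment spans")
  if (fwd$span[1L] > rev$span[2L])
    stop("forward motif starts after reverse motif ends: check primer order")
  as.integer(3L * (rev$span[2L] - fwd$span[1L] + 1L))
}

#' Degenerate consensus primer pairs for family I.5 lipase prospecting
#'
#' The four conserved-motif anchors used to recover lipase genes from
#' Bacillus/Geobacillus genomic DNA, as named primer specifications:
#' the pair shared by the short (B. cereus group, 20-35 kDa) and long
#' (Geobacillus, 40-45 kDa) clusters (motifs SSNWDRACE / YDFKLDQW), and the
#' Geobacillus-specific pair flanking the common central region
#' (GWGREEM / NDGIVNT). Calling [backtranslate()] / [reverse_primer()] on
#' the motifs regenerates the primer sequences.
#'
#' @return data.frame with columns name, motif, direction, primer.
#' @export
lipase_primer_presets <- function() {
  data.frame(
    name = c("FWintLipGBCdeg", "BWintLipGBCdeg", "FWintLipGdeg", "BWintLipGdeg"),
    motif = c("SSNWDRACE", "YDFKLDQW", "GWGREEM", "NDGIVNT"),
    direction = c("forward", "reverse", "forward", "reverse"),
    primer = c("WSNWSNAAYTGGGAYMGNGCNTGYGAR", "CCAYTGRTCNARYTTRAARTCRTA",
               "GGNTGGGGNMGNGARGARATG", "NGTRTTNACDATNCCRTCRTT"),
    stringsAsFactors = FALSE
  )
}

#' Build the primer report table for a set of motifs
#'
#' Convenience wrapper: back-translates each motif in the requested
#' direction, optionally tails it, and stacks [primer_report()] rows —
#' the TSV emitted by the `primers` pipeline stage.
#'
#' @param motifs character vector of motif strings (names used as primer
#'   names) or list of `protein_motif`.
#' @param direction `"forward"`, `"reverse"`, or a vector matching `motifs`.
#' @param table codon table.
#' @param tail concrete tail prepended to every primer (default none).
#' @param site,enzyme optional restriction-site annotation.
#' @return data.frame of primer metrics with a `primer` sequence column.
#' @export
design_primers <- function(motifs, direction = "forward", table = codon_table(),
                           tail = "", site = NULL, enzyme = NA_character_) {
  if (!is.list(motifs)) motifs <- as.list(motifs)
  nm <- names(motifs)
  direction <- rep_len(direction, length(motifs))
  rows <- lapply(seq_along(motifs), function(i) {
    m <- protein_motif(motifs[[i]])
    core <- if (direction[i] == "reverse") reverse_primer(m, table)
            else backtranslate(m, table)
    p <- tail_primer(core, tail = tail, site = site, enzyme = enzyme,
                     direction = direction[i],
                     name = if (!is.null(nm) && nzchar(nm[i])) nm[i] else m$residues)
    cbind(primer_report(p),
          motif = m$residues, primer = unclass(p$full),
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
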