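# Conserved-block discovery in pre-aligned protein families: per-column
# plurality conservation, length-based cluster splitting (the short
# B. cereus-like vs long Geobacillus-like molecular-mass split), block
# sharing across clusters, and nucleotide consensus construction.

#' Aligned protein family
#'
#' @param records named character vector (or named list) of aligned
#'   sequences, gaps as `-`; all of equal length, unique ids.
#' @return an `aligned_family` object.
#' @export
aligned_family <- function(records) {
  if (inherits(records, "aligned_family")) return(records)
  recs <- toupper(unlist(records))
  if (is.null(names(recs)) || anyDuplicated(names(recs)))
    stop("records need unique ids (names)")
  w <- unique(nchar(recs))
  if (length(w) != 1L) stop("aligned sequences must all have equal length")
  structure(list(records = recs, n_cols = w, n_seqs = length(recs)),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat("Aligned family: ", x$n_seqs, " sequences x ", x$n_cols, " columns\n", sep = "")
  invisible(x)
}

#' Read an alignment from aligned FASTA or Clustal format
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return `aligned_family`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  s <- as.character(aln)
  aligned_family(s)
}

# character matrix view of the alignment, sequences in rows
.aln_matrix <- function(fam) {
  do.call(rbind, strsplit(unname(fam$records), "", fixed = TRUE))
}

#' Per-column conservation score
#'
#' Frequency of the plurality (most common non-gap) residue in the column,
#' over all sequences: gaps count as mismatches against the plurality
#' residue and can never themselves be the plurality. An all-gap column
#' scores 0.
#'
#' @param fam `aligned_family`.
#' @param col 1-based column index (vectorized).
#' @return numeric score(s) in `[0, 1]`.
#' @export
column_conservation <- function(fam, col) {
  fam <- aligned_family(fam)
  if (any(col < 1L | col > fam$n_cols))
    stop("column out of range 1..", fam$n_cols)
  mat <- .aln_matrix(fam)
  vapply(col, function(j) {
    x <- mat[, j]
    x <- x[x != "-"]
    if (!length(x)) return(0)
    max(table(x)) / fam$n_seqs
  }, 0)
}

# plurality residue per column ("-" only when all-gap)
.plurality_residues <- function(mat) {
  apply(mat, 2L, function(x) {
    x <- x[x != "-"]
    if (!length(x)) return("-")
    names(which.max(table(x)))
  })
}

#' Find conserved blocks in an aligned family
#'
#' Maximal runs of at least `min_len` consecutive columns whose plurality
#' conservation is at least `min_cons` and whose gap fraction is below
#' `1 - min_cons` (blocks must be essentially gap-free). Block motifs are
#' the column plurality residues; blocks are reported left-to-right and are
#' non-overlapping by construction.
#'
#' @param fam `aligned_family`.
#' @param min_len minimum block length in columns (default 7: useful primer
#'   anchors are 7-9 residues).
#' @param min_cons minimum per-column conservation (default 0.8).
#' @param scope label stored on the returned blocks.
#' @return data.frame of class `conserved_blocks` with columns motif,
#'   start, end, conservation, scope.
#' @export
find_conserved_blocks <- function(fam, min_len = 7L, min_cons = 0.8,
                                  scope = NA_character_) {
  fam <- aligned_family(fam)
  if (min_len < 3L) stop("min_len must be >= 3")
  if (min_cons <= 0 || min_cons > 1) stop("min_cons must be in (0, 1]")
  mat <- .aln_matrix(fam)
  cons <- column_conservation(fam, seq_len(fam$n_cols))
  gapfrac <- colMeans(mat == "-")
  ok <- cons >= min_cons & gapfrac < (1 - min_cons + 1e-12)
  plur <- .plurality_residues(mat)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= min_len)
  rows <- lapply(keep, function(k) {
    s <- starts[k]; e <- ends[k]
    data.frame(motif = paste(plur[s:e], collapse = ""),
               start = s, end = e,
               conservation = mean(cons[s:e]),
               scope = scope, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(motif = character(), start = integer(), end = integer(),
                         conservation = numeric(), scope = character(),
                         stringsAsFactors = FALSE)
  class(out) <- c("conserved_blocks", "data.frame")
  out
}

#' Split a family into short and long clusters by ungapped length
#'
#' One-dimensional split at the largest gap between sorted ungapped
#' sequence lengths — the operational form of a molecular-mass split (e.g.
#' 20-35 kDa vs 40-45 kDa lipase clusters). Ties at the split point go to
#' the short cluster. If all lengths are identical the family cannot be
#' split: both elements contain every sequence and `degenerate = TRUE`.
#'
#' @param fam `aligned_family`.
#' @return list with `short` and `long` (each: member_ids, length_range),
#'   `split_at` (largest-gap boundary) and `degenerate` flag.
#' @export
cluster_by_length <- function(fam) {
  fam <- aligned_family(fam)
  if (fam$n_seqs < 2L) stop("need at least 2 sequences")
  len <- nchar(gsub("-", "", fam$records, fixed = TRUE))
  if (length(unique(len)) == 1L) {
    warning("all ungapped lengths identical; returning a single degenerate cluster")
    cl <- list(member_ids = names(len), length_range = range(len))
    return(list(short = cl, long = cl, split_at = NA_real_, degenerate = TRUE))
  }
  o <- order(len)
  sorted <- len[o]
  gaps <- diff(sorted)
  k <- which.max(gaps)                       # first largest gap: ties -> short
  cut <- (sorted[k] + sorted[k + 1L]) / 2
  short_ids <- names(len)[len <= sorted[k]]
  long_ids <- setdiff(names(len), short_ids)
  list(short = list(member_ids = short_ids, length_range = range(len[short_ids])),
       long = list(member_ids = long_ids, length_range = range(len[long_ids])),
       split_at = cut, degenerate = FALSE)
}

#' Identify blocks shared between two clusters
#'
#' Blocks from the two clusters (same alignment coordinates) whose spans
#' agree within `span_tolerance` columns at both ends and whose plurality
#' motifs are identical are re-tagged `shared`; the rest keep a
#' cluster-only scope.
#'
#' @param blocksA,blocksB `conserved_blocks` from [find_conserved_blocks()].
#' @param span_tolerance maximum per-end column slack (default 2).
#' @param labels scope labels for unshared blocks, in order (A, B).
#' @return single `conserved_blocks` data.frame (shared blocks listed once).
#' @export
shared_blocks <- function(blocksA, blocksB, span_tolerance = 2L,
                          labels = c("clusterA-only", "clusterB-only")) {
  matched_b <- logical(nrow(blocksB))
  rows <- list()
  for (i in seq_len(nrow(blocksA))) {
    hit <- 0L
    for (j in seq_len(nrow(blocksB))) {
      if (matched_b[j]) next
      if (abs(blocksA$start[i] - blocksB$start[j]) <= span_tolerance &&
          abs(blocksA$end[i] - blocksB$end[j]) <= span_tolerance &&
          identical(blocksA$motif[i], blocksB$motif[j])) { hit <- j; break }
    }
    r <- blocksA[i, , drop = FALSE]
    if (hit > 0L) {
      matched_b[hit] <- TRUE
      r$scope <- "shared"
      r$conservation <- mean(c(blocksA$conservation[i], blocksB$conservation[hit]))
    } else r$scope <- labels[1L]
    rows[[length(rows) + 1L]] <- r
  }
  for (j in which(!matched_b)) {
    r <- blocksB[j, , drop = FALSE]
    r$scope <- labels[2L]
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$start), , drop = FALSE]
  class(out) <- c("conserved_blocks", "data.frame")
  out
}

#' Nucleotide consensus of equal-length aligned sequences
#'
#' Column-wise consensus: a column is emitted iff its gap frequency is
#' below 0.5; the consensus symbol is the plurality base when its frequency
#' among observed (non-gap) bases reaches `plurality_threshold`, otherwise
#' the IUPAC union of all observed bases.
#'
#' @param aligned_nt character vector of equal-length nucleotide strings
#'   (gaps as `-`).
#' @param plurality_threshold fraction in `(0, 1]` (default 0.6).
#' @return `degenerate_seq` consensus.
#' @export
nucleotide_consensus <- function(aligned_nt, plurality_threshold = 0.6) {
  s <- .normalize_nt(unlist(aligned_nt))
  if (length(s) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(s))) != 1L) stop("sequences must have equal length")
  mat <- do.call(rbind, strsplit(s, "", fixed = TRUE))
  cols <- lapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    if (mean(x == "-") >= 0.5) return(NULL)
    x <- x[x != "-"]
    tab <- sort(table(x), decreasing = TRUE)
    if (tab[1L] / length(x) >= plurality_threshold) names(tab)[1L]
    else iupac_union(names(tab))
  })
  degenerate_seq(paste(unlist(cols), collapse = ""))
}

#' Write conserved blocks as JSON
#'
#' The JSON sidecar consumed by the primer-design stage: one record per
#' block with motif, 1-based span, mean conservation and scope.
#'
#' @param blocks `conserved_blocks`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blocks_json <- function(blocks, path) {
  recs <- lapply(seq_len(nrow(blocks)), function(i) list(
    motif = blocks$motif[i],
    span = c(blocks$start[i], blocks$end[i]),
    conservation = blocks$conservation[i],
    scope = blocks$scope[i]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read conserved blocks from JSON
#'
#' @param path JSON written by [write_blocks_json()].
#' @return `conserved_blocks` data.frame.
#' @export
read_blocks_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- do.call(rbind, lapply(recs, function(r)
    data.frame(motif = r$motif, start = r$span[[1L]], end = r$span[[2L]],
               conservation = r$conservation,
               scope = if (is.null(r$scope)) NA_character_ else r$scope,
               stringsAsFactors = FALSE)))
  class(out) <- c("conserved_blocks", "data.frame")
  out
}
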