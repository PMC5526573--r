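# Seeded synthetic-data generators mirroring the statistical structure each
# analysis stage assumes: two-cluster protein families with planted
# conserved blocks, CCD responses from a known quadratic surface, MM rate
# curves, and first-order thermal-decay series. Every generator returns its
# ground truth alongside the data so round-trip tests can compare against
# planted values.
#
# Seeding contract: one top-level seed; each generator draws from an
# independent substream with seed (seed * 7919 + offset) mod 2^31 - 1,
# offsets msa = 1, ccd = 2, mm = 3, decay = 4. Adding a generator therefore
# never perturbs existing fixtures.

.substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Simulate a two-cluster aligned protein family with planted blocks
#'
#' Emulates a lipase-family alignment that splits into a short cluster
#' (B. cereus-like, ~20-35 kDa) and a long cluster (Geobacillus-like,
#' ~40-45 kDa): a random consensus is drawn per cluster over the columns
#' that cluster occupies, conserved blocks are planted verbatim at fixed
#' columns (scope `"shared"` plants identically in both clusters,
#' `"long-only"` / `"short-only"` in one), every non-block site is mutated
#' i.i.d. at `substitution_rate`, and short-cluster sequences carry a
#' contiguous terminal gap region so the alignment width equals the long
#' ungapped length. The two cluster consensuses are drawn to differ at
#' every shared-occupancy column outside planted blocks, reflecting
#' inter-genus divergence: conserved columns of the mixed family are then
#' exactly the planted shared blocks.
#'
#' @param n_short,n_long sequences per cluster (defaults 6 and 6).
#' @param len_short,len_long ungapped lengths (defaults 210 and 390
#'   residues, i.e. roughly 23 vs 43 kDa).
#' @param planted_blocks data.frame with columns `motif`, `column`
#'   (1-based start), `scope` in shared/short-only/long-only.
#' @param substitution_rate per-site substitution probability outside
#'   blocks, in `[0, 1)` (default 0.1).
#' @param seed top-level seed.
#' @return list: `family` (an [aligned_family()]), `truth` (blocks with
#'   spans, cluster assignment).
#' @export
sim_family <- function(n_short = 6L, n_long = 6L,
                       len_short = 210L, len_long = 390L,
                       planted_blocks = data.frame(
                         motif = c("SSNWDRACE", "YDFKLDQW", "GWGREEM", "NDGIVNT"),
                         column = c(60L, 150L, 230L, 330L),
                         scope = c("shared", "shared", "long-only", "long-only"),
                         stringsAsFactors = FALSE),
                       substitution_rate = 0.1, seed = 1L) {
  if (substitution_rate < 0 || substitution_rate >= 1)
    stop("substitution_rate must be in [0, 1)")
  pb <- planted_blocks
  pb$start <- as.integer(pb$column)
  pb$end <- pb$start + nchar(pb$motif) - 1L
  if (any(pb$end > len_long)) stop("planted block out of range")
  shared_or_short <- pb$scope %in% c("shared", "short-only")
  if (any(pb$end[shared_or_short] > len_short))
    stop("shared/short-only blocks must lie within the short-cluster columns")
  o <- order(pb$start)
  if (any(pb$start[o][-1L] <= pb$end[o][-length(o)]))
    stop("planted blocks overlap")

  set.seed(.substream_seed(seed, 1L))
  width <- len_long
  block_cols_for <- function(scopes) {
    unlist(mapply(function(s, e) s:e, pb$start[pb$scope %in% scopes],
                  pb$end[pb$scope %in% scopes], SIMPLIFY = FALSE))
  }
  make_consensus <- function(occupied_cols, scopes, avoid = NULL) {
    consensus <- rep("-", width)
    consensus[occupied_cols] <- sample(.AA20, length(occupied_cols), replace = TRUE)
    if (!is.null(avoid)) {
      # divergent background: never match the other cluster's consensus
      clash <- occupied_cols[consensus[occupied_cols] == avoid[occupied_cols] &
                             avoid[occupied_cols] != "-"]
      for (j in clash)
        consensus[j] <- sample(setdiff(.AA20, avoid[j]), 1L)
    }
    for (k in which(pb$scope %in% scopes))
      consensus[pb$start[k]:pb$end[k]] <- strsplit(pb$motif[k], "")[[1L]]
    consensus
  }
  make_cluster <- function(n, consensus, occupied_cols, scopes) {
    free <- setdiff(occupied_cols, block_cols_for(scopes))
    t(vapply(seq_len(n), function(i) {
      s <- consensus
      mut <- free[stats::runif(length(free)) < substitution_rate]
      if (length(mut)) s[mut] <- sample(.AA20, length(mut), replace = TRUE)
      s
    }, character(width)))
  }
  cons_short <- make_consensus(seq_len(len_short), c("shared", "short-only"))
  cons_long <- make_consensus(seq_len(len_long), c("shared", "long-only"),
                              avoid = cons_short)
  short_mat <- make_cluster(n_short, cons_short, seq_len(len_short),
                            c("shared", "short-only"))
  long_mat <- make_cluster(n_long, cons_long, seq_len(len_long),
                           c("shared", "long-only"))
  seqs <- c(apply(short_mat, 1L, paste, collapse = ""),
            apply(long_mat, 1L, paste, collapse = ""))
  ids <- c(sprintf("short_%02d", seq_len(n_short)),
           sprintf("long_%02d", seq_len(n_long)))
  names(seqs) <- ids
  list(family = aligned_family(seqs),
       truth = list(
         blocks = pb[, c("motif", "start", "end", "scope")],
         clusters = list(short = ids[seq_len(n_short)],
                         long = ids[n_short + seq_len(n_long)])))
}

#' Simulate CCD responses from a known quadratic surface
#'
#' Adds independent Gaussian noise `N(0, noise_sd^2)` to the true-surface
#' prediction at every design run.
#'
#' @param design `ccd_design` from [generate_ccd()].
#' @param true_model `surface_model` supplying the data-generating
#'   coefficients.
#' @param noise_sd response standard deviation (>= 0).
#' @param seed top-level seed.
#' @param z_name response column name (default `"activity"`).
#' @return the design with a response column appended.
#' @export
sim_ccd <- function(design, true_model, noise_sd = 0, seed = 1L,
                    z_name = "activity") {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(.substream_seed(seed, 2L))
  xn <- attr(design, "x_name") %||% "pH"
  yn <- attr(design, "y_name") %||% "temp_C"
  mu <- predict_surface(true_model, design[[xn]], design[[yn]])
  design[[z_name]] <- mu + stats::rnorm(nrow(design), 0, noise_sd)
  design
}

#' Simulate a Michaelis-Menten rate curve
#'
#' `v = Vmax S / (Km + S)` plus Gaussian noise, absolute
#' (`noise_sd` in rate units) or relative (`noise_sd * v_true`).
#'
#' @param Km,Vmax true parameters (> 0).
#' @param S_grid positive increasing substrate concentrations (mM).
#' @param noise_sd noise standard deviation (default 0).
#' @param relative interpret `noise_sd` as a fraction of the true rate.
#' @param seed top-level seed.
#' @return list: `data` ([kinetic_dataset()]), `truth` (Km, Vmax).
#' @export
sim_mm <- function(Km, Vmax, S_grid, noise_sd = 0, relative = FALSE, seed = 1L) {
  if (Km <= 0 || Vmax <= 0) stop("Km and Vmax must be positive")
  if (length(S_grid) < 2L)
    stop("S_grid too short to support fitting (need >= 2, >= 4 for fit_mm)")
  set.seed(.substream_seed(seed, 3L))
  v_true <- Vmax * S_grid / (Km + S_grid)
  sd_vec <- if (relative) noise_sd * v_true else rep(noise_sd, length(S_grid))
  v <- v_true + stats::rnorm(length(S_grid), 0, sd_vec)
  list(data = kinetic_dataset(S_grid, v), truth = c(Km = Km, Vmax = Vmax))
}

#' Simulate first-order thermal decay
#'
#' `residual = 100 exp(-k t)` plus Gaussian noise, clipped at 0; the
#' time-0 point is pinned at 100%.
#'
#' @param k_per_h decay rate constant (1/h); half-loss time is `ln(2)/k`.
#' @param times hours, increasing from 0.
#' @param noise_sd noise on residual percentage (default 0).
#' @param seed top-level seed.
#' @return list: `series` ([stability_series()]), `truth`
#'   (k, half_life_h).
#' @export
sim_decay <- function(k_per_h, times, noise_sd = 0, seed = 1L) {
  if (k_per_h < 0) stop("decay rate must be non-negative")
  set.seed(.substream_seed(seed, 4L))
  r <- 100 * exp(-k_per_h * times) + stats::rnorm(length(times), 0, noise_sd)
  r <- pmax(r, 0)
  r[times == 0] <- 100
  list(series = stability_series(times, r),
       truth = c(k = k_per_h, half_life_h = log(2) / k_per_h))
}
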