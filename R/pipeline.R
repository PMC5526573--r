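# Pipeline driver binding the stages (motif discovery -> primer design,
# response-surface analysis, kinetics) behind a single configuration, with
# a checksummed artifact manifest so identical config + seed reproduce
# byte-identical outputs.

.known_stage_keys <- list(
  motifs = c("alignment", "format", "min_len", "min_cons", "out"),
  primers = c("motifs", "motifs_json", "direction", "table_id", "tail",
              "site", "enzyme", "out"),
  rsm = c("runs_csv", "x_name", "y_name", "z_name", "out"),
  kinetics = c("csv", "h_threshold", "out")
)

#' Load and validate a pipeline configuration
#'
#' Configurations are YAML (or an equivalent R list) with top-level keys
#' `seed`, `out_dir`, `verbose` and a `stages` block holding any of
#' `motifs`, `primers`, `rsm`, `kinetics`. Unknown keys are rejected so a
#' typo cannot silently disable an option.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list of class `pipeline_config`.
#' @export
load_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  top_ok <- c("seed", "out_dir", "verbose", "stages")
  unknown <- setdiff(names(cfg), top_ok)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$verbose <- as.integer(cfg$verbose %||% 0L)
  for (st in names(cfg$stages)) {
    if (!st %in% names(.known_stage_keys)) stop("unknown stage: ", st)
    bad <- setdiff(names(cfg$stages[[st]]), .known_stage_keys[[st]])
    if (length(bad))
      stop("unknown key(s) in stage '", st, "': ", paste(bad, collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

.log_msg <- function(cfg, ...) if (cfg$verbose > 0) message(...)

#' Run the configured pipeline
#'
#' Executes the configured stages in order motifs -> primers -> rsm ->
#' kinetics, writes each stage's artifact under `out_dir`, and finishes
#' with `manifest.json` listing every output file with its MD5 checksum.
#' Logging (controlled by `verbose`) never alters outputs.
#'
#' @param config path to YAML config or list (see [load_config()]).
#' @return (invisibly) the manifest: list of file/checksum records.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  blocks <- NULL

  st <- cfg$stages$motifs
  if (!is.null(st)) {
    .log_msg(cfg, "stage motifs: ", st$alignment)
    fam <- read_alignment(st$alignment, format = st$format %||% "fasta")
    if (fam$n_seqs == 0L || fam$n_cols == 0L) stop("empty input alignment")
    blocks <- find_conserved_blocks(fam,
                                    min_len = st$min_len %||% 7L,
                                    min_cons = st$min_cons %||% 0.8)
    f <- file.path(cfg$out_dir, st$out %||% "blocks.json")
    write_blocks_json(blocks, f)
    outputs <- c(outputs, f)
  }

  st <- cfg$stages$primers
  if (!is.null(st)) {
    motifs <- st$motifs
    direction <- st$direction %||% "forward"
    if (!is.null(st$motifs_json)) {
      blocks <- read_blocks_json(st$motifs_json)
      motifs <- blocks$motif
    } else if (is.null(motifs) && !is.null(blocks)) motifs <- blocks$motif
    if (is.null(motifs) || !length(motifs)) stop("primers stage has no motifs")
    .log_msg(cfg, "stage primers: ", length(motifs), " motif(s)")
    tab <- design_primers(motifs, direction = direction,
                          table = codon_table(st$table_id %||% "1"),
                          tail = st$tail %||% "", site = st$site,
                          enzyme = st$enzyme %||% NA_character_)
    f <- file.path(cfg$out_dir, st$out %||% "primers.tsv")
    utils::write.table(format_primer_table(tab), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f)
  }

  st <- cfg$stages$rsm
  if (!is.null(st)) {
    .log_msg(cfg, "stage rsm: ", st$runs_csv)
    runs <- utils::read.csv(st$runs_csv, stringsAsFactors = FALSE)
    model <- fit_quadratic(runs, x_name = st$x_name %||% "pH",
                           y_name = st$y_name %||% "temp_C",
                           z_name = st$z_name %||% "activity")
    an <- rsm_anova(model)
    sp <- stationary_point(model)
    res <- list(
      coefficients = as.list(model$coefficients),
      n = model$n, r_squared = model$r_squared,
      adj_r_squared = model$adj_r_squared,
      anova = as.data.frame(an),
      stationary_point = list(x = sp$x_star, y = sp$y_star, z = sp$z_star,
                              nature = sp$nature))
    f <- file.path(cfg$out_dir, st$out %||% "rsm.json")
    jsonlite::write_json(res, f, auto_unbox = TRUE, digits = 6, dataframe = "rows")
    outputs <- c(outputs, f)
  }

  st <- cfg$stages$kinetics
  if (!is.null(st)) {
    .log_msg(cfg, "stage kinetics: ", st$csv)
    kd <- utils::read.csv(st$csv, stringsAsFactors = FALSE)
    scr <- activation_screen(kinetic_dataset(kd$S_mM, kd$v),
                             h_threshold = st$h_threshold %||% 0.3)
    res <- list(Km = scr$mm$Km, Vmax = scr$mm$Vmax,
                se = as.list(scr$mm$se), ssr = scr$mm$ssr,
                activation = scr$verdict, hill_exponent = scr$hill_exponent)
    f <- file.path(cfg$out_dir, st$out %||% "kinetics.json")
    jsonlite::write_json(res, f, auto_unbox = TRUE, digits = 6)
    outputs <- c(outputs, f)
  }

  manifest <- lapply(outputs, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  mf <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  invisible(manifest)
}

#' Format a primer table with stable precision
#'
#' Numeric columns are printed with fixed rules (GC fractions 3 decimals,
#' Tm whole degrees) so written TSVs are byte-stable across platforms.
#'
#' @param tab data.frame from [design_primers()].
#' @return data.frame of characters ready for writing.
#' @export
format_primer_table <- function(tab) {
  out <- tab[, c("name", "direction", "motif", "primer", "length", "degeneracy",
                 "gc_min", "gc_max", "tm_min", "tm_max")]
  out$gc_min <- sprintf("%.3f", tab$gc_min)
  out$gc_max <- sprintf("%.3f", tab$gc_max)
  out$tm_min <- sprintf("%.0f", tab$tm_min)
  out$tm_max <- sprintf("%.0f", tab$tm_max)
  out$degeneracy <- sprintf("%.0f", tab$degeneracy)
  out
}
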