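## run configuration: a flat key-value document (YAML subset), every key
## validated, infinite T serialized as the literal string "inf"

config_defaults <- function() {
  list(kind = "modifier", seed = 1, N = 1000, S = 0, h1 = 0.5, h2 = 0.5,
       hb = 0.5, sigma_BB = 0, t_switch = Inf,
       selection_mode = "absorbing_viability",
       n_generations = 1000, n_replicates = 200,
       init = "hwe", n_copies_a = 1, sweep_kind = "modifier",
       trajectories = FALSE, out_dir = ".", verbose = 1,
       S_grid = NULL, sigma_BB_grid = NULL, t_switch_grid = NULL,
       N_grid = NULL, h1_grid = NULL, h2_grid = NULL, hb_grid = NULL)
}

parse_t_switch <- function(x) {
  if (is.character(x)) {
    if (tolower(x) %in% c("inf", "infinite")) return(Inf)
    x <- suppressWarnings(as.numeric(x))
  }
  x
}

#' Load and validate a run configuration
#'
#' Reads a flat key-value YAML document, fills unspecified keys with the
#' model defaults (N = 1000, all dominance degrees 0.5, horizon 1000
#' generations), and validates every field through [model_params()].
#' Unknown keys are rejected by name. The infinite switch interval is
#' written as the literal string `"inf"`.
#'
#' @param path Path to the config file.
#' @return A validated named list of class `sge_config`.
#' @seealso [write_config()], [cli_main()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) abort("Config must be a key-value document.")
  as_config(raw, source = path)
}

as_config <- function(raw, source = "config") {
  raw$sgesim_version <- NULL # manifests record the version; not a parameter
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s) in %s: %s", source,
                  paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, raw, keep.null = TRUE)
  cfg$t_switch <- parse_t_switch(cfg$t_switch)
  if (!cfg$kind %in% c("fixation", "modifier", "sweep", "symmetric")) {
    abort('`kind` must be one of "fixation", "modifier", "sweep", "symmetric".')
  }
  if (!cfg$init %in% c("hwe", "fixed_A", "fixed_a")) {
    abort('`init` must be one of "hwe", "fixed_A", "fixed_a".')
  }
  if (!cfg$sweep_kind %in% c("modifier", "fixation")) {
    abort('`sweep_kind` must be "modifier" or "fixation".')
  }
  if (cfg$kind == "symmetric") cfg$selection_mode <- "symmetric_fecundity"
  for (g in grep("_grid$", names(cfg), value = TRUE)) {
    if (!is.null(cfg[[g]])) {
      cfg[[g]] <- if (g == "t_switch_grid") {
        vapply(cfg[[g]], parse_t_switch, numeric(1), USE.NAMES = FALSE)
      } else {
        as.numeric(cfg[[g]])
      }
    }
  }
  config_params(cfg) # side effect: validates all scalar fields
  structure(cfg, class = "sge_config")
}

#' @rdname load_config
#' @param config An `sge_config` list.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  if (is.infinite(out$t_switch)) out$t_switch <- "inf"
  if (!is.null(out$t_switch_grid)) {
    out$t_switch_grid <- as.list(unname(ifelse(is.infinite(out$t_switch_grid),
                                               "inf", out$t_switch_grid)))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  yaml::write_yaml(out, path)
  invisible(path)
}

## model_params slice of a config
config_params <- function(cfg) {
  model_params(N = cfg$N, S = cfg$S, h1 = cfg$h1, h2 = cfg$h2, hb = cfg$hb,
               sigma_BB = cfg$sigma_BB, t_switch = cfg$t_switch,
               selection_mode = cfg$selection_mode,
               n_generations = cfg$n_generations,
               n_replicates = cfg$n_replicates, seed = cfg$seed)
}

#' Write and read tab-separated result tables
#'
#' Result tables are plain TSV with `#`-prefixed comment lines carrying
#' run metadata, one row per grid cell (or per generation for
#' trajectories). Numeric columns are written with 6 significant digits —
#' stable to diff across platforms, finer than Monte-Carlo precision.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param comments Character vector of metadata lines (written as
#'   `# <line>`).
#' @return `path`, invisibly (`write_results_tsv`); a tibble
#'   (`read_results_tsv`).
#' @export
write_results_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]])) fmt[[j]] <- formatC(fmt[[j]], digits = 6,
                                                  format = "g")
  }
  write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                       stringsAsFactors = FALSE))
}

## manifest: every resolved parameter plus the seed; deliberately free of
## timestamps so a run is byte-identical given the same command line
write_manifest <- function(cfg, path) {
  out <- unclass(cfg)
  if (is.infinite(out$t_switch)) out$t_switch <- "inf"
  if (!is.null(out$t_switch_grid)) {
    out$t_switch_grid <- as.list(unname(ifelse(is.infinite(out$t_switch_grid),
                                               "inf", out$t_switch_grid)))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  out$sgesim_version <- as.character(packageVersion("sgesim"))
  yaml::write_yaml(out, path)
  invisible(path)
}
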