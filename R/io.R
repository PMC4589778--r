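# Configuration and result serialization. All outputs are deterministic
# plain text: headered CSV tables, JSON metadata, 0/1 grid files and
# optional PGM images.

.config_defaults <- function() {
  list(L = 100, b = 1.1, s = 0.5, K = 0.1, P_pd = 0.2, P_sd = -0.2,
       noise_prob = 0.1, noise_mode = "set", relax = 20000, avg = 2000,
       record_every = 1, runs = 10, seed = 1, init = "random",
       block_side = NULL, output_dir = ".")
}

#' Load and validate a simulation configuration
#'
#' Reads an optional JSON document, applies `...` overrides on top of the
#' package defaults, validates every field with an error naming the field,
#' and splits the result into game parameters and run configuration.
#'
#' @param path optional path to a JSON configuration file.
#' @param ... named overrides of individual fields (e.g. `b = 1.2`,
#'   `runs = 30`).
#' @return A list with `params` (an [game_params()]) and `config` (a list of
#'   class `"idg_config"` with the run fields).
#' @export
load_config <- function(path = NULL, ...) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown))
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots

  # field-by-field validation with named errors
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid '", field, "': ", msg, call. = FALSE)
  chk(is.numeric(cfg$L) && cfg$L >= 3, "L", "must be >= 3")
  chk(is.numeric(cfg$b) && cfg$b > 1 && cfg$b <= 2, "b",
      "must satisfy 1 < b <= 2")
  chk(is.numeric(cfg$s) && cfg$s >= 0 && cfg$s <= 1, "s",
      "must lie in [0, 1]")
  chk(is.numeric(cfg$K) && cfg$K > 0, "K", "must be > 0")
  chk(is.numeric(cfg$noise_prob) && cfg$noise_prob >= 0 &&
        cfg$noise_prob <= 1, "noise_prob", "must lie in [0, 1]")
  chk(cfg$noise_mode %in% .noise_modes, "noise_mode",
      paste("must be one of", paste(.noise_modes, collapse = ", ")))
  chk(is.numeric(cfg$relax) && cfg$relax >= 0, "relax", "must be >= 0")
  chk(is.numeric(cfg$avg) && cfg$avg >= 0, "avg", "must be >= 0")
  chk(is.numeric(cfg$record_every) && cfg$record_every >= 1, "record_every",
      "must be >= 1")
  chk(is.numeric(cfg$runs) && cfg$runs >= 1, "runs", "must be >= 1")
  chk(is.numeric(cfg$seed), "seed", "must be an integer")
  chk(cfg$init %in% c("random", "block"), "init",
      "must be 'random' or 'block'")
  if (!is.null(cfg$block_side))
    chk(cfg$block_side > 0 && cfg$block_side <= cfg$L, "block_side",
        "must satisfy 0 < block_side <= L")

  params <- game_params(b = cfg$b, s = cfg$s, K = cfg$K, P_pd = cfg$P_pd,
                        P_sd = cfg$P_sd, noise_prob = cfg$noise_prob,
                        noise_mode = cfg$noise_mode)
  config <- cfg[c("L", "relax", "avg", "record_every", "runs", "seed",
                  "init", "block_side", "output_dir")]
  class(config) <- "idg_config"
  list(params = params, config = config)
}

#' Write a configuration to JSON
#'
#' The written file round-trips: `load_config(write_config(...))` restores
#' the same parameters and configuration.
#'
#' @param params an [game_params()] object.
#' @param config an `"idg_config"` list (as returned by [load_config()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, config, path) {
  cfg <- c(unclass(config)[c("L", "relax", "avg", "record_every", "runs",
                             "seed", "init", "block_side", "output_dir")],
           list(b = params$b, s = params$s, K = params$K,
                P_pd = params$P_pd, P_sd = params$P_sd,
                noise_prob = params$noise_prob,
                noise_mode = params$noise_mode))
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a strategy grid as plain text
#'
#' Row-major, one line per lattice row, entries space-separated,
#' `1` = cooperator, `0` = defector.
#'
#' @param grid a 0/1 integer matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  lines <- apply(grid, 1, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' Read a strategy grid written by [write_grid()]
#'
#' @param path input file path.
#' @return A 0/1 integer matrix.
#' @export
read_grid <- function(path) {
  rows <- strsplit(readLines(path), " ", fixed = TRUE)
  out <- do.call(rbind, lapply(rows, as.integer))
  storage.mode(out) <- "integer"
  out
}

#' Write a grid as a portable graymap (PGM) image
#'
#' Plain (P2) format; cooperators white, defectors black.
#'
#' @param grid a 0/1 integer matrix.
#' @param path output file path (conventionally `.pgm`).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(grid), nrow(grid)), "1"), con)
  writeLines(apply(grid, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Write experiment results to a directory
#'
#' Serializes sweeps, phase diagrams, time courses, snapshot series and
#' single runs as headered CSV tables, JSON metadata and plain-text grids.
#' Re-running with an identical object reproduces identical files.
#'
#' @param x a result object (`idg_sweep`, `idg_phase`, `idg_timecourse`,
#'   `idg_snapshots` or `idg_run`).
#' @param output_dir directory to write into (created if needed).
#' @param ... passed to methods.
#' @return The paths written, invisibly.
#' @export
write_results <- function(x, output_dir = ".", ...) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  UseMethod("write_results")
}

#' @export
write_results.idg_sweep <- function(x, output_dir = ".", ...) {
  axis <- attr(x, "axis")
  long <- do.call(rbind, lapply(c("SD", "PD"), function(ly) {
    suf <- switch(ly, SD = "sd", PD = "pd")
    data.frame(x = x[[axis]], layer = ly,
               fc = x[[paste0("fc_", suf)]], se = x[[paste0("se_", suf)]],
               phase = x[[paste0("phase_", suf)]])
  }))
  names(long)[1] <- axis
  long <- long[order(long[[axis]]), ]
  csv <- file.path(output_dir, paste0("sweep_", axis, ".csv"))
  write.csv(long, csv, row.names = FALSE)
  meta <- file.path(output_dir, paste0("sweep_", axis, "_meta.json"))
  jsonlite::write_json(c(attr(x, "config"),
                         list(axis = axis, fixed = attr(x, "fixed"),
                              package_version =
                                as.character(utils::packageVersion("idnetgame")))),
                       meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, meta))
}

#' @export
write_results.idg_phase <- function(x, output_dir = ".", ...) {
  grid <- expand.grid(b = x$b, s = x$s, KEEP.OUT.ATTRS = FALSE)
  long <- data.frame(grid,
                     fc_sys = as.vector(x$fc_sys),
                     fc_sd = as.vector(x$fc_sd),
                     fc_pd = as.vector(x$fc_pd),
                     phase_sd = as.vector(x$phase_sd),
                     phase_pd = as.vector(x$phase_pd))
  csv <- file.path(output_dir, "phase_diagram.csv")
  write.csv(long, csv, row.names = FALSE)
  meta <- file.path(output_dir, "phase_diagram_meta.json")
  jsonlite::write_json(x$config, meta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, meta))
}

#' @export
write_results.idg_timecourse <- function(x, output_dir = ".", ...) {
  csv <- file.path(output_dir, "timecourse.csv")
  write.csv(as.data.frame(x), csv, row.names = FALSE)
  meta <- file.path(output_dir, "timecourse_meta.json")
  jsonlite::write_json(list(b = attr(x, "b"), s = attr(x, "s"),
                            L = attr(x, "L"), seed = attr(x, "seed")),
                       meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, meta))
}

#' @export
write_results.idg_snapshots <- function(x, output_dir = ".", pgm = FALSE,
                                        ...) {
  paths <- character(0)
  for (i in seq_along(x$times)) {
    t <- x$times[i]
    for (ly in c("sd", "pd")) {
      p <- file.path(output_dir, sprintf("snap_%06d_%s.txt", t, ly))
      write_grid(x$states[[i]][[ly]], p)
      paths <- c(paths, p)
      if (pgm) {
        pp <- file.path(output_dir, sprintf("snap_%06d_%s.pgm", t, ly))
        write_pgm(x$states[[i]][[ly]], pp)
        paths <- c(paths, pp)
      }
    }
  }
  meta <- file.path(output_dir, "snapshots_meta.json")
  jsonlite::write_json(list(times = x$times, b = x$b, s = x$s, L = x$L,
                            block_side = x$block_side, seed = x$seed),
                       meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, meta))
}

#' @export
write_results.idg_run <- function(x, output_dir = ".", ...) {
  csv <- file.path(output_dir, "run_timeseries.csv")
  write.csv(x$ts, csv, row.names = FALSE)
  g1 <- file.path(output_dir, "final_sd.txt")
  g2 <- file.path(output_dir, "final_pd.txt")
  write_grid(x$final$sd, g1)
  write_grid(x$final$pd, g2)
  meta <- file.path(output_dir, "run_meta.json")
  jsonlite::write_json(list(L = x$L, relax = x$relax, avg = x$avg,
                            seed = x$seed, init = x$init,
                            b = x$params$b, s = x$params$s, K = x$params$K,
                            P_pd = x$params$P_pd, P_sd = x$params$P_sd,
                            noise_prob = x$params$noise_prob,
                            noise_mode = x$params$noise_mode),
                       meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, g1, g2, meta))
}
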