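## Configuration loading/validation and file output, shared by the R API and
## the command-line interface. Every written artifact gets a JSON metadata
## sidecar (package version, seed, content checksum).

pfl_config_defaults <- function() {
  list(parameters = list(k1f = 1, k2f = 1, k3f = 1,
                         k1r = 0.1, k2r = 0.1, k3r = 0.1, n = 2),
       feedback = list(mode = "ramp", tau_F = 14, F_max = 1,
                       S_threshold = NULL, breakpoints = NULL),
       mapping = list(sigma = 5e-5, exponent = 2),
       solver = list(rtol = 1e-8, atol = 1e-10),
       seed = 1)
}

.config_blocks <- c("parameters", "schedule", "feedback", "mapping", "solver",
                    "seed", "protocol", "bifurcation", "treatment", "phase",
                    "fit", "quantify", "synth")

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
}

merge_defaults <- function(given, defaults) {
  for (nm in names(defaults))
    if (is.null(given[[nm]])) given[nm] <- defaults[nm]
  given
}

#' Normalize a configuration list
#'
#' Fills documented defaults into the standard blocks (`parameters`,
#' `feedback`, `mapping`, `solver`, `seed`), validates value ranges and
#' rejects unknown keys. Normalization is idempotent:
#' `normalize_pfl_config(normalize_pfl_config(x))` equals
#' `normalize_pfl_config(x)`.
#'
#' @param cfg A named list (e.g. parsed from JSON).
#' @return The normalized configuration list.
#' @export
normalize_pfl_config <- function(cfg) {
  if (!is.list(cfg)) stop("configuration must be a named list", call. = FALSE)
  defs <- pfl_config_defaults()
  check_keys(cfg, .config_blocks, "configuration")
  cfg$parameters <- merge_defaults(cfg$parameters, defs$parameters)
  check_keys(cfg$parameters, names(defs$parameters), "'parameters'")
  cfg$feedback <- merge_defaults(cfg$feedback, defs$feedback)
  check_keys(cfg$feedback, names(defs$feedback), "'feedback'")
  cfg$mapping <- merge_defaults(cfg$mapping, defs$mapping)
  check_keys(cfg$mapping, names(defs$mapping), "'mapping'")
  cfg$solver <- merge_defaults(cfg$solver, defs$solver)
  check_keys(cfg$solver, names(defs$solver), "'solver'")
  if (is.null(cfg$seed)) cfg$seed <- defs$seed
  ## value validation via the constructors
  do.call(pfl_params, cfg$parameters)
  do.call(stiffness_mapping, cfg$mapping)
  build_feedback(cfg$feedback)
  if (!is.null(cfg$schedule)) {
    segs <- as.data.frame(cfg$schedule)
    pfl_schedule(segs, feedback = build_feedback(cfg$feedback),
                 mapping = do.call(stiffness_mapping, cfg$mapping))
  }
  cfg
}

build_feedback <- function(fb) {
  if (identical(fb$mode, "explicit")) {
    bp <- fb$breakpoints
    if (is.null(bp)) stop("explicit feedback needs 'breakpoints'", call. = FALSE)
    feedback_explicit(as.numeric(bp$times), as.numeric(bp$values))
  } else if (identical(fb$mode, "ramp")) {
    feedback_ramp(tau_F = fb$tau_F, F_max = fb$F_max,
                  S_threshold = fb$S_threshold)
  } else stop("feedback mode must be 'ramp' or 'explicit'", call. = FALSE)
}

#' Load and validate a configuration file
#'
#' Reads a JSON configuration, injects defaults, validates it (unknown keys
#' and out-of-range values are rejected) and builds the model objects.
#'
#' @param path Path to a JSON file, or a named list already in memory.
#' @return An object of class `pfl_config`: list with the normalized `raw`
#'   configuration plus built `params`, `mapping`, `feedback`, `schedule`
#'   (or `NULL`), `solver` and `seed`.
#' @export
load_pfl_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else path
  cfg <- normalize_pfl_config(cfg)
  params <- do.call(pfl_params, cfg$parameters)
  mapping <- do.call(stiffness_mapping, cfg$mapping)
  feedback <- build_feedback(cfg$feedback)
  schedule <- if (!is.null(cfg$schedule))
    pfl_schedule(as.data.frame(cfg$schedule), feedback = feedback,
                 mapping = mapping)
  structure(list(raw = cfg, params = params, mapping = mapping,
                 feedback = feedback, schedule = schedule,
                 solver = cfg$solver, seed = cfg$seed),
            class = "pfl_config")
}

#' @rdname load_pfl_config
#' @param cfg A `pfl_config` or normalized configuration list.
#' @param path Output path for the JSON file.
#' @export
write_pfl_config <- function(cfg, path) {
  raw <- if (inherits(cfg, "pfl_config")) cfg$raw else normalize_pfl_config(cfg)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

write_meta_sidecar <- function(path, seed = NULL, extra = list()) {
  meta <- c(list(package = "mechanopfl",
                 version = as.character(utils::packageVersion("mechanopfl")),
                 seed = seed,
                 md5 = unname(tools::md5sum(path))), extra)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Writes the exact column set `t,C_I,C_P,C_a,S,F,u_I,u_P`, one row per grid
#' point, floats at 10 significant digits, plus a `.meta.json` sidecar.
#'
#' @param trajectory A `pfl_trajectory`.
#' @param path Output CSV path.
#' @param seed Seed recorded in the sidecar (if any).
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, seed = NULL) {
  cols <- c("t", "C_I", "C_P", "C_a", "S", "F", "u_I", "u_P")
  df <- as.data.frame(trajectory)[, cols]
  fm <- vapply(seq_len(nrow(df)), function(i)
    paste(signif(unlist(df[i, ]), 10), collapse = ","), "")
  writeLines(c(paste(cols, collapse = ","), fm), path)
  write_meta_sidecar(path, seed)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write a bifurcation diagram to JSON and CSV
#'
#' The JSON carries `axis`, `values`, per-value `fixed_points` (state and
#' stability) and `folds`; the CSV is the flat table
#' `param,C_I,C_P,C_a,stability`.
#'
#' @param bd A `pfl_bifurcation`.
#' @param json_path,csv_path Output paths (`NULL` to skip one format).
#' @param seed Seed recorded in the sidecars.
#' @return Invisibly, the written paths.
#' @export
write_bifurcation <- function(bd, json_path = NULL, csv_path = NULL,
                              seed = NULL) {
  stopifnot(inherits(bd, "pfl_bifurcation"))
  if (!is.null(json_path)) {
    fp_by_val <- lapply(bd$values, function(v) {
      sub <- bd$points[abs(bd$points$param - v) < 1e-12, , drop = FALSE]
      lapply(seq_len(nrow(sub)), function(i)
        list(state = unname(unlist(sub[i, c("C_I", "C_P", "C_a")])),
             stability = sub$stability[i]))
    })
    jsonlite::write_json(list(axis = bd$axis, values = bd$values,
                              fixed_points = fp_by_val, folds = bd$folds),
                         json_path, auto_unbox = TRUE, digits = NA)
    write_meta_sidecar(json_path, seed)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(bd$points, csv_path, row.names = FALSE, quote = FALSE)
    write_meta_sidecar(csv_path, seed)
  }
  invisible(c(json_path, csv_path))
}

#' Write a phase diagram to JSON and CSV
#'
#' JSON: `x_name`, `y_name`, `x_values`, `y_values`, row-major `labels` and
#' `final_Ca`. CSV: long format `x,y,label,final_Ca`.
#'
#' @param pd A `pfl_phase`.
#' @param json_path,csv_path Output paths (`NULL` to skip one format).
#' @param seed Seed recorded in the sidecars.
#' @return Invisibly, the written paths.
#' @export
write_phase <- function(pd, json_path = NULL, csv_path = NULL, seed = NULL) {
  stopifnot(inherits(pd, "pfl_phase"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(x_name = pd$x_name, y_name = pd$y_name,
           x_values = pd$x_values, y_values = pd$y_values,
           labels = as.vector(t(pd$labels)),
           final_Ca = as.vector(t(pd$final_Ca))),
      json_path, auto_unbox = TRUE, digits = NA)
    write_meta_sidecar(json_path, seed)
  }
  if (!is.null(csv_path)) {
    long <- expand.grid(y = pd$y_values, x = pd$x_values,
                        KEEP.OUT.ATTRS = FALSE)[, c("x", "y")]
    long$label <- as.vector(t(pd$labels))
    long$final_Ca <- as.vector(t(pd$final_Ca))
    names(long)[1:2] <- c(pd$x_name, pd$y_name)
    utils::write.csv(long, csv_path, row.names = FALSE, quote = FALSE)
    write_meta_sidecar(csv_path, seed)
  }
  invisible(c(json_path, csv_path))
}
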