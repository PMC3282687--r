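# Configuration, archive serialization, seed fan-out and test fixtures.

#' Deterministic per-phase child seeds
#'
#' A single run seed fans out to one child seed per named phase through a
#' fixed linear-congruential rule, so each subsystem (random phase, GA,
#' fixtures) is independently reproducible. Child seeds stay below 2^31.
#'
#' @param seed Integer run seed.
#' @param labels Character vector of phase names.
#' @return Named integer vector of child seeds.
#' @export
derive_seeds <- function(seed, labels) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  base <- abs(as.numeric(seed)) %% 2147483647
  s <- vapply(seq_along(labels), function(k)
    as.integer((base * 48271 + k * 1664525) %% 2147483646 + 1), integer(1))
  setNames(s, labels)
}

# ---- archive serialization -------------------------------------------------

.archive_format_version <- 1L

#' Save / load a solution archive
#'
#' JSON round trip preserving full double precision (parameter values are
#' bitwise identical after `save_archive()` then `load_archive()`). A file
#' whose format version does not match the package's is rejected; truncated
#' or malformed files raise a parse error rather than a partial archive. On
#' load, every entry's stored period and amplitude are re-checked against
#' the stored config's fitness windows.
#'
#' @param archive A `solution_archive` from [run_tps()].
#' @param path File path (`.json`).
#' @return `save_archive` returns `path` invisibly; `load_archive` returns
#'   the archive.
#' @export
save_archive <- function(archive, path) {
  stopifnot(inherits(archive, "solution_archive"))
  x <- unclass(archive)
  x$format_version <- .archive_format_version
  x$config <- unclass(x$config)
  x$entries <- lapply(x$entries, function(e) {
    e$params <- as.list(e$params)
    e$mean_levels <- as.list(e$mean_levels)
    e
  })
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_archive
#' @export
load_archive <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$format_version) ||
      x$format_version != .archive_format_version)
    stop("archive format version mismatch", call. = FALSE)
  num1 <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  cfg <- x$config
  cfg <- lapply(cfg, function(v)
    if (is.list(v)) unlist(v) else v)
  cfg$y_stratum <- if (is.null(cfg$y_stratum)) NULL else as.numeric(cfg$y_stratum)
  config <- do.call(search_config, cfg[names(cfg) %in%
                                         names(formals(search_config))])
  entries <- lapply(x$entries, function(e) {
    e$params <- unlist(e$params)
    e$mean_levels <- unlist(e$mean_levels)
    for (nm in c("period", "amplitude", "period_cv", "amplitude_cv",
                 "total_y", "gamma"))
      e[[nm]] <- num1(e[[nm]])
    e$n_peaks <- as.integer(e$n_peaks)
    e$generation <- as.integer(e$generation)
    e$phase <- as.character(e$phase)
    e
  })
  for (e in entries) {
    if (is.finite(e$period) &&
        (e$period < config$period_window[1] - 1e-9 ||
         e$period > config$period_window[2] + 1e-9 ||
         e$amplitude < config$amplitude_window[1] - 1e-9 ||
         e$amplitude > config$amplitude_window[2] + 1e-9))
      stop("archive entry violates the stored fitness windows", call. = FALSE)
  }
  structure(list(architecture = as.character(x$architecture),
                 config = config, entries = entries,
                 seed = as.integer(x$seed),
                 n_evaluated = as.integer(x$n_evaluated),
                 generations = as.integer(x$generations)),
            class = "solution_archive")
}

#' Export an archive as a flat CSV of parameters and features
#'
#' One row per accepted parameter set; numbers are written with 17
#' significant digits (documented lossy relative to the JSON archive).
#'
#' @param archive A `solution_archive`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_archive_csv <- function(archive, path) {
  df <- as.data.frame(archive)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Re-validate archive entries by re-simulation
#'
#' Re-simulates `k` randomly chosen entries from their stored parameters and
#' checks that each reproduces a sustained oscillation with period and
#' amplitude inside the archive's fitness windows.
#'
#' @param archive A `solution_archive`.
#' @param k Number of entries to spot-check.
#' @return `TRUE` (invisibly) or an error describing the failing entry.
#' @export
validate_archive <- function(archive, k = 3) {
  stopifnot(inherits(archive, "solution_archive"))
  model <- clock_model(archive$architecture)
  cfg <- archive$config
  idx <- sample(length(archive$entries), min(k, length(archive$entries)))
  for (i in idx) {
    p <- archive$entries[[i]]$params
    traj <- integrate_clock(model, params = p, horizon = cfg$horizon,
                            dt = cfg$dt, transient = cfg$transient,
                            record_from = cfg$transient)
    f <- oscillation_features(traj, model, min_peaks = cfg$min_peaks,
                              period_cv_max = cfg$period_cv_max,
                              amplitude_cv_max = cfg$amplitude_cv_max)
    if (!f$sustained ||
        f$period < cfg$period_window[1] || f$period > cfg$period_window[2] ||
        f$amplitude < cfg$amplitude_window[1] ||
        f$amplitude > cfg$amplitude_window[2])
      stop(sprintf("entry %d failed re-simulation", i), call. = FALSE)
  }
  invisible(TRUE)
}

# ---- run configuration -----------------------------------------------------

.run_config_keys <- c("model", "seed", "search", "qmps", "entrainment", "out")

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration with keys `model` (architecture name),
#' `seed`, `search` (any [search_config()] argument), `qmps` (`delta`,
#' `targets`), `entrainment` (`zeta`, `delta` grids as `from`/`to`/`n`,
#' `cycles`, `discard`) and `out` (output paths). Unknown keys, unknown
#' architecture names, and attempts to search the fixed Hill coefficient are
#' rejected with an error naming the key. Omitted settings take the package
#' defaults (0.1-10 fold bounds, 23-25 h and 2-6 nM windows, QMPS delta
#' 0.001).
#'
#' @param path Path to a `.yml`/`.yaml` or `.json` file.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_run_config(raw)
}

#' @rdname load_run_config
#' @param x A named list with the schema of `load_run_config()`.
#' @export
as_run_config <- function(x) {
  stopifnot(is.list(x))
  unknown <- setdiff(names(x), .run_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  model <- x$model %||% "single"
  if (!model %in% architectures())
    stop("unknown model: ", model, call. = FALSE)
  search <- as.list(x$search %||% list())
  bad <- intersect(names(search), c("h", "hill_coefficient"))
  if (length(bad) == 0 && !is.null(search$searched))
    if (any(c("h", "hill_coefficient") %in% unlist(search$searched)))
      bad <- "searched"
  if (length(bad))
    stop("the Hill coefficient is fixed and cannot be searched (key: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  search$searched <- NULL
  unknown_s <- setdiff(names(search), names(formals(search_config)))
  if (length(unknown_s))
    stop("unknown search key(s): ", paste(unknown_s, collapse = ", "),
         call. = FALSE)
  if (!is.null(x$seed)) search$seed <- as.integer(x$seed)
  qm <- modifyList(list(delta = 0.001, targets = c("period", "amplitude")),
                   as.list(x$qmps %||% list()))
  if (qm$delta <= 0 || qm$delta > 0.01)
    stop("qmps delta must lie in (0, 0.01]", call. = FALSE)
  ent <- modifyList(list(zeta = list(from = 16, to = 32, n = 33),
                         delta = list(from = 0.1, to = 1, n = 33),
                         cycles = 80, discard = 40),
                    as.list(x$entrainment %||% list()))
  structure(list(model = model,
                 seed = as.integer(x$seed %||% search$seed %||% 1L),
                 search = do.call(search_config, search),
                 qmps = qm, entrainment = ent,
                 out = x$out %||% list()),
            class = "run_config")
}

#' Save a run configuration
#'
#' @param config A `run_config`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$search <- unclass(x$search)
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- cached test fixture ---------------------------------------------------

#' One known-good oscillating parameter set per architecture
#'
#' Runs a small two-phase search to produce a single accepted parameter set
#' for unit tests and examples; the result is cached on disk keyed by
#' architecture, rho, seed and archive format version, so repeated calls are
#' instant and identical.
#'
#' @param architecture One of [architectures()].
#' @param seed Integer seed.
#' @param rho Kinetic symmetry (dual/redundant only).
#' @param cache_dir Cache directory (created if needed).
#' @return List with `params` (named vector) and `entry` (the full archive
#'   entry, including features).
#' @export
fixture_oscillator <- function(architecture = architectures(), seed = 1,
                               rho = 99,
                               cache_dir = file.path(tempdir(),
                                                     "clockloops-cache")) {
  architecture <- match.arg(architecture)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  key <- sprintf("fixture_%s_rho%s_seed%d_v%d.json", architecture,
                 gsub("[^0-9a-zA-Z.]", "-", format(rho)), seed,
                 .archive_format_version)
  path <- file.path(cache_dir, key)
  if (file.exists(path)) {
    arc <- load_archive(path)
  } else {
    cfg <- search_config(rho = rho, n_solutions = 1, random_trials = 400,
                         pop_size = 40, max_generations = 60, seed = seed)
    arc <- suppressWarnings(run_tps(clock_model(architecture), cfg))
    if (!length(arc$entries))
      stop(sprintf("fixture search failed for '%s' (seed %d)",
                   architecture, seed), call. = FALSE)
    save_archive(arc, path)
  }
  entry <- arc$entries[[1]]
  list(params = entry$params, entry = entry)
}
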