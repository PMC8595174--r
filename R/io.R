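# ---- result cache -----------------------------------------------------------
# Growth simulations and pore sweeps dominate the pipeline cost; results are
# memoised in-session by a content key over all inputs, and optionally on disk
# (options(scaffopt.cache_dir = ...)).

.cache_env <- new.env(parent = emptyenv())

.cache_key <- function(...) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(list(...), tf, version = 2)
  unname(tools::md5sum(tf))
}

.cached <- function(..., compute) {
  key <- .cache_key(...)
  hit <- .cache_env[[key]]
  if (!is.null(hit)) return(hit)
  dir <- getOption("scaffopt.cache_dir", NULL)
  if (!is.null(dir)) {
    f <- file.path(dir, paste0(key, ".rds"))
    if (file.exists(f)) {
      val <- readRDS(f)
      assign(key, val, envir = .cache_env)
      return(val)
    }
  }
  val <- compute()
  assign(key, val, envir = .cache_env)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(val, file.path(dir, paste0(key, ".rds")))
  }
  val
}

#' Clear the in-session result cache
#' @return Invisibly, the number of entries dropped.
#' @export
clear_cache <- function() {
  n <- length(ls(.cache_env))
  rm(list = ls(.cache_env), envir = .cache_env)
  invisible(n)
}

# ---- voxel-grid files -------------------------------------------------------

#' Write a voxel grid to an NRRD file
#'
#' Plain-text (ascii-encoded) NRRD with the occupancy as uint8 and the
#' physical spacing and origin carried in the header at full precision.
#'
#' @param grid A [voxel_grid()].
#' @param path Output path (conventionally `.nrrd`).
#' @return Invisibly, `path`.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$occupancy)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "type: uint8",
           "dimension: 3",
           paste("sizes:", paste(d, collapse = " ")),
           sprintf("spacings: %.17g %.17g %.17g",
                   grid$spacing, grid$spacing, grid$spacing),
           "encoding: ascii",
           sprintf("origin mm:=%.17g %.17g %.17g",
                   grid$origin[1], grid$origin[2], grid$origin[3]),
           "")
  writeLines(hdr, con)
  vals <- as.integer(grid$occupancy)
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' Read a voxel grid from an NRRD file written by [write_grid()]
#'
#' @param path File path.
#' @return A [voxel_grid()].
#' @export
read_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2 || !startsWith(lines[1], "NRRD"))
    stop("not an NRRD file: ", path)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("corrupt NRRD header (no blank separator): ", path)
  hdr <- lines[2:(blank - 1)]
  get_field <- function(name) {
    hit <- grep(paste0("^", name, ":"), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", name, ":=?\\s*"), "", hit[1])
  }
  dim_n <- as.integer(get_field("dimension"))
  if (!identical(dim_n, 3L))
    stop("expected a 3-D grid, file declares dimension ", dim_n)
  sizes <- as.integer(strsplit(trimws(get_field("sizes")), "\\s+")[[1]])
  spac <- as.numeric(strsplit(trimws(get_field("spacings")), "\\s+")[[1]])
  origin <- get_field("origin mm")
  origin <- if (is.null(origin)) c(0, 0, 0)
            else as.numeric(strsplit(trimws(origin), "\\s+")[[1]])
  vals <- as.integer(strsplit(trimws(paste(lines[(blank + 1):length(lines)],
                                           collapse = " ")), "\\s+")[[1]])
  if (length(vals) != prod(sizes))
    stop("corrupt NRRD data: expected ", prod(sizes), " values, found ",
         length(vals))
  voxel_grid(array(vals != 0L, dim = sizes), spacing = spac[1], origin = origin)
}

# ---- configuration ----------------------------------------------------------

.default_config_list <- function() {
  list(
    types = tpms_types(),
    cell_size = 1,
    seed = 1L,
    pore = list(d_lo = 100, d_hi = 400, resolution = 60, tiling = 3),
    stiffness = list(E = 1.8e9, D = 30, L = 30, k_lo = 1000, k_hi = 2700),
    growth = list(dt = 1e-4, lambda_coef = 1, max_days = 21,
                  fill_threshold = 0.005, redistance_interval = 25,
                  resolution = 64),
    optimise = list(vf_min = 0.2, vf_max = 0.9, vf_step = 0.05,
                    window_source = "intersection",
                    manual_windows = NULL))
}

.merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", paste0(path, nm))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration block ", paste0(path, nm), " must be a mapping")
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]],
                                  paste0(path, nm, "."))
    } else if (is.null(user[[nm]])) {
      base[nm] <- list(NULL)   # keep explicit NULLs instead of deleting
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

.validate_config_list <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("configuration error: ", msg)
  chk(all(tolower(cfg$types) %in% tpms_types()),
      paste("types must be among", paste(tpms_types(), collapse = ", ")))
  chk(cfg$cell_size > 0, "cell_size must be > 0")
  chk(cfg$pore$d_lo > 0 && cfg$pore$d_hi > cfg$pore$d_lo,
      "pore limits need 0 < d_lo < d_hi")
  chk(cfg$pore$resolution >= 8, "pore.resolution must be >= 8")
  chk(cfg$stiffness$k_lo >= 0 && cfg$stiffness$k_hi > cfg$stiffness$k_lo,
      "stiffness limits need 0 <= k_lo < k_hi")
  chk(all(c(cfg$stiffness$E, cfg$stiffness$D, cfg$stiffness$L) > 0),
      "stiffness constants must be positive")
  chk(cfg$growth$dt > 0, "growth.dt must be > 0")
  chk(cfg$growth$lambda_coef > 0, "growth.lambda_coef must be > 0")
  chk(cfg$optimise$vf_min >= 0.2 - 1e-9 && cfg$optimise$vf_max <= 0.9 + 1e-9 &&
        cfg$optimise$vf_min < cfg$optimise$vf_max,
      "optimise VF range must lie within [0.2, 0.9]")
  chk(cfg$optimise$window_source %in%
        c("intersection", "pore", "stiffness", "manual"),
      "optimise.window_source must be intersection/pore/stiffness/manual")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Missing fields are filled with the package defaults (1 mm unit cell,
#' 100-400 um pore limits, 1000-2700 N/mm stiffness window with E = 1.8 GPa
#' and D = L = 30 mm, dimensionless growth step 1e-4, 21-day horizon). Unknown
#' keys raise an error naming them. An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path.
#' @return A `scaffopt_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(.default_config_list(), user)
  cfg$types <- tolower(cfg$types)
  .validate_config_list(cfg)
  structure(cfg, class = "scaffopt_config")
}

#' Default pipeline configuration
#'
#' @param ... Named overrides merged into the defaults (nested lists allowed).
#' @return A `scaffopt_config` list.
#' @export
default_config <- function(...) {
  over <- list(...)
  cfg <- .merge_config(.default_config_list(), over)
  cfg$types <- tolower(cfg$types)
  .validate_config_list(cfg)
  structure(cfg, class = "scaffopt_config")
}

#' Save a configuration to YAML
#'
#' @param config A `scaffopt_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# ---- run manifest -----------------------------------------------------------

#' Write a run manifest
#'
#' Records the configuration snapshot, package version, random seed and
#' per-stage content hashes so a report can be reproduced byte-identically.
#'
#' @param config A `scaffopt_config`.
#' @param path Output YAML path.
#' @param seed Random seed used for the run.
#' @param hashes Optional named character vector of per-stage content hashes.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(config, path, seed = config$seed, hashes = NULL) {
  man <- list(package = "scaffopt",
              version = as.character(utils::packageVersion("scaffopt")),
              seed = as.integer(seed),
              config = unclass(config),
              hashes = as.list(hashes),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(man, path)
  invisible(man)
}

#' Read a run manifest
#' @param path Manifest YAML path.
#' @return The manifest list; its `config` element is a `scaffopt_config`.
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  man$config <- structure(.merge_config(.default_config_list(), man$config),
                          class = "scaffopt_config")
  man
}

# fixed numeric formatting for CSV reproducibility
.fmt6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

.write_csv6 <- function(df, path) {
  df[] <- lapply(df, .fmt6)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
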