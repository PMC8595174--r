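#' Intersection of two volume-fraction windows
#'
#' Order-independent and idempotent; an empty operand gives an empty result.
#' `NULL` stands for "no constraint".
#'
#' @param a,b `vf_window` lists (or `NULL`).
#' @return A `vf_window`.
#' @export
window_intersect <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (isTRUE(a$empty)) return(a)
  if (isTRUE(b$empty)) return(b)
  lo <- max(a$lo, b$lo)
  hi <- min(a$hi, b$hi)
  if (lo > hi)
    return(structure(list(lo = NA_real_, hi = NA_real_, empty = TRUE,
                          reason = "constraint windows do not overlap"),
                     class = "vf_window"))
  structure(list(lo = lo, hi = hi, empty = FALSE, reason = NA_character_),
            class = "vf_window")
}

.vf_window <- function(lo, hi) {
  structure(list(lo = lo, hi = hi, empty = FALSE, reason = NA_character_),
            class = "vf_window")
}

#' Published reference design windows
#'
#' Final admissible volume-fraction windows reported in the motivating
#' experimental literature for the four lattice types that satisfy the pore
#' constraints. Useful as `manual_windows` for reproduction runs, since the
#' published stiffness-window provenance cannot be re-derived from the printed
#' constants alone (see the methods vignette).
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
reference_vf_windows <- function() {
  list(gyroid = c(0.47, 0.66), split_p = c(0.44, 0.54),
       diamond = c(0.44, 0.66), lidinoid = c(0.49, 0.59))
}

#' Constraint windows for a set of scaffold types
#'
#' Computes, per TPMS type, the pore-size window (medial-axis analysis on a
#' tiled scaffold), the stiffness window (closed-form inversion of the
#' Gibson-Ashby law against the stiffness envelope) and the final window
#' selected by `config$optimise$window_source`: the intersection of the two
#' (`"intersection"`), one of them alone (`"pore"`, `"stiffness"`), or
#' externally supplied windows (`"manual"`, e.g. [reference_vf_windows()]).
#' Both constituent windows are always reported separately so the provenance
#' of every edge is visible. Types without a shipped scaling law (Primitive,
#' Neovius) carry no stiffness window; they are normally excluded at the pore
#' stage.
#'
#' @param config A [default_config()]/[load_config()] configuration.
#' @param types Types to analyse (default `config$types`).
#' @param laws Named list of [scaling_law()]s (default
#'   [default_scaling_laws()]).
#' @return Named list per type: `pore`, `stiffness`, `final` windows,
#'   `excluded` flag and `reason`.
#' @export
constraint_windows <- function(config = default_config(),
                               types = config$types,
                               laws = default_scaling_laws()) {
  src <- config$optimise$window_source
  vf_sweep <- seq(config$optimise$vf_min, config$optimise$vf_max,
                  by = config$optimise$vf_step)
  limits <- pore_limits(config$pore$d_lo, config$pore$d_hi)
  env <- stiffness_envelope(config$stiffness$E, config$stiffness$D,
                            config$stiffness$L, config$stiffness$k_lo,
                            config$stiffness$k_hi)
  manual <- config$optimise$manual_windows
  if (src == "manual" && is.null(manual))
    stop("window_source = 'manual' requires optimise$manual_windows")

  out <- lapply(types, function(ty) {
    pw <- if (!src %in% c("intersection", "pore")) NULL else
      pore_window(ty, vf_sweep, resolution = config$pore$resolution,
                  limits = limits, tiling = config$pore$tiling,
                  cell_size = config$cell_size)
    sw <- if (!is.null(laws[[ty]])) stiffness_window(laws[[ty]], env) else NULL
    fin <- switch(src,
      pore = pw,
      stiffness = sw,
      intersection = window_intersect(pw, sw),
      manual = {
        mw <- manual[[ty]]
        if (is.null(mw))
          structure(list(lo = NA_real_, hi = NA_real_, empty = TRUE,
                         reason = "no manual window supplied for this type"),
                    class = "vf_window")
        else .vf_window(as.numeric(mw[[1]]), as.numeric(mw[[2]]))
      })
    excluded <- isTRUE(fin$empty)
    list(pore = pw, stiffness = sw, final = fin, excluded = excluded,
         reason = if (excluded) fin$reason else NA_character_)
  })
  names(out) <- types
  out
}

#' Average growth rate across the admissible window
#'
#' Simulates the level-set growth model at every sweep volume fraction inside
#' the window, with the window edges always appended as sweep points. Each
#' simulation runs on one periodic unit cell at the configured growth
#' resolution. Unfilled simulations are flagged and later excluded from the
#' optimum search.
#'
#' @param tpms_type One of [tpms_types()].
#' @param window A non-empty `vf_window`.
#' @param config Pipeline configuration.
#' @return data.frame with `type`, `vf`, `rate` (mm^3/day), `filled`.
#' @export
growth_sweep <- function(tpms_type, window, config = default_config()) {
  if (isTRUE(window$empty)) stop("cannot sweep an empty window")
  vf_sweep <- seq(config$optimise$vf_min, config$optimise$vf_max,
                  by = config$optimise$vf_step)
  pts <- sort(unique(round(c(window$lo, window$hi,
                             vf_sweep[vf_sweep > window$lo &
                                      vf_sweep < window$hi]), 6)))
  g <- config$growth
  params <- growth_params(dt = g$dt, lambda_coef = g$lambda_coef,
                          max_days = g$max_days,
                          fill_threshold = g$fill_threshold,
                          redistance_interval = g$redistance_interval)
  rows <- lapply(pts, function(vf) {
    curve <- .cached("growth", tpms_type, vf, g$resolution, config$cell_size,
                     g$dt, g$fill_threshold, g$redistance_interval,
                     compute = function() {
      t <- calibrate_t(tpms_type, vf, resolution = g$resolution,
                       cell_size = config$cell_size)
      grid <- voxelize(scaffold_spec(tpms_type, t, config$cell_size, 1L),
                       g$resolution)
      # run in dimensionless time; lambda only rescales the time axis
      simulate_growth(grid, growth_params(
        dt = g$dt, lambda_coef = 1, max_days = Inf,
        fill_threshold = g$fill_threshold,
        redistance_interval = g$redistance_interval), periodic = TRUE)
    })
    rate <- if (curve$filled)
      curve$initial_void_volume / (curve$fill_time / g$lambda_coef)
    else NA_real_
    if (!curve$filled)
      warning(sprintf("%s at VF %.3f did not fill; excluded from the optimum search",
                      tpms_type, vf))
    data.frame(type = tpms_type, vf = vf, rate = rate, filled = curve$filled)
  })
  do.call(rbind, rows)
}

#' Select the optimal design per type
#'
#' The optimum volume fraction is the argmax of the average growth rate within
#' the final window (ties resolved toward the lower volume fraction -- less
#' material for equal growth); types are ranked by their maximum rate.
#'
#' @param rates data.frame from [growth_sweep()] rows (possibly several
#'   types).
#' @param windows Output of [constraint_windows()].
#' @return data.frame with one row per type: `type`, `optimal_vf`, `max_rate`,
#'   `rank` (NA for excluded types), `excluded`, `reason`.
#' @export
select_optimum <- function(rates, windows) {
  rows <- lapply(names(windows), function(ty) {
    w <- windows[[ty]]
    if (isTRUE(w$excluded))
      return(data.frame(type = ty, optimal_vf = NA_real_, max_rate = NA_real_,
                        excluded = TRUE, reason = w$reason))
    r <- rates[rates$type == ty & !is.na(rates$rate), , drop = FALSE]
    if (nrow(r) == 0)
      return(data.frame(type = ty, optimal_vf = NA_real_, max_rate = NA_real_,
                        excluded = TRUE,
                        reason = "no filled growth simulation in the window"))
    r <- r[order(r$vf), , drop = FALSE]
    best <- which.max(r$rate)  # first max = lowest VF on ties
    data.frame(type = ty, optimal_vf = r$vf[best], max_rate = r$rate[best],
               excluded = FALSE, reason = NA_character_)
  })
  out <- do.call(rbind, rows)
  out$rank <- NA_integer_
  ok <- !out$excluded
  out$rank[ok] <- rank(-out$max_rate[ok], ties.method = "first")
  if (!any(ok)) warning("all scaffold types excluded; no admissible design")
  out[order(out$rank, out$type, na.last = TRUE), ,
      drop = FALSE]
}

#' Run the full multiscale optimisation pipeline
#'
#' Applies the pore-size and stiffness constraints to obtain per-type
#' admissible volume-fraction windows, sweeps the curvature-driven growth rate
#' across each window, and selects the optimal type and volume fraction.
#'
#' @param config Pipeline configuration ([default_config()]).
#' @return Object of class `scaffopt_result` with elements `config`,
#'   `windows`, `rates`, `optima`.
#' @export
optimise_scaffold <- function(config = default_config()) {
  windows <- constraint_windows(config)
  rates <- do.call(rbind, lapply(names(windows), function(ty) {
    if (isTRUE(windows[[ty]]$excluded)) return(NULL)
    growth_sweep(ty, windows[[ty]]$final, config)
  }))
  optima <- select_optimum(rates, windows)
  structure(list(config = config, windows = windows, rates = rates,
                 optima = optima),
            class = "scaffopt_result")
}

#' @export
print.scaffopt_result <- function(x, ...) {
  cat("scaffold optimisation result\n")
  print(x$optima, row.names = FALSE)
  invisible(x)
}

.windows_table <- function(windows) {
  g <- function(w, f) if (is.null(w)) NA_real_ else w[[f]]
  do.call(rbind, lapply(names(windows), function(ty) {
    w <- windows[[ty]]
    data.frame(type = ty,
               pore_lo = g(w$pore, "lo"), pore_hi = g(w$pore, "hi"),
               stiffness_lo = g(w$stiffness, "lo"),
               stiffness_hi = g(w$stiffness, "hi"),
               final_lo = g(w$final, "lo"), final_hi = g(w$final, "hi"),
               excluded = w$excluded,
               reason = ifelse(is.na(w$reason), "", w$reason))
  }))
}

#' Write the report artefacts of an optimisation run
#'
#' Emits CSV tables (scaling-law constants, per-type constraint windows with
#' both constituent windows shown so every edge's provenance is visible,
#' growth-rate curves, optimal designs), diagnostic plots, and a run manifest.
#' Excluded types appear with their exclusion reasons. Numeric output is fixed
#' at 6 significant digits so re-running from the same manifest reproduces
#' byte-identical CSVs.
#'
#' @param result A [optimise_scaffold()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
report <- function(result, outdir) {
  stopifnot(inherits(result, "scaffopt_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  w <- function(df, name) {
    p <- file.path(outdir, name)
    .write_csv6(df, p)
    files <<- c(files, p)
  }

  laws <- default_scaling_laws()
  w(do.call(rbind, lapply(laws, function(l)
    data.frame(type = l$tpms_type, C1 = l$C1, n = l$n_exp, E0 = l$E0))),
    "scaling_laws.csv")
  w(.windows_table(result$windows), "constraint_windows.csv")
  if (!is.null(result$rates)) w(result$rates, "growth_rates.csv")
  w(result$optima, "optimal_designs.csv")

  pore_sweeps <- do.call(rbind, lapply(result$windows, function(x)
    if (!is.null(x$pore)) x$pore$sweep else NULL))
  if (!is.null(pore_sweeps)) w(pore_sweeps, "pore_sizes.csv")

  # stiffness curves from the shipped laws
  vf <- seq(0.2, 0.9, by = 0.01)
  env <- stiffness_envelope(result$config$stiffness$E,
                            result$config$stiffness$D,
                            result$config$stiffness$L,
                            result$config$stiffness$k_lo,
                            result$config$stiffness$k_hi)
  stiff <- do.call(rbind, lapply(laws, function(l)
    data.frame(type = l$tpms_type, vf = vf,
               E_star = suppressWarnings(relative_modulus(l, vf)),
               k_N_mm = axial_stiffness(
                 suppressWarnings(relative_modulus(l, vf)), env))))
  w(stiff, "stiffness_curves.csv")

  files <- c(files, .report_plots(result, pore_sweeps, stiff, outdir))
  man <- file.path(outdir, "manifest.yaml")
  write_manifest(result$config, man)
  invisible(c(files, man))
}

# diagnostic plots; skipped with a warning when no graphics device is usable
.report_plots <- function(result, pore_sweeps, stiff, outdir) {
  written <- character(0)
  save_plot <- function(p, name) {
    path <- file.path(outdir, name)
    ok <- tryCatch({
      ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 120)
      TRUE
    }, error = function(e) {
      warning("plot ", name, " skipped: ", conditionMessage(e))
      FALSE
    })
    if (ok) written <<- c(written, path)
  }
  lim <- pore_limits(result$config$pore$d_lo, result$config$pore$d_hi)
  if (!is.null(pore_sweeps) && nrow(pore_sweeps)) {
    p <- ggplot2::ggplot(pore_sweeps, ggplot2::aes(x = vf)) +
      ggplot2::geom_line(ggplot2::aes(y = d_max_um, colour = type)) +
      ggplot2::geom_line(ggplot2::aes(y = d_min_um, colour = type),
                         linetype = "dashed") +
      ggplot2::geom_hline(yintercept = c(lim$d_lo, lim$d_hi), alpha = 0.4) +
      ggplot2::labs(x = "volume fraction", y = "pore diameter (um)",
                    title = "Largest (solid) and smallest (dashed) pores") +
      ggplot2::theme_minimal()
    save_plot(p, "pore_sizes.png")
  }
  if (!is.null(stiff)) {
    p <- ggplot2::ggplot(stiff, ggplot2::aes(vf, k_N_mm, colour = type)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = c(result$config$stiffness$k_lo,
                                         result$config$stiffness$k_hi),
                          alpha = 0.4) +
      ggplot2::labs(x = "volume fraction", y = "axial stiffness (N/mm)") +
      ggplot2::theme_minimal()
    save_plot(p, "stiffness.png")
  }
  if (!is.null(result$rates)) {
    p <- ggplot2::ggplot(result$rates[!is.na(result$rates$rate), ],
                         ggplot2::aes(vf, rate, colour = type)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "volume fraction",
                    y = "average growth rate (mm^3/day)") +
      ggplot2::theme_minimal()
    save_plot(p, "growth_rates.png")
  }
  written
}
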