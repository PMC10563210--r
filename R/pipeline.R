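#' Run configuration
#'
#' The pipeline stages are driven by a flat key=value configuration.
#' `default_config()` lists every key with its default;
#' `read_run_config()` parses a plain-text file of `key = value` lines
#' (`#` comments and blank lines ignored; unknown keys are an error) and
#' merges it over the defaults.
#'
#' Keys (defaults in parentheses): output directory `out_dir` ("output");
#' input paths `panel_path`, `regions_path`, `prevalence_path`,
#' `demand_path` (defaulting to files under `out_dir/data` as written by the
#' simulate stage); generator settings `sim_n_rows` (6), `sim_n_cols` (5),
#' `sim_n_years` (9), `sim_start_year` (2014), `sim_base_level` (100),
#' `sim_trend_rate` (0.08), `sim_gradient_strength` (0.15),
#' `sim_spatial_rho` (0.5), `sim_noise_cv` (0.1), `sim_seasonal_peak`
#' (1.25); cleaning `outlier_z` (4), `max_gap` (2); decomposition
#' `s_window` (13), `stl_robust` (FALSE), `ses_alpha` (NA = no smoothing);
#' spatial `weights_scheme` ("queen"), `n_perm` (999), `alpha` (0.05),
#' `gi_correction` ("none"); kriging `vgm_family` ("spherical"),
#' `vgm_bins` (12), `trend_order` (2), `grid_ncols` (40); `years` ("" = all
#' panel years, else comma-separated); and the global `seed` (1).
#'
#' @param path Path to a key=value text file.
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    out_dir = "output",
    panel_path = NA_character_,
    regions_path = NA_character_,
    prevalence_path = NA_character_,
    demand_path = NA_character_,
    sim_n_rows = 6L, sim_n_cols = 5L, sim_n_years = 9L,
    sim_start_year = 2014L, sim_base_level = 100, sim_trend_rate = 0.08,
    sim_gradient_strength = 0.15, sim_spatial_rho = 0.5, sim_noise_cv = 0.1,
    sim_seasonal_peak = 1.25,
    outlier_z = 4, max_gap = 2L,
    s_window = 13L, stl_robust = FALSE, ses_alpha = NA_real_,
    weights_scheme = "queen", n_perm = 999L, alpha = 0.05,
    gi_correction = "none",
    vgm_family = "spherical", vgm_bins = 12L, trend_order = 2L,
    grid_ncols = 40L,
    years = "",
    seed = 1L)
}

#' @rdname default_config
#' @export
read_run_config <- function(path) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_arg("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) stop_arg("malformed config line: ", ln)
    key <- kv[2L]; val <- trimws(kv[3L])
    if (!key %in% names(cfg)) stop_arg("unknown config key: ", key)
    proto <- cfg[[key]]
    cfg[[key]] <- if (is.logical(proto)) toupper(val) %in% c("TRUE", "T", "1", "YES")
      else if (is.integer(proto)) as.integer(val)
      else if (is.numeric(proto)) as.numeric(val)
      else val
  }
  cfg
}

write_resolved_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0(k, " = ", if (length(v) == 1L && is.na(v)) "" else as.character(v))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

log_line <- function(cfg, ...) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = file.path(cfg$out_dir, "run.log"), append = TRUE, sep = "")
  invisible(msg)
}

out_path <- function(cfg, ...) {
  p <- file.path(cfg$out_dir, ...)
  dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
  p
}

cfg_or <- function(cfg, key, fallback) {
  v <- cfg[[key]]
  if (is.null(v) || (length(v) == 1L && is.na(v))) fallback else v
}

write_table_csv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], sprintf_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

load_inputs <- function(cfg) {
  panel <- read_panel(cfg_or(cfg, "panel_path", out_path(cfg, "data", "panel.csv")))
  regions <- read_regions(cfg_or(cfg, "regions_path", out_path(cfg, "data", "regions.geojson")))
  list(panel = panel, regions = regions)
}

panel_years <- function(cfg, panel) {
  if (nzchar(cfg$years)) as.integer(strsplit(cfg$years, ",")[[1L]])
  else sort(unique(panel$year))
}

# Per-region mean index for one year (the per-region scalar the spatial
# stages analyse by default).
region_year_means <- function(panel, regions, year) {
  d <- panel[panel$year == year & !is.na(panel$value), , drop = FALSE]
  m <- tapply(d$value, d$region_id, mean)
  v <- as.numeric(m[regions$region_id])
  if (anyNA(v)) {
    stop_arg("year ", year, ": no index data for region(s) ",
             paste(regions$region_id[is.na(v)], collapse = ", "))
  }
  v
}

#' Pipeline stages
#'
#' Each stage reads its inputs from the paths in the configuration, writes
#' its outputs under `out_dir`, appends to `out_dir/run.log` and records the
#' resolved configuration (with the seed) next to the outputs. All stages
#' are deterministic given (inputs, config, seed). `stage_report()` runs the
#' full study: simulate (if no inputs exist), clean, decompose, strength,
#' peaks, per-year global Moran table, LISA, Gi* hot spots, the standard
#' deviational ellipse, ordinary kriging, Spearman validation and demand
#' shares.
#'
#' @param cfg A configuration list from [read_run_config()] /
#'   [default_config()].
#' @return The stage's main result, invisibly; `stage_report()` returns a
#'   named list of all results.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
stage_simulate <- function(cfg) {
  dir.create(out_path(cfg, "data"), showWarnings = FALSE, recursive = TRUE)
  config <- panel_config(
    n_rows = cfg$sim_n_rows, n_cols = cfg$sim_n_cols, n_years = cfg$sim_n_years,
    start_year = cfg$sim_start_year, base_level = cfg$sim_base_level,
    trend_rate = cfg$sim_trend_rate,
    seasonal_amplitudes = spring_peak_amplitudes(cfg$sim_seasonal_peak),
    gradient_strength = cfg$sim_gradient_strength,
    spatial_rho = cfg$sim_spatial_rho, noise_cv = cfg$sim_noise_cv,
    seed = cfg$seed)
  regions <- generate_geometry(cfg$sim_n_rows, cfg$sim_n_cols)
  panel <- generate_panel(config, regions)
  # prevalence emulates an external annual series that tracks the index
  # strongly but not perfectly (noise ~5% of the base level can flip the
  # ranks of adjacent years)
  prevalence <- generate_prevalence(panel, rank_noise = 0.05 * cfg$sim_base_level,
                                    seed = cfg$seed + 1L)
  demand <- generate_demand_terms(seed = cfg$seed + 2L)
  write_regions(regions, out_path(cfg, "data", "regions.geojson"))
  write_panel(panel, out_path(cfg, "data", "panel.csv"))
  write_annual_series(prevalence, out_path(cfg, "data", "prevalence.csv"))
  write_table_csv(demand, out_path(cfg, "data", "demand.csv"))
  write_resolved_config(cfg, out_path(cfg, "run-config.txt"))
  log_line(cfg, "simulate: ", nrow(regions), " regions x ",
           12L * cfg$sim_n_years, " months, seed ", cfg$seed)
  invisible(list(regions = regions, panel = panel, prevalence = prevalence,
                 demand = demand))
}

#' @rdname pipeline
#' @export
stage_clean <- function(cfg) {
  inp <- load_inputs(cfg)
  res <- clean_panel(inp$panel, outlier_z = cfg$outlier_z, max_gap = cfg$max_gap)
  write_panel(res$panel, out_path(cfg, "clean", "panel_clean.csv"))
  write_table_csv(res$report, out_path(cfg, "clean", "cleaning_report.csv"))
  log_line(cfg, "clean: ", nrow(res$report), " changes reported")
  invisible(res)
}

cleaned_panel <- function(cfg) {
  p <- out_path(cfg, "clean", "panel_clean.csv")
  if (file.exists(p)) read_panel(p) else stage_clean(cfg)$panel
}

#' @rdname pipeline
#' @export
stage_decompose <- function(cfg) {
  panel <- cleaned_panel(cfg)
  decs <- decompose_panel(panel, s_window = cfg$s_window,
                          robust = cfg$stl_robust,
                          ses_alpha = if (is.na(cfg$ses_alpha)) NULL else cfg$ses_alpha)
  rows <- lapply(names(decs), function(rid) {
    d <- decs[[rid]]
    data.frame(region_id = rid, t = d$t, trend = d$trend,
               seasonal = d$seasonal, remainder = d$remainder,
               stringsAsFactors = FALSE)
  })
  write_table_csv(do.call(rbind, rows), out_path(cfg, "timeseries", "components.csv"))
  log_line(cfg, "decompose: ", length(decs), " series (incl. national)")
  invisible(decs)
}

#' @rdname pipeline
#' @export
stage_strength <- function(cfg) {
  decs <- stage_decompose(cfg)
  tab <- panel_strength(decs)
  write_table_csv(tab, out_path(cfg, "timeseries", "strength.csv"))
  log_line(cfg, "strength: ", sum(tab$is_seasonal), "/", nrow(tab),
           " series seasonal (F_S >= 0.4)")
  invisible(tab)
}

#' @rdname pipeline
#' @export
stage_peaks <- function(cfg) {
  decs <- stage_decompose(cfg)
  sub <- subseries_table(decs)
  write_table_csv(sub, out_path(cfg, "timeseries", "subseries.csv"))
  peaks <- seasonal_peak(decs$national)
  write_table_csv(data.frame(month = peaks$peak_months,
                             month_name = month_names[peaks$peak_months]),
                  out_path(cfg, "timeseries", "peak_months.csv"))
  log_line(cfg, "peaks: national peak months ",
           paste(month_names[peaks$peak_months], collapse = ","))
  invisible(peaks)
}

moran_weights <- function(cfg, regions) {
  build_weights(regions, scheme = cfg$weights_scheme, row_standardize = TRUE)
}

#' @rdname pipeline
#' @export
stage_moran <- function(cfg) {
  inp <- load_inputs(cfg)
  panel <- cleaned_panel(cfg)
  W <- moran_weights(cfg, inp$regions)
  rows <- lapply(panel_years(cfg, panel), function(yr) {
    v <- region_year_means(panel, inp$regions, yr)
    m <- global_morans_i(v, W, n_perm = cfg$n_perm, seed = cfg$seed + yr)
    data.frame(year = yr, I = m$I, expected = m$expected, z = m$z,
               p_analytic = m$p_analytic, p_perm = m$p_perm)
  })
  tab <- do.call(rbind, rows)
  write_table_csv(tab, out_path(cfg, "spatial", "moran_by_year.csv"))
  log_line(cfg, "moran: ", sum(tab$p_perm < cfg$alpha), "/", nrow(tab),
           " years with p_perm < ", cfg$alpha)
  invisible(tab)
}

#' @rdname pipeline
#' @export
stage_lisa <- function(cfg) {
  inp <- load_inputs(cfg)
  panel <- cleaned_panel(cfg)
  W <- moran_weights(cfg, inp$regions)
  yrs <- panel_years(cfg, panel)
  v <- rowMeans(vapply(yrs, function(yr) region_year_means(panel, inp$regions, yr),
                       numeric(nrow(inp$regions))))
  lisa <- local_morans_i(v, W, n_perm = cfg$n_perm, seed = cfg$seed,
                         alpha = cfg$alpha)
  write_table_csv(as.data.frame(lisa), out_path(cfg, "spatial", "lisa.csv"))
  write_regions(inp$regions, out_path(cfg, "spatial", "lisa.geojson"),
                properties = data.frame(region_id = lisa$region_id,
                                        lisa_label = lisa$label,
                                        lisa_p = lisa$p_perm))
  log_line(cfg, "lisa: ", sum(lisa$label != "Not significant"),
           " significant regions")
  invisible(lisa)
}

#' @rdname pipeline
#' @export
stage_hotspots <- function(cfg) {
  inp <- load_inputs(cfg)
  panel <- cleaned_panel(cfg)
  Wg <- build_weights(inp$regions, scheme = "distance_band", include_self = TRUE)
  yrs <- panel_years(cfg, panel)
  v <- rowMeans(vapply(yrs, function(yr) region_year_means(panel, inp$regions, yr),
                       numeric(nrow(inp$regions))))
  gi <- getis_ord_gi_star(v, Wg, correction = cfg$gi_correction)
  write_table_csv(as.data.frame(gi), out_path(cfg, "spatial", "gistar.csv"))
  write_regions(inp$regions, out_path(cfg, "spatial", "gistar.geojson"),
                properties = data.frame(region_id = gi$region_id,
                                        gi_z = gi$gi_z, gi_bin = gi$bin))
  log_line(cfg, "hotspots: ", sum(grepl("^hot", gi$bin)), " hot / ",
           sum(grepl("^cold", gi$bin)), " cold regions")
  invisible(gi)
}

#' @rdname pipeline
#' @export
stage_ellipse <- function(cfg) {
  inp <- load_inputs(cfg)
  panel <- cleaned_panel(cfg)
  yrs <- panel_years(cfg, panel)
  v <- rowMeans(vapply(yrs, function(yr) region_year_means(panel, inp$regions, yr),
                       numeric(nrow(inp$regions))))
  ell <- std_dev_ellipse(centroids(inp$regions), weights = v)
  ring <- ellipse_polygon(ell)
  fc <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(theta_deg = ell$theta, sigma_x = ell$sigma_x,
                      sigma_y = ell$sigma_y,
                      center_x = unname(ell$center[1L]),
                      center_y = unname(ell$center[2L])),
    geometry = list(type = "Polygon",
                    coordinates = list(lapply(seq_len(nrow(ring)),
                                              function(j) c(ring[j, 1L], ring[j, 2L])))))))
  jsonlite::write_json(fc, out_path(cfg, "spatial", "ellipse.geojson"),
                       auto_unbox = TRUE, digits = 10)
  log_line(cfg, "ellipse: theta ", format(ell$theta, digits = 4), " deg")
  invisible(ell)
}

#' @rdname pipeline
#' @export
stage_krige <- function(cfg) {
  inp <- load_inputs(cfg)
  panel <- cleaned_panel(cfg)
  yrs <- panel_years(cfg, panel)
  v <- rowMeans(vapply(yrs, function(yr) region_year_means(panel, inp$regions, yr),
                       numeric(nrow(inp$regions))))
  xy <- centroids(inp$regions)
  tr <- remove_trend(xy, v, order = cfg$trend_order)
  z <- tr$residuals
  emp <- empirical_semivariogram(xy, z, n_bins = cfg$vgm_bins)
  if (nrow(emp) < 4L) {
    # few distinct distances within half the max lag (small lattices):
    # widen the binning to the full distance range
    full <- max(stats::dist(xy))
    emp <- empirical_semivariogram(xy, z, n_bins = cfg$vgm_bins, max_lag = full)
  }
  vm <- fit_variogram(emp, family = cfg$vgm_family)
  grid <- grid_over_regions(inp$regions, ncols = cfg$grid_ncols)
  kr <- ordinary_krige(xy, z, vm, grid, trend = tr$model)
  write_surface(kr$prediction, out_path(cfg, "kriging", "surface.asc"))
  write_surface(kr$variance, out_path(cfg, "kriging", "variance.asc"))
  fitted <- data.frame(h = emp$h, gamma = emp$gamma, np = emp$np,
                       gamma_model = variogram_gamma(vm, emp$h))
  write_table_csv(fitted, out_path(cfg, "kriging", "variogram.csv"))
  cv <- loo_cross_validate(xy, v, vm, trend = tr$model)
  diag <- list(
    variogram = list(family = vm$family, nugget = vm$nugget, psill = vm$psill,
                     range = vm$range, wrss = vm$wrss),
    trend = list(order = tr$model$order,
                 coefficients = as.list(tr$model$coef)),
    residual_normality = list(
      shapiro_p = tryCatch(stats::shapiro.test(z)$p.value,
                           error = function(e) NA_real_),
      skewness = mean((z - mean(z))^3) / (mean((z - mean(z))^2))^1.5),
    cross_validation = list(rmse = cv$rmse, mean_error = cv$me,
                            mean_standardized_error = cv$mse_standardized))
  jsonlite::write_json(diag, out_path(cfg, "kriging", "diagnostics.json"),
                       auto_unbox = TRUE, digits = 10, na = "null")
  log_line(cfg, "krige: ", cfg$vgm_family, " model, LOO RMSE ",
           format(cv$rmse, digits = 4))
  invisible(list(variogram = vm, surface = kr, cv = cv, trend = tr$model,
                 diagnostics = diag))
}

#' @rdname pipeline
#' @export
stage_validate <- function(cfg) {
  panel <- cleaned_panel(cfg)
  prev <- read_annual_series(cfg_or(cfg, "prevalence_path",
                                    out_path(cfg, "data", "prevalence.csv")))
  annual <- tapply(panel$value, panel$year, mean, na.rm = TRUE)
  common <- intersect(as.integer(names(annual)), prev$year)
  if (length(common) < 4L) stop_arg("fewer than 4 overlapping years for validation")
  sp <- spearman(as.numeric(annual[as.character(common)]),
                 prev$value[match(common, prev$year)])
  res <- data.frame(n = sp$n, rho = sp$rho, p_exact = sp$p_exact,
                    p_asymptotic = sp$p_asymptotic)
  write_table_csv(res, out_path(cfg, "validation", "spearman.csv"))
  log_line(cfg, "validate: rho ", format(sp$rho, digits = 4), " over ",
           sp$n, " years")
  invisible(sp)
}

#' @rdname pipeline
#' @export
stage_demand <- function(cfg) {
  path <- cfg_or(cfg, "demand_path", out_path(cfg, "data", "demand.csv"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  shares <- seasonal_demand_shares(raw)
  write_table_csv(as.data.frame(shares), out_path(cfg, "demand", "demand_shares.csv"))
  per_season <- lapply(split(shares, shares$season), function(d) {
    list(top_term = d$term[d$rank == 1L], top_share = d$share[d$rank == 1L])
  })
  jsonlite::write_json(per_season, out_path(cfg, "demand", "demand_summary.json"),
                       auto_unbox = TRUE, digits = 10)
  log_line(cfg, "demand: top share ",
           format(max(shares$share), digits = 4))
  invisible(shares)
}

#' @rdname pipeline
#' @export
stage_report <- function(cfg) {
  if (!file.exists(cfg_or(cfg, "panel_path", out_path(cfg, "data", "panel.csv")))) {
    stage_simulate(cfg)
  }
  write_resolved_config(cfg, out_path(cfg, "run-config.txt"))
  res <- list(
    clean = stage_clean(cfg),
    strength = stage_strength(cfg),
    peaks = stage_peaks(cfg),
    moran = stage_moran(cfg),
    lisa = stage_lisa(cfg),
    hotspots = stage_hotspots(cfg),
    ellipse = stage_ellipse(cfg),
    krige = stage_krige(cfg),
    validate = stage_validate(cfg),
    demand = stage_demand(cfg))
  log_line(cfg, "report: complete")
  invisible(res)
}

#' Command-line entry point
#'
#' Dispatches `run_cli(c("<subcommand>", "<config-file>"))` to the matching
#' stage. Subcommands: simulate, clean, decompose, strength, peaks, moran,
#' lisa, hotspots, ellipse, krige, validate, demand, report. The config file
#' is optional; defaults are used when omitted. A thin Rscript wrapper lives
#' at `system.file("scripts", "searchscape-cli.R", package = "searchscape")`.
#'
#' @param args Character vector of command-line arguments.
#' @return The stage result, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- list(simulate = stage_simulate, clean = stage_clean,
                 decompose = stage_decompose, strength = stage_strength,
                 peaks = stage_peaks, moran = stage_moran, lisa = stage_lisa,
                 hotspots = stage_hotspots, ellipse = stage_ellipse,
                 krige = stage_krige, validate = stage_validate,
                 demand = stage_demand, report = stage_report)
  if (length(args) < 1L || !args[1L] %in% names(stages)) {
    stop_arg("usage: <subcommand> [config-file]; subcommands: ",
             paste(names(stages), collapse = ", "))
  }
  cfg <- read_run_config(if (length(args) >= 2L) args[2L] else NULL)
  stages[[args[1L]]](cfg)
}
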