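# Orchestration plumbing: validated configuration, command dispatch,
# run manifests. The same machinery backs the exec/srs-workbench
# command-line script.

.wb_defaults <- function() {
  list(
    command = NULL,
    model = "homogeneous_skin",       # preset name or model config file
    wavelength = "770",
    n_photons = 1e5,
    seed = 1,
    voxel_size = 0.2,
    tally_mode = "depth_profile",
    ring_width = 1.0,
    rings = "auto",                   # auto | fine | numeric centers
    pair = c(3, 5),
    rho2 = c(5, 10, 20, 30),
    rho1_step = 0.5,
    roulette_threshold = 1e-4,
    roulette_survival = 0.1,
    max_total_path = 1e4,
    inversion = "diffusion",
    extinction_path = NULL,
    mu_a_grid = NULL,                 # lut command
    input = NULL,                     # oximeter command: readings CSV
    maps_dir = NULL,                  # regress command: directory of map CSVs
    depths = seq(0.5, 7, by = 0.5),   # phantom command (blood-layer top)
    probes = c("3-5", "6-8", "9-14", "20-30"),
    out_dir = "."
  )
}

#' Load and validate a workbench configuration
#'
#' Reads a YAML or JSON configuration file (or takes a named list of
#' overrides), fills in documented defaults, rejects unknown keys, and
#' validates every numeric parameter against the preconditions of the
#' module it feeds before any computation starts.
#'
#' @param path Path to a YAML/JSON config file, or `NULL`.
#' @param overrides Named list merged over the file values (e.g. from
#'   command-line flags).
#' @return Object of class `workbench_config` (a validated named list).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- .wb_defaults()
  user <- list()
  if (!is.null(path)) user <- read_config_file(path)
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg <- utils::modifyList(cfg, user)
  # modifyList drops keys a file serialized as null; restore them so a
  # load -> serialize -> load round trip is exact
  defaults <- .wb_defaults()
  for (k in setdiff(names(defaults), names(cfg))) cfg[k] <- list(defaults[[k]])
  cfg <- cfg[names(defaults)]

  chk_num <- function(key, lo = -Inf, hi = Inf, lo_open = FALSE) {
    v <- cfg[[key]]
    if (!is.numeric(v) || any(!is.finite(v)) ||
        any(if (lo_open) v <= lo else v < lo) || any(v > hi))
      stop(sprintf("config key '%s' must be numeric in %s%g, %g]",
                   key, if (lo_open) "(" else "[", lo, hi), call. = FALSE)
  }
  chk_num("n_photons", 1)
  chk_num("voxel_size", 0, lo_open = TRUE)
  chk_num("ring_width", 0, lo_open = TRUE)
  chk_num("rho1_step", 0, lo_open = TRUE)
  chk_num("roulette_threshold", 0)
  chk_num("roulette_survival", 0, 1, lo_open = TRUE)
  if (cfg$roulette_survival >= 1)
    stop("config key 'roulette_survival' must be numeric in (0, 1)",
         call. = FALSE)
  chk_num("max_total_path", 0, lo_open = TRUE)
  chk_num("seed")
  if (!cfg$tally_mode %in% c("depth_profile", "full_3d"))
    stop("config key 'tally_mode' must be depth_profile or full_3d",
         call. = FALSE)
  if (!cfg$inversion %in% c("diffusion", "lut"))
    stop("config key 'inversion' must be diffusion or lut", call. = FALSE)
  if (length(cfg$pair) != 2L || !is.numeric(cfg$pair) ||
      !(cfg$pair[1] > 0 && cfg$pair[2] > cfg$pair[1]))
    stop("config key 'pair' must be numeric c(rho1, rho2) with 0 < rho1 < rho2",
         call. = FALSE)
  chk_num("rho2", 1)
  if (!is.numeric(cfg$depths) || any(cfg$depths < 0))
    stop("config key 'depths' must be non-negative numeric", call. = FALSE)
  structure(cfg, class = "workbench_config")
}

#' Serialize a workbench config back to a plain list
#' @param config A `workbench_config`.
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "workbench_config"))
  unclass(config)
}

.wb_model <- function(cfg) {
  if (cfg$model %in% c("homogeneous_skin", "skin_subcutaneous", "gastric"))
    make_preset_model(cfg$model, cfg$wavelength)
  else
    model_from_config(cfg$model)
}

.wb_runconfig <- function(cfg) {
  run_config(n_photons = cfg$n_photons, seed = cfg$seed,
             voxel_size = cfg$voxel_size, tally_mode = cfg$tally_mode,
             roulette_threshold = cfg$roulette_threshold,
             roulette_survival = cfg$roulette_survival,
             max_total_path = cfg$max_total_path)
}

.wb_annuli <- function(cfg, model) {
  if (identical(cfg$rings, "fine"))
    fine_annuli(max(cfg$rho2) + 0.5, width = cfg$rho1_step)
  else if (identical(cfg$rings, "auto"))
    annuli_at(unlist(lapply(standard_probes(), function(p) c(p$rho1, p$rho2))),
              width = cfg$ring_width)
  else
    annuli_at(as.numeric(cfg$rings), width = cfg$ring_width)
}

# Atomic CSV write: write to a temp file in the same directory, then rename.
.write_csv_atomic <- function(d, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  utils::write.csv(d, tmp, row.names = FALSE)
  file.rename(tmp, path)
  path
}

#' Write a JSON run manifest alongside an output file
#'
#' @param outputs Character vector of produced file paths.
#' @param config The `workbench_config` that produced them.
#' @param extra Named list of additional fields (ledger totals, ...).
#' @param path Manifest path; default first output + `.manifest.json`.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(outputs, config, extra = list(), path = NULL) {
  if (is.null(path)) path <- paste0(outputs[1], ".manifest.json")
  manifest <- c(list(
    tool = paste0("srsdepth ",
                  as.character(utils::packageVersion("srsdepth"))),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config_to_list(config),
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  ), extra)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run a workbench command
#'
#' Dispatches a validated configuration to the corresponding module:
#' \describe{
#'   \item{simulate}{One Monte Carlo run; tallies RDS + manifest.}
#'   \item{sensitivity}{Depth profile and metrics of `pair`; CSV + JSON.}
#'   \item{table2}{Profile metrics for all four standard probes from one
#'     shared run; CSV.}
#'   \item{map}{Normalized depth maps for each `rho2`; CSV per map.}
#'   \item{regress}{Peak-depth regression over map CSVs in `maps_dir`
#'     (or freshly computed maps); JSON coefficients.}
#'   \item{lut}{Slope lookup table for `pair`; CSV.}
#'   \item{oximeter}{rSO2 over an intensity log `input`; CSV.}
#'   \item{phantom}{Blood-layer depth sweep; CSV.}
#' }
#' Every command writes its outputs plus a JSON manifest into
#' `out_dir` and is reproducible from the manifest alone.
#'
#' @param config A `workbench_config` from [load_config()].
#' @return Named list of produced file paths, invisibly.
#' @export
run_command <- function(config) {
  stopifnot(inherits(config, "workbench_config"))
  cfg <- config
  if (is.null(cfg$command))
    stop("config key 'command' is missing", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(
    cfg$command,
    simulate = {
      model <- .wb_model(cfg)
      t <- run_simulation(model, .wb_runconfig(cfg), .wb_annuli(cfg, model),
                          wavelength = cfg$wavelength)
      f <- file.path(cfg$out_dir, "tallies.rds")
      write_tallies(t, f)
      led <- weight_ledger(t)
      write_manifest(f, cfg, extra = list(ledger = as.list(led)))
      list(tallies = f)
    },
    sensitivity = {
      model <- .wb_model(cfg)
      ann <- annuli_at(cfg$pair, width = cfg$ring_width)
      t <- run_simulation(model, .wb_runconfig(cfg), ann,
                          wavelength = cfg$wavelength)
      prof <- depth_profile(t, pair = cfg$pair)
      met <- profile_metrics(prof)
      f1 <- .write_csv_atomic(as.data.frame(prof),
                              file.path(cfg$out_dir, "depth_profile.csv"))
      f2 <- file.path(cfg$out_dir, "profile_metrics.json")
      jsonlite::write_json(unclass(met)[c("peak_depth", "half_range_low",
                                          "half_range_high", "depth_10pct",
                                          "pair")],
                           f2, auto_unbox = TRUE, digits = NA)
      write_manifest(c(f1, f2), cfg)
      list(profile = f1, metrics = f2)
    },
    table2 = {
      model <- .wb_model(cfg)
      ann <- .wb_annuli(cfg, model)
      t <- run_simulation(model, .wb_runconfig(cfg), ann,
                          wavelength = cfg$wavelength)
      rows <- lapply(standard_probes(), function(p) {
        met <- profile_metrics(depth_profile(t, pair = c(p$rho1, p$rho2)))
        data.frame(pair = p$label, peak_depth = met$peak_depth,
                   half_range_low = met$half_range_low,
                   half_range_high = met$half_range_high,
                   depth_10pct = met$depth_10pct)
      })
      f <- .write_csv_atomic(do.call(rbind, rows),
                             file.path(cfg$out_dir, "depth_metrics.csv"))
      write_manifest(f, cfg)
      list(metrics = f)
    },
    map = {
      model <- .wb_model(cfg)
      cfg2 <- cfg
      cfg2$rings <- "fine"
      ann <- .wb_annuli(cfg2, model)
      t <- run_simulation(model, .wb_runconfig(cfg), ann,
                          wavelength = cfg$wavelength)
      files <- character()
      for (r2 in cfg$rho2) {
        m <- sweep_depth_map(tallies = t, rho2 = r2,
                             rho1_step = cfg$rho1_step)
        f <- .write_csv_atomic(as.data.frame(m),
                               file.path(cfg$out_dir,
                                         sprintf("depth_map_rho2_%g.csv", r2)))
        files <- c(files, f)
      }
      write_manifest(files, cfg)
      list(maps = files)
    },
    regress = {
      pts <- if (!is.null(cfg$maps_dir)) {
        fl <- list.files(cfg$maps_dir, pattern = "\\.csv$", full.names = TRUE)
        if (!length(fl)) stop("maps_dir holds no CSV maps", call. = FALSE)
        do.call(rbind, lapply(fl, utils::read.csv))
      } else {
        res <- run_command(`class<-`(utils::modifyList(
          config_to_list(cfg), list(command = "map")), "workbench_config"))
        do.call(rbind, lapply(res$maps, utils::read.csv))
      }
      fit <- fit_dp_regression(pts)
      f <- file.path(cfg$out_dir, "dp_regression.json")
      jsonlite::write_json(list(coef_rho1 = fit$coef_rho1,
                                coef_rho2 = fit$coef_rho2,
                                intercept = fit$intercept,
                                rmse = fit$rmse, n_points = fit$n_points),
                           f, auto_unbox = TRUE, digits = NA)
      write_manifest(f, cfg)
      list(regression = f)
    },
    lut = {
      model <- .wb_model(cfg)
      p0 <- model$layers[[1]]$props[[normalize_wavelength(cfg$wavelength)]]
      grid <- if (is.null(cfg$mu_a_grid))
        seq(0.001, 0.06, length.out = 13) else as.numeric(cfg$mu_a_grid)
      lut <- build_slope_lut(p0$mu_s, p0$g, p0$n,
                             probe_geometry(cfg$pair[1], cfg$pair[2]),
                             grid, .wb_runconfig(cfg),
                             wavelength = cfg$wavelength,
                             ring_width = cfg$ring_width)
      f <- file.path(cfg$out_dir,
                     sprintf("slope_lut_%g_%g_%snm.csv", cfg$pair[1],
                             cfg$pair[2], normalize_wavelength(cfg$wavelength)))
      write_slope_lut(lut, f)
      write_manifest(f, cfg)
      list(lut = f)
    },
    oximeter = {
      if (is.null(cfg$input)) stop("oximeter needs 'input'", call. = FALSE)
      eps <- if (is.null(cfg$extinction_path)) extinction_table()
             else extinction_table(cfg$extinction_path)
      model <- .wb_model(cfg)
      wl <- normalize_wavelength(cfg$wavelength)
      msp <- vapply(c("770", "830"), function(w) {
        p <- model$layers[[1]]$props[[w]]
        mu_s_prime(p)
      }, numeric(1))
      d <- oximeter_from_log(cfg$input,
                             probe_geometry(cfg$pair[1], cfg$pair[2]),
                             inversion = "diffusion", eps = eps,
                             mu_s_prime = msp)
      f <- .write_csv_atomic(d, file.path(cfg$out_dir, "rso2.csv"))
      write_manifest(f, cfg)
      list(rso2 = f)
    },
    phantom = {
      eps <- if (is.null(cfg$extinction_path)) extinction_table()
             else extinction_table(cfg$extinction_path)
      probes <- standard_probes()[cfg$probes]
      d <- phantom_depth_sweep(phantom_spec(), probes = probes,
                               depths = cfg$depths,
                               config = .wb_runconfig(cfg), eps = eps,
                               inversion = cfg$inversion,
                               ring_width = cfg$ring_width)
      f <- .write_csv_atomic(d, file.path(cfg$out_dir, "phantom_rso2.csv"))
      write_manifest(f, cfg)
      list(phantom = f)
    },
    stop(sprintf("unknown command '%s'", cfg$command), call. = FALSE)
  )
  invisible(out)
}
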