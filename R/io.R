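#' Load a scenario configuration file
#'
#' Reads a YAML configuration with sections `parameters`, `community`,
#' `initial_conditions`, `solver`, `extensions` and `scenario`, validates
#' every key, fills defaults, and returns the corresponding package
#' objects. Unknown keys are rejected by name.
#'
#' ```yaml
#' parameters: {alpha: 1, gamma: 1e-3, delta: 1, k: 1e-9, b: 10}
#' community:
#'   classes: [[0, 0.5], [0.5], [0.5]]
#' initial_conditions: {log10_range: [6, 9], seed: 1, equal_lysogens: no}
#' solver: {rtol: 1e-8, atol: 1e-10, dt: 0.1}
#' scenario: {duration: 2000}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A list with `params`, `config`, `settings`, `extensions`,
#'   `init` (a seeded [community_state()] if `initial_conditions` provides
#'   a seed, else `NULL`), `scenario` (name/duration/seeds list), and
#'   `raw` (the parsed YAML after defaults were filled).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("parameters", "community", "initial_conditions", "solver",
             "extensions", "scenario")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  pdef <- default_parameters()
  pin <- raw$parameters
  if (!is.null(pin)) {
    badk <- setdiff(names(pin), c("alpha", "gamma", "delta", "k", "b"))
    if (length(badk))
      stop("unknown parameter key(s): ", paste(badk, collapse = ", "),
           call. = FALSE)
  }
  params <- model_parameters(
    alpha = pin$alpha %||% pdef$alpha, gamma = pin$gamma %||% pdef$gamma,
    delta = pin$delta %||% pdef$delta, k = pin$k %||% pdef$k,
    b = pin$b %||% pdef$b)

  if (is.null(raw$community$classes))
    stop("config must provide community: classes", call. = FALSE)
  badk <- setdiff(names(raw$community), c("classes", "overrides"))
  if (length(badk))
    stop("unknown community key(s): ", paste(badk, collapse = ", "),
         call. = FALSE)
  ov <- raw$community$overrides
  config <- community_config(lapply(raw$community$classes, as.numeric),
                             overrides = if (!is.null(ov))
                               as.data.frame(ov))

  sin <- raw$solver
  if (!is.null(sin)) {
    badk <- setdiff(names(sin),
                    c("method", "rtol", "atol", "dt", "floor",
                      "extinction_threshold", "transient_frac", "maxsteps"))
    if (length(badk))
      stop("unknown solver key(s): ", paste(badk, collapse = ", "),
           call. = FALSE)
  }
  sdef <- solver_settings()
  settings <- solver_settings(
    method = sin$method %||% sdef$method, rtol = sin$rtol %||% sdef$rtol,
    atol = sin$atol %||% sdef$atol, dt = sin$dt %||% sdef$dt,
    floor = sin$floor %||% sdef$floor,
    extinction_threshold = sin$extinction_threshold,
    transient_frac = sin$transient_frac %||% sdef$transient_frac,
    maxsteps = sin$maxsteps %||% sdef$maxsteps)

  ein <- raw$extensions
  if (!is.null(ein)) {
    badk <- setdiff(names(ein), c("sensitive_bacteria", "double_lysogens",
                                  "lysis_time_tau", "coinfection_kappa",
                                  "heterogeneity_spread"))
    if (length(badk))
      stop("unknown extensions key(s): ", paste(badk, collapse = ", "),
           call. = FALSE)
  }
  ext <- extensions(sensitive = ein$sensitive_bacteria %||% FALSE,
                    double_lysogens = ein$double_lysogens %||% FALSE,
                    tau = ein$lysis_time_tau %||% 0,
                    kappa = ein$coinfection_kappa %||% 0)

  iin <- raw$initial_conditions
  init <- NULL
  if (!is.null(iin)) {
    badk <- setdiff(names(iin), c("log10_range", "seed", "equal_lysogens",
                                  "P", "L"))
    if (length(badk))
      stop("unknown initial_conditions key(s): ",
           paste(badk, collapse = ", "), call. = FALSE)
    if (!is.null(iin$P)) {
      init <- community_state(as.numeric(iin$P), as.numeric(iin$L %||%
                                                              numeric(0)),
                              config)
    } else if (!is.null(iin$seed)) {
      init <- sample_initial_state(
        config, as.numeric(iin$log10_range %||% c(6, 9)),
        seed = iin$seed,
        equal_lysogens = iin$equal_lysogens %||% FALSE)
    }
  }

  scn <- raw$scenario
  if (!is.null(scn)) {
    badk <- setdiff(names(scn), c("name", "duration", "seeds"))
    if (length(badk))
      stop("unknown scenario key(s): ", paste(badk, collapse = ", "),
           call. = FALSE)
  }
  list(params = params, config = config, settings = settings,
       extensions = ext, init = init,
       scenario = list(name = scn$name %||% NA_character_,
                       duration = scn$duration %||% 2000,
                       seeds = scn$seeds %||% 1L),
       raw = raw,
       heterogeneity_spread = ein$heterogeneity_spread %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a configuration file
#'
#' Writes the YAML counterpart of [load_config()]; a round trip through
#' save and load reproduces identical objects.
#'
#' @param params,config,settings,extensions Package objects to serialize
#'   (any may be `NULL` to use defaults on reload).
#' @param path Output path.
#' @param initial_conditions,scenario Optional lists copied verbatim into
#'   the respective sections.
#' @return `path`, invisibly.
#' @export
save_config <- function(path, params = NULL, config = NULL, settings = NULL,
                        extensions = NULL, initial_conditions = NULL,
                        scenario = NULL) {
  out <- list()
  if (!is.null(params))
    out$parameters <- params[c("alpha", "gamma", "delta", "k", "b")]
  if (!is.null(config)) {
    out$community <- list(classes = lapply(config$classes, as.numeric))
    if (!is.null(config$overrides))
      out$community$overrides <- as.list(config$overrides)
  }
  if (!is.null(settings))
    out$solver <- Filter(Negate(is.null),
                         settings[c("method", "rtol", "atol", "dt", "floor",
                                    "extinction_threshold",
                                    "transient_frac", "maxsteps")])
  if (!is.null(extensions)) {
    ext <- normalize_extensions(extensions)
    out$extensions <- list(sensitive_bacteria = ext$sensitive,
                           double_lysogens = ext$double_lysogens,
                           lysis_time_tau = ext$tau,
                           coinfection_kappa = ext$kappa)
  }
  if (!is.null(initial_conditions)) out$initial_conditions <- initial_conditions
  if (!is.null(scenario)) out$scenario <- scenario
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Write / read a trajectory as tidy CSV plus a JSON provenance sidecar
#'
#' The CSV holds the long-format densities (`time`, `class`, `strain_f`,
#' `population_type`, `density`, 17 significant digits); the sidecar
#' (`<file>.json`) holds parameters, community structure, solver settings,
#' extension flags and the seed, and round-trips exactly.
#'
#' @param traj A [simulate_community()] trajectory.
#' @param file CSV path; the sidecar is written next to it.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "phage_trajectory"))
  df <- as.data.frame(traj)
  df$density <- formatC(df$density, digits = 17, format = "g")
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  side <- list(parameters = traj$params[c("alpha", "gamma", "delta",
                                          "k", "b")],
               community = list(classes = traj$config$classes),
               solver = traj$settings[c("method", "rtol", "atol", "dt",
                                        "floor", "transient_frac")],
               extensions = unclass(traj$extensions),
               seed = traj$seed,
               t_range = range(traj$times),
               state_names = colnames(traj$log_state))
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(file)
}

#' @rdname write_trajectory
#' @param log_state Return the matrix in log densities (natural log).
#' @return For `read_trajectory`: a list with `times`, `state` (wide
#'   density matrix) and `provenance` (the parsed sidecar).
#' @export
read_trajectory <- function(file, log_state = FALSE) {
  df <- utils::read.csv(file)
  side_path <- paste0(file, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path,
                                                          simplifyVector = TRUE)
  times <- sort(unique(df$time))
  key <- paste(df$population_type, df$class, df$strain_f)
  cols <- unique(key)
  state <- matrix(NA_real_, length(times), length(cols),
                  dimnames = list(NULL, cols))
  ti <- match(df$time, times)
  ci <- match(key, cols)
  state[cbind(ti, ci)] <- df$density
  if (!is.null(side$state_names) &&
      length(side$state_names) == ncol(state))
    colnames(state) <- side$state_names
  list(times = times,
       state = if (log_state) log(state) else state,
       provenance = side)
}

#' Write a scenario ensemble to disk
#'
#' Writes one trajectory CSV (+ JSON sidecar) per run, the ensemble table
#' as CSV, the per-run summaries as JSON, and a manifest
#' (`manifest.json`) listing package version, scenario, seeds, a
#' configuration hash stable under key reordering, and the files actually
#' written. Re-running with identical inputs overwrites deterministically.
#'
#' @param result A [run_scenario()] result (or an [run_nc_sweep()] result,
#'   which writes its tables only).
#' @param out_dir Output directory, created if needed.
#' @param trajectories Also write per-run trajectory CSVs (they are large).
#' @return The manifest, invisibly.
#' @export
write_ensemble <- function(result, out_dir, trajectories = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (inherits(result, "scenario_result")) {
    if (trajectories) {
      for (nm in names(result$runs)) {
        f <- file.path(out_dir, sprintf("trajectory_seed%s.csv", nm))
        write_trajectory(result$runs[[nm]]$trajectory, f)
        files <- c(files, f, paste0(f, ".json"))
      }
    }
    if (!is.null(result$ensemble) && nrow(result$ensemble)) {
      f <- file.path(out_dir, "ensemble.csv")
      utils::write.csv(format_sig(result$ensemble), f, row.names = FALSE,
                       quote = FALSE)
      files <- c(files, f)
    }
    summaries <- lapply(result$runs, function(r)
      c(list(seed = r$seed, outcome = r$stats$outcome,
             lyapunov = if (!is.null(r$stats$lyapunov))
               r$stats$lyapunov$lambda),
        list(strains = r$stats$strains)))
    f <- file.path(out_dir, "summaries.json")
    jsonlite::write_json(summaries, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
    files <- c(files, f)
    cfg_for_hash <- list(name = result$spec$name,
                         classes = result$spec$config$classes,
                         params = unclass(result$spec$params),
                         duration = result$spec$duration,
                         seeds = result$spec$seeds)
    scen_name <- result$spec$name
    seeds <- result$spec$seeds
  } else if (inherits(result, "nc_sweep")) {
    f <- file.path(out_dir, "sweep_table.csv")
    utils::write.csv(format_sig(result$table), f, row.names = FALSE,
                     quote = FALSE)
    f2 <- file.path(out_dir, "sweep_summary.csv")
    utils::write.csv(format_sig(result$summary), f2, row.names = FALSE,
                     quote = FALSE)
    files <- c(files, f, f2)
    cfg_for_hash <- list(params = unclass(result$params), f = result$f,
                         duration = result$duration,
                         ncs = unique(result$table$nc))
    scen_name <- "nc_sweep"
    seeds <- unique(result$table$seed)
  } else stop("unsupported result type", call. = FALSE)

  manifest <- list(
    package = "lysochaos",
    version = as.character(utils::packageVersion("lysochaos")),
    scenario = scen_name,
    config_hash = config_hash(cfg_for_hash),
    seeds = seeds,
    timestamp = format(Sys.time(), tz = "UTC"),
    files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

format_sig <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
  df
}

#' Order-independent configuration hash
#'
#' Canonicalizes a nested list (sorting names at every level) and hashes
#' its JSON serialization with FNV-1a (64-bit, reported as hex). Stable
#' under key reordering; any value change changes the hash.
#'
#' @param x A nested list of scalars/vectors.
#' @return A 16-character hex string.
#' @export
config_hash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v)) && any(nzchar(names(v))))
        v <- v[order(names(v))]
      lapply(v, canon)
    } else v
  }
  s <- jsonlite::toJSON(canon(x), auto_unbox = TRUE, digits = NA)
  fnv1a64(charToRaw(as.character(s)))
}

# 64-bit FNV-1a implemented on two 32-bit halves (R has no native uint64).
fnv1a64 <- function(bytes) {
  lo <- 0x84222325; hi <- 0xcbf29ce4
  plo <- 0x1b3; phi <- 0x100
  mask <- 2^32
  for (b in as.integer(bytes)) {
    lo <- bitwXor32(lo, b)
    # (hi,lo) * (phi,plo) mod 2^64, schoolbook on 16-bit limbs via doubles
    new_lo <- (lo * plo) %% mask
    carry <- floor((lo * plo) / mask)
    new_hi <- (hi * plo + lo * phi + carry) %% mask
    lo <- new_lo; hi <- new_hi
  }
  paste0(hex32(hi), hex32(lo))
}

hex32 <- function(v) {
  sprintf("%04x%04x", as.integer(v %/% 65536), as.integer(v %% 65536))
}

bitwXor32 <- function(a, b) {
  # R's bitwXor works on 32-bit signed ints; keep values in [0, 2^32)
  r <- bitwXor(as.integer(a %% 2^31), as.integer(b %% 2^31))
  if (a >= 2^31) r <- r + 2^31
  (r %% 2^32)
}

#' Deterministic small test fixtures
#'
#' Canonical small instances used across the test suite and examples.
#'
#' * `tiny`: two classes, one temperate strain each, 50 generations.
#' * `chaos`: the three-class single-temperate chaotic community.
#' * `fixed-point`: a symmetric community initialized exactly at its fixed
#'   point.
#' * `pairwise`: the same-class lytic/temperate competition pair.
#'
#' @param kind One of `"tiny"`, `"chaos"`, `"fixed-point"`, `"pairwise"`.
#' @param seed Base seed; derived seeds are deterministic in it.
#' @return A list with `config`, `params`, `init`, `settings`, `t_end`,
#'   `seed`.
#' @export
#' @examples
#' fx <- make_fixture("tiny", seed = 1)
#' traj <- simulate_community(fx$config, fx$params, fx$init, fx$t_end, fx$settings)
make_fixture <- function(kind = c("tiny", "chaos", "fixed-point",
                                  "pairwise"), seed = 1) {
  kind <- match.arg(kind)
  params <- default_parameters()
  settings <- solver_settings()
  if (kind == "tiny") {
    config <- community_config(list(0.3, 0.3))
    init <- sample_initial_state(config, seed = seed)
    t_end <- 50
  } else if (kind == "chaos") {
    config <- community_config(rep(list(0.3), 3))
    init <- sample_initial_state(config, seed = seed)
    t_end <- 2000
  } else if (kind == "fixed-point") {
    fp <- fixed_point_state(params, Nc = 3, f = 0.3)
    config <- fp$config
    init <- fp$state
    t_end <- 100
  } else {
    config <- community_config(list(c(0, 0.3)))
    init <- sample_initial_state(config, seed = seed)
    t_end <- 2000
  }
  list(config = config, params = params, init = init,
       settings = settings, t_end = t_end, seed = seed)
}
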