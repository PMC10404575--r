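.config_keys <- c("task", "model", "profile", "delta_I", "D", "t_max", "dt",
                  "seed", "store_dt", "burn_in", "u_resp", "resp_frac",
                  "min_cycles", "sigma", "tau_n", "delta_I_values", "reps",
                  "control", "from", "to", "step", "points", "out_dir")

#' Run a declarative analysis configuration
#'
#' Executes a pipeline described by a flat configuration (a YAML file path or
#' an equivalent named list) and writes its artifacts to `out_dir`. Tasks:
#' \describe{
#'   \item{`simulate`}{(default) simulate, classify percepts, compute
#'     statistics; writes `trajectory.csv`, `durations.csv`, `stats.json`.}
#'   \item{`levelt`}{mean-duration curve over `delta_I_values`; writes
#'     `levelt.csv`.}
#'   \item{`bistability`}{regime scan of the simplified model over a `D` grid
#'     (`from`, `to`, `step`); writes `regimes.csv`.}
#'   \item{`fit_sigmoid`}{least-squares nonlinearity fit to a `points` CSV
#'     (columns `delta_I`, `f`); writes `nonlinearity.json`.}
#' }
#' Outputs are written atomically (temporary file, then rename), and
#' `run.log` records the effective parameters and seed. Unknown configuration
#' keys raise a validation error naming them.
#'
#' @param config path to a YAML file, or a named list.
#' @param out_dir output directory (created if missing); defaults to the
#'   config's `out_dir` or `"."`.
#' @return Invisibly, a named list of the files written.
#' @export
run_config <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a file path or a named list")
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  get <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  task <- get("task", "simulate")
  out_dir <- if (!is.null(out_dir)) out_dir else get("out_dir", ".")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- get("seed", 1L)
  profile <- model_profile(get("profile", "table1"))
  if (!is.null(cfg$sigma)) profile$noise$sigma <- cfg$sigma
  if (!is.null(cfg$tau_n)) profile$noise$tau_n <- cfg$tau_n

  atomically <- function(filename, writer) {
    path <- file.path(out_dir, filename)
    tmp <- tempfile(tmpdir = out_dir)
    ok <- FALSE
    tryCatch({ writer(tmp); ok <- TRUE }, finally = if (!ok) unlink(tmp))
    file.rename(tmp, path)
    path
  }
  written <- list()

  if (task == "simulate") {
    stim <- stimulus_params(get("delta_I", 2))
    traj <- simulate_model(get("model", "full"), stim = stim,
                           profile = profile, t_max = get("t_max", 90),
                           dt = get("dt", 1e-5), seed = seed,
                           D = get("D", NULL),
                           store_dt = get("store_dt", 1e-3),
                           burn_in = get("burn_in", 2))
    seqp <- percept_durations(traj, u_resp = get("u_resp", 0.5),
                              resp_frac = get("resp_frac", 0.5),
                              min_cycles = get("min_cycles", 1))
    written$trajectory <- atomically("trajectory.csv",
                                     function(p) write_trajectory(traj, p))
    written$durations <- atomically("durations.csv",
                                    function(p) write_percepts(seqp, p))
    st <- tryCatch(duration_stats(seqp), error = function(e) NULL)
    if (!is.null(st)) {
      written$stats <- atomically("stats.json",
                                  function(p) write_stats_json(st, p))
    }
  } else if (task == "levelt") {
    dvals <- get("delta_I_values", c(0.5, 1, 2, 4, 6))
    lc <- levelt_curve(dvals, reps = get("reps", 5),
                       t_max = get("t_max", 600), seed = seed,
                       profile = profile, dt = get("dt", 5e-5))
    written$levelt <- atomically("levelt.csv", function(p)
      utils::write.csv(lc, p, row.names = FALSE))
  } else if (task == "bistability") {
    grid <- seq(get("from", 0.5), get("to", 2.5), by = get("step", 0.1))
    sc <- bistability_scan(grid, model = get("model", "simplified"),
                           control = get("control", "D"),
                           stim = stimulus_params(get("delta_I", 0.5)),
                           t_max = get("t_max", 50), dt = get("dt", 5e-5))
    written$regimes <- atomically("regimes.csv", function(p)
      utils::write.csv(sc, p, row.names = FALSE))
  } else if (task == "fit_sigmoid") {
    pts <- if (!is.null(cfg$points)) utils::read.csv(cfg$points) else f_points()
    nl <- fit_sigmoid(pts, seed = seed)
    written$nonlinearity <- atomically("nonlinearity.json", function(p)
      jsonlite::write_json(list(f0 = nl$f0, f1 = nl$f1, r = nl$r,
                                delta_I0 = nl$delta_I0,
                                sse = attr(nl, "sse"),
                                converged = attr(nl, "converged")),
                           p, auto_unbox = TRUE, digits = NA))
  } else {
    stop("unknown task: ", task)
  }

  log_lines <- c(sprintf("tactrivalry %s",
                         as.character(utils::packageVersion("tactrivalry"))),
                 sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("task: %s", task),
                 sprintf("seed: %s", seed),
                 sprintf("profile: %s", profile$profile),
                 paste0("params: ",
                        paste(names(flatten_params(profile)),
                              unlist(flatten_params(profile)),
                              sep = "=", collapse = " ")),
                 paste0("config: ",
                        paste(names(cfg), unlist(lapply(cfg, paste,
                                                        collapse = ",")),
                              sep = "=", collapse = " ")))
  written$log <- atomically("run.log", function(p) writeLines(log_lines, p))
  invisible(written)
}
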