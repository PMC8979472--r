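#' Write a trajectory to CSV
#'
#' Header `time,M,P1,...,PJ,P[,AT][,V|R]`.  The full effective
#' configuration (model variant and parameters) is embedded as a JSON
#' comment on the first line, so a file round-trips to an identical run
#' setup.
#'
#' @param traj a `clock_trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "clock_trajectory"))
  meta <- jsonlite::toJSON(
    list(spec = unclass(traj$spec), params = unclass(traj$params)),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  df <- data.frame(time = traj$times, traj$states)
  names(df) <- c("time", traj$species)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV file.
#' @return a `clock_trajectory`.
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# "))
    stop("not a trajectory file (missing configuration header)")
  meta <- jsonlite::fromJSON(sub("^# ", "", first))
  spec <- clock_model(meta$spec$family, meta$spec$law, meta$spec$degradation,
                      meta$spec$N)
  params <- do.call(clock_params, c(list(spec = spec), meta$params))
  df <- read.csv(path, comment.char = "#")
  structure(
    list(times = df$time,
         states = unname(as.matrix(df[, -1, drop = FALSE])),
         species = names(df)[-1], spec = spec, params = params),
    class = "clock_trajectory")
}

#' Write an oscillation summary (or any result list) as JSON
#'
#' @param x an `osc_summary` or plain list.
#' @param path output file.
#' @param config optional configuration list embedded under `$config`.
#' @export
write_summary <- function(x, path, config = NULL) {
  out <- lapply(unclass(x), function(v) if (is.numeric(v) || is.logical(v) ||
                                            is.character(v)) v else NULL)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!is.null(config)) out$config <- config
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Assemble a run configuration
#'
#' A declarative description of one run of the toolkit: what model (a
#' preset name, or an explicit spec + parameter list -- mutually
#' exclusive), which kind of computation, the numerical settings, the
#' seed, and where to write outputs.
#'
#' @param kind one of "simulate", "hopf", "fivepoint", "calibrate",
#'   "scan", "optimize".
#' @param preset preset name understood by [clock_preset()], or `NULL`.
#' @param spec,params explicit model (used when `preset` is `NULL`).
#' @param out output file path (or `NULL` for no file output).
#' @param seed RNG seed recorded in every output.
#' @param options named list of kind-specific settings (e.g. `t_end`,
#'   `rtol`, grids, `beta_hat`, `iterations`, `restarts`).
#' @return a `run_config` list.
#' @export
run_config <- function(kind = c("simulate", "hopf", "fivepoint",
                                "calibrate", "scan", "optimize"),
                       preset = NULL, spec = NULL, params = NULL,
                       out = NULL, seed = 1, options = list()) {
  kind <- match.arg(kind)
  if (!is.null(preset) && (!is.null(spec) || !is.null(params)))
    stop("give either a preset or an explicit spec + params, not both")
  if (is.null(preset) && (is.null(spec) || is.null(params)) &&
      kind != "hopf")
    stop("a preset or an explicit spec + params is required")
  structure(list(kind = kind, preset = preset, spec = spec, params = params,
                 out = out, seed = seed, options = options),
            class = "run_config")
}

config_model <- function(config) {
  if (!is.null(config$preset)) {
    p <- clock_preset(config$preset)
    list(spec = p$spec, params = p$params, beta_hat = p$beta_hat)
  } else {
    list(spec = config$spec, params = config$params,
         beta_hat = config$options$beta_hat %||% NA_real_)
  }
}

serializable_config <- function(config) {
  list(kind = config$kind, preset = config$preset,
       spec = if (!is.null(config$spec)) unclass(config$spec),
       params = if (!is.null(config$params)) unclass(config$params),
       seed = config$seed, options = config$options)
}

#' Execute a run configuration
#'
#' Dispatches on `config$kind`, writes the requested artifacts (CSV for
#' trajectories and loci, JSON for summaries; every output embeds the
#' effective configuration and seed), and returns the computed result
#' invisibly.
#'
#' @param config a [run_config()].
#' @return the result object of the underlying computation, invisibly.
#' @export
run_clock <- function(config) {
  stopifnot(inherits(config, "run_config"))
  opt <- config$options
  set.seed(config$seed)
  m <- config_model(config)
  cfg <- serializable_config(config)

  result <- switch(config$kind,
    simulate = {
      r <- simulate_clock(m$spec, m$params,
                          t_end = opt$t_end %||% 600,
                          rtol = opt$rtol %||% 1e-8,
                          atol = opt$atol %||% 1e-10)
      if (!is.null(config$out)) {
        write_trajectory(r$trajectory, config$out)
        write_summary(r$summary, paste0(config$out, ".summary.json"),
                      config = cfg)
      }
      r
    },
    hopf = {
      N <- opt$N %||% m$spec$N %||% 3
      law <- opt$law %||% m$spec$law %||% "law0"
      K_A <- opt$K_A %||% (m$params$K_A %||% 0)
      grid <- opt$A_T_grid %||%
        exp(seq(log(1), log(1e4), length.out = 200))
      locus <- hopf_locus(N, grid, K_A = K_A, law = law)
      if (!is.null(config$out))
        write.csv(as.data.frame(locus), config$out, row.names = FALSE)
      locus
    },
    fivepoint = {
      r <- five_point(m$spec, m$params)
      if (!is.null(config$out))
        write_summary(list(pass = r$pass, verdicts = as.list(r$verdicts)),
                      config$out, config = cfg)
      r
    },
    calibrate = {
      r <- calibration_report(m$spec, m$params,
                              beta_hat = if (is.na(m$beta_hat)) NULL
                                         else m$beta_hat)
      if (!is.null(config$out)) write_summary(r, config$out, config = cfg)
      r
    },
    scan = {
      sc <- domain_scan(m$spec, m$params,
                        x_name = opt$x_name %||% "alpha",
                        y_name = opt$y_name %||% "A_T",
                        x_grid = opt$x_grid, y_grid = opt$y_grid,
                        t_end = opt$t_end %||% 300,
                        n_out = opt$n_out %||% 6000,
                        rtol = opt$rtol %||% 1e-6,
                        atol = opt$atol %||% 1e-8)
      if (!is.null(config$out)) {
        df <- data.frame(
          x = rep(sc$x_grid, times = length(sc$y_grid)),
          y = rep(sc$y_grid, each = length(sc$x_grid)),
          oscillatory = as.vector(sc$mask),
          period = as.vector(sc$period))
        names(df)[1:2] <- c(sc$x_name, sc$y_name)
        write.csv(df, config$out, row.names = FALSE)
        write_summary(list(n_oscillatory = sum(sc$mask)),
                      paste0(config$out, ".meta.json"), config = cfg)
      }
      sc
    },
    optimize = {
      problem <- search_problem(m$spec)
      r <- anneal(problem,
                  iterations = opt$iterations %||% 300,
                  restarts = opt$restarts %||% 20,
                  seed = config$seed)
      if (!is.null(config$out)) {
        lines <- if (!is.null(r$batch))
          vapply(seq_len(nrow(r$batch)), function(i)
            as.character(jsonlite::toJSON(as.list(r$batch[i, ]),
                                          auto_unbox = TRUE, digits = NA)),
            character(1)) else character(0)
        writeLines(lines, config$out)
        write_summary(r$summary %||% list(), paste0(config$out, ".summary.json"),
                      config = cfg)
      }
      r
    })
  invisible(result)
}
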