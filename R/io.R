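# Valid flat-config keys and their domains. Parameter fields resolve into
# rescue_params; run fields steer the drivers.
config_keys <- function() {
  list(
    preset = "one of the preset names",
    lambda_s = "[0, Inf) 1/day", mu_s = "[0, Inf) 1/day",
    lambda_a = "[0, Inf) 1/day", mu_a = "[0, Inf) 1/day",
    lambda_m = "[0, Inf) 1/day", mu_m = "[0, Inf) 1/day",
    u = "[0, 1) per division", u_pre = "[0, 1) per division",
    v = "[0, 1) per division", v_a = "[0, 1) per division",
    c = "(0, Inf) 1/day", n_init = "(0, Inf) cells",
    carrying_capacity = "(0, Inf) cells or empty",
    method = "ssa | tau | logistic", replicates = "integer >= 1",
    seed = "integer", tau_step = "(0, Inf) days",
    record_interval = "(0, Inf) days",
    max_time = "(0, Inf) days", max_events = "(0, Inf)",
    establishment = "integer >= 0", recurrence_target = "integer >= 1",
    detection_target = "integer >= 1",
    out_dir = "writable directory", scaled = "true | false"
  )
}

param_fields <- c("lambda_s", "mu_s", "lambda_a", "mu_a", "lambda_m", "mu_m",
                  "u", "u_pre", "v", "v_a", "c", "n_init", "carrying_capacity")

#' Load a flat key-value run configuration
#'
#' Reads a plain-text configuration of `key = value` lines (`#` comments
#' and blank lines ignored; scientific notation accepted for numerics).
#' Unknown keys are rejected with the list of valid keys; type and range
#' violations are reported with the key name and expected domain. A
#' `preset` key resolves the full literature parameter set and any
#' parameter key of the same name overrides the preset value.
#'
#' @param path Path to the configuration file.
#' @param overrides Named list applied on top of the file (CLI flags).
#' @return A list of class `rescue_config` with elements `params`
#'   (a `rescue_params` tibble) and the run fields.
#' @export
load_config <- function(path, overrides = list()) {
  if (!is.null(path) && !file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path))
  }
  kv <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) != 3) {
        rlang::abort(paste0("cannot parse config line: '", ln,
                            "'; expected 'key = value'"))
      }
      kv[[m[2]]] <- trimws(m[3])
    }
  }
  kv[names(overrides)] <- overrides
  resolve_config(kv)
}

resolve_config <- function(kv) {
  valid <- names(config_keys())
  bad <- setdiff(names(kv), valid)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown config key(s): ", paste(bad, collapse = ", "),
                        "; valid keys: ", paste(valid, collapse = ", ")))
  }
  num <- function(key, lo = -Inf, hi = Inf, lo_open = FALSE, hi_open = FALSE) {
    if (is.null(kv[[key]])) return(NULL)
    x <- suppressWarnings(as.numeric(kv[[key]]))
    domain <- config_keys()[[key]]
    if (is.na(x)) {
      rlang::abort(paste0("config key `", key, "`: '", kv[[key]],
                          "' is not a number; expected ", domain))
    }
    ok <- (if (lo_open) x > lo else x >= lo) &
          (if (hi_open) x < hi else x <= hi)
    if (!ok) {
      rlang::abort(paste0("config key `", key, "` = ", x,
                          " outside its domain ", domain))
    }
    x
  }
  # parameter block: preset plus overrides, or explicit fields
  par_over <- list()
  for (f in param_fields) {
    val <- switch(f,
      u = , u_pre = , v = , v_a = num(f, 0, 1, hi_open = TRUE),
      c = , n_init = , carrying_capacity = num(f, 0, Inf, lo_open = TRUE),
      num(f, 0, Inf))
    if (!is.null(val)) par_over[[f]] <- val
  }
  params <- if (!is.null(kv$preset)) {
    do.call(rescue_preset, c(list(name = kv$preset), par_over))
  } else if (length(par_over) > 0) {
    needed <- setdiff(c("lambda_s", "mu_s", "lambda_a", "mu_a",
                        "lambda_m", "mu_m", "u"), names(par_over))
    if (length(needed) > 0) {
      rlang::abort(paste0("no preset given and parameter fields missing: ",
                          paste(needed, collapse = ", ")))
    }
    do.call(rescue_params, par_over)
  } else {
    NULL
  }
  structure(list(
    params = params,
    method = if (is.null(kv$method)) "ssa" else
      match.arg(kv$method, c("ssa", "tau", "logistic")),
    replicates = if (is.null(kv$replicates)) 100L else
      as.integer(num("replicates", 1, Inf)),
    seed = if (is.null(kv$seed)) NULL else as.integer(num("seed")),
    tau_step = if (is.null(kv$tau_step)) 0.1 else
      num("tau_step", 0, Inf, lo_open = TRUE),
    record_interval = num("record_interval", 0, Inf, lo_open = TRUE),
    max_time = if (is.null(kv$max_time)) 1e6 else
      num("max_time", 0, Inf, lo_open = TRUE),
    max_events = if (is.null(kv$max_events)) 1e9 else
      num("max_events", 0, Inf, lo_open = TRUE),
    establishment = if (is.null(kv$establishment)) NULL else
      num("establishment", 0, Inf),
    recurrence_target = if (is.null(kv$recurrence_target)) NULL else
      num("recurrence_target", 1, Inf),
    detection_target = if (is.null(kv$detection_target)) NULL else
      num("detection_target", 1, Inf),
    out_dir = kv$out_dir,
    scaled = isTRUE(tolower(kv$scaled %||% "false") == "true")
  ), class = "rescue_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_num <- function(x) {
  vapply(x, function(xi) {
    if (is.na(xi)) "NA"
    else if (xi == round(xi) && abs(xi) < 1e15) {
      format(xi, scientific = FALSE, trim = TRUE)
    } else {
      formatC(xi, digits = 12, format = "g")
    }
  }, character(1))
}

write_delim_12 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- format_num(out[[j]])
    if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write and read a trajectory as CSV
#'
#' Fixed dialect: comma separators, one header line `t,s,a,m`, `.` decimal
#' marker, no thousands separators; floating values carry 12 significant
#' digits. Times are in days.
#'
#' @param traj A `rescue_trajectory` tibble.
#' @param path Output path.
#' @return `path` (write) / a tibble (read), invisibly for write.
#' @export
write_trajectory <- function(traj, path) {
  write_delim_12(traj[, c("t", "s", "a", "m")], path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write an ensemble summary as CSV
#'
#' Writes exactly the nine documented columns: `replicate`, `seed`,
#' `outcome`, `rescue_time`, `recurrence_time`, `detection_time`,
#' `final_s`, `final_a`, `final_m`.
#'
#' @param ens A `rescue_ensemble` tibble.
#' @param path Output path.
#' @export
write_ensemble <- function(ens, path) {
  cols <- c("replicate", "seed", "outcome", "rescue_time", "recurrence_time",
            "detection_time", "final_s", "final_a", "final_m")
  write_delim_12(ens[, cols], path)
}

#' Build a run manifest
#'
#' Structured record of everything needed to reproduce a run: resolved
#' parameters, seeds, method, stop rule and package version. Written as
#' JSON next to the data files.
#'
#' @param params A `rescue_params` tibble.
#' @param seed Base seed used.
#' @param method Simulation method.
#' @param stop A [stop_rule()] (optional).
#' @param extra Named list of additional fields.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(params, seed, method = NULL, stop = NULL,
                         extra = list()) {
  m <- c(list(
    package = "aneurescue",
    version = as.character(utils::packageVersion("aneurescue")),
    rng = "R Mersenne-Twister via set.seed; replicate seeds on a Weyl ring",
    seed = seed,
    method = method,
    parameters = as.list(params[1, ]),
    stop_rule = if (!is.null(stop)) unclass(stop)
  ), extra)
  structure(m, class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output path (JSON).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}
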