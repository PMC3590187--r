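# Configuration parsing, seed management, and tabular serialization shared
# by the CLI subcommands.

#' Deterministic child seeds from a master seed
#'
#' One master seed spawns an independent integer seed per replicate, so each
#' replicate is individually reproducible and the set of results does not
#' depend on evaluation order. With `seed = NULL` the seeds are drawn from
#' the current global RNG state (still recorded, so a run can be replayed).
#'
#' @param n Number of child seeds.
#' @param seed Master seed, or `NULL`.
#' @return Integer vector of length `n`.
#' @export
spawn_seeds <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# defaults shared by parse_config and simulation_config
config_defaults <- function() {
  list(mu = 3.2, D = 0.5, L = 30L, L_c = 10L, rho = 0.4, theta = 60, R = 3,
       model = "M1", n_transient = 500L, n_l = 500L, s_t = 500L, seed = NULL,
       coupling_variant = "plain", weight_exponent = 1,
       coupling_form = "map-of-mean", tie_rule = "count-random",
       boundary = "clip")
}

#' Parse a simulation configuration
#'
#' Builds a validated [simulation_config()] from a YAML or JSON file, a
#' named list, or both (`overrides` win over the file, which wins over the
#' defaults). Unknown keys are an error, as is any invariant violation;
#' the error names the offending field.
#'
#' @param source Path to a `.yaml`/`.yml`/`.json` file, a named list, or
#'   `NULL` (defaults only).
#' @param overrides Named list merged on top of `source` (e.g. parsed CLI
#'   flags).
#' @return A [simulation_config()].
#' @examples
#' cfg <- parse_config(list(mu = 3.5, rho = 0.2))
#' cfg$grid$n_ind  # 180
#' @export
parse_config <- function(source = NULL, overrides = list()) {
  vals <- config_defaults()
  from_file <- list()
  if (is.character(source)) {
    if (!file.exists(source)) stop("config file not found: ", source)
    from_file <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
      jsonlite::read_json(source, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(source)
    }
  } else if (is.list(source)) {
    from_file <- source
  } else if (!is.null(source)) {
    stop("'source' must be a file path, a named list, or NULL")
  }
  for (lst in list(from_file, overrides)) {
    if (length(lst) == 0L) next
    if (is.null(names(lst)) || any(names(lst) == "")) {
      stop("config entries must all be named")
    }
    unknown <- setdiff(names(lst), names(vals))
    if (length(unknown) > 0L) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    vals[names(lst)] <- lst
  }
  simulation_config(
    mu = vals$mu, D = vals$D,
    grid = grid_config(vals$L, vals$L_c, vals$rho),
    theta = vals$theta, R = vals$R, model = vals$model,
    n_transient = vals$n_transient, n_l = vals$n_l, s_t = vals$s_t,
    seed = vals$seed,
    coupling_variant = vals$coupling_variant,
    weight_exponent = vals$weight_exponent,
    coupling_form = vals$coupling_form,
    tie_rule = vals$tie_rule, boundary = vals$boundary
  )
}

# flat named list view of a config, for metadata echo and round-trips
config_as_list <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  list(mu = config$mu, D = config$D, L = config$grid$L,
       L_c = config$grid$L_c, rho = config$grid$rho, theta = config$theta,
       R = config$R, model = config$model, n_transient = config$n_transient,
       n_l = config$n_l, s_t = config$s_t, seed = config$seed,
       coupling_variant = config$coupling_variant,
       weight_exponent = config$weight_exponent,
       coupling_form = config$coupling_form, tie_rule = config$tie_rule,
       boundary = config$boundary)
}

# coerce the package's result objects to flat data frames for CSV output
as_result_tables <- function(x) {
  if (inherits(x, "trajectory_set")) {
    nt <- nrow(x$traj)
    list(
      trajectories = data.frame(
        time = rep(seq_len(nt) - 1L, times = ncol(x$traj)),
        individual_id = rep(seq_len(ncol(x$traj)), each = nt),
        x = as.numeric(x$traj)),
      edges = x$network$edges
    )
  } else if (inherits(x, "network_stats")) {
    list(network_stats = data.frame(
      n_leaders = x$n_leaders, n_followers = x$n_followers,
      leaders_per_follower = x$leaders_per_follower,
      leaders_per_follower_influence = x$leaders_per_follower_influence,
      reciprocal_per_participant = x$reciprocal_per_participant,
      n_components = length(x$component_sizes),
      largest_component = if (length(x$component_sizes)) {
        max(x$component_sizes)
      } else NA_integer_))
  } else if (inherits(x, "correlation_summary")) {
    list(replicates = x$per_replicate,
         summary = data.frame(r_global = x$r_global,
                              n_contributing = x$n_contributing,
                              window = x$window))
  } else if (inherits(x, "sync_threshold")) {
    list(threshold_scan = x$table,
         summary = data.frame(threshold = x$threshold, mu = x$mu,
                              mode = x$mode, trials = x$trials))
  } else if (is.data.frame(x)) {
    list(table = x[, !vapply(x, is.list, logical(1)), drop = FALSE])
  } else {
    stop("no serialization rule for class: ", paste(class(x), collapse = "/"))
  }
}

#' Write results and run metadata to disk
#'
#' Serializes a result object (a sweep table, a `"trajectory_set"`, a
#' `"network_stats"`, a `"correlation_summary"` or a `"sync_threshold"`) as
#' CSV files with stable column order, plus a JSON metadata record echoing
#' the configuration, the seed, the package version, timestamps and an MD5
#' manifest of every emitted file. Writing the same run twice yields
#' identical CSV payloads (checksums match).
#'
#' @param x The result object.
#' @param destination Directory to write into (created if needed).
#' @param name Stem used for the file names.
#' @param config Optional [simulation_config()] echoed in the metadata.
#' @param seed Optional master seed echoed in the metadata.
#' @return Invisibly, a list of class `"run_record"`: `files` (paths),
#'   `checksums`, `config`, `seed`, `version`, `started`, `finished`.
#' @export
write_results <- function(x, destination, name = "run", config = NULL,
                          seed = NULL) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!dir.exists(destination)) {
    ok <- dir.create(destination, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create destination directory: ", destination)
  }
  tables <- as_result_tables(x)
  files <- character(0)
  for (tab in names(tables)) {
    path <- file.path(destination, paste0(name, "_", tab, ".csv"))
    utils::write.csv(tables[[tab]], path, row.names = FALSE)
    files <- c(files, path)
  }
  meta_path <- file.path(destination, paste0(name, "_metadata.json"))
  checks <- as.list(tools::md5sum(files))
  names(checks) <- basename(files)
  meta <- list(
    name = name,
    config = if (!is.null(config)) config_as_list(config) else NULL,
    seed = seed,
    package_version = as.character(utils::packageVersion("crabsync")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = checks
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  files <- c(files, meta_path)
  invisible(structure(
    list(files = files, checksums = checks, config = config, seed = seed,
         version = meta$package_version, started = meta$started,
         finished = meta$finished),
    class = "run_record"))
}
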