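#' Read a dihedral ensemble from tabular files
#'
#' The ensemble table is comma- or tab-separated with columns `state_id`,
#' `observable_id`, `obs_type`, `phi_deg` (one row per state/observable
#' pair).  The optional population table has columns `state_id`,
#' `population`; when absent, uniform populations are substituted with a
#' notice.
#'
#' @param path path to the ensemble table.
#' @param populations_path optional path to the population table.
#' @return a [dihedral_ensemble()].
#' @export
read_ensemble <- function(path, populations_path = NULL) {
  tab <- read_table_auto(path)
  need <- c("state_id", "observable_id", "obs_type", "phi_deg")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("ensemble table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  states <- sort(unique(tab$state_id))
  obs <- unique(tab$observable_id)
  phi <- matrix(NA_real_, length(states), length(obs),
                dimnames = list(states, obs))
  idx <- cbind(match(tab$state_id, states), match(tab$observable_id, obs))
  if (anyDuplicated(idx))
    stop("duplicate state/observable pair in ", path, call. = FALSE)
  phi[idx] <- tab$phi_deg
  if (anyNA(phi)) {
    bad <- which(is.na(phi), arr.ind = TRUE)[1, ]
    stop(sprintf("missing angle for state %s, observable %s",
                 states[bad[1]], obs[bad[2]]), call. = FALSE)
  }
  obs_type <- tab$obs_type[match(obs, tab$observable_id)]
  pop <- NULL
  if (!is.null(populations_path)) {
    pt <- read_table_auto(populations_path)
    if (!all(c("state_id", "population") %in% names(pt)))
      stop("population table needs columns state_id, population", call. = FALSE)
    pop <- pt$population[match(states, pt$state_id)]
    if (anyNA(pop)) stop("population table is missing states", call. = FALSE)
    if (abs(sum(pop) - 1) > 1e-6)
      stop(sprintf("populations sum to %.6f, not 1", sum(pop)), call. = FALSE)
  } else {
    message("no population table given; assuming uniform prior populations")
  }
  ens <- dihedral_ensemble(phi, pop, obs_type)
  ens$observable_id <- obs
  ens
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' Write an ensemble (and populations) to tabular files
#'
#' @param ensemble a [dihedral_ensemble()].
#' @param path output path for the ensemble table (CSV).
#' @param populations_path optional output path for the population table.
#' @export
write_ensemble <- function(ensemble, path, populations_path = NULL) {
  stopifnot(inherits(ensemble, "dihedral_ensemble"))
  obs_id <- ensemble$observable_id %||% paste0("obs", seq_len(ensemble$n_obs))
  tab <- data.frame(
    state_id = rep(seq_len(ensemble$n_states), ensemble$n_obs),
    observable_id = rep(obs_id, each = ensemble$n_states),
    obs_type = rep(ensemble$obs_type, each = ensemble$n_states),
    phi_deg = as.numeric(ensemble$phi))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (!is.null(populations_path))
    utils::write.csv(data.frame(state_id = seq_len(ensemble$n_states),
                                population = ensemble$prior_pop),
                     populations_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read experimental observables
#'
#' Table with columns `observable_id`, `obs_type`, `J_exp_Hz`; observables
#' are aligned to the ensemble when one is given.
#'
#' @param path path to the observable table.
#' @param ensemble optional [dihedral_ensemble()] to align against.
#' @return data frame with the validated observables (aligned to the
#'   ensemble order when given).
#' @export
read_observables <- function(path, ensemble = NULL) {
  tab <- read_table_auto(path)
  need <- c("observable_id", "obs_type", "J_exp_Hz")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("observable table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$observable_id))
    stop("duplicate observable_id in ", path, call. = FALSE)
  if (!is.null(ensemble)) {
    ids <- ensemble$observable_id %||% paste0("obs", seq_len(ensemble$n_obs))
    missing_ids <- setdiff(tab$observable_id, ids)
    if (length(missing_ids))
      stop("observable id(s) not in ensemble: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    tab <- tab[match(ids, tab$observable_id), ]
    if (anyNA(tab$observable_id))
      stop("observable table does not cover every ensemble observable",
           call. = FALSE)
  }
  tab
}

#' Read a run configuration from YAML
#'
#' Validates keys against the documented schema and fills defaults; unknown
#' keys are rejected.
#'
#' @param path YAML file.
#' @return a named list of settings.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("ensemble", "populations", "observables", "likelihood",
             "sigma_bounds", "phi_bounds", "theta_bounds", "severity_levels",
             "n_replicas", "n_burn", "n_steps", "lrate", "eta", "step_sigma",
             "step_phi", "step_theta", "seed", "n_chains", "thin",
             "xi_count", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults <- list(likelihood = "good_bad", seed = 1, xi_count = 11,
                   output_dir = ".")
  utils::modifyList(defaults, cfg)
}

config_to_sampler <- function(cfg) {
  args <- cfg[intersect(names(cfg), names(formals(sampler_config)))]
  do.call(sampler_config, args)
}

#' Write a run manifest
#'
#' JSON record of the configuration, seeds, package version, wall time and
#' per-stage acceptance statistics -- enough to regenerate the run.
#'
#' @param path output path.
#' @param config configuration list/object used.
#' @param seed master seed.
#' @param extra named list of additional entries (acceptance rates, stage
#'   summaries).
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  manifest <- c(list(
    package = "bicepsfm",
    version = as.character(utils::packageVersion("bicepsfm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config)), extra)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  file.rename(tmp, path)   # atomic write
  invisible(path)
}

#' Write a posterior trace to CSV
#'
#' Full-precision columnar record of the production samples.
#'
#' @param trace a `posterior_trace`.
#' @param path output CSV path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "posterior_trace"))
  df <- data.frame(u = trace$u, u_prior = trace$u_prior,
                   u_data = trace$u_data)
  for (p in c("A", "B", "C", "sigma_B", "phi")) {
    m <- trace[[p]]
    colnames(m) <- paste(p, trace$types, sep = ".")
    df <- cbind(df, m)
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
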