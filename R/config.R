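#' Default run configuration
#'
#' The full effective configuration of a run: cohort design, learning
#' parameters of the simulator, trial configuration, sonification
#' configuration, and the master seed. Every field has a documented
#' default (see the respective constructors).
#'
#' @param seed master seed.
#' @return An object of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(design = cohort_design(), learning = learning_params(),
                 trial = trial_config(), sonification = sonification_config(),
                 seed = as.integer(seed)), class = "run_config")
}

config_constructors <- function() {
  list(design = cohort_design, learning = learning_params,
       trial = trial_config, sonification = sonification_config)
}

#' Load a run configuration from YAML
#'
#' Reads a flat-sectioned YAML file (`design:`, `learning:`, `trial:`,
#' `sonification:`, `seed:`), applies defaults for every omitted field,
#' and validates each section through its constructor. Unknown sections
#' or keys are rejected with an error naming the offender; so are values
#' that violate a constructor's invariants (e.g. a negative
#' `target_offset`).
#'
#' @param path YAML file path; an empty file yields all defaults.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cons <- config_constructors()
  known <- c(names(cons), "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  cfg <- default_run_config()
  for (sec in names(cons)) {
    vals <- raw[[sec]]
    if (is.null(vals)) next
    fml <- names(formals(cons[[sec]]))
    bad <- setdiff(names(vals), fml)
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    full <- modifyList(lapply(unclass(cfg[[sec]]), identity), vals)
    cfg[[sec]] <- do.call(cons[[sec]], full[intersect(names(full), fml)])
  }
  if (!is.null(raw$seed)) {
    if (!is.numeric(raw$seed) || raw$seed != round(raw$seed))
      stop("seed must be an integer")
    cfg$seed <- as.integer(raw$seed)
  }
  cfg
}

#' Write a run configuration as YAML
#'
#' Inverse of [load_config()]: `load_config(dump_config(cfg))` reproduces
#' `cfg`. Every run's output directory receives a copy of the effective
#' configuration for provenance.
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  plain <- list(design = unclass(cfg$design),
                learning = unclass(cfg$learning),
                trial = unclass(cfg$trial),
                sonification = unclass(cfg$sonification),
                seed = cfg$seed)
  # drop NULL-valued optional fields (YAML has no distinct representation)
  plain <- lapply(plain, function(x) if (is.list(x)) Filter(Negate(is.null), x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  design: %d/group x %d days, %gs @ %g fps\n",
              x$design$n_per_group, x$design$n_days,
              x$design$session_length, x$design$fps))
  cat(sprintf("  trial: target %g mm, tolerance %g mm, refractory %g s\n",
              x$trial$target_offset, x$trial$start_tolerance,
              x$trial$refractory))
  cat(sprintf("  sonification: %g-%g Hz over 0-%g mm\n",
              x$sonification$f_min, x$sonification$f_max,
              x$sonification$d_max))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
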