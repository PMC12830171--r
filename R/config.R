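#' Load a run configuration (YAML or JSON)
#'
#' The configuration externalizes the institutional tables: the alpha/beta
#' assignment list, the default alpha/beta, dose scaling factors per course
#' (optionally per structure), cumulative constraints, DVH bin width, the
#' near-target margin and the default number of optimization structures.
#' Unknown top-level keys are rejected so typos cannot silently change a
#' clinical parameter.
#'
#' @param path .yaml/.yml or .json file.
#' @return object of class \code{run_config} with fields \code{ab_map},
#'   \code{constraints}, \code{dsf}, \code{dvh_bin_width},
#'   \code{near_margin_mm}, \code{n_structures}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  known <- c("alpha_beta", "default_ab", "ab_map_version", "dsf",
             "constraints", "dvh_bin_width", "near_margin_mm", "n_structures")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  entries <- if (length(raw$alpha_beta))
    do.call(rbind, lapply(raw$alpha_beta, function(e)
      data.frame(structure = e$structure, ab = e$ab, priority = e$priority)))
  else NULL
  ab_map <- alpha_beta_map(entries, default_ab = raw$default_ab %||% 3,
                           version = raw$ab_map_version %||% "unversioned")
  constraints <- lapply(raw$constraints %||% list(), function(cn)
    constraint(cn$structure, cn$metric, cn$limit,
               alpha_beta = cn$alpha_beta %||% (raw$default_ab %||% 3)))
  dsf <- lapply(raw$dsf %||% list(), function(e)
    list(course = e$course, structure = e$structure,
         value = dose_scaling_factor(e$value)$value))
  structure(list(ab_map = ab_map, constraints = constraints, dsf = dsf,
                 dvh_bin_width = raw$dvh_bin_width %||% 0.1,
                 near_margin_mm = raw$near_margin_mm %||% 20,
                 n_structures = raw$n_structures %||% 3),
            class = "run_config")
}

#' Default run configuration (neutral values; no institutional table)
#' @return a \code{run_config} with default_ab = 3 Gy, no constraints, no
#'   scaling factors.
#' @export
default_run_config <- function() {
  structure(list(ab_map = alpha_beta_map(), constraints = list(),
                 dsf = list(), dvh_bin_width = 0.1, near_margin_mm = 20,
                 n_structures = 3),
            class = "run_config")
}
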