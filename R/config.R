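# Structured key-value model configuration (YAML).

#' Read a model configuration file
#'
#' Reads a YAML file with top-level keys `abundances`, `kinetics` and
#' optionally `u`, and builds the corresponding network. Missing abundance
#' or kinetic entries fall back to the package defaults.
#'
#' @param path path to the YAML configuration.
#' @return An `rr_network`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ab <- unclass(default_abundances())
  if (!is.null(cfg$abundances)) {
    unknown <- setdiff(names(cfg$abundances), abundance_names())
    if (length(unknown) > 0) stop("unknown abundance field(s): ",
                                  paste(unknown, collapse = ", "))
    ab[names(cfg$abundances)] <- as.numeric(cfg$abundances)
  }
  kin <- unclass(default_kinetics())
  if (!is.null(cfg$kinetics)) {
    unknown <- setdiff(names(cfg$kinetics), kinetics_names())
    if (length(unknown) > 0) stop("unknown kinetic constant(s): ",
                                  paste(unknown, collapse = ", "))
    kin[names(cfg$kinetics)] <- as.numeric(cfg$kinetics)
  }
  u <- if (is.null(cfg$u)) 0 else as.numeric(cfg$u)
  build_network(structure(ab, class = "rr_abundances"),
                as_kinetics(kin), u = u)
}

#' Write a network to a model configuration file
#'
#' @param network an `rr_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(network, path) {
  cfg <- list(
    abundances = as.list(setNames(as.numeric(network$abundances),
                                  abundance_names())),
    kinetics = as.list(setNames(as.numeric(network$kinetics),
                                kinetics_names())),
    u = network$u
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
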