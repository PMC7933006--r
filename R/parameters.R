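#' Kinetic parameter sets
#'
#' A \code{trp_params} object holds, per reaction, the capacity
#' \code{vmax} (concentration/time) and per-substrate affinities \code{km}
#' (concentration) for Michaelis-Menten reactions, the reversibility bias
#' \code{keq_bias} for antiport exchange, the rate constant \code{kclear}
#' (1/time) for first-order clearances, and \code{km_oxygen} for
#' oxygen-dependent reactions (used only when the model's oxygen term is
#' enabled); plus the global dimensionless \code{oxygen_level} in [0, 1].
#'
#' @param reactions named list of per-reaction parameter lists.
#' @param oxygen_level global oxygen availability in [0, 1].
#' @return a \code{trp_params} object.
#' @export
trp_params <- function(reactions, oxygen_level = 1) {
  p <- structure(list(reactions = reactions, oxygen_level = oxygen_level),
                 class = "trp_params")
  validate_trp_params(p)
  p
}

#' @rdname trp_params
#' @param params object to validate.
#' @export
validate_trp_params <- function(params) {
  stopifnot(inherits(params, "trp_params"))
  if (!is.numeric(params$oxygen_level) || params$oxygen_level < 0 ||
      params$oxygen_level > 1)
    stop("oxygen_level must lie in [0, 1]")
  for (id in names(params$reactions)) {
    p <- params$reactions[[id]]
    for (f in c("vmax", "kclear", "keq_bias", "km_oxygen"))
      if (!is.null(p[[f]]) && (!is.numeric(p[[f]]) || any(p[[f]] <= 0)))
        stop("parameter ", f, " of ", id, " must be > 0")
    if (!is.null(p$km) && any(unlist(p$km) <= 0))
      stop("km of ", id, " must be > 0")
  }
  invisible(params)
}

#' Default kinetic parameters for the hepatocyte Trp model
#'
#' Reads the versioned parameter file shipped with the package
#' (\code{extdata/trp_parameters_v1.yaml}) and subsets it to the reactions
#' present in \code{model}. The defaults are designed so that at the
#' normoxic baseline every reaction operates below saturation (steady-state
#' substrate within roughly an order of magnitude of its Km, so expression
#' scaling of capacities propagates into fluxes) and the kynurenine pathway
#' carries the large majority of Trp consumption, as it does in liver.
#'
#' @param model a \code{trp_model}.
#' @param file alternative parameter YAML path.
#' @return a \code{trp_params} object.
#' @export
default_parameters <- function(model,
                               file = system.file("extdata",
                                                  "trp_parameters_v1.yaml",
                                                  package = "trpflux")) {
  if (!nzchar(file) || !file.exists(file))
    stop("parameter file not found: ", file)
  all <- read_parameters(file)
  need <- names(model$reactions)
  missing <- setdiff(need, names(all$reactions))
  if (length(missing))
    stop("parameter file lacks reactions: ", paste(missing, collapse = ", "))
  trp_params(all$reactions[need], oxygen_level = all$oxygen_level)
}

#' Read / write parameter sets as YAML
#'
#' @param file YAML path.
#' @return \code{read_parameters} returns a \code{trp_params};
#'   \code{write_parameters} returns the path invisibly.
#' @export
read_parameters <- function(file) {
  y <- yaml::read_yaml(file)
  rx <- lapply(y$reactions, function(p) {
    if (!is.null(p$km)) p$km <- unlist(p$km)
    p
  })
  trp_params(rx, oxygen_level = if (is.null(y$oxygen_level)) 1 else y$oxygen_level)
}

#' @rdname read_parameters
#' @param params a \code{trp_params}.
#' @export
write_parameters <- function(params, file) {
  validate_trp_params(params)
  y <- list(oxygen_level = params$oxygen_level,
            reactions = lapply(params$reactions, function(p) {
              if (!is.null(p$km)) p$km <- as.list(p$km)
              p
            }))
  yaml::write_yaml(y, file)
  invisible(file)
}
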