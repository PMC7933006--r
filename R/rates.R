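#' Stoichiometric matrix of a model
#'
#' Net stoichiometric coefficients of every dynamic species (rows) in every
#' reaction (columns). Boundary species are clamped and therefore excluded
#' from the rows; their participation in a reaction affects the rate law
#' but not the state derivative.
#'
#' @param model a \code{trp_model}.
#' @return numeric matrix, dynamic species x reactions, with dimnames.
#' @examples
#' N <- stoichiometric_matrix(build_trp_model())
#' N["Trp", "R_TDO2"]   # -1
#' @export
stoichiometric_matrix <- function(model) {
  dyn <- dynamic_species(model)
  N <- matrix(0, nrow = length(dyn), ncol = length(model$reactions),
              dimnames = list(dyn, names(model$reactions)))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (s in names(r$substrates))
      if (s %in% dyn) N[s, j] <- N[s, j] - r$substrates[[s]]
    for (s in names(r$products))
      if (s %in% dyn) N[s, j] <- N[s, j] + r$products[[s]]
  }
  N
}

#' Evaluate reaction rates at a concentration state
#'
#' Rate laws:
#' \itemize{
#'   \item \code{irreversible_mm}: \eqn{v = V_{max} S/(K_m+S)}, multiplied by
#'     \eqn{O_2/(K_{m,O_2}+O_2)} when the model's oxygen term is enabled and
#'     the reaction is oxygen-dependent;
#'   \item \code{antiport_exchange} (substrate order S_out, C_in; product
#'     order S_in, C_out): \eqn{v = V_{max}(S_{out}C_{in} - b\,S_{in}C_{out})
#'     / ((K_{m,S}+S_{out}+S_{in})(K_{m,C}+C_{in}+C_{out}))} with
#'     reversibility bias \eqn{b} (\code{keq_bias}); net inward transport of
#'     S is positive;
#'   \item \code{first_order_clearance}: \eqn{v = k_{clear} S}.
#' }
#'
#' @param model a \code{trp_model}.
#' @param conc named numeric vector of concentrations covering every species
#'   in the model (boundary included). Must be non-negative.
#' @param params a \code{trp_params} object; defaults to the model's.
#' @return named numeric vector of per-reaction rates.
#' @examples
#' m <- build_trp_model()
#' conc <- setNames(m$species$initial_concentration, m$species$id)
#' conc["Trp"] <- 2  # at S = Km the TDO2 rate is Vmax/2
#' evaluate_rates(m, conc)["R_TDO2"]
#' @export
evaluate_rates <- function(model, conc, params = model$params) {
  missing <- setdiff(model$species$id, names(conc))
  if (length(missing))
    stop("concentrations missing for species: ", paste(missing, collapse = ", "))
  if (any(!is.finite(conc[model$species$id])))
    stop("non-finite concentration")
  if (any(conc[model$species$id] < 0))
    stop("negative concentration: ",
         paste(names(conc)[conc < 0 & names(conc) %in% model$species$id],
               collapse = ", "))
  o2 <- params$oxygen_level
  v <- numeric(length(model$reactions))
  names(v) <- names(model$reactions)
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    p <- params$reactions[[r$id]]
    if (is.null(p)) stop("no parameters for reaction ", r$id)
    v[j] <- switch(r$rate_law,
      irreversible_mm = {
        s <- conc[[names(r$substrates)[1L]]]
        rate <- p$vmax * s / (p$km[[names(r$substrates)[1L]]] + s)
        if (model$oxygen_term && isTRUE(r$oxygen_dependent))
          rate <- rate * o2 / (p$km_oxygen + o2)
        rate
      },
      antiport_exchange = {
        s_out <- conc[[names(r$substrates)[1L]]]
        c_in  <- conc[[names(r$substrates)[2L]]]
        s_in  <- conc[[names(r$products)[1L]]]
        c_out <- conc[[names(r$products)[2L]]]
        km_s <- p$km[[names(r$substrates)[1L]]]
        km_c <- p$km[[names(r$substrates)[2L]]]
        p$vmax * (s_out * c_in - p$keq_bias * s_in * c_out) /
          ((km_s + s_out + s_in) * (km_c + c_in + c_out))
      },
      first_order_clearance = p$kclear * conc[[names(r$substrates)[1L]]],
      stop("unknown rate law: ", r$rate_law))
  }
  v
}

#' Time derivatives of the dynamic species
#'
#' \eqn{dC/dt = N v(C)} with boundary species clamped. Used by the
#' steady-state solvers; exported for diagnostics.
#'
#' @inheritParams evaluate_rates
#' @return named numeric vector over the dynamic species.
#' @export
state_derivative <- function(model, conc, params = model$params) {
  N <- stoichiometric_matrix(model)
  drop(N %*% evaluate_rates(model, conc, params))
}
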