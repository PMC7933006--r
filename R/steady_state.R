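# Steady-state solvers: stiff ODE relaxation (deSolve::lsoda), damped Newton
# polish, and the hybrid default. Convergence uses the relative rate criterion
# max_i |dC_i/dt| <= tol * max(1, |C_i|).

full_concentrations <- function(model, dyn_conc) {
  conc <- stats::setNames(model$species$initial_concentration, model$species$id)
  conc[names(dyn_conc)] <- dyn_conc
  conc
}

default_init <- function(model) {
  dyn <- dynamic_species(model)
  stats::setNames(model$species[dyn, "initial_concentration"], dyn)
}

rate_residual <- function(model, params, dyn_conc) {
  dcdt <- state_derivative(model, full_concentrations(model, dyn_conc), params)
  list(dcdt = dcdt,
       norm = max(abs(dcdt)),
       rel = max(abs(dcdt) / pmax(1, abs(dyn_conc))))
}

new_steady_state <- function(model, params, conc, converged, method,
                             diagnostics) {
  res <- rate_residual(model, params, conc)
  structure(list(
    concentrations = conc,
    fluxes = evaluate_rates(model, full_concentrations(model, conc), params),
    converged = converged,
    residual_norm = res$norm,
    residual_rel = res$rel,
    method = method,
    diagnostics = diagnostics), class = "trp_steady_state")
}

#' Steady-state concentrations and fluxes
#'
#' Computes the steady state of \eqn{dC/dt = N v(C)} with boundary species
#' clamped. Three methods:
#' \describe{
#'   \item{relaxation}{stiff integration (\code{deSolve::lsoda}) over
#'     geometrically growing time chunks until the relative rate criterion
#'     \eqn{\max_i |dC_i/dt| \le tol\,\max(1,|C_i|)} holds or \code{t_max}
#'     is reached;}
#'   \item{newton}{damped Newton iteration on \eqn{F(C)=Nv(C)} from
#'     \code{init} (see \code{\link{refine_newton}});}
#'   \item{hybrid}{relaxation followed by a Newton polish — the default,
#'     robust on the stiff kynurenine-pathway kinetics while delivering
#'     near machine-precision residuals.}
#' }
#'
#' @param model a \code{trp_model}.
#' @param params a \code{trp_params}; defaults to the model's.
#' @param init named non-negative initial concentrations for the dynamic
#'   species; defaults to the model's initial state (for the default
#'   hepatocyte model: everything 0 except intracellular Trp at 1\% of
#'   extracellular Trp).
#' @param tol relative rate threshold per unit time (default 1e-9).
#' @param t_max integration horizon (default 1e6 time units).
#' @param method one of \code{"hybrid"}, \code{"relaxation"},
#'   \code{"newton"}.
#' @return a \code{trp_steady_state} object: \code{concentrations} (dynamic
#'   species), \code{fluxes} (per reaction), \code{converged},
#'   \code{residual_norm} (max |dC/dt|), \code{method}, \code{diagnostics}.
#' @examples
#' ss <- steady_state(build_trp_model())
#' ss$converged
#' head(ss$fluxes)
#' @export
steady_state <- function(model, params = model$params, init = NULL,
                         tol = 1e-9, t_max = 1e6,
                         method = c("hybrid", "relaxation", "newton")) {
  method <- match.arg(method)
  validate_trp_params(params)
  stopifnot(tol > 0)
  if (is.null(init)) init <- default_init(model)
  dyn <- dynamic_species(model)
  missing <- setdiff(dyn, names(init))
  if (length(missing))
    stop("init lacks species: ", paste(missing, collapse = ", "))
  init <- init[dyn]
  if (any(init < 0)) stop("negative initial concentration")

  if (method == "newton") return(refine_newton(model, params, init, tol = tol))

  relax <- relax_to_steady_state(model, params, init, tol, t_max)
  if (method == "relaxation") return(relax)
  if (!relax$converged) {  # polish, never rescue, a failed relaxation
    relax$method <- "hybrid"
    return(relax)
  }

  polished <- refine_newton(model, params, relax$concentrations, tol = tol)
  if (polished$converged) {
    polished$method <- "hybrid"
    polished$diagnostics <- c(relax$diagnostics,
                              newton_iterations = polished$diagnostics[["iterations"]])
    polished
  } else {
    relax$method <- "hybrid"
    relax
  }
}

relax_to_steady_state <- function(model, params, init, tol, t_max) {
  N <- stoichiometric_matrix(model)
  dyn <- rownames(N)
  base <- stats::setNames(model$species$initial_concentration, model$species$id)
  deriv <- function(t, y, p) {
    conc <- base
    conc[dyn] <- pmax(y, 0)  # rates evaluated on the non-negative cone
    list(drop(N %*% evaluate_rates(model, conc, params)))
  }
  y <- init
  t0 <- 0
  t1 <- 1
  chunks <- 0L
  converged <- FALSE
  repeat {
    sol <- deSolve::lsoda(y, c(t0, min(t1, t_max)), deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    y_new <- sol[nrow(sol), -1L]
    if (any(!is.finite(y_new)))
      stop("non-finite state during integration at t=", t0,
           "; last valid state: ",
           paste(sprintf("%s=%.6g", dyn, y), collapse = ", "))
    y <- y_new
    chunks <- chunks + 1L
    # validate small negatives from the unclipped integrator, then clamp
    if (any(y < -10 * .Machine$double.eps * max(1, max(abs(y)))))
      message("clamping negative concentrations to 0: ",
              paste(dyn[y < 0], collapse = ", "))
    y <- pmax(y, 0)
    res <- rate_residual(model, params, stats::setNames(y, dyn))
    if (res$rel <= tol) { converged <- TRUE; break }
    if (t1 >= t_max) break
    t0 <- t1
    t1 <- t1 * 10
  }
  new_steady_state(model, params, stats::setNames(y, dyn), converged,
                   "relaxation",
                   list(t_end = min(t1, t_max), chunks = chunks,
                        iterations = NA_integer_))
}

#' Newton refinement of a steady-state guess
#'
#' Damped Newton iteration on \eqn{F(C) = N v(C)} with a finite-difference
#' Jacobian. Steps that would produce negative concentrations or fail to
#' reduce \eqn{\|F\|} are halved; a singular Jacobian (after damping
#' attempts) returns a non-converged result rather than diverging, so the
#' caller can fall back to the relaxation solution.
#'
#' @inheritParams steady_state
#' @param guess named non-negative concentrations of the dynamic species.
#' @param max_iter iteration cap.
#' @return a \code{trp_steady_state} (method \code{"newton"}).
#' @export
refine_newton <- function(model, params = model$params, guess,
                          tol = 1e-9, max_iter = 50L) {
  dyn <- dynamic_species(model)
  guess <- guess[dyn]
  if (any(guess < 0)) stop("negative concentration in guess")
  N <- stoichiometric_matrix(model)
  Ffun <- function(x)
    drop(N %*% evaluate_rates(model, full_concentrations(model,
                                      stats::setNames(x, dyn)), params))
  x <- as.numeric(guess)
  Fx <- Ffun(x)
  it <- 0L
  singular <- FALSE
  diverged <- FALSE
  growth_cap <- 1e6 * max(1, max(abs(x)))
  crit <- function(x, Fx) max(abs(Fx) / pmax(1, abs(x)))
  while (crit(x, Fx) > tol && it < max_iter) {
    J <- matrix(0, length(x), length(x))
    for (k in seq_along(x)) {
      h <- max(1e-8, 1e-8 * abs(x[k]))
      xp <- x; xp[k] <- x[k] + h
      J[, k] <- (Ffun(xp) - Fx) / h
    }
    dx <- tryCatch(solve(J, -Fx), error = function(e) NULL)
    if (is.null(dx)) {
      # ridge-damped retry before giving up
      dx <- tryCatch(solve(J + diag(1e-8 * max(abs(J)), nrow(J)), -Fx),
                     error = function(e) NULL)
      if (is.null(dx)) { singular <- TRUE; break }
    }
    lambda <- 1
    accepted <- FALSE
    f0 <- max(abs(Fx))
    for (half in 1:30) {
      xn <- x + lambda * dx
      if (all(xn >= 0)) {
        Fn <- Ffun(xn)
        if (max(abs(Fn)) < f0 || max(abs(Fn)) <= tol) {
          x <- xn; Fx <- Fn; accepted <- TRUE; break
        }
      }
      lambda <- lambda / 2
    }
    it <- it + 1L
    if (!accepted) break
    if (max(abs(x)) > growth_cap) { diverged <- TRUE; break }
  }
  converged <- !singular && !diverged && crit(x, Fx) <= tol
  new_steady_state(model, params, stats::setNames(x, dyn), converged,
                   "newton", list(iterations = it, singular = singular,
                                  diverged = diverged))
}

#' Fluxes at a converged state
#'
#' Evaluates all reaction rates at a steady-state concentration vector and
#' checks the conservation residual \eqn{\|N v\|_\infty}.
#'
#' @inheritParams steady_state
#' @param steady named concentrations of the dynamic species (a converged
#'   state), or a \code{trp_steady_state}.
#' @return named per-reaction flux vector with attribute
#'   \code{conservation_residual}.
#' @export
compute_fluxes <- function(model, params = model$params, steady) {
  if (inherits(steady, "trp_steady_state")) steady <- steady$concentrations
  v <- evaluate_rates(model, full_concentrations(model, steady), params)
  N <- stoichiometric_matrix(model)
  attr(v, "conservation_residual") <- max(abs(N %*% v))
  v
}

#' @export
print.trp_steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s): %s, max |dC/dt| = %.3g\n", x$method,
              if (x$converged) "converged" else "NOT converged",
              x$residual_norm))
  cat("Concentrations:\n")
  print(signif(x$concentrations, 6))
  cat("Fluxes:\n")
  print(signif(x$fluxes, 6))
  invisible(x)
}
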