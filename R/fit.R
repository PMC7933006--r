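#' Fit the expression-constrained Trp model to a two-condition experiment
#'
#' The central modelling verb: converts a per-replicate expression table
#' into per-replicate parameter sets (expression-proportional Vmax
#' scaling), computes one steady state per replicate and condition, and
#' compares the two conditions quantity by quantity. This mirrors the
#' study workflow: expression -> scaled kinetic models -> steady-state
#' concentrations and fluxes -> mean +/- SEM with unpaired two-tailed
#' t-tests.
#'
#' @param expression an expression table (data frame or CSV path; see
#'   \code{\link{read_expression}}) with exactly two conditions.
#' @param model a \code{trp_model}; default \code{\link{build_trp_model}()}.
#' @param reference label of the reference condition (default
#'   \code{"normoxia"}); scaling ratios are relative to its per-gene mean.
#' @param test t-test flavour for the differential table, \code{"welch"}
#'   (default) or \code{"student"}.
#' @param transform expression-to-capacity transform, \code{"linear"}
#'   (default) or \code{"log_linear"}.
#' @param tol steady-state tolerance (see \code{\link{steady_state}}).
#' @param method steady-state method (default \code{"hybrid"}).
#' @return an object of class \code{trp_fit}: the model, the per-replicate
#'   \code{trp_steady_state} results (\code{$results}, a named list per
#'   condition), the \code{trp_differential} table (\code{$differential})
#'   and the conditions. Use \code{summary()} for the differential table
#'   plus sign-pattern report, \code{coef()} for mean fluxes,
#'   \code{fitted()} for mean concentrations, \code{plot()} for the
#'   bar-plot figure.
#' @examples
#' \donttest{
#' tab <- generate_expression(cv = 0.1, seed = 1)
#' fit <- trp_fit(tab)
#' summary(fit)
#' }
#' @export
trp_fit <- function(expression, model = build_trp_model(),
                    reference = "normoxia",
                    test = c("welch", "student"),
                    transform = c("linear", "log_linear"),
                    tol = 1e-9, method = "hybrid") {
  test <- match.arg(test)
  transform <- match.arg(transform)
  if (is.character(expression)) expression <- read_expression(expression)
  expression <- validate_expression_table(expression)
  conds <- unique(expression$condition)
  if (!reference %in% conds)
    stop("reference condition '", reference, "' absent from expression table")
  if (length(conds) != 2L)
    stop("expression table must contain exactly two conditions, found: ",
         paste(conds, collapse = ", "))
  other <- setdiff(conds, reference)

  map <- gene_reaction_map(model)
  norm <- function(x) tolower(trimws(x))
  unmapped <- setdiff(unique(expression$gene),
                      unique(expression$gene)[norm(unique(expression$gene))
                                              %in% norm(names(map))])
  if (length(unmapped))
    message("gene(s) without a mapped reaction, ignored: ",
            paste(unmapped, collapse = ", "))
  mapped <- setdiff(unique(expression$gene), unmapped)

  factors <- compute_scaling_factors(expression, reference)
  factors <- factors[factors$gene %in% mapped, ]

  run_condition <- function(cond) {
    ratios <- replicate_ratios(factors, cond)
    lapply(ratios, function(r) {
      p <- scale_parameters(model$params, r, map, transform = transform)
      steady_state(model, p, tol = tol, method = method)
    })
  }
  results <- stats::setNames(lapply(c(reference, other), run_condition),
                             c(reference, other))
  diff_tab <- compare_conditions(results[[reference]], results[[other]],
                                 test = test,
                                 conditions = c(reference, other))
  structure(list(model = model, expression = expression,
                 reference = reference, conditions = c(reference, other),
                 transform = transform, test = test,
                 results = results, differential = diff_tab),
            class = "trp_fit")
}

#' @export
print.trp_fit <- function(x, ...) {
  nrep <- vapply(x$results, length, integer(1))
  conv <- vapply(x$results, function(r)
    sum(vapply(r, function(s) isTRUE(s$converged), logical(1))), integer(1))
  cat("Expression-constrained Trp metabolism fit\n")
  cat(sprintf("  conditions: %s (reference) vs %s\n",
              x$conditions[1], x$conditions[2]))
  for (cond in names(nrep))
    cat(sprintf("  %s: %d replicate(s), %d converged\n",
                cond, nrep[[cond]], conv[[cond]]))
  cat(sprintf("  %d fluxes, %d concentrations compared (%s t-test)\n",
              sum(x$differential$kind == "flux"),
              sum(x$differential$kind == "concentration"), x$test))
  invisible(x)
}

#' @export
summary.trp_fit <- function(object, expectations = default_expectations(),
                            ...) {
  structure(list(fit = object,
                 differential = object$differential,
                 sign_report = sign_pattern(object$differential,
                                            expectations)),
            class = "summary.trp_fit")
}

#' @export
print.summary.trp_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$differential)
  cat("\n")
  print(x$sign_report)
  invisible(x)
}

#' @export
coef.trp_fit <- function(object, kind = c("flux", "concentration"), ...) {
  kind <- match.arg(kind)
  tab <- object$differential[object$differential$kind == kind, ]
  out <- cbind(tab$mean_A, tab$mean_B)
  dimnames(out) <- list(tab$quantity, object$conditions)
  out
}

#' @export
fitted.trp_fit <- function(object, ...) {
  coef(object, kind = "concentration")
}

#' Simulate noisy metabolite measurements from a fit
#'
#' Draws left-censored metabolite measurement tables from each condition's
#' first-replicate steady state (log-normal multiplicative noise),
#' emulating a uHPLC panel of the fitted states.
#'
#' @param object a \code{trp_fit}.
#' @param nsim replicates per condition.
#' @param seed RNG seed.
#' @param cv measurement coefficient of variation.
#' @param lod detection limit (scalar or named per metabolite).
#' @param ... unused.
#' @return named list (condition) of measurement data frames.
#' @export
simulate.trp_fit <- function(object, nsim = 3, seed = 1, cv = 0.1, lod = 0,
                             ...) {
  out <- list()
  for (i in seq_along(object$results)) {
    cond <- names(object$results)[i]
    ss <- object$results[[cond]][[1]]
    conc <- ss$concentrations
    lodv <- if (length(lod) == 1L)
      stats::setNames(rep(lod, length(conc)), names(conc)) else lod[names(conc)]
    sdlog <- sqrt(log1p(cv^2))
    out[[cond]] <- with_seed(seed + i - 1L, {
      do.call(rbind, lapply(names(conc), function(m) {
        noise <- if (cv == 0) rep(1, nsim)
                 else stats::rlnorm(nsim, -sdlog^2 / 2, sdlog)
        val <- conc[[m]] * noise
        cens <- val < lodv[[m]]
        data.frame(metabolite = m, replicate = seq_len(nsim),
                   value = ifelse(cens, NA_real_, val), censored = cens,
                   lod = lodv[[m]], stringsAsFactors = FALSE)
      }))
    })
  }
  out
}

#' Bar-plot of condition means with SEM bars and significance stars
#'
#' Grouped bars (reference condition first) per quantity, mean +/- SEM,
#' annotated with the significance code — the layout of the study's flux
#' and metabolite panels.
#'
#' @param x a \code{trp_fit}.
#' @param quantities quantity ids to show; defaults to the constrained
#'   quantities of \code{\link{default_expectations}}.
#' @param kind used only when \code{quantities} is NULL.
#' @param ... passed to \code{graphics::barplot}.
#' @return invisibly, the matrix of plotted means.
#' @export
plot.trp_fit <- function(x, quantities = names(default_expectations()),
                         kind = NULL, ...) {
  tab <- x$differential
  if (!is.null(kind)) quantities <- tab$quantity[tab$kind == kind]
  tab <- tab[match(quantities, tab$quantity), ]
  if (any(is.na(tab$quantity))) stop("unknown quantity requested")
  means <- t(cbind(tab$mean_A, tab$mean_B))
  sems <- t(cbind(tab$sem_A, tab$sem_B))
  rownames(means) <- x$conditions
  colnames(means) <- tab$quantity
  op <- graphics::par(mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  bp <- graphics::barplot(means, beside = TRUE,
                          col = c("white", "steelblue"),
                          ylim = c(0, 1.25 * max(means + sems)),
                          las = 2, ylab = "steady-state value",
                          legend.text = x$conditions, ...)
  graphics::arrows(bp, means - sems, bp, means + sems,
                   angle = 90, code = 3, length = 0.02)
  stars <- ifelse(tab$significance_code == "ns", "", tab$significance_code)
  graphics::text(colMeans(bp), apply(means + sems, 2, max),
                 stars, pos = 3, cex = 0.9)
  invisible(means)
}
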