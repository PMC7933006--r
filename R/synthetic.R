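# Seeded synthetic data: expression tables with the statistical structure of
# the normoxia/hypoxia study (log-normal multiplicative replicate noise,
# n = 3 per condition) and left-censored metabolite measurement fixtures.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default hypoxic regulation profile
#'
#' One row per gene with the normoxic baseline mean (linear intensity
#' scale) and the multiplicative hypoxia/normoxia fold change. Directions
#' follow the study's readout: the kynurenine-pathway genes and both
#' transporters are down-regulated, Ddc and Inmt are up-regulated, Tph1
#' weakly up, Il4i1 unchanged, and Ndrg1 is a strongly induced hypoxia
#' marker that maps to no reaction. The magnitudes are fixture choices
#' encoding only those directions and are freely configurable.
#'
#' @param baseline_mean common normoxic baseline (default 100).
#' @return data frame with columns \code{gene}, \code{baseline_mean},
#'   \code{fold_change}.
#' @export
default_regulation_profile <- function(baseline_mean = 100) {
  fc <- c(Tdo2 = 0.1, Kmo = 0.4, Kynu = 0.5, Kyat1 = 0.5,
          Slc7a5 = 0.5, Slc7a8 = 0.5, Haao = 0.6, Qprt = 0.6,
          Ddc = 2.0, Inmt = 2.5, Tph1 = 1.3, Il4i1 = 1.0, Ndrg1 = 8.0)
  data.frame(gene = names(fc), baseline_mean = baseline_mean,
             fold_change = unname(fc), stringsAsFactors = FALSE)
}

#' Generate a synthetic normoxia/hypoxia expression table
#'
#' For each gene and condition, draws \code{n_replicates} values
#' \eqn{baseline \cdot fc \cdot \epsilon} where \eqn{fc} is the gene's fold
#' change (1 under the reference condition) and \eqn{\epsilon} is
#' log-normal multiplicative noise with unit mean and coefficient of
#' variation \code{cv} (\eqn{\sigma^2_{log} = \log(1+cv^2)}, mean-corrected).
#' Deterministic given \code{seed}; \code{cv = 0} yields exactly
#' \eqn{baseline \cdot fc}.
#'
#' @param profile regulation profile data frame
#'   (\code{\link{default_regulation_profile}}).
#' @param cv replicate coefficient of variation (>= 0; default 0.1).
#' @param n_replicates replicates per condition (>= 2; default 3, as in the
#'   study's figure legends).
#' @param seed RNG seed.
#' @param conditions length-2 labels, reference first.
#' @return an expression table (see \code{\link{read_expression}}).
#' @examples
#' tab <- generate_expression(seed = 1)
#' head(tab)
#' @export
generate_expression <- function(profile = default_regulation_profile(),
                                cv = 0.1, n_replicates = 3, seed = 1,
                                conditions = c("normoxia", "hypoxia")) {
  stopifnot(cv >= 0, n_replicates >= 2, length(conditions) == 2,
            all(profile$fold_change > 0), all(profile$baseline_mean > 0))
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- -sdlog^2 / 2
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(profile))) {
      for (cond in conditions) {
        fc <- if (cond == conditions[2]) profile$fold_change[i] else 1
        noise <- if (cv == 0) rep(1, n_replicates)
                 else stats::rlnorm(n_replicates, meanlog, sdlog)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = profile$gene[i], condition = cond,
          replicate = seq_len(n_replicates),
          value = profile$baseline_mean[i] * fc * noise,
          stringsAsFactors = FALSE)
      }
    }
    validate_expression_table(do.call(rbind, rows))
  })
}

#' Generate a left-censored metabolite measurement fixture
#'
#' Emulates an intracellular metabolite panel: the model's steady-state
#' concentrations perturbed by per-replicate log-normal noise, with values
#' below the detection limit reported as censored ("nd") and the limit
#' recorded.
#'
#' @param model a \code{trp_model}.
#' @param params a \code{trp_params} (must yield a converged steady state).
#' @param cv measurement coefficient of variation.
#' @param n_replicates replicates.
#' @param seed RNG seed.
#' @param lod scalar or per-metabolite named detection limit (default 0,
#'   no censoring).
#' @return data frame with columns \code{metabolite}, \code{replicate},
#'   \code{value} (NA when censored), \code{censored}, \code{lod}.
#' @export
generate_metabolite_fixture <- function(model, params = model$params,
                                        cv = 0.1, n_replicates = 3,
                                        seed = 1, lod = 0) {
  ss <- steady_state(model, params)
  if (!ss$converged)
    stop("parameters do not yield a converged steady state")
  conc <- ss$concentrations
  lodv <- if (length(lod) == 1L) stats::setNames(rep(lod, length(conc)),
                                                 names(conc))
          else lod[names(conc)]
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- -sdlog^2 / 2
  with_seed(seed, {
    rows <- lapply(names(conc), function(m) {
      noise <- if (cv == 0) rep(1, n_replicates)
               else stats::rlnorm(n_replicates, meanlog, sdlog)
      val <- conc[[m]] * noise
      cens <- val < lodv[[m]]
      data.frame(metabolite = m, replicate = seq_len(n_replicates),
                 value = ifelse(cens, NA_real_, val), censored = cens,
                 lod = lodv[[m]], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
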