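#' Hepatocyte tryptophan metabolism network
#'
#' Constructs the default kinetic model of hepatic tryptophan (Trp)
#' metabolism: uptake of extracellular Trp in exchange for intracellular
#' kynurenine (Kyn) through the antiporters LAT1 (Slc7a5) and LAT2 (Slc7a8),
#' the kynurenine pathway (TDO2 -> Kyn -> \{KynA | 3HKyn -> 3HAA -> Quin ->
#' NaMN\} plus the kynureninase shunt Kyn -> anthranilic acid), the tryptamine
#' branch (DDC -> tryptamine -> methyltryptamine -> DMT via INMT), the
#' serotonin branch (TPH1, DDC) and the indole-3-pyruvate branch (IL4I1).
#' Terminal products carry first-order clearances so that a steady state
#' exists. TDO2 lumps N-formylkynurenine hydrolysis; HAAO lumps the
#' non-enzymatic ACMS cyclization to quinolinate.
#'
#' Extracellular Trp and Kyn are boundary species with clamped
#' concentrations. The default extracellular Trp concentration is 10
#' model-units, matching the upper bound of blood free-Trp used in the
#' study design; the unit label is configurable because the physiological
#' plausibility of that magnitude is debatable (see the methods vignette).
#'
#' @param trp_ext clamped extracellular Trp concentration (default 10).
#' @param kyn_ext clamped extracellular Kyn concentration (default 0.01;
#'   nonzero so the antiport exchange is well-posed, small so the reverse
#'   Trp-efflux term does not dominate at low intracellular Kyn).
#' @param branches named logical vector toggling the optional branches
#'   \code{il4i1}, \code{serotonin}, \code{tryptamine}. Core kynurenine
#'   pathway reactions cannot be disabled.
#' @param oxygen_term logical; if \code{TRUE}, oxygen-dependent reactions
#'   (TDO2, KMO, HAAO, TPH1, IL4I1) are multiplied by a Michaelis term
#'   \eqn{O_2/(K_{m,O_2}+O_2)}. Off by default: the study encodes hypoxia
#'   purely through expression scaling.
#' @param oxygen_level dimensionless oxygen availability in [0,1].
#' @param kyn_coupling stoichiometric fraction of the antiport counter-flux
#'   carried by kynurenine, in (0, 1]. LAT1/LAT2 exchange Trp against the
#'   whole system-L amino-acid pool; Kyn is the modelled component. Full
#'   coupling (1) makes the combined Trp+Kyn pool a closed node whose only
#'   steady state is the trivial zero state, so the default is 0.5 (see the
#'   methods vignette).
#' @param params optional \code{trp_params} object; defaults to the shipped
#'   versioned parameter file.
#' @param units list with \code{concentration} and \code{time} labels.
#' @return an object of class \code{trp_model} with components
#'   \code{species} (data frame), \code{reactions} (list), \code{params}
#'   (\code{trp_params}) and \code{units}.
#' @examples
#' m <- build_trp_model()
#' m
#' @export
build_trp_model <- function(trp_ext = 10, kyn_ext = 0.01,
                            branches = c(il4i1 = TRUE, serotonin = TRUE,
                                         tryptamine = TRUE),
                            oxygen_term = FALSE, oxygen_level = 1,
                            kyn_coupling = 0.5,
                            params = NULL,
                            units = list(concentration = "mM-equivalent",
                                         time = "h")) {
  stopifnot(is.finite(trp_ext), trp_ext >= 0, is.finite(kyn_ext), kyn_ext >= 0,
            is.finite(kyn_coupling), kyn_coupling > 0, kyn_coupling <= 1)
  b <- c(il4i1 = TRUE, serotonin = TRUE, tryptamine = TRUE)
  if (length(branches)) {
    if (is.null(names(branches)) || !all(names(branches) %in% names(b)))
      stop("unknown branch toggle; known branches: ", paste(names(b), collapse = ", "))
    b[names(branches)] <- branches
  }

  sp <- function(id, name, compartment, boundary = FALSE, init = 0)
    list(id = id, display_name = name, compartment = compartment,
         is_boundary = boundary, initial_concentration = init)

  species <- list(
    sp("Trp_ext", "extracellular tryptophan", "extracellular", TRUE, trp_ext),
    sp("Kyn_ext", "extracellular kynurenine", "extracellular", TRUE, kyn_ext),
    # default init: Trp at 1% of the clamped extracellular level, all other
    # dynamic species at 0 — deterministic and biologically innocuous
    sp("Trp",  "tryptophan",               "intracellular",
       init = 0.01 * trp_ext),
    sp("Kyn",  "kynurenine",               "intracellular"),
    sp("KynA", "kynurenic acid",           "intracellular"),
    sp("HKyn3", "3-hydroxykynurenine",     "intracellular"),
    sp("HAA3", "3-hydroxyanthranilic acid", "intracellular"),
    sp("AA",   "anthranilic acid",         "intracellular"),
    sp("Quin", "quinolinic acid",          "intracellular"),
    sp("NaMN_sinkpool", "NaMN / NAD-precursor pool", "intracellular"))
  if (b["tryptamine"]) species <- c(species, list(
    sp("Trypta", "tryptamine",             "intracellular"),
    sp("MeTrypta", "N-methyltryptamine",   "intracellular"),
    sp("DMT",  "N,N-dimethyltryptamine",   "intracellular")))
  if (b["serotonin"]) species <- c(species, list(
    sp("HTP5", "5-hydroxytryptophan",      "intracellular"),
    sp("Serotonin", "serotonin",           "intracellular")))
  if (b["il4i1"]) species <- c(species, list(
    sp("I3P", "indole-3-pyruvate",         "intracellular")))

  rx <- function(id, gene, substrates, products, rate_law,
                 oxygen_dependent = FALSE)
    list(id = id, gene = gene, substrates = substrates, products = products,
         rate_law = rate_law, oxygen_dependent = oxygen_dependent)

  reactions <- list(
    # antiport: substrate order (S_out, C_in), product order (S_in, C_out)
    rx("R_LAT1", "Slc7a5", c(Trp_ext = 1, Kyn = kyn_coupling),
       c(Trp = 1, Kyn_ext = kyn_coupling), "antiport_exchange"),
    rx("R_LAT2", "Slc7a8", c(Trp_ext = 1, Kyn = kyn_coupling),
       c(Trp = 1, Kyn_ext = kyn_coupling), "antiport_exchange"),
    rx("R_TDO2", "Tdo2", c(Trp = 1), c(Kyn = 1), "irreversible_mm", TRUE),
    rx("R_KAT", "Kyat1", c(Kyn = 1), c(KynA = 1), "irreversible_mm"),
    rx("R_KMO", "Kmo", c(Kyn = 1), c(HKyn3 = 1), "irreversible_mm", TRUE),
    rx("R_KYNU_a", "Kynu", c(Kyn = 1), c(AA = 1), "irreversible_mm"),
    rx("R_KYNU_b", "Kynu", c(HKyn3 = 1), c(HAA3 = 1), "irreversible_mm"),
    rx("R_HAAO", "Haao", c(HAA3 = 1), c(Quin = 1), "irreversible_mm", TRUE),
    rx("R_QPRT", "Qprt", c(Quin = 1), c(NaMN_sinkpool = 1), "irreversible_mm"))
  if (b["tryptamine"]) reactions <- c(reactions, list(
    rx("R_DDC_trp", "Ddc", c(Trp = 1), c(Trypta = 1), "irreversible_mm"),
    rx("R_INMT_1", "Inmt", c(Trypta = 1), c(MeTrypta = 1), "irreversible_mm"),
    rx("R_INMT_2", "Inmt", c(MeTrypta = 1), c(DMT = 1), "irreversible_mm")))
  if (b["serotonin"]) reactions <- c(reactions, list(
    rx("R_TPH1", "Tph1", c(Trp = 1), c(HTP5 = 1), "irreversible_mm", TRUE),
    rx("R_DDC_5htp", "Ddc", c(HTP5 = 1), c(Serotonin = 1), "irreversible_mm")))
  if (b["il4i1"]) reactions <- c(reactions, list(
    rx("R_IL4I1", "Il4i1", c(Trp = 1), c(I3P = 1), "irreversible_mm", TRUE)))

  clr <- function(species_id, tag = species_id)
    rx(paste0("R_clr_", tag), NA_character_, stats::setNames(1, species_id),
       numeric(0), "first_order_clearance")
  clearances <- list(clr("KynA"), clr("AA"), clr("NaMN_sinkpool"))
  if (b["tryptamine"]) clearances <- c(clearances,
    list(clr("Trypta", "Trypta_MAO"), clr("DMT")))
  if (b["serotonin"]) clearances <- c(clearances, list(clr("Serotonin")))
  if (b["il4i1"]) clearances <- c(clearances, list(clr("I3P")))
  reactions <- c(reactions, clearances)

  species_df <- do.call(rbind, lapply(species, function(s)
    data.frame(id = s$id, display_name = s$display_name,
               compartment = s$compartment, is_boundary = s$is_boundary,
               initial_concentration = s$initial_concentration,
               stringsAsFactors = FALSE)))
  rownames(species_df) <- species_df$id
  names(reactions) <- vapply(reactions, `[[`, "", "id")

  model <- structure(list(species = species_df, reactions = reactions,
                          params = NULL, units = units,
                          oxygen_term = isTRUE(oxygen_term),
                          branches = b),
                     class = "trp_model")
  model$params <- if (is.null(params)) default_parameters(model) else params
  if (!is.null(oxygen_level)) model$params$oxygen_level <- oxygen_level
  validate_trp_model(model)
  model
}

#' Low-level model constructor
#'
#' Assembles a \code{trp_model} from explicit parts. Useful for small test
#' networks; most users want \code{\link{build_trp_model}}.
#'
#' @param species data frame with columns \code{id}, \code{display_name},
#'   \code{compartment}, \code{is_boundary}, \code{initial_concentration}.
#' @param reactions named list of reaction definitions (\code{id},
#'   \code{gene}, \code{substrates}, \code{products}, \code{rate_law},
#'   \code{oxygen_dependent}).
#' @param params a \code{trp_params}.
#' @param units list with \code{concentration} and \code{time} labels.
#' @param oxygen_term logical, enable the oxygen Michaelis term.
#' @return a validated \code{trp_model}.
#' @export
trp_model <- function(species, reactions, params,
                      units = list(concentration = "au", time = "h"),
                      oxygen_term = FALSE) {
  if (is.null(names(reactions)))
    names(reactions) <- vapply(reactions, `[[`, "", "id")
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    if (is.null(r$gene)) r$gene <- NA_character_
    if (is.null(r$oxygen_dependent)) r$oxygen_dependent <- FALSE
    if (is.null(r$products)) r$products <- numeric(0)
    reactions[[i]] <- r
  }
  rownames(species) <- species$id
  m <- structure(list(species = species, reactions = reactions,
                      params = params, units = units,
                      oxygen_term = isTRUE(oxygen_term),
                      branches = NULL),
                 class = "trp_model")
  validate_trp_model(m)
  m
}

#' Validate a trp_model
#'
#' Checks structural invariants: unique species ids, finite non-negative
#' boundary concentrations, every referenced species exists, antiport
#' reactions have exactly 2 substrates and 2 products, clearances exactly
#' one substrate and no products, at least one boundary species, and no
#' orphan dynamic species.
#'
#' @param model a \code{trp_model}.
#' @return the model, invisibly; errors on violation.
#' @export
validate_trp_model <- function(model) {
  stopifnot(inherits(model, "trp_model"))
  sdf <- model$species
  if (anyDuplicated(sdf$id))
    stop("duplicate species ids: ",
         paste(unique(sdf$id[duplicated(sdf$id)]), collapse = ", "))
  bnd <- sdf[sdf$is_boundary, ]
  if (nrow(bnd) == 0L) stop("model needs at least one boundary species")
  if (any(!is.finite(bnd$initial_concentration)) ||
      any(bnd$initial_concentration < 0))
    stop("boundary species must have finite concentration >= 0")
  referenced <- character(0)
  for (r in model$reactions) {
    ids <- c(names(r$substrates), names(r$products))
    missing <- setdiff(ids, sdf$id)
    if (length(missing))
      stop("reaction ", r$id, " references unknown species: ",
           paste(missing, collapse = ", "))
    if (r$rate_law == "antiport_exchange" &&
        (length(r$substrates) != 2L || length(r$products) != 2L))
      stop("antiport reaction ", r$id, " must have 2 substrates and 2 products")
    if (r$rate_law == "first_order_clearance" &&
        (length(r$substrates) != 1L || length(r$products) != 0L))
      stop("clearance reaction ", r$id, " must have 1 substrate, 0 products")
    referenced <- c(referenced, ids)
  }
  orphan <- setdiff(sdf$id[!sdf$is_boundary], referenced)
  if (length(orphan))
    stop("orphan dynamic species: ", paste(orphan, collapse = ", "))
  invisible(model)
}

#' @export
print.trp_model <- function(x, ...) {
  nb <- sum(x$species$is_boundary)
  cat("Kinetic model of hepatic tryptophan metabolism\n")
  cat(sprintf("  %d species (%d dynamic, %d boundary), %d reactions (%d clearances)\n",
              nrow(x$species), nrow(x$species) - nb, nb,
              length(x$reactions),
              sum(vapply(x$reactions, function(r)
                r$rate_law == "first_order_clearance", logical(1)))))
  cat(sprintf("  boundary: %s\n",
              paste(sprintf("%s = %g", x$species$id[x$species$is_boundary],
                            x$species$initial_concentration[x$species$is_boundary]),
                    collapse = ", ")))
  cat(sprintf("  oxygen term: %s (oxygen level %g)\n",
              if (x$oxygen_term) "enabled" else "disabled",
              x$params$oxygen_level))
  cat(sprintf("  units: concentration [%s], time [%s]\n",
              x$units$concentration, x$units$time))
  invisible(x)
}

#' Species ids of the dynamic (non-boundary) species
#' @param model a \code{trp_model}.
#' @return character vector.
#' @export
dynamic_species <- function(model) {
  model$species$id[!model$species$is_boundary]
}

#' Gene-to-reaction map of a model
#'
#' Returns the mapping from gene symbols to the reactions whose capacity
#' they drive. One gene may drive several reactions (Ddc, Kynu and Inmt
#' each drive two).
#'
#' @param model a \code{trp_model}.
#' @return named list, gene symbol -> character vector of reaction ids.
#' @export
gene_reaction_map <- function(model) {
  genes <- vapply(model$reactions, `[[`, "", "gene")
  ok <- !is.na(genes)
  split(names(model$reactions)[ok], genes[ok])
}
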