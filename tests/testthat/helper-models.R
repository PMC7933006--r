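# Small networks and cached pipeline fits shared across test files.

# One-species toy: (near-)constant source k0 into S, Michaelis-Menten
# consumption. Closed-form steady state: S* = Km * k0 / (Vmax - k0).
# The source is an MM reaction from a large clamped pool with tiny Km, so
# its flux is k0 to ~1e-11 relative.
toy_source_sink <- function(k0 = 1, vmax = 2, km = 1) {
  species <- data.frame(
    id = c("Src", "S"),
    display_name = c("source pool", "substrate"),
    compartment = c("extracellular", "intracellular"),
    is_boundary = c(TRUE, FALSE),
    initial_concentration = c(100, 0),
    stringsAsFactors = FALSE)
  reactions <- list(
    R_in = list(id = "R_in", substrates = c(Src = 1), products = c(S = 1),
                rate_law = "irreversible_mm"),
    R_out = list(id = "R_out", substrates = c(S = 1), products = numeric(0),
                 rate_law = "irreversible_mm"))
  params <- trp_params(list(
    R_in = list(vmax = k0, km = c(Src = 1e-9)),
    R_out = list(vmax = vmax, km = c(S = km))))
  trp_model(species, reactions, params)
}

# Linear chain A -> B -> C with first-order clearance of C; X is an unused
# clamped species so the model has a boundary.
toy_chain <- function() {
  species <- data.frame(
    id = c("X", "A", "B", "C"),
    display_name = c("anchor", "A", "B", "C"),
    compartment = "intracellular",
    is_boundary = c(TRUE, FALSE, FALSE, FALSE),
    initial_concentration = c(1, 2, 0, 0),
    stringsAsFactors = FALSE)
  reactions <- list(
    R1 = list(id = "R1", substrates = c(A = 1), products = c(B = 1),
              rate_law = "irreversible_mm"),
    R2 = list(id = "R2", substrates = c(B = 1), products = c(C = 1),
              rate_law = "irreversible_mm"),
    R3 = list(id = "R3", substrates = c(C = 1), products = numeric(0),
              rate_law = "first_order_clearance"))
  params <- trp_params(list(
    R1 = list(vmax = 1, km = c(A = 1)),
    R2 = list(vmax = 2, km = c(B = 1)),
    R3 = list(kclear = 0.5)))
  trp_model(species, reactions, params)
}

full_concs <- function(model, ...) {
  conc <- stats::setNames(model$species$initial_concentration,
                          model$species$id)
  dots <- c(...)
  conc[names(dots)] <- dots
  conc
}

hypoxia_fold_changes <- function() {
  prof <- default_regulation_profile()
  stats::setNames(prof$fold_change, prof$gene)
}

# fits are expensive enough to share across test blocks
.fit_cache <- new.env(parent = emptyenv())
cached_fit <- function(cv, seed = 1) {
  key <- sprintf("cv%g_seed%d", cv, seed)
  if (is.null(.fit_cache[[key]]))
    .fit_cache[[key]] <- suppressMessages(
      trp_fit(generate_expression(cv = cv, seed = seed)))
  .fit_cache[[key]]
}
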