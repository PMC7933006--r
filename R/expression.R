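#' Read / write expression tables
#'
#' An expression table is a long-format data frame with columns
#' \code{gene} (symbol), \code{condition} (label), \code{replicate}
#' (integer index) and \code{value} (non-negative, linear scale). The CSV
#' schema is \code{gene,condition,replicate,value} and round-trips exactly.
#'
#' @param file CSV path.
#' @return \code{read_expression} returns the validated data frame.
#' @export
read_expression <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_expression_table(tab)
}

#' @rdname read_expression
#' @param table an expression table.
#' @export
write_expression <- function(table, file) {
  validate_expression_table(table)
  utils::write.csv(table[, c("gene", "condition", "replicate", "value")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname read_expression
#' @export
validate_expression_table <- function(table) {
  need <- c("gene", "condition", "replicate", "value")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("expression table lacks columns: ", paste(missing, collapse = ", "))
  if (any(!is.finite(table$value)) || any(table$value < 0))
    stop("expression values must be finite and >= 0")
  key <- paste(table$gene, table$condition, table$replicate)
  if (anyDuplicated(key))
    stop("duplicate (gene, condition, replicate) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  table
}

#' Expression-to-capacity scaling factors
#'
#' Per-replicate ratios of expression to the mean expression of the
#' reference condition for the same gene; the reference-condition mean maps
#' to ratio 1. With \code{aggregation = "mean"} one ratio per (gene,
#' condition) is returned instead (condition mean / reference mean).
#'
#' @param table expression table (see \code{\link{read_expression}}).
#' @param reference_condition label of the reference (normoxia) condition.
#' @param aggregation \code{"per_replicate"} (default; one scaled model per
#'   replicate, matching the study's n = 3 mean +/- SEM statistics) or
#'   \code{"mean"}.
#' @return data frame with columns \code{gene}, \code{condition},
#'   \code{replicate} (NA for \code{"mean"}), \code{ratio}.
#' @export
compute_scaling_factors <- function(table, reference_condition,
                                    aggregation = c("per_replicate", "mean")) {
  aggregation <- match.arg(aggregation)
  table <- validate_expression_table(table)
  if (!reference_condition %in% table$condition)
    stop("reference condition '", reference_condition, "' absent from table")
  ref <- table[table$condition == reference_condition, ]
  ref_mean <- tapply(ref$value, ref$gene, mean)
  zero <- names(ref_mean)[ref_mean == 0]
  if (length(zero))
    stop("all-zero reference expression for gene(s): ",
         paste(zero, collapse = ", "))
  absent <- setdiff(unique(table$gene), names(ref_mean))
  if (length(absent))
    stop("gene(s) missing from reference condition: ",
         paste(absent, collapse = ", "))
  if (aggregation == "per_replicate") {
    data.frame(gene = table$gene, condition = table$condition,
               replicate = table$replicate,
               ratio = table$value / as.numeric(ref_mean[table$gene]),
               stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(value ~ gene + condition, table, mean)
    data.frame(gene = agg$gene, condition = agg$condition,
               replicate = NA_integer_,
               ratio = agg$value / as.numeric(ref_mean[agg$gene]),
               stringsAsFactors = FALSE)
  }
}

#' Scale reaction capacities by expression ratios
#'
#' Multiplies the Vmax of every reaction driven by a mapped gene by that
#' gene's expression ratio (linear expression-proportional capacity
#' scaling; a log-linear transform is available via \code{transform}).
#' Km values, clearance constants and boundary concentrations are never
#' touched. Gene symbols are matched case-insensitively after trimming.
#' Genes without a mapped reaction (e.g. the hypoxia marker Ndrg1) are
#' ignored with a notice.
#'
#' @param baseline a \code{trp_params}.
#' @param ratios named non-negative numeric vector, gene symbol -> ratio
#'   (one replicate's scaling factors).
#' @param map gene-to-reaction map as returned by
#'   \code{\link{gene_reaction_map}}.
#' @param transform \code{"linear"} (default, Vmax x ratio) or
#'   \code{"log_linear"} (Vmax x (1 + log(ratio)), floored at 0 exposure
#'   guarded to stay positive).
#' @return a scaled \code{trp_params}.
#' @export
scale_parameters <- function(baseline, ratios, map,
                             transform = c("linear", "log_linear")) {
  transform <- match.arg(transform)
  validate_trp_params(baseline)
  if (any(ratios < 0)) stop("expression ratios must be >= 0")
  norm <- function(x) tolower(trimws(x))
  map_genes <- norm(names(map))
  scaled <- baseline
  unmapped <- character(0)
  for (g in names(ratios)) {
    i <- match(norm(g), map_genes)
    if (is.na(i)) { unmapped <- c(unmapped, g); next }
    fac <- switch(transform,
                  linear = ratios[[g]],
                  log_linear = max(1 + log(max(ratios[[g]],
                                               .Machine$double.eps)), 0))
    for (rid in map[[i]]) {
      if (is.null(scaled$reactions[[rid]]))
        stop("mapped reaction absent from parameter set: ", rid)
      scaled$reactions[[rid]]$vmax <- scaled$reactions[[rid]]$vmax * fac
    }
  }
  if (length(unmapped))
    message("unmapped gene(s) ignored: ", paste(unmapped, collapse = ", "))
  scaled
}

#' Per-replicate ratio vectors for one condition
#'
#' Convenience accessor: splits the output of
#' \code{\link{compute_scaling_factors}} into one named gene->ratio vector
#' per replicate of \code{condition}.
#'
#' @param factors data frame from \code{\link{compute_scaling_factors}}.
#' @param condition condition label.
#' @return named list (replicate index) of named numeric vectors.
#' @export
replicate_ratios <- function(factors, condition) {
  sub <- factors[factors$condition == condition, ]
  if (!nrow(sub)) stop("condition '", condition, "' absent")
  lapply(split(sub, sub$replicate), function(d)
    stats::setNames(d$ratio, d$gene))
}
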