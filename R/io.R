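#' Serialize a steady-state result
#'
#' TSV: one row per dynamic species (\code{kind = concentration}) and one
#' per reaction (\code{kind = flux}), values at 12 significant digits for
#' diffability. JSON additionally carries the convergence diagnostics.
#'
#' @param result a \code{trp_steady_state}.
#' @param file output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return the path, invisibly.
#' @export
write_steady_state <- function(result, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- data.frame(
    id = c(names(result$concentrations), names(result$fluxes)),
    kind = rep(c("concentration", "flux"),
               c(length(result$concentrations), length(result$fluxes))),
    value = signif(c(result$concentrations, result$fluxes), 12),
    stringsAsFactors = FALSE)
  if (format == "tsv") {
    utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(values = tab,
           converged = result$converged,
           residual_norm = result$residual_norm,
           method = result$method,
           diagnostics = result$diagnostics),
      file, digits = NA, auto_unbox = TRUE, na = "null")
  }
  invisible(file)
}

#' Read back a steady-state TSV
#' @param file TSV written by \code{\link{write_steady_state}}.
#' @return data frame with columns \code{id}, \code{kind}, \code{value}.
#' @export
read_steady_state <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
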