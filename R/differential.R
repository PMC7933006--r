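# Condition comparison of per-replicate steady states: mean +/- SEM, fold
# change, unpaired two-tailed t-test (Welch default, Student optional),
# GraphPad-style significance codes, and sign-pattern checking against the
# expected hypoxic rewiring.

two_sample_p <- function(x, y, var_equal = FALSE) {
  # stats::t.test errors on (essentially) constant data; replicate-identical
  # inputs are legitimate here (noise-free synthetic runs), so fall back to
  # the degenerate limit: p = 0 if the means differ, 1 if they coincide.
  out <- tryCatch(stats::t.test(y, x, var.equal = var_equal)$p.value,
                  error = function(e) NULL)
  if (!is.null(out)) return(out)
  if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
}

#' Significance code for a p-value
#'
#' GraphPad-style stars: \code{ns} for p > 0.05, then \code{*},
#' \code{**}, \code{***}, \code{****} at p <= 0.05, 0.01, 0.001, 0.0001.
#'
#' @param p numeric vector of p-values.
#' @return character vector of codes.
#' @export
significance_code <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 1e-4) "****"
    else if (pi <= 1e-3) "***"
    else if (pi <= 1e-2) "**"
    else if (pi <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' Compare steady states between two conditions
#'
#' For every flux and every dynamic-species concentration, computes the
#' per-condition mean and SEM over replicates, the fold change (condition B
#' over condition A, linear scale), an unpaired two-tailed t-test p-value,
#' its significance code and a direction call (\code{up} / \code{down} when
#' significant, \code{flat} otherwise). Non-converged replicates are
#' excluded with a warning; if fewer than two converged replicates remain
#' in either condition, quantities are flagged untestable (NA p-values).
#'
#' Both Welch and pooled-variance Student p-values are carried in the
#' table (\code{p_welch}, \code{p_student}); \code{test} selects which one
#' drives \code{p_value}, codes and directions. A Benjamini-Hochberg
#' adjusted column is emitted as supplementary output and does not affect
#' the codes, matching per-quantity star semantics.
#'
#' @param results_A,results_B lists of \code{trp_steady_state} (replicates
#'   of condition A, the reference, and condition B).
#' @param test \code{"welch"} (default) or \code{"student"}.
#' @param conditions labels for the two conditions (cosmetic).
#' @return a \code{trp_differential} data frame.
#' @export
compare_conditions <- function(results_A, results_B,
                               test = c("welch", "student"),
                               conditions = c("A", "B")) {
  test <- match.arg(test)
  keep <- function(res, lab) {
    ok <- vapply(res, function(r) isTRUE(r$converged), logical(1))
    if (any(!ok))
      warning(sum(!ok), " non-converged replicate(s) excluded from condition ",
              lab)
    res[ok]
  }
  results_A <- keep(results_A, conditions[1])
  results_B <- keep(results_B, conditions[2])
  untestable <- length(results_A) < 2L || length(results_B) < 2L
  if (untestable)
    warning("fewer than 2 converged replicates in a condition; ",
            "p-values flagged untestable")

  gather <- function(res, field)
    do.call(rbind, lapply(res, `[[`, field))
  mat_A <- cbind(gather(results_A, "fluxes"), gather(results_A, "concentrations"))
  mat_B <- cbind(gather(results_B, "fluxes"), gather(results_B, "concentrations"))
  if (!identical(colnames(mat_A), colnames(mat_B)))
    stop("conditions come from different models")
  kind <- rep(c("flux", "concentration"),
              c(length(results_A[[1]]$fluxes),
                length(results_A[[1]]$concentrations)))

  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(seq_len(ncol(mat_A)), function(j) {
    a <- mat_A[, j]; b <- mat_B[, j]
    pw <- if (untestable) NA_real_ else two_sample_p(a, b, var_equal = FALSE)
    ps <- if (untestable) NA_real_ else two_sample_p(a, b, var_equal = TRUE)
    data.frame(quantity = colnames(mat_A)[j], kind = kind[j],
               mean_A = mean(a), mean_B = mean(b),
               sem_A = sem(a), sem_B = sem(b),
               fold_change = mean(b) / mean(a),
               p_welch = pw, p_student = ps,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_value <- if (test == "welch") tab$p_welch else tab$p_student
  tab$p_adj_BH <- stats::p.adjust(tab$p_value, method = "BH")
  tab$significance_code <- significance_code(tab$p_value)
  tab$direction <- ifelse(is.na(tab$p_value) | tab$significance_code == "ns",
                          "flat",
                          ifelse(tab$fold_change > 1, "up",
                                 ifelse(tab$fold_change < 1, "down", "flat")))
  attr(tab, "conditions") <- conditions
  attr(tab, "test") <- test
  class(tab) <- c("trp_differential", "data.frame")
  tab
}

#' Expected direction of the hypoxic flux rewiring
#'
#' The default expectation set for \code{\link{sign_pattern}}: under
#' hypoxia the transporter exchange and every kynurenine-pathway flux fall,
#' the tryptamine-branch fluxes rise; kynurenine, 3-hydroxyanthranilic acid
#' and quinolinate concentrations fall while tryptamine rises. TPH1 flux,
#' kynurenic acid, indole-3-pyruvate and the remaining quantities are left
#' unconstrained.
#'
#' @return named character vector, quantity id -> \code{"up"}/\code{"down"}.
#' @export
default_expectations <- function() {
  c(R_LAT1 = "down", R_LAT2 = "down", R_TDO2 = "down", R_KAT = "down",
    R_KYNU_a = "down", R_KYNU_b = "down", R_KMO = "down", R_HAAO = "down",
    R_QPRT = "down",
    R_DDC_trp = "up", R_INMT_1 = "up", R_INMT_2 = "up",
    Kyn = "down", HAA3 = "down", Quin = "down", Trypta = "up")
}

#' Check a differential table against expected directions
#'
#' @param table a \code{trp_differential}.
#' @param expectations named character vector quantity -> expected
#'   direction (\code{"up"} or \code{"down"}); defaults to
#'   \code{\link{default_expectations}}.
#' @return a \code{trp_sign_report}: data frame of (quantity, expected,
#'   observed, pass) with attribute \code{overall_pass}.
#' @export
sign_pattern <- function(table, expectations = default_expectations()) {
  if (!nrow(table)) {
    warning("empty differential table; sign pattern vacuously passes")
    rep <- data.frame(quantity = character(0), expected = character(0),
                      observed = character(0), pass = logical(0))
    attr(rep, "overall_pass") <- TRUE
    class(rep) <- c("trp_sign_report", "data.frame")
    return(rep)
  }
  missing <- setdiff(names(expectations), table$quantity)
  if (length(missing))
    stop("expectations reference unknown quantities: ",
         paste(missing, collapse = ", "))
  obs <- table$direction[match(names(expectations), table$quantity)]
  rep <- data.frame(quantity = names(expectations),
                    expected = unname(expectations),
                    observed = obs,
                    pass = obs == unname(expectations),
                    stringsAsFactors = FALSE)
  attr(rep, "overall_pass") <- all(rep$pass)
  class(rep) <- c("trp_sign_report", "data.frame")
  rep
}

#' @export
print.trp_sign_report <- function(x, ...) {
  cat(sprintf("Sign-pattern report: %s (%d/%d quantities match)\n",
              if (attr(x, "overall_pass")) "PASS" else "FAIL",
              sum(x$pass), nrow(x)))
  if (any(!x$pass)) {
    cat("Mismatches:\n")
    print.data.frame(x[!x$pass, ], row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.trp_differential <- function(x, ...) {
  cc <- attr(x, "conditions")
  cat(sprintf("Differential table (%s vs %s, %s t-test), %d quantities\n",
              cc[2], cc[1], attr(x, "test"), nrow(x)))
  d <- as.data.frame(x)
  d[] <- lapply(d, function(col) if (is.numeric(col)) signif(col, 4) else col)
  print.data.frame(d, row.names = FALSE)
  invisible(x)
}

#' Write a differential table to TSV / JSON
#' @param table a \code{trp_differential}.
#' @param file output path (.tsv or .json decided by \code{format}).
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
write_differential <- function(table, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- as.data.frame(table)
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], signif, digits = 12)
    utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(as.data.frame(table), file, digits = NA, na = "null",
                         auto_unbox = TRUE)
  }
  invisible(file)
}
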