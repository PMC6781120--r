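#' Write model solutions as TSV
#'
#' One row per effect level: `effect`, `level`, `estimate`.
#'
#' @param fit A `vc_fit` or `rnm_fit`.
#' @param path Output TSV path.
#' @export
write_solutions <- function(fit, path) {
  vc <- if (inherits(fit, "rnm_fit")) fit$vc else fit
  sol <- vc$solutions
  rows <- data.frame(effect = "fixed", level = names(sol$fixed),
                     estimate = unname(sol$fixed))
  for (nm in names(sol$random)) {
    r <- sol$random[[nm]]
    if (is.matrix(r)) {
      rows <- rbind(rows,
                    data.frame(effect = paste0(nm, "_a0"),
                               level = rownames(r), estimate = r[, "a0"]),
                    data.frame(effect = paste0(nm, "_a1"),
                               level = rownames(r), estimate = r[, "a1"]))
    } else {
      rows <- rbind(rows, data.frame(effect = nm, level = names(r),
                                     estimate = unname(r)))
    }
  }
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write single-step GWAS results as TSV
#'
#' `<prefix>_effects.tsv` (marker, chrom, pos, u0, u1, weight) and
#' `<prefix>_windows.tsv` (window, chrom, start, end, size, percentage of
#' intercept and slope variance).
#'
#' @param gwas Output of [run_ssgwas()].
#' @param prefix Path prefix.
#' @export
write_ssgwas <- function(gwas, prefix) {
  pe <- paste0(prefix, "_effects.tsv")
  pw <- paste0(prefix, "_windows.tsv")
  utils::write.table(gwas$effects, pe, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(gwas$windows, pw, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(pe, pw))
}

#' Reference reaction-norm variance components for fertility traits
#'
#' Reads the bundled table of variance components (intercept variance,
#' slope variance, intercept-slope covariance, permanent environmental,
#' herd-year and residual variances, and the reported intercept-slope
#' correlation) estimated with reaction norm models for the four female
#' fertility traits of a Danish Holstein population (ICF, IFL, AIS, NRR),
#' under both the pedigree (A) and the combined pedigree-genomic (H)
#' relationship matrix. Useful as reference inputs for the summary
#' statistics in this package.
#'
#' @return A `data.frame`, one row per trait x matrix.
#' @export
fertility_rnm_components <- function() {
  utils::read.delim(system.file("extdata",
                                "holstein_fertility_rnm_components.tsv",
                                package = "ssrnm", mustWork = TRUE))
}
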