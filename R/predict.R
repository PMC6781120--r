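#' Combine intercept and slope into a breeding value
#'
#' `a_hat = a0_hat + f_bar * a1_hat`: the breeding value of a bull at the
#' mean environmental gradient of its daughters' herds.
#'
#' @param a0,a1 Intercept and slope estimates (vectorised).
#' @param f_bar Mean daughter-herd effect per animal (0 = population mean
#'   environment, used for animals without daughters).
#' @return Combined breeding values.
#' @export
combine_ebv <- function(a0, a1, f_bar = 0) {
  a0 + f_bar * a1
}

#' Mean daughter-herd environmental gradient per sire
#'
#' For each sire, the mean of the herd effects over its daughters' records
#' (so herds are weighted by daughter record counts); 0 for sires without
#' daughter records.
#'
#' @param sires Sire ids to compute for.
#' @param pedigree Pedigree `data.frame`.
#' @param data Phenotype records.
#' @param f Named herd-effect vector.
#' @return Named vector of mean gradients.
#' @export
mean_daughter_eg <- function(sires, pedigree, data, f) {
  sire_of <- stats::setNames(pedigree$sire, pedigree$id)
  rec_sire <- sire_of[as.character(data$animal)]
  rec_f <- unname(f[as.character(data$herd)])
  fbar <- tapply(rec_f, rec_sire, mean)
  out <- stats::setNames(rep(0, length(sires)), sires)
  got <- as.character(sires) %in% names(fbar)
  out[got] <- fbar[as.character(sires)[got]]
  out
}

#' Training/validation split by bull birthdate
#'
#' The youngest `fraction` of bulls with daughter records form the
#' validation set; their daughters' records are excluded from the training
#' fit and used only for daughter yield deviations.
#'
#' @param pedigree Pedigree `data.frame` with `birthdate`.
#' @param data Phenotype records.
#' @param fraction Validation fraction (default: youngest 20%).
#' @return List with `validation` and `training` sire ids, the `cutoff`
#'   birthdate, and `training_data` (records of non-validation daughters).
#' @export
validation_split <- function(pedigree, data, fraction = 0.2) {
  sire_of <- stats::setNames(pedigree$sire, pedigree$id)
  rec_sire <- sire_of[as.character(data$animal)]
  bulls <- sort(unique(rec_sire[rec_sire != 0]))
  bd <- pedigree$birthdate[match(bulls, pedigree$id)]
  n_val <- max(1L, floor(fraction * length(bulls)))
  ord <- order(bd, decreasing = TRUE)
  validation <- bulls[ord[seq_len(n_val)]]
  cutoff <- min(bd[ord[seq_len(n_val)]])
  training <- setdiff(bulls, validation)
  keep <- !(rec_sire %in% validation)
  list(validation = validation, training = training, cutoff = cutoff,
       training_data = data[keep, , drop = FALSE])
}

#' Daughter yield deviations
#'
#' The average performance of a sire's daughters adjusted for all fixed
#' effects and the non-genetic random effects (herd-year, permanent
#' environment) as well as half the dam's additive genetic effect. Fixed
#' and random adjustments come from the supplied fit; levels unseen in that
#' fit (e.g. herd-years of held-out records) contribute zero.
#'
#' @param data Records of the daughters to average (may include records the
#'   fit never saw).
#' @param fit An `rnm_fit` (the training fit).
#' @param pedigree Pedigree `data.frame`.
#' @param min_daughters Sires with fewer daughter records are flagged.
#' @return `data.frame` with `sire`, `dyd`, `n_daughter_records`, `flagged`.
#' @export
compute_dyd <- function(data, fit, pedigree, min_daughters = 10L) {
  data <- add_age_class(data)
  vc <- fit$vc
  fe <- vc$solutions$fixed
  ## fixed-part prediction with drop-first treatment coding
  adj <- rep(unname(fe["(Intercept)"]), nrow(data))
  for (col in vc$spec$fixed) {
    idx <- match(paste0(col, data[[col]]), names(fe))
    v <- numeric(nrow(data))
    ok <- !is.na(idx)
    v[ok] <- fe[idx[ok]]
    adj <- adj + v
  }
  hy <- vc$solutions$random$herd_year
  adj <- adj + ifelse(data$herd_year %in% names(hy),
                      hy[as.character(data$herd_year)], 0)
  pe <- vc$solutions$random$pe
  adj <- adj + ifelse(as.character(data$animal) %in% names(pe),
                      pe[as.character(data$animal)], 0)
  ## dam's additive genetic effect at the record's environment
  dam <- pedigree$dam[match(data$animal, pedigree$id)]
  eg <- unname(fit$f[as.character(data$herd)])
  dam_chr <- as.character(dam)
  a0d <- ifelse(dam_chr %in% names(fit$a0), fit$a0[dam_chr], 0)
  a1d <- ifelse(dam_chr %in% names(fit$a1), fit$a1[dam_chr], 0)
  dev <- data$value - adj - 0.5 * (a0d + a1d * eg)

  sire <- pedigree$sire[match(data$animal, pedigree$id)]
  keep <- sire != 0
  dyd <- tapply(dev[keep], sire[keep], mean)
  n <- tapply(dev[keep], sire[keep], length)
  out <- data.frame(sire = as.integer(names(dyd)), dyd = as.numeric(dyd),
                    n_daughter_records = as.integer(n))
  out$flagged <- out$n_daughter_records < min_daughters
  out
}

#' Forward-prediction accuracy against daughter yield deviations
#'
#' Pearson correlation between predicted breeding values and daughter
#' yield deviations over the validation sires.
#'
#' @param predictions Named vector of predicted breeding values (by sire).
#' @param dyds Output of [compute_dyd()] (or a named vector).
#' @param validation_ids Sires to evaluate (default: all sires present in
#'   both).
#' @param use_flagged Include sires below the daughter-count minimum.
#' @return The correlation (scalar).
#' @export
validation_accuracy <- function(predictions, dyds, validation_ids = NULL,
                                use_flagged = TRUE) {
  if (is.data.frame(dyds)) {
    if (!use_flagged) dyds <- dyds[!dyds$flagged, ]
    dv <- stats::setNames(dyds$dyd, dyds$sire)
  } else dv <- dyds
  ids <- intersect(names(predictions), names(dv))
  if (!is.null(validation_ids))
    ids <- intersect(ids, as.character(validation_ids))
  if (length(ids) < 3) stop("fewer than 3 sires with both values")
  p <- predictions[ids]; d <- dv[ids]
  if (stats::sd(p) == 0 || stats::sd(d) == 0)
    stop("degenerate (zero-variance) inputs")
  stats::cor(p, d)
}

#' Overlap of top-ranked animals between two environments
#'
#' Animals are ranked by `a0 + f * a1` at the two gradient values; for
#' traits where smaller is better (interval and count fertility traits)
#' ranking is ascending, otherwise descending. Returns the size of the
#' intersection of the two top-k sets.
#'
#' @param a0,a1 Named intercept and slope estimates (same animals).
#' @param f1,f2 Environmental gradient values.
#' @param k Top-list size.
#' @param direction `"asc"` (smaller is better) or `"desc"`.
#' @return Integer overlap in \[0, k\].
#' @export
top_k_overlap <- function(a0, a1, f1, f2, k = 50L,
                          direction = c("asc", "desc")) {
  direction <- match.arg(direction)
  if (k > length(a0)) stop("k exceeds the number of animals")
  v1 <- combine_ebv(a0, a1, f1)
  v2 <- combine_ebv(a0, a1, f2)
  dec <- direction == "desc"
  top1 <- names(sort(v1, decreasing = dec))[seq_len(k)]
  top2 <- names(sort(v2, decreasing = dec))[seq_len(k)]
  length(intersect(top1, top2))
}
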