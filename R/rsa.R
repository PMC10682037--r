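# Partial Spearman RSA: rank correlation between a neural RDV and a model
# RDV after removing, by least squares on ranks, the variance explained by
# covariate RDVs.

# Partial Pearson correlation of pre-ranked vectors given a covariate
# matrix (columns already ranked).  Zero-variance residuals return 0 by
# convention (with a warning from the public wrapper).
partial_cor_ranked <- function(rx, ry, z = NULL) {
  if (!is.null(z) && ncol(z) > 0L) {
    qx <- qr(cbind(1, z))
    rx <- qr.resid(qx, rx)
    ry <- qr.resid(qx, ry)
  } else {
    rx <- rx - mean(rx)
    ry <- ry - mean(ry)
  }
  sx <- sqrt(sum(rx^2))
  sy <- sqrt(sum(ry^2))
  if (sx < 1e-12 || sy < 1e-12) return(structure(0, degenerate = TRUE))
  sum(rx * ry) / (sx * sy)
}

#' Partial Spearman correlation between two RDVs
#'
#' All vectors are rank-transformed (average ranks for ties); target and
#' model ranks are regressed on the covariate ranks (with intercept) by
#' least squares, and the Pearson correlation of the two residual vectors
#' is returned.  With no covariates this is the plain Spearman
#' correlation.  Rank-deficient covariate sets are handled by the pivoted
#' QR (dependent covariates contribute nothing).  Zero-variance residuals
#' yield 0 with a warning — the documented convention for degenerate
#' inputs.
#'
#' @param target,model numeric vectors (e.g. RDVs) of equal length >= 4.
#' @param covariates list of numeric vectors of the same length (possibly
#'   empty).
#' @return partial Spearman correlation in `[-1, 1]`.
#' @export
partial_spearman <- function(target, model, covariates = list()) {
  x <- as.numeric(target)
  y <- as.numeric(model)
  if (length(x) != length(y)) stop("target and model differ in length")
  if (length(x) < 4L) stop("need at least 4 pairs")
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  z <- NULL
  if (length(covariates)) {
    z <- vapply(covariates, function(v) {
      v <- as.numeric(v)
      if (length(v) != length(x)) stop("covariate length mismatch")
      rank(v)
    }, numeric(length(x)))
    if (anyNA(z)) return(NA_real_)
  }
  r <- partial_cor_ranked(rank(x), rank(y), z)
  if (isTRUE(attr(r, "degenerate")))
    warning("zero-variance residuals; returning 0")
  as.numeric(r)
}

#' RSA time-course for one subject
#'
#' Applies [partial_spearman()] between the neural RDV at every valid
#' timepoint and a model RDV, controlling for covariate model RDVs, which
#' isolates the tested model's unique effect.  Invalid timepoints
#' propagate as NA.
#'
#' @param neural a `neural_rdm_series`.
#' @param model a model `rdv` (or numeric vector) subsetted to the same
#'   items as `neural`.
#' @param covariates list of covariate RDVs (same items).
#' @return numeric vector of effects, one per timepoint, with NA at
#'   invalid timepoints.
#' @export
rsa_timecourse <- function(neural, model, covariates = list()) {
  stopifnot(inherits(neural, "neural_rdm_series"))
  check_item_alignment(neural, model)
  for (cv in covariates) check_item_alignment(neural, cv)
  n_pairs <- ncol(neural$rdvs)
  rm_ <- rank(as.numeric(model))
  z <- if (length(covariates))
    vapply(covariates, function(v) rank(as.numeric(v)), numeric(n_pairs))
  eff <- rep(NA_real_, nrow(neural$rdvs))
  n_degen <- 0L
  for (t in which(neural$valid_timepoints)) {
    v <- neural$rdvs[t, ]
    if (anyNA(v)) next
    r <- partial_cor_ranked(rank(v), rm_, z)
    if (isTRUE(attr(r, "degenerate"))) n_degen <- n_degen + 1L
    eff[t] <- as.numeric(r)
  }
  if (n_degen > 0L)
    warning("zero-variance residuals at ", n_degen,
            " timepoint(s); effects set to 0 there")
  eff
}

check_item_alignment <- function(neural, rdv) {
  lab <- attr(rdv, "item_labels")
  if (!is.null(lab) && !identical(lab, neural$item_labels))
    stop("item labels of model RDV do not match the neural series")
  if (length(rdv) != ncol(neural$rdvs))
    stop("RDV length does not match the neural series pair count")
  invisible(TRUE)
}

#' Group RSA time-courses
#'
#' Runs [rsa_timecourse()] for each subject's neural series and stacks the
#' results into a subjects x timepoints effects matrix.
#'
#' @param neural_list list of per-subject `neural_rdm_series` sharing a
#'   time axis.
#' @param model tested model RDV.
#' @param covariates list of covariate model RDVs.
#' @param model_name,covariate_names labels stored on the result.
#' @return an `rsa_timecourses` object: list with `effects` (subjects x
#'   timepoints), `time_ms`, `model`, `covariates`.
#' @export
rsa_group <- function(neural_list, model, covariates = list(),
                      model_name = "model", covariate_names = character()) {
  effects <- t(vapply(neural_list, rsa_timecourse,
                      numeric(nrow(neural_list[[1L]]$rdvs)),
                      model = model, covariates = covariates))
  structure(list(effects = effects, time_ms = neural_list[[1L]]$time_ms,
                 model = model_name, covariates = covariate_names),
            class = "rsa_timecourses")
}

#' @export
print.rsa_timecourses <- function(x, ...) {
  cat(sprintf("rsa_timecourses: model '%s', %d subjects x %d timepoints\n",
              x$model, nrow(x$effects), ncol(x$effects)))
  invisible(x)
}
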