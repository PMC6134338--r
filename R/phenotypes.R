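#' Fit a one-factor model to the language battery
#'
#' Fits a single-factor model to the four language subtests (verbal
#' comprehension, oromotor sequences, sentence repetition, vocabulary) on
#' complete cases by maximum likelihood ([stats::factanal()]); when ML
#' fails (for example a singular or rank-deficient battery) the first
#' principal component is used instead and the fallback is recorded.
#' Factor scores are regression (Thomson) scores, computed for every sample
#' with at least `min_items` observed subtests by restricting the
#' model-implied covariance to the observed items, so partially tested
#' children are scored with available-item reweighting.
#'
#' Loadings are sign-fixed so that higher subtest scores mean a higher
#' (better) factor score.
#'
#' @param battery data frame of subtest scores (one column per subtest,
#'   missing values allowed).
#' @param min_items minimum observed subtests for a sample to be scored.
#' @param min_complete minimum complete cases needed to fit loadings.
#' @return List of class `language_factor_fit`: `loadings`, `uniquenesses`,
#'   `scores` (NA for unscorable samples), `method` (`"ml"` or `"pca"`),
#'   `n_complete`, `scored` (logical), `center`/`scale` used to standardize
#'   subtests.
#' @export
fit_language_factor <- function(battery, min_items = 2L, min_complete = 10L) {
  battery <- as.data.frame(battery)
  X <- as.matrix(battery)
  storage.mode(X) <- "double"
  complete <- stats::complete.cases(X)
  if (sum(complete) < min_complete) {
    stop(sprintf("need at least %d complete cases to fit loadings", min_complete))
  }
  center <- colMeans(X[complete, , drop = FALSE])
  scl <- apply(X[complete, , drop = FALSE], 2, stats::sd)
  if (any(!is.finite(scl) | scl == 0)) stop("zero-variance subtest in battery")
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")
  R <- stats::cor(Z[complete, , drop = FALSE])
  if (any(!is.finite(R))) stop("battery correlation matrix is not defined")

  method <- "ml"
  fit <- tryCatch(
    stats::factanal(covmat = R, factors = 1, n.obs = sum(complete)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    lambda <- as.numeric(fit$loadings)
    psi <- fit$uniquenesses
  } else {
    method <- "pca"
    e <- eigen(R, symmetric = TRUE)
    lambda <- e$vectors[, 1] * sqrt(e$values[1])
    lambda <- pmin(pmax(lambda, -0.999), 0.999)
    psi <- pmax(1 - lambda^2, 1e-6)
  }
  if (sum(lambda) < 0) lambda <- -lambda # positive = better language
  names(lambda) <- names(psi) <- colnames(battery)

  n_obs_items <- rowSums(!is.na(Z))
  scored <- n_obs_items >= min_items
  scores <- rep(NA_real_, nrow(Z))
  sigma <- tcrossprod(lambda) + diag(psi, length(lambda))
  # cache the scoring weights per missingness pattern
  patterns <- apply(matrix(as.integer(!is.na(Z)), nrow(Z)), 1, paste, collapse = "")
  for (pat in unique(patterns[scored])) {
    obs <- which(strsplit(pat, "")[[1]] == "1")
    rows <- which(patterns == pat & scored)
    w <- solve(sigma[obs, obs, drop = FALSE], lambda[obs])
    scores[rows] <- as.matrix(Z[rows, obs, drop = FALSE]) %*% w
  }
  structure(
    list(
      loadings = lambda, uniquenesses = psi, scores = scores,
      method = method, n_complete = sum(complete), scored = scored,
      center = center, scale = scl
    ),
    class = "language_factor_fit"
  )
}

#' @export
print.language_factor_fit <- function(x, ...) {
  cat(sprintf(
    "<language_factor_fit> method=%s, %d complete cases, %d scored samples\n",
    x$method, x$n_complete, sum(x$scored)
  ))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Orient and standardize the three analysis phenotypes
#'
#' Ensures all three outcome measures point the same way (low score =
#' impaired) and z-standardizes the language factor against a reference
#' sample (by default the pooled twin comparison subsamples, the natural
#' norming population; falls back to all samples when no reference ids are
#' given). The global burden index is sign-flipped when it is supplied in
#' the raw orientation where a high score means many problems.
#'
#' @param pheno data frame with columns `nonword_repetition`,
#'   `language_factor`, `global_burden` (plus anything else, passed through).
#' @param reference_ids sample ids (matched against `pheno$sample_id`)
#'   defining the standardization reference population; `NULL` uses all rows.
#' @param burden_high_is_impaired `TRUE` when the supplied burden column is
#'   raw (high = many problems) and must be inverted.
#' @param standardize_burden also z-standardize the (oriented) burden index
#'   against the reference sample.
#' @return `pheno` with oriented/standardized measure columns and an
#'   attribute `orientation_log` describing what was done.
#' @export
orient_and_standardize <- function(pheno, reference_ids = NULL,
                                   burden_high_is_impaired = FALSE,
                                   standardize_burden = FALSE) {
  needed <- c("nonword_repetition", "language_factor", "global_burden")
  missing_cols <- setdiff(needed, names(pheno))
  if (length(missing_cols)) {
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  log <- character()
  if (burden_high_is_impaired) {
    pheno$global_burden <- -pheno$global_burden
    log <- c(log, "global_burden inverted so low score = impaired")
  }
  ref <- if (is.null(reference_ids)) {
    rep(TRUE, nrow(pheno))
  } else {
    pheno$sample_id %in% reference_ids
  }
  if (!any(ref)) stop("reference population is empty")
  zstd <- function(x, label) {
    mu <- mean(x[ref], na.rm = TRUE)
    s <- stats::sd(x[ref], na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero-variance measure: ", label)
    (x - mu) / s
  }
  pheno$language_factor <- zstd(pheno$language_factor, "language_factor")
  log <- c(log, sprintf(
    "language_factor z-standardized against %s",
    if (is.null(reference_ids)) "all samples" else
      sprintf("%d reference samples", sum(ref))
  ))
  if (standardize_burden) {
    pheno$global_burden <- zstd(pheno$global_burden, "global_burden")
    log <- c(log, "global_burden z-standardized against reference")
  }
  attr(pheno, "orientation_log") <- log
  pheno
}
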