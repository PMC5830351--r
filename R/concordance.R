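#' Concordance of change points across regions of interest
#'
#' Tests whether estimated change points differ between ROIs (one-way ANOVA
#' with ROI as factor, subjects as replicates) and whether they covary
#' across subjects (PCA on the correlation matrix of the ROI columns; a
#' first-component variance fraction well above `1/k` indicates concerted
#' timing). Optionally correlates the first-component scores with a
#' per-subject covariate such as the heart-rate conditioning effect.
#'
#' @param change_points Numeric subjects x ROIs matrix (no missing cells;
#'   >= 3 subjects, >= 2 ROIs).
#' @param covariate Optional per-subject numeric vector.
#' @return An object of class `concordance`: ANOVA `F`, `df`, `p`;
#'   `eigen_fractions` (variance explained per component, summing to 1);
#'   `pc1_scores`; `loadings`; and, when a covariate is given,
#'   `covariate_r`/`covariate_p` from a Pearson correlation test.
#' @export
roi_concordance <- function(change_points, covariate = NULL) {
  M <- as.matrix(change_points)
  if (ncol(M) < 2L) stop("need at least 2 ROIs")
  if (nrow(M) < 3L) stop("need at least 3 subjects")
  if (anyNA(M)) stop("missing cells in the change-point matrix")
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI column(s): ",
         paste(colnames(M)[sds == 0] %||% which(sds == 0), collapse = ", "))
  }
  rois <- colnames(M) %||% paste0("roi", seq_len(ncol(M)))

  long <- data.frame(value = as.vector(M),
                     roi = factor(rep(rois, each = nrow(M)), levels = rois))
  an <- stats::anova(stats::lm(value ~ roi, data = long))
  pca <- pca_sign_fixed(M)
  fractions <- pca$sdev^2 / sum(pca$sdev^2)

  res <- list(F = an$`F value`[1],
              df = c(an$Df[1], an$Df[2]),
              p = an$`Pr(>F)`[1],
              eigen_fractions = fractions,
              pc1_scores = unname(pca$x[, 1]),
              loadings = pca$rotation,
              rois = rois,
              n_subjects = nrow(M),
              covariate_r = NA_real_, covariate_p = NA_real_)
  if (!is.null(covariate)) {
    if (length(covariate) != nrow(M)) stop("covariate length must equal the subject count")
    ct <- stats::cor.test(res$pc1_scores, covariate)
    res$covariate_r <- unname(ct$estimate)
    res$covariate_p <- ct$p.value
  }
  structure(res, class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance> %d subjects x %d ROIs\n", x$n_subjects, length(x$rois)))
  cat(sprintf("  ANOVA F(%d,%d) = %.3g, p = %.3g\n", x$df[1], x$df[2], x$F, x$p))
  cat(sprintf("  PC1 explains %.1f%% of variance (independence baseline %.1f%%)\n",
              100 * x$eigen_fractions[1], 100 / length(x$rois)))
  if (!is.na(x$covariate_r)) {
    cat(sprintf("  PC1 score vs covariate: r = %.3g, p = %.3g\n",
                x$covariate_r, x$covariate_p))
  }
  invisible(x)
}

# PCA on the correlation matrix with a fixed sign convention: PC1 loadings
# sum to a positive value, so scores point along the common latent and
# covariate correlations have an interpretable sign.
pca_sign_fixed <- function(M) {
  pca <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  if (sum(pca$rotation[, 1]) < 0) {
    pca$rotation[, 1] <- -pca$rotation[, 1]
    pca$x[, 1] <- -pca$x[, 1]
  }
  pca
}

#' First-component variance fraction under independence
#'
#' For `k` mutually independent variables the population correlation matrix
#' is the identity, every eigenvalue is 1, and the first principal component
#' explains exactly `1/k` of the variance. Computed here by eigendecomposing
#' the identity correlation matrix; this is the reference value against
#' which an observed PC1 fraction is judged.
#'
#' @param k Number of variables (>= 1).
#' @return Fraction in `(0, 1]`.
#' @examples
#' pc1_fraction_independent(3)  # 1/3
#' pc1_fraction_independent(2)  # 1/2
#' @export
pc1_fraction_independent <- function(k) {
  stopifnot(k >= 1)
  ev <- eigen(diag(k), symmetric = TRUE, only.values = TRUE)$values
  max(ev) / sum(ev)
}

#' Concordance of dissimilarity slopes across ROIs
#'
#' Pairwise Pearson correlations between per-subject dissimilarity slopes of
#' different ROIs, PCA on their correlation matrix, and (optionally) the
#' correlation of the first-component scores with an external per-subject
#' slope such as the univariate amygdala adaptation rate.
#'
#' @param slopes Numeric subjects x ROIs matrix of dissimilarity slopes.
#' @param external_slope Optional per-subject numeric vector.
#' @return An object of class `slope_set`: `pairwise` (data.frame of ROI
#'   pairs with r and p), `eigen_fractions`, `pc1_scores`, and
#'   `external_r`/`external_p` when an external slope is given.
#' @export
slope_concordance <- function(slopes, external_slope = NULL) {
  M <- as.matrix(slopes)
  if (ncol(M) < 2L) stop("need at least 2 ROIs")
  if (nrow(M) < 3L) stop("need at least 3 subjects")
  if (anyNA(M)) stop("missing slopes")
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0)) stop("zero-variance slope column(s)")
  rois <- colnames(M) %||% paste0("roi", seq_len(ncol(M)))

  pairs <- utils::combn(seq_len(ncol(M)), 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    ct <- stats::cor.test(M[, i1], M[, i2])
    data.frame(roi1 = rois[i1], roi2 = rois[i2],
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))

  pca <- pca_sign_fixed(M)
  res <- list(pairwise = pairwise,
              eigen_fractions = pca$sdev^2 / sum(pca$sdev^2),
              pc1_scores = unname(pca$x[, 1]),
              loadings = pca$rotation,
              rois = rois,
              n_subjects = nrow(M),
              external_r = NA_real_, external_p = NA_real_)
  if (!is.null(external_slope)) {
    if (length(external_slope) != nrow(M)) {
      stop("external slope length must equal the subject count")
    }
    ct <- stats::cor.test(res$pc1_scores, external_slope)
    res$external_r <- unname(ct$estimate)
    res$external_p <- ct$p.value
  }
  structure(res, class = "slope_set")
}

#' @export
print.slope_set <- function(x, ...) {
  cat(sprintf("<slope_set> %d subjects x %d ROIs\n", x$n_subjects, length(x$rois)))
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("  %s vs %s: r = %.3g, p = %.3g\n",
                x$pairwise$roi1[i], x$pairwise$roi2[i],
                x$pairwise$r[i], x$pairwise$p[i]))
  }
  cat(sprintf("  PC1 explains %.1f%% of variance (independence baseline %.1f%%)\n",
              100 * x$eigen_fractions[1], 100 / length(x$rois)))
  if (!is.na(x$external_r)) {
    cat(sprintf("  PC1 score vs external slope: r = %.3g, p = %.3g\n",
                x$external_r, x$external_p))
  }
  invisible(x)
}
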