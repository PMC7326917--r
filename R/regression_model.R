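#' Construct a tolerance model
#'
#' A linear tolerance score: Y = intercept + sum of coefficient_i * STI_i
#' over the seven traits, in \code{\link{trait_names}} order.
#'
#' @param coefficients Named (or trait-ordered) numeric vector of 7
#'   unstandardized coefficients.
#' @param intercept Scalar intercept (the fit's "random error term").
#' @param fitted_on Panel size the model was fitted on, or \code{NA}.
#' @param r_squared Coefficient of determination of the fit, or \code{NA}.
#' @return An object of class \code{"tolerance_model"}.
#' @export
tolerance_model <- function(coefficients, intercept,
                            fitted_on = NA_integer_, r_squared = NA_real_) {
  if (length(coefficients) != 7L)
    .stopf("a tolerance model has exactly 7 coefficients")
  if (is.null(names(coefficients))) names(coefficients) <- .TRAITS
  if (!identical(sort(names(coefficients)), sort(.TRAITS)))
    .stopf("coefficients must be named by the seven traits")
  structure(list(coefficients = coefficients[.TRAITS],
                 intercept = unname(intercept),
                 fitted_on = fitted_on, r_squared = r_squared),
            class = "tolerance_model")
}

#' @export
print.tolerance_model <- function(x, ...) {
  cat("Linear salt-tolerance score: Y = intercept + sum(beta_i * STI_i)\n")
  print(round(c(x$coefficients, intercept = x$intercept), 5))
  if (!is.na(x$fitted_on))
    cat(sprintf("fitted on %d germplasms, R-squared %.6f\n",
                x$fitted_on, x$r_squared))
  invisible(x)
}

#' Fit the linear tolerance model
#'
#' Ordinary least squares of mean MFV on the seven salt-tolerance indices
#' (with intercept), solved by QR decomposition. Because mean MFV is, by
#' construction of the membership normalization, an affine function of the
#' STIs, a fit on a complete panel is exact: coefficient_i =
#' 1 / (7 * (max_i - min_i)), intercept = -sum(min_i / (7 * (max_i -
#' min_i))), residuals ~ 0 and R-squared = 1. The fitted score lets new
#' germplasms be graded from their STIs alone.
#'
#' @param sti STI table (\code{\link{sti_table}}) or germplasm x 7 matrix;
#'   no missing entries (use the \code{zero_fill} policy upstream).
#' @param mean_mfvs Mean MFV per germplasm, aligned with \code{sti} rows.
#' @return A \code{"tolerance_model"}.
#' @export
fit_tolerance_model <- function(sti, mean_mfvs) {
  m <- .as_trait_matrix(sti)
  if (nrow(m) != length(mean_mfvs))
    .stopf("STI rows (%d) and mean MFV values (%d) differ", nrow(m), length(mean_mfvs))
  if (nrow(m) < 9L)
    .stopf("fitting needs at least 9 germplasms (more rows than parameters)")
  if (anyNA(m) || anyNA(mean_mfvs))
    .stopf("missing values in the design; apply the zero_fill policy first")
  df <- as.data.frame(m)
  names(df) <- .TRAITS
  df$.y <- mean_mfvs
  fit <- stats::lm(.y ~ ., data = df)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    bad <- setdiff(names(beta)[is.na(beta)], "(Intercept)")
    .stopf("rank-deficient design: trait(s) %s carry no independent information",
           paste(bad, collapse = ", "))
  }
  tss <- sum((mean_mfvs - mean(mean_mfvs))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  tolerance_model(beta[.TRAITS], beta[["(Intercept)"]],
                  fitted_on = nrow(m), r_squared = r2)
}

#' Predict the tolerance score Y
#'
#' Y = intercept + sum(coefficient_i * STI_i). All seven STIs must be
#' present (zero-filled values count as present).
#'
#' @param model A \code{"tolerance_model"}.
#' @param sti STI table, germplasm x 7 matrix, or a single named 7-vector.
#' @return Numeric vector of Y scores, named by germplasm when available.
#' @export
#' @examples
#' predict_y(published_model(), c(GR = 0.936, GI = 0.836, GE = 0.676,
#'                                RL = 0.230, GVI = 0.193, FW = 1.087,
#'                                WC = 1.228))
predict_y <- function(model, sti) {
  stopifnot(inherits(model, "tolerance_model"))
  m <- .as_trait_matrix(sti)
  if (anyNA(m)) .stopf("missing STI value; Y needs all seven traits")
  drop(m %*% model$coefficients) + model$intercept
}

#' Validate a model against observed mean MFV
#'
#' Mean, maximum and minimum of |Y - mean MFV| over a panel. On the panel a
#' model was fitted on with complete traits these are all numerically zero
#' (the fit is exact); on other panels they quantify transferability.
#'
#' @param model A \code{"tolerance_model"}.
#' @param sti STI table or matrix.
#' @param mean_mfvs Observed mean MFV per germplasm.
#' @return List with \code{mean}, \code{max}, \code{min} absolute
#'   differences and \code{n}.
#' @export
validate_model <- function(model, sti, mean_mfvs) {
  y <- predict_y(model, sti)
  if (!length(y)) .stopf("empty panel")
  if (length(y) != length(mean_mfvs))
    .stopf("panel size mismatch between STI rows and mean MFV values")
  d <- abs(y - mean_mfvs)
  list(mean = mean(d), max = max(d), min = min(d), n = length(d))
}

.validated_matrix <- function(sti, mean_mfvs) {
  m <- .as_trait_matrix(sti)
  if (nrow(m) < 3L) .stopf("need at least 3 germplasms")
  if (anyNA(m) || anyNA(mean_mfvs)) .stopf("missing values in correlation input")
  x <- cbind(m, mean_MFV = mean_mfvs)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    .stopf("zero-variance column(s): %s",
           paste(colnames(x)[sds == 0], collapse = ", "))
  x
}

#' Pearson correlation matrix of STIs and mean MFV
#'
#' The 8 x 8 matrix of pairwise Pearson correlations among the seven
#' salt-tolerance indices and the mean MFV (last row/column).
#'
#' @inheritParams validate_model
#' @return 8 x 8 symmetric correlation matrix.
#' @export
correlation_matrix <- function(sti, mean_mfvs) {
  stats::cor(.validated_matrix(sti, mean_mfvs))
}

#' Per-trait coefficient of determination
#'
#' R-squared of the simple least-squares line of mean MFV on each STI;
#' identical to the squared Pearson correlation with mean MFV. Identifies
#' the single traits most predictive of overall tolerance.
#'
#' @inheritParams validate_model
#' @return Named numeric vector, one R-squared per trait.
#' @export
per_trait_r2 <- function(sti, mean_mfvs) {
  x <- .validated_matrix(sti, mean_mfvs)
  r <- stats::cor(x[, .TRAITS, drop = FALSE], x[, "mean_MFV"])
  setNames(drop(r)^2, .TRAITS)
}

#' Standardized coefficients of a fitted model
#'
#' beta_i * sd(STI_i) / sd(mean MFV): the coefficients the fit would have on
#' z-scored columns, comparable across traits.
#'
#' @param model A \code{"tolerance_model"}.
#' @inheritParams validate_model
#' @return Named numeric vector of standardized coefficients.
#' @export
standardized_coefficients <- function(model, sti, mean_mfvs) {
  stopifnot(inherits(model, "tolerance_model"))
  x <- .validated_matrix(sti, mean_mfvs)
  sds <- apply(x, 2, stats::sd)
  model$coefficients * sds[.TRAITS] / sds["mean_MFV"]
}

#' The published sunflower tolerance model
#'
#' The reference regression fitted on the 552-line sunflower panel screened
#' at 300 mM NaCl: Y = 0.143 STI_GR + 0.146 STI_GI + 0.152 STI_GE +
#' 0.213 STI_RL + 0.369 STI_GVI + 0.119 STI_FW + 0.088 STI_WC, intercept
#' -3.33e-16 (numerically zero because every trait's panel-minimum STI was
#' 0). Pair it with \code{\link{published_grade_scheme}} to grade new
#' sunflower germplasms.
#'
#' @return A \code{"tolerance_model"}.
#' @export
#' @examples
#' published_model()
published_model <- function() {
  tolerance_model(
    c(GR = 0.143, GI = 0.146, GE = 0.152, RL = 0.213,
      GVI = 0.369, FW = 0.119, WC = 0.088),
    intercept = -3.33e-16, fitted_on = 552L)
}
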