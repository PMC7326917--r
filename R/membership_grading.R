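#' Per-trait STI extremes across a panel
#'
#' The minimum and maximum salt-tolerance index observed for each trait
#' across all germplasms in the panel, over present (including zero-filled)
#' values. These extremes anchor the membership-function normalization.
#'
#' @param sti STI table (\code{\link{sti_table}}) or a germplasm x 7 matrix
#'   in \code{\link{trait_names}} order.
#' @return Data frame with columns trait, min, max.
#' @export
panel_extremes <- function(sti) {
  m <- .as_trait_matrix(sti)
  if (nrow(m) < 2L) .stopf("panel extremes need at least 2 germplasms")
  out <- data.frame(trait = .TRAITS, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(.TRAITS)) {
    x <- m[, i]
    x <- x[!is.na(x)]
    if (!length(x)) .stopf("trait %s has no present STI values", .TRAITS[i])
    out$min[i] <- min(x)
    out$max[i] <- max(x)
  }
  out
}

#' Membership-function value
#'
#' Min-max normalization of one STI value against the panel extremes of its
#' trait: (x - min) / (max - min), stored as a fraction in \[0, 1\].
#'
#' @param x STI value, within \[min, max\].
#' @param min,max Panel extremes for the trait, max > min.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' mfv(0.5, min = 0.2, max = 0.8)
mfv <- function(x, min, max) {
  if (max <= min)
    .stopf("degenerate trait: max (%g) must exceed min (%g) for membership normalization",
           max, min)
  if (any(x < min - 1e-12) || any(x > max + 1e-12))
    .stopf("STI value outside the panel extremes [%g, %g]", min, max)
  pmin(1, pmax(0, (x - min) / (max - min)))
}

#' Membership table for a panel
#'
#' Normalizes every STI to its membership-function value and appends the
#' unweighted mean over the seven traits (mean MFV), the panel's composite
#' tolerance score. All seven MFVs must be present for a germplasm; the
#' \code{zero_fill} policy upstream guarantees this.
#'
#' @param sti STI table from \code{\link{sti_table}}.
#' @param extremes Optional \code{\link{panel_extremes}} result; computed
#'   from \code{sti} when omitted (normalizing against a reference panel's
#'   extremes is possible by passing them explicitly).
#' @return Data frame: germplasm, \code{MFV_*} columns, \code{mean_MFV}.
#' @export
membership_table <- function(sti, extremes = NULL) {
  m <- .sti_matrix(sti)
  if (anyNA(m))
    .stopf("missing STI values reach the membership stage; use the zero_fill policy or drop incomplete germplasms")
  if (is.null(extremes)) extremes <- panel_extremes(m)
  out <- data.frame(germplasm = sti$germplasm, stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, nrow(m), 7L)
  for (i in seq_along(.TRAITS))
    vals[, i] <- mfv(m[, i], extremes$min[i], extremes$max[i])
  colnames(vals) <- paste0("MFV_", .TRAITS)
  out <- cbind(out, as.data.frame(vals))
  out$mean_MFV <- rowMeans(vals)
  out
}

#' Mean membership-function value
#'
#' Unweighted arithmetic mean of the seven per-trait MFVs.
#'
#' @param mfvs Numeric vector of 7 membership values in trait order.
#' @return The mean, in \[0, 1\].
#' @export
#' @examples
#' mean_mfv(c(0.936, 0.856, 0.719, 0.343, 0.488, 0.905, 0.758))
mean_mfv <- function(mfvs) {
  if (length(mfvs) != 7L || anyNA(mfvs))
    .stopf("mean MFV needs all seven trait membership values")
  mean(mfvs)
}

.new_grade_scheme <- function(mean, sd, cuts) {
  structure(list(mean = mean, sd = sd,
                 cuts = setNames(cuts, c("HST", "ST", "MST", "SS")),
                 grades = .GRADES),
            class = "grade_scheme")
}

#' Five-grade tolerance scheme from a panel
#'
#' Derives the grade cut points from the panel's mean MFV distribution:
#' grades split at mean + 1.64 SD, mean + 1 SD, mean - 1 SD and
#' mean - 1.64 SD, giving HST / ST / MST / SS / HSS. Under an approximately
#' normal score distribution the tails place about 5\% of lines in each of
#' HST and HSS.
#'
#' @param mean_mfvs Mean-MFV values of all panel germplasms (>= 2).
#' @param sd_type \code{"sample"} (n - 1 denominator, default) or
#'   \code{"population"}.
#' @return A \code{"grade_scheme"}: mean, sd, the four cuts (named by the
#'   grade whose lower bound they are), and the grade labels.
#' @export
grade_scheme <- function(mean_mfvs, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(mean_mfvs) < 2L) .stopf("a grade scheme needs at least 2 germplasms")
  m <- mean(mean_mfvs)
  s <- stats::sd(mean_mfvs)
  if (sd_type == "population")
    s <- s * sqrt((length(mean_mfvs) - 1) / length(mean_mfvs))
  if (!is.finite(s) || s == 0)
    .stopf("mean MFV has zero spread; grading cannot discriminate")
  .new_grade_scheme(m, s, m + c(1.64, 1, -1, -1.64) * s)
}

#' Grade scheme from stated mean and SD
#'
#' @param mean,sd Panel mean and standard deviation of mean MFV.
#' @return A \code{"grade_scheme"}.
#' @export
grade_scheme_from_stats <- function(mean, sd) {
  if (sd <= 0) .stopf("sd must be positive")
  .new_grade_scheme(mean, sd, mean + c(1.64, 1, -1, -1.64) * sd)
}

#' The published sunflower grade scheme
#'
#' Cut points established on the reference panel of 552 sunflower inbred
#' lines screened at 300 mM NaCl: HST at mean MFV >= 0.5216, ST >= 0.4302,
#' MST >= 0.1446, SS >= 0.0532, HSS below. Use it to grade new germplasms
#' by their Y score without re-normalizing a full panel.
#'
#' @return A \code{"grade_scheme"} with the published cuts.
#' @export
#' @examples
#' classify(0.715, published_grade_scheme())
published_grade_scheme <- function() {
  structure(list(mean = 0.287, sd = 0.143,
                 cuts = c(HST = 0.5216, ST = 0.4302, MST = 0.1446, SS = 0.0532),
                 grades = .GRADES),
            class = "grade_scheme")
}

#' @export
print.grade_scheme <- function(x, ...) {
  cat("Five-grade salt-tolerance scheme (mean MFV or Y)\n")
  cat(sprintf("  panel mean %.4f, SD %.4f\n", x$mean, x$sd))
  cat(sprintf("  HST >= %.4f > ST >= %.4f > MST >= %.4f > SS >= %.4f > HSS\n",
              x$cuts[1], x$cuts[2], x$cuts[3], x$cuts[4]))
  invisible(x)
}

#' Classify tolerance scores into the five grades
#'
#' Assigns HST / ST / MST / SS / HSS by comparing a mean MFV (or Y score)
#' against the scheme's cut points; each grade's lower bound is inclusive.
#'
#' @param value Numeric vector of mean MFV or Y scores.
#' @param scheme A \code{"grade_scheme"}.
#' @return Factor with levels HST, ST, MST, SS, HSS.
#' @export
classify <- function(value, scheme) {
  stopifnot(inherits(scheme, "grade_scheme"))
  if (any(!is.finite(value))) .stopf("scores must be finite")
  idx <- 5L - findInterval(value, rev(scheme$cuts))  # lower bounds inclusive
  factor(.GRADES[idx], levels = .GRADES)
}
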