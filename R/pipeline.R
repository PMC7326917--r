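#' Evaluate a germplasm panel end to end
#'
#' Runs the full screening pipeline: traits per condition, salt-tolerance
#' indices, membership normalization across the panel, mean MFV, the
#' five-grade classification, and (optionally) the linear Y score.
#'
#' @param germination Germination counts (\code{\link{read_germination_csv}}).
#' @param endpoints Endpoint measures (\code{\link{read_endpoint_csv}}), or
#'   \code{NULL}.
#' @param config A \code{\link{panel_config}}.
#' @param scheme \code{"panel"} derives grade cuts from this panel's mean
#'   MFV distribution; \code{"published"} uses the published sunflower
#'   cuts; or pass a \code{"grade_scheme"} object.
#' @param model \code{NULL} (no Y column), \code{"fit"} (fit the tolerance
#'   model on this panel and predict Y), \code{"published"}, or a
#'   \code{"tolerance_model"}.
#' @return A list of class \code{"panel_evaluation"}: \code{evaluation}
#'   (per-germplasm data frame with STI, MFV, mean MFV, grade, Y),
#'   \code{traits}, \code{extremes}, \code{scheme} and \code{model}
#'   (\code{NULL} unless fitted or supplied).
#' @export
evaluate_panel <- function(germination, endpoints = NULL,
                           config = panel_config(),
                           scheme = c("panel", "published"),
                           model = NULL) {
  traits <- compute_traits(germination, endpoints)
  stis <- sti_table(traits, config)
  extremes <- panel_extremes(stis)
  memb <- membership_table(stis, extremes)

  if (inherits(scheme, "grade_scheme")) sch <- scheme
  else {
    scheme <- match.arg(scheme)
    sch <- if (scheme == "published") published_grade_scheme()
    else grade_scheme(memb$mean_MFV)
  }

  mdl <- NULL
  if (!is.null(model)) {
    mdl <- if (inherits(model, "tolerance_model")) model
    else if (identical(model, "published")) published_model()
    else if (identical(model, "fit")) fit_tolerance_model(stis, memb$mean_MFV)
    else .stopf("model must be NULL, \"fit\", \"published\" or a tolerance_model")
  }

  ev <- merge(stis[c("germplasm", paste0("STI_", .TRAITS))], memb,
              by = "germplasm", sort = TRUE)
  ev$grade <- classify(ev$mean_MFV, sch)
  if (!is.null(mdl)) ev$Y <- predict_y(mdl, ev)
  names(ev)[names(ev) == "mean_MFV"] <- "mean_MFV"  # fixed order below
  ev <- ev[c("germplasm", paste0("STI_", .TRAITS), paste0("MFV_", .TRAITS),
             "mean_MFV", "grade", if (!is.null(mdl)) "Y")]
  structure(list(evaluation = ev, traits = traits, sti = stis,
                 extremes = extremes, scheme = sch, model = mdl),
            class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  n <- nrow(x$evaluation)
  cat(sprintf("Salt-tolerance evaluation of %d germplasms\n", n))
  print(table(x$evaluation$grade))
  cat(sprintf("mean MFV: %.3f to %.3f (panel mean %.3f, SD %.3f)\n",
              min(x$evaluation$mean_MFV), max(x$evaluation$mean_MFV),
              mean(x$evaluation$mean_MFV), stats::sd(x$evaluation$mean_MFV)))
  invisible(x)
}
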