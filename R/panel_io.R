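#' germscreen: germination-stage salt-tolerance screening
#'
#' Pipeline from raw daily germination counts and seedling endpoint
#' measurements to salt-tolerance indices (STI), membership-function values
#' (MFV), a five-grade tolerance classification, and a linear tolerance
#' score (Y), plus a synthetic germplasm-panel generator for validation.
#'
#' @section Typical workflow:
#' \enumerate{
#'   \item \code{\link{read_germination_csv}}, \code{\link{read_endpoint_csv}}
#'   \item \code{\link{compute_traits}} per germplasm and condition
#'   \item \code{\link{sti_table}} salt/control ratios
#'   \item \code{\link{membership_table}}, \code{\link{grade_scheme}},
#'         \code{\link{classify}}
#'   \item \code{\link{fit_tolerance_model}} / \code{\link{published_model}},
#'         \code{\link{predict_y}}
#'   \item or all at once: \code{\link{evaluate_panel}}
#' }
#' @name germscreen-package
#' @keywords internal
"_PACKAGE"

# Fixed evaluation-trait order used everywhere downstream:
# germination rate, germination index, germination energy, root length,
# germination vigor index, fresh weight, water content.
.TRAITS <- c("GR", "GI", "GE", "RL", "GVI", "FW", "WC")
.CONDITIONS <- c("control", "salt")
.GRADES <- c("HST", "ST", "MST", "SS", "HSS")

#' Fixed trait order of the evaluation
#'
#' The seven traits evaluated per germplasm, in the canonical order used in
#' all tables, matrices and model coefficient vectors: GR (germination
#' rate), GI (germination index), GE (germination energy), RL (root length,
#' cm), GVI (germination vigor index), FW (fresh weight, g), WC (water
#' content).
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' trait_names()
trait_names <- function() .TRAITS

#' Pipeline configuration
#'
#' @param missing_sti_policy How unmeasurable salt-tolerance indices are
#'   handled before membership normalization. \code{"zero_fill"} (default)
#'   sets them to 0 with a provenance flag, so every germplasm enters the
#'   MFV stage with a complete profile; \code{"exclude_trait"} leaves them
#'   missing.
#' @param count_interpretation Whether \code{cum_germinated} in the
#'   germination CSV holds cumulative counts by day (default) or daily new
#'   germinations, which are converted to cumulative on ingest.
#' @return A list of class \code{"panel_config"}.
#' @export
#' @examples
#' panel_config()
#' panel_config(missing_sti_policy = "exclude_trait")
panel_config <- function(missing_sti_policy = c("zero_fill", "exclude_trait"),
                         count_interpretation = c("cumulative", "daily_new")) {
  cfg <- list(
    missing_sti_policy = match.arg(missing_sti_policy),
    count_interpretation = match.arg(count_interpretation),
    trait_names = .TRAITS
  )
  class(cfg) <- "panel_config"
  cfg
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_condition <- function(x, rows = NULL) {
  bad <- !x %in% .CONDITIONS
  if (any(bad)) {
    where <- if (is.null(rows)) which(bad)[1] else rows[bad][1]
    .stopf("row %d: condition must be one of %s (got '%s')",
           where, paste(.CONDITIONS, collapse = "/"), x[bad][1])
  }
}

#' Read daily germination counts
#'
#' Reads a long-format CSV with columns
#' \code{germplasm,condition,replicate,n_seeds,day,cum_germinated}
#' (condition \code{control} or \code{salt}, day 1..7) and validates it into
#' a germination time-course table: one row per (germplasm, condition,
#' replicate, day), counts cumulative. Every (germplasm, condition,
#' replicate) must contribute exactly days 1 through 7 with non-decreasing
#' counts bounded by \code{n_seeds}.
#'
#' @param path Path to the CSV file.
#' @param count_interpretation \code{"cumulative"} (the file already stores
#'   cumulative counts, the default) or \code{"daily_new"} (the file stores
#'   new germinations per day, summed to cumulative on ingest).
#' @return A validated data frame of class \code{"germination_counts"} with
#'   the columns above, \code{cum_germinated} always cumulative.
#' @export
read_germination_csv <- function(path,
                                 count_interpretation = c("cumulative", "daily_new")) {
  count_interpretation <- match.arg(count_interpretation)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("germplasm", "condition", "replicate", "n_seeds", "day",
            "cum_germinated")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("germination CSV is missing column(s): %s",
           paste(miss, collapse = ", "))
  df <- df[need]
  df$germplasm <- as.character(df$germplasm)
  rows <- seq_len(nrow(df)) + 1L  # header is line 1
  .check_condition(df$condition, rows)
  for (col in c("replicate", "n_seeds", "day", "cum_germinated")) {
    if (any(is.na(df[[col]])))
      .stopf("row %d: missing value in '%s'", rows[which(is.na(df[[col]]))[1]], col)
    if (any(df[[col]] != as.integer(df[[col]])))
      .stopf("row %d: '%s' must be an integer",
             rows[which(df[[col]] != as.integer(df[[col]]))[1]], col)
    df[[col]] <- as.integer(df[[col]])
  }
  if (any(df$day < 1L | df$day > 7L))
    .stopf("row %d: day must be in 1..7", rows[which(df$day < 1L | df$day > 7L)[1]])
  if (any(df$n_seeds < 1L))
    .stopf("row %d: n_seeds must be >= 1", rows[which(df$n_seeds < 1L)[1]])
  if (any(df$replicate < 1L))
    .stopf("row %d: replicate must be >= 1", rows[which(df$replicate < 1L)[1]])
  if (any(df$cum_germinated < 0L))
    .stopf("row %d: negative count", rows[which(df$cum_germinated < 0L)[1]])

  key <- paste(df$germplasm, df$condition, df$replicate, df$day, sep = "\r")
  if (anyDuplicated(key))
    .stopf("row %d: duplicate (germplasm, condition, replicate, day) entry",
           rows[which(duplicated(key))[1]])

  grp <- paste(df$germplasm, df$condition, df$replicate, sep = "\r")
  ord <- order(df$germplasm, df$condition, df$replicate, df$day)
  df <- df[ord, , drop = FALSE]
  rows <- rows[ord]
  grp <- grp[ord]
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sub <- df[idx, ]
    if (!identical(sub$day, 1:7)) {
      gap <- setdiff(1:7, sub$day)
      .stopf("germplasm '%s' %s replicate %d: missing day(s) %s",
             sub$germplasm[1], sub$condition[1], sub$replicate[1],
             paste(gap, collapse = ", "))
    }
    if (length(unique(sub$n_seeds)) > 1L)
      .stopf("germplasm '%s' %s replicate %d: inconsistent n_seeds",
             sub$germplasm[1], sub$condition[1], sub$replicate[1])
    if (count_interpretation == "daily_new")
      df$cum_germinated[idx] <- cumsum(sub$cum_germinated)
    counts <- df$cum_germinated[idx]
    if (any(diff(counts) < 0L))
      .stopf("row %d: decreasing cumulative count for germplasm '%s' %s replicate %d",
             rows[idx][which(diff(counts) < 0L)[1] + 1L],
             sub$germplasm[1], sub$condition[1], sub$replicate[1])
    if (any(counts > sub$n_seeds))
      .stopf("row %d: count exceeds n_seeds for germplasm '%s' %s replicate %d",
             rows[idx][which(counts > sub$n_seeds)[1]],
             sub$germplasm[1], sub$condition[1], sub$replicate[1])
  }
  rownames(df) <- NULL
  class(df) <- c("germination_counts", "data.frame")
  df
}

#' Read seedling endpoint measurements
#'
#' Reads a CSV with columns
#' \code{germplasm,condition,replicate,root_length_cm,fresh_weight_g,dry_weight_g};
#' blank cells become \code{NA} (seedlings that germinated without cotyledon
#' growth have no measurable fresh weight). Negative values and dry weight
#' exceeding fresh weight are rejected.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame of class \code{"endpoint_measures"}.
#' @export
read_endpoint_csv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("germplasm", "condition", "replicate", "root_length_cm",
            "fresh_weight_g", "dry_weight_g")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("endpoint CSV is missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[need]
  df$germplasm <- as.character(df$germplasm)
  rows <- seq_len(nrow(df)) + 1L
  .check_condition(df$condition, rows)
  df$replicate <- as.integer(df$replicate)
  for (col in c("root_length_cm", "fresh_weight_g", "dry_weight_g")) {
    df[[col]] <- as.numeric(df[[col]])
    neg <- !is.na(df[[col]]) & df[[col]] < 0
    if (any(neg)) .stopf("row %d: negative %s", rows[which(neg)[1]], col)
  }
  bad <- !is.na(df$dry_weight_g) & !is.na(df$fresh_weight_g) &
    df$dry_weight_g > df$fresh_weight_g
  if (any(bad))
    .stopf("row %d: dry weight exceeds fresh weight", rows[which(bad)[1]])
  key <- paste(df$germplasm, df$condition, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    .stopf("row %d: duplicate (germplasm, condition, replicate) entry",
           rows[which(duplicated(key))[1]])
  rownames(df) <- NULL
  class(df) <- c("endpoint_measures", "data.frame")
  df
}

#' Write an evaluation table
#'
#' Writes the per-germplasm evaluation (STI, MFV, mean MFV, grade, and Y
#' when present) with a deterministic column order and rows sorted by
#' germplasm id. Values are written at full precision by default; the
#' conventional display rounding for reports is 3 decimals for STI/MFV and
#' 5 for Y, available via \code{digits}.
#'
#' @param evaluation Evaluation data frame as produced by
#'   \code{\link{evaluate_panel}}.
#' @param path Output CSV path.
#' @param digits \code{NULL} (full precision, default) or
#'   \code{"display"} for 3-decimal STI/MFV and 5-decimal Y rounding.
#' @return The path, invisibly.
#' @export
write_evaluation_csv <- function(evaluation, path, digits = NULL) {
  cols <- c("germplasm",
            paste0("STI_", .TRAITS),
            paste0("MFV_", .TRAITS),
            "mean_MFV", "grade")
  if ("Y" %in% names(evaluation)) cols <- c(cols, "Y")
  miss <- setdiff(cols, names(evaluation))
  if (length(miss))
    .stopf("evaluation table is missing column(s): %s", paste(miss, collapse = ", "))
  out <- evaluation[order(evaluation$germplasm), cols, drop = FALSE]
  if (!is.null(digits)) {
    if (!identical(digits, "display"))
      .stopf("digits must be NULL or \"display\"")
    num3 <- c(paste0("STI_", .TRAITS), paste0("MFV_", .TRAITS), "mean_MFV")
    for (col in num3) out[[col]] <- round(out[[col]], 3)
    if ("Y" %in% cols) out$Y <- round(out$Y, 5)
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .stopf("cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' Read back an evaluation table
#'
#' Inverse of \code{\link{write_evaluation_csv}} (full-precision files
#' round-trip exactly).
#'
#' @param path CSV path written by \code{\link{write_evaluation_csv}}.
#' @return Evaluation data frame.
#' @export
read_evaluation_csv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$germplasm <- as.character(df$germplasm)
  df
}

#' Save a tolerance model as JSON
#'
#' Stores coefficients in the fixed trait order at full precision, the
#' intercept, fit metadata, and (optionally) grade-scheme cut points.
#'
#' @param model A \code{"tolerance_model"} (see
#'   \code{\link{fit_tolerance_model}}).
#' @param path Output JSON path.
#' @param scheme Optional \code{"grade_scheme"} stored alongside the model.
#' @return The path, invisibly.
#' @export
write_model_json <- function(model, path, scheme = NULL) {
  stopifnot(inherits(model, "tolerance_model"))
  obj <- list(
    trait_order = .TRAITS,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    fitted_on = model$fitted_on,
    r_squared = model$r_squared
  )
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "grade_scheme"))
    obj$grade_scheme <- list(mean = scheme$mean, sd = scheme$sd,
                             cuts = as.list(scheme$cuts))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a tolerance model from JSON
#'
#' @param path JSON path written by \code{\link{write_model_json}}.
#' @return A list with \code{model} (a \code{"tolerance_model"}) and
#'   \code{scheme} (a \code{"grade_scheme"} or \code{NULL}).
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- tolerance_model(unlist(obj$coefficients)[.TRAITS], obj$intercept,
                           fitted_on = obj$fitted_on,
                           r_squared = obj$r_squared)
  scheme <- NULL
  if (!is.null(obj$grade_scheme))
    scheme <- structure(list(mean = obj$grade_scheme$mean,
                             sd = obj$grade_scheme$sd,
                             cuts = unlist(obj$grade_scheme$cuts),
                             grades = .GRADES),
                        class = "grade_scheme")
  list(model = model, scheme = scheme)
}
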