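#' Salt-tolerance index of one trait
#'
#' STI = V_salt / V_control, the ratio of a trait's value under salt stress
#' to its value under control conditions. 1 means unaffected; values above
#' 1 (trait slightly increased under salt) are legitimate and occur for
#' fresh weight and water content in real panels.
#'
#' @param treatment_value Trait value under salt stress (>= 0 or \code{NA}).
#' @param control_value Trait value under control conditions.
#' @return The ratio, or \code{NA} when either value is missing or the
#'   control is 0 (the ratio is undefined, not an error).
#' @export
#' @examples
#' sti(0.5, 1.0)
#' sti(0, 0.8)
sti <- function(treatment_value, control_value) {
  stopifnot(is.na(treatment_value) || treatment_value >= 0,
            is.na(control_value) || control_value >= 0)
  if (is.na(treatment_value) || is.na(control_value) || control_value == 0)
    return(NA_real_)
  treatment_value / control_value
}

# Flag vocabulary for STI provenance.
.STI_FLAGS <- c("measured", "zero_filled_no_germination",
                "missing_control", "missing_treatment")

#' STI profile for one germplasm
#'
#' Converts a salt/control trait-vector pair into the seven per-trait
#' salt-tolerance indices with provenance flags. When the germplasm did not
#' germinate at all under salt (salt GR = 0 or unmeasurable), the
#' \code{zero_fill} policy sets all seven STIs to 0 — such lines are the
#' panel's most affected and enter the membership stage as ordinary all-zero
#' rows. Traits unmeasurable for other reasons (e.g. germination without
#' cotyledon growth, so no fresh weight) are zero-filled with a flag naming
#' the missing side, or left \code{NA} under \code{exclude_trait}.
#'
#' @param salt One-row trait data frame for the salt treatment
#'   (\code{\link{compute_trait_vector}}).
#' @param control Matching one-row trait data frame for the control.
#' @param config A \code{\link{panel_config}}; only
#'   \code{missing_sti_policy} is used.
#' @return One-row data frame: germplasm, \code{STI_*} columns in trait
#'   order, and \code{flag_*} provenance columns.
#' @export
sti_profile <- function(salt, control, config = panel_config()) {
  stopifnot(nrow(salt) == 1L, nrow(control) == 1L)
  if (salt$germplasm != control$germplasm)
    .stopf("germplasm mismatch: '%s' vs '%s'", salt$germplasm, control$germplasm)
  zero_fill <- config$missing_sti_policy == "zero_fill"

  vals <- setNames(rep(NA_real_, 7L), .TRAITS)
  flags <- setNames(rep("measured", 7L), .TRAITS)
  no_germ <- is.na(salt$GR) || salt$GR == 0
  for (tr in .TRAITS) {
    v_n <- salt[[tr]]
    v_c <- control[[tr]]
    if (no_germ) {
      vals[tr] <- if (zero_fill) 0 else NA_real_
      flags[tr] <- "zero_filled_no_germination"
    } else if (is.na(v_n)) {
      vals[tr] <- if (zero_fill) 0 else NA_real_
      flags[tr] <- "missing_treatment"
    } else if (is.na(v_c) || v_c == 0) {
      vals[tr] <- if (zero_fill) 0 else NA_real_
      flags[tr] <- "missing_control"
    } else {
      vals[tr] <- v_n / v_c
    }
  }
  out <- data.frame(germplasm = salt$germplasm, stringsAsFactors = FALSE)
  for (tr in .TRAITS) out[[paste0("STI_", tr)]] <- vals[[tr]]
  for (tr in .TRAITS) out[[paste0("flag_", tr)]] <- flags[[tr]]
  out
}

#' STI table for a whole panel
#'
#' Pairs each germplasm's salt and control trait rows and applies
#' \code{\link{sti_profile}}. Germplasms lacking either condition are
#' rejected.
#'
#' @param traits Trait table from \code{\link{compute_traits}} holding both
#'   conditions for every germplasm.
#' @param config A \code{\link{panel_config}}.
#' @return Data frame with one row per germplasm (sorted by id), \code{STI_*}
#'   and \code{flag_*} columns.
#' @export
sti_table <- function(traits, config = panel_config()) {
  ids <- sort(unique(traits$germplasm))
  out <- lapply(ids, function(g) {
    sub <- traits[traits$germplasm == g, , drop = FALSE]
    s <- sub[sub$condition == "salt", , drop = FALSE]
    c_ <- sub[sub$condition == "control", , drop = FALSE]
    if (nrow(s) != 1L || nrow(c_) != 1L)
      .stopf("germplasm '%s' must have exactly one salt and one control trait row", g)
    sti_profile(s, c_, config)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.sti_matrix <- function(sti_table) {
  m <- as.matrix(sti_table[paste0("STI_", .TRAITS)])
  rownames(m) <- sti_table$germplasm
  colnames(m) <- .TRAITS
  m
}

# accept STI values as a table (STI_* columns), a matrix named by trait or
# STI_*, an unnamed 7-column matrix, or a named 7-vector
.as_trait_matrix <- function(x) {
  if (is.data.frame(x)) return(.sti_matrix(x))
  if (!is.matrix(x)) {
    if (length(x) != 7L) .stopf("an STI profile has exactly 7 values")
    if (!is.null(names(x))) x <- x[.TRAITS]
    return(matrix(x, nrow = 1, dimnames = list(NULL, .TRAITS)))
  }
  if (!is.null(colnames(x))) {
    if (all(.TRAITS %in% colnames(x))) x <- x[, .TRAITS, drop = FALSE]
    else if (all(paste0("STI_", .TRAITS) %in% colnames(x)))
      x <- x[, paste0("STI_", .TRAITS), drop = FALSE]
    else .stopf("STI matrix must carry the seven trait columns")
  } else if (ncol(x) != 7L) {
    .stopf("an unnamed STI matrix must have 7 columns in trait order")
  }
  colnames(x) <- .TRAITS
  x
}
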