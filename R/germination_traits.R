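#' Germination rate
#'
#' Fraction of sown seeds germinated by day 7: G7 / N.
#'
#' @param counts Cumulative germinated-seed counts for days 1..7.
#' @param n_seeds Total seeds sown (N).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' germination_rate(c(2, 5, 8, 9, 10, 10, 10), 11)
germination_rate <- function(counts, n_seeds) {
  .check_course(counts, n_seeds)
  counts[7] / n_seeds
}

#' Germination energy
#'
#' Fraction of sown seeds germinated by day 1: G1 / N. An early-vigor
#' measure; under strong salt stress it is usually 0.
#'
#' @inheritParams germination_rate
#' @return Fraction in \[0, 1\].
#' @export
germination_energy <- function(counts, n_seeds) {
  .check_course(counts, n_seeds)
  counts[1] / n_seeds
}

#' Germination index
#'
#' Sum over days of the cumulative germinated count divided by the day
#' number: sum(G_t / t) for t = 1..7. Rewards fast germination; the upper
#' bound N * (1 + 1/2 + ... + 1/7) is attained iff all seeds germinate on
#' day 1.
#'
#' @inheritParams germination_rate
#' @return Nonnegative index (seeds/day, summed).
#' @export
#' @examples
#' germination_index(c(2, 5, 8, 9, 10, 10, 10), 11)
germination_index <- function(counts, n_seeds = max(counts)) {
  .check_course(counts, max(n_seeds, 1L))
  sum(counts / seq_len(7L))
}

#' Germination vigor index
#'
#' Germination index scaled by the average seedling fresh weight (AFW) of
#' the same condition: GVI = GI * AFW.
#'
#' @param gi Germination index.
#' @param afw Average fresh weight per seedling (g), or \code{NA}.
#' @return GVI, or \code{NA} when \code{afw} is missing.
#' @export
germination_vigor_index <- function(gi, afw) {
  stopifnot(is.na(gi) || gi >= 0, is.na(afw) || afw >= 0)
  gi * afw
}

#' Seedling water content
#'
#' WC = (FW - DW) / FW, the fraction of seedling fresh mass that is water.
#'
#' @param fw Fresh weight (g).
#' @param dw Dry weight (g); must not exceed \code{fw}.
#' @return Fraction in \[0, 1\]; \code{NA} when \code{fw} is missing or 0.
#' @export
#' @examples
#' water_content(0.50, 0.05)
water_content <- function(fw, dw) {
  if (is.na(fw) || fw == 0 || is.na(dw)) return(NA_real_)
  if (dw > fw) .stopf("dry weight (%g) exceeds fresh weight (%g)", dw, fw)
  if (fw < 0 || dw < 0) .stopf("weights must be nonnegative")
  (fw - dw) / fw
}

.check_course <- function(counts, n_seeds) {
  if (length(counts) != 7L) .stopf("a time course has exactly 7 daily counts")
  if (any(is.na(counts))) .stopf("time course contains missing counts")
  if (any(diff(counts) < 0)) .stopf("decreasing cumulative count")
  if (any(counts < 0) || any(counts > n_seeds))
    .stopf("counts must lie in [0, n_seeds]")
  if (n_seeds < 1) .stopf("n_seeds must be >= 1")
  invisible(TRUE)
}

#' Trait vector for one germplasm under one condition
#'
#' Computes the seven evaluated traits from replicate time courses and
#' endpoint measures. GR/GE/GI are computed per replicate and averaged;
#' RL, FW and DW are averaged over the replicates where they were measured;
#' WC is the ratio of the replicate-mean weights; AFW (mean FW of the same
#' condition) scales GI into GVI. Traits whose inputs are entirely missing
#' come back \code{NA}.
#'
#' @param germination Rows of a \code{"germination_counts"} table for a
#'   single germplasm and condition (>= 1 replicate).
#' @param endpoints Matching rows of an \code{"endpoint_measures"} table
#'   (may be empty).
#' @return One-row data frame: germplasm, condition, n_replicates, and the
#'   seven traits in \code{\link{trait_names}} order.
#' @export
compute_trait_vector <- function(germination, endpoints = NULL) {
  if (nrow(germination) == 0L) .stopf("no germination records supplied")
  if (length(unique(germination$germplasm)) != 1L ||
      length(unique(germination$condition)) != 1L)
    .stopf("mixed germplasm or condition in trait computation")
  gid <- germination$germplasm[1]
  cond <- germination$condition[1]
  if (!is.null(endpoints) && nrow(endpoints)) {
    if (any(endpoints$germplasm != gid) || any(endpoints$condition != cond))
      .stopf("endpoint records do not match germplasm '%s' (%s)", gid, cond)
  }

  reps <- split(germination, germination$replicate)
  per_rep <- vapply(reps, function(sub) {
    sub <- sub[order(sub$day), ]
    counts <- sub$cum_germinated
    n <- sub$n_seeds[1]
    c(GR = germination_rate(counts, n),
      GE = germination_energy(counts, n),
      GI = germination_index(counts, n))
  }, numeric(3))
  gr <- mean(per_rep["GR", ])
  ge <- mean(per_rep["GE", ])
  gi <- mean(per_rep["GI", ])

  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  rl <- fw <- dw <- NA_real_
  if (!is.null(endpoints) && nrow(endpoints)) {
    rl <- mean_or_na(endpoints$root_length_cm)
    fw <- mean_or_na(endpoints$fresh_weight_g)
    dw <- mean_or_na(endpoints$dry_weight_g)
  }
  wc <- if (is.na(fw) || fw == 0 || is.na(dw)) NA_real_ else water_content(fw, dw)
  gvi <- if (is.na(fw)) NA_real_ else germination_vigor_index(gi, fw)

  data.frame(germplasm = gid, condition = cond,
             n_replicates = length(reps),
             GR = gr, GI = gi, GE = ge, RL = rl, GVI = gvi, FW = fw, WC = wc,
             stringsAsFactors = FALSE)
}

#' Trait table for a whole panel
#'
#' Applies \code{\link{compute_trait_vector}} to every (germplasm,
#' condition) present in the germination table.
#'
#' @param germination A \code{"germination_counts"} table
#'   (\code{\link{read_germination_csv}}).
#' @param endpoints An \code{"endpoint_measures"} table
#'   (\code{\link{read_endpoint_csv}}), or \code{NULL}.
#' @return Data frame with one row per (germplasm, condition), sorted by
#'   germplasm then condition.
#' @export
compute_traits <- function(germination, endpoints = NULL) {
  key_g <- paste(germination$germplasm, germination$condition, sep = "\r")
  key_e <- if (!is.null(endpoints) && nrow(endpoints))
    paste(endpoints$germplasm, endpoints$condition, sep = "\r") else character()
  out <- lapply(unique(key_g), function(k) {
    compute_trait_vector(germination[key_g == k, , drop = FALSE],
                         if (length(key_e)) endpoints[key_e == k, , drop = FALSE])
  })
  out <- do.call(rbind, out)
  out <- out[order(out$germplasm, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}
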