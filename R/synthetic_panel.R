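#' Configuration of the synthetic germplasm-panel generator
#'
#' Defines the stochastic model behind \code{\link{generate_panel}}. Each
#' germplasm carries a latent salt tolerance theta in \[0, 1\] drawn from a
#' Beta distribution; theta drives every observable through a single common
#' factor, which reproduces the strong inter-trait correlations real panels
#' show. Per seed, germination is Bernoulli with a condition-dependent
#' probability (near 1 under control, emulating the >99\% viability
#' pre-screen; logistic in theta under salt) and, conditional on
#' germination, the germination day is 1 plus a Poisson-distributed delay;
#' seeds past day 7 are censored as non-germinated. Day-1 germination under
#' salt is further thinned, reflecting the near-total suppression of
#' germination energy under stress. Seedling biomass means respond
#' monotonically to theta under salt, with multiplicative lognormal
#' replicate noise; the dry-mass fraction rises as theta falls (stressed
#' seedlings hold less water). Replicates with no germinated seeds have no
#' measurable endpoints, and lines below \code{cotyledon_theta_min}
#' germinate without cotyledon growth, so their salt fresh and dry weights
#' are unmeasurable.
#'
#' @param n_germplasms Number of germplasm lines.
#' @param n_replicates Biological replicates per condition (default 4).
#' @param n_seeds Seeds sown per replicate (default 11).
#' @param theta_shape1,theta_shape2 Beta shape parameters of the latent
#'   tolerance distribution.
#' @param theta_fixed If non-\code{NULL}, every line gets this theta
#'   (useful for null-stress checks).
#' @param control_germination_prob Per-seed germination probability under
#'   control.
#' @param salt_logit_intercept,salt_logit_slope Per-seed salt germination
#'   probability is \code{plogis(intercept + slope * theta)}.
#' @param control_day_lambda Poisson mean of the germination-day delay
#'   (day = 1 + delay) under control.
#' @param salt_delay_base,salt_delay_slope Salt delay mean is
#'   \code{max(0, base - slope * theta)}: less tolerant lines germinate
#'   later.
#' @param day1_salt_prob_scale Probability that a salt germination drawn on
#'   day 1 actually stays on day 1 (otherwise it slips to day 2).
#' @param rl_control_cm,fw_control_g Control seedling means: root length
#'   (cm) and per-seedling fresh weight (g).
#' @param dry_fraction_control Control dry-mass fraction of fresh weight.
#' @param rl_response_floor,rl_response_slope Salt root-length mean is
#'   control mean times \code{floor + slope * theta}.
#' @param fw_response_floor,fw_response_slope Same for fresh weight; the
#'   default allows slightly > 1 at high theta (fresh weight occasionally
#'   unaffected or increased under salt).
#' @param dry_fraction_salt_slope Salt dry fraction is the control fraction
#'   plus \code{slope * (1 - theta)}.
#' @param cotyledon_theta_min Below this theta, salt-grown seedlings develop
#'   no cotyledons: fresh and dry weight unmeasurable (root length still
#'   measured).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   replicate noise on biomass.
#' @param rng_seed Default seed used by \code{\link{generate_panel}}.
#' @return A validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_germplasms = 200L,
                              n_replicates = 4L,
                              n_seeds = 11L,
                              theta_shape1 = 2,
                              theta_shape2 = 3,
                              theta_fixed = NULL,
                              control_germination_prob = 0.995,
                              salt_logit_intercept = -4,
                              salt_logit_slope = 7,
                              control_day_lambda = 0.4,
                              salt_delay_base = 3.4,
                              salt_delay_slope = 2.8,
                              day1_salt_prob_scale = 0.8,
                              rl_control_cm = 5,
                              fw_control_g = 0.5,
                              dry_fraction_control = 0.10,
                              rl_response_floor = 0.05,
                              rl_response_slope = 0.95,
                              fw_response_floor = 0.02,
                              fw_response_slope = 1.0,
                              dry_fraction_salt_slope = 0.25,
                              cotyledon_theta_min = 0.03,
                              noise_cv = 0.15,
                              rng_seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_germplasms >= 1, n_replicates >= 1, n_seeds >= 1,
              theta_shape1 > 0, theta_shape2 > 0,
              control_germination_prob >= 0, control_germination_prob <= 1,
              day1_salt_prob_scale >= 0, day1_salt_prob_scale <= 1,
              control_day_lambda >= 0, salt_delay_base >= 0,
              dry_fraction_control >= 0, dry_fraction_control < 1,
              noise_cv >= 0)
    if (!is.null(theta_fixed))
      stopifnot(theta_fixed >= 0, theta_fixed <= 1)
  })
  class(cfg) <- "simulation_config"
  cfg
}

# lognormal multiplier with mean 1 and coefficient of variation cv
.log_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# cumulative germination counts for one replicate
.sim_counts <- function(cfg, theta, condition) {
  n <- cfg$n_seeds
  if (condition == "control") {
    p <- cfg$control_germination_prob
    lambda <- cfg$control_day_lambda
  } else {
    p <- stats::plogis(cfg$salt_logit_intercept + cfg$salt_logit_slope * theta)
    lambda <- max(0, cfg$salt_delay_base - cfg$salt_delay_slope * theta)
  }
  germ <- stats::runif(n) < p
  day <- rep(NA_integer_, n)
  k <- sum(germ)
  if (k) {
    d <- 1L + stats::rpois(k, lambda)
    if (condition == "salt" && cfg$day1_salt_prob_scale < 1) {
      slip <- d == 1L & stats::runif(k) >= cfg$day1_salt_prob_scale
      d[slip] <- 2L
    }
    day[germ] <- d
  }
  day[!is.na(day) & day > 7L] <- NA_integer_  # censored past the week
  vapply(1:7, function(t) sum(!is.na(day) & day <= t), integer(1))
}

# replicate endpoint means under one condition given theta
.sim_biomass_means <- function(cfg, theta, condition) {
  if (condition == "control") {
    list(rl = cfg$rl_control_cm, fw = cfg$fw_control_g,
         dry_frac = cfg$dry_fraction_control)
  } else {
    list(rl = cfg$rl_control_cm *
           (cfg$rl_response_floor + cfg$rl_response_slope * theta),
         fw = cfg$fw_control_g *
           (cfg$fw_response_floor + cfg$fw_response_slope * theta),
         dry_frac = min(0.95, cfg$dry_fraction_control +
                          cfg$dry_fraction_salt_slope * (1 - theta)))
  }
}

#' Generate a synthetic germplasm panel
#'
#' Draws a full screening dataset — latent tolerances, daily germination
#' counts and endpoint measurements for both conditions — from the model
#' described in \code{\link{simulation_config}}. Fully reproducible from the
#' seed; the output tables pass the package's CSV validators.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param seed Integer RNG seed (defaults to \code{config$rng_seed}).
#' @return A list of class \code{"synthetic_panel"}: \code{truth}
#'   (germplasm, theta), \code{germination} (long cumulative-count table)
#'   and \code{endpoints}.
#' @export
#' @examples
#' panel <- generate_panel(simulation_config(n_germplasms = 12), seed = 7)
#' head(panel$truth)
generate_panel <- function(config = simulation_config(),
                           seed = config$rng_seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n <- config$n_germplasms
  ids <- sprintf("SG%04d", seq_len(n))
  theta <- if (!is.null(config$theta_fixed)) rep(config$theta_fixed, n)
  else stats::rbeta(n, config$theta_shape1, config$theta_shape2)

  germ <- vector("list", n * 2L * config$n_replicates)
  endp <- vector("list", length(germ))
  k <- 0L
  for (g in seq_len(n)) {
    for (cond in .CONDITIONS) {
      bm <- .sim_biomass_means(config, theta[g], cond)
      for (r in seq_len(config$n_replicates)) {
        k <- k + 1L
        counts <- .sim_counts(config, theta[g], cond)
        germ[[k]] <- data.frame(
          germplasm = ids[g], condition = cond, replicate = r,
          n_seeds = config$n_seeds, day = 1:7, cum_germinated = counts,
          stringsAsFactors = FALSE)
        if (counts[7] == 0L) {
          rl <- fw <- dw <- NA_real_  # nothing germinated: nothing to measure
        } else {
          noise <- .log_noise(2L, config$noise_cv)
          rl <- bm$rl * noise[1]
          fw <- bm$fw * noise[2]
          dw <- fw * bm$dry_frac
          if (cond == "salt" && theta[g] < config$cotyledon_theta_min)
            fw <- dw <- NA_real_  # germinated but no cotyledon growth
        }
        endp[[k]] <- data.frame(
          germplasm = ids[g], condition = cond, replicate = r,
          root_length_cm = rl, fresh_weight_g = fw, dry_weight_g = dw,
          stringsAsFactors = FALSE)
      }
    }
  }
  germination <- do.call(rbind, germ)
  endpoints <- do.call(rbind, endp)
  class(germination) <- c("germination_counts", "data.frame")
  class(endpoints) <- c("endpoint_measures", "data.frame")
  structure(list(truth = data.frame(germplasm = ids, theta = theta,
                                    stringsAsFactors = FALSE),
                 germination = germination, endpoints = endpoints,
                 config = config, seed = seed),
            class = "synthetic_panel")
}

#' Write a synthetic panel to CSV files
#'
#' @param panel A \code{"synthetic_panel"}.
#' @param dir Output directory (created if needed); writes
#'   \code{germination.csv}, \code{endpoints.csv}, \code{truth.csv}.
#' @return The directory, invisibly.
#' @export
write_panel_csv <- function(panel, dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(panel$germination, file.path(dir, "germination.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(panel$endpoints, file.path(dir, "endpoints.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(panel$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Latent-tolerance recovery of the full pipeline
#'
#' End-to-end validation harness: evaluates a synthetic panel (traits, STI,
#' MFV, grading, model fit, Y) and reports the Spearman rank correlation of
#' the known latent tolerance theta with mean MFV and with the fitted Y
#' score. Near-1 values mean the pipeline ranks germplasms by their true
#' tolerance.
#'
#' @param panel A \code{"synthetic_panel"}.
#' @param config A \code{\link{panel_config}} for the evaluation.
#' @return List: \code{spearman_mfv}, \code{spearman_y}, and the full
#'   \code{"panel_evaluation"}.
#' @export
recover_tolerance <- function(panel, config = panel_config()) {
  stopifnot(inherits(panel, "synthetic_panel"))
  res <- evaluate_panel(panel$germination, panel$endpoints, config,
                        scheme = "panel", model = "fit")
  ev <- res$evaluation[match(panel$truth$germplasm, res$evaluation$germplasm), ]
  list(
    spearman_mfv = stats::cor(panel$truth$theta, ev$mean_MFV,
                              method = "spearman"),
    spearman_y = stats::cor(panel$truth$theta, ev$Y, method = "spearman"),
    evaluation = res
  )
}
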