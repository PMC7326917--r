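# Builders for tiny in-memory panels used across the tests.

germ_rows <- function(germplasm, condition, replicate, counts, n_seeds = 11L) {
  data.frame(germplasm = germplasm, condition = condition,
             replicate = replicate, n_seeds = n_seeds, day = 1:7,
             cum_germinated = as.integer(counts), stringsAsFactors = FALSE)
}

endpoint_row <- function(germplasm, condition, replicate,
                         rl = NA_real_, fw = NA_real_, dw = NA_real_) {
  data.frame(germplasm = germplasm, condition = condition,
             replicate = replicate, root_length_cm = rl,
             fresh_weight_g = fw, dry_weight_g = dw,
             stringsAsFactors = FALSE)
}

# a random but valid cumulative 7-day time course
random_course <- function(n_seeds = 11L) {
  day <- sample(c(1:7, NA), n_seeds, replace = TRUE,
                prob = c(rep(0.1, 7), 0.3))
  vapply(1:7, function(t) sum(!is.na(day) & day <= t), integer(1))
}

# small complete two-condition panel (every trait measurable, no salt zeros)
complete_panel <- function(n = 12L, seed = 42L) {
  cfg <- simulation_config(n_germplasms = n, theta_shape1 = 5,
                           theta_shape2 = 2, salt_logit_intercept = 0,
                           salt_logit_slope = 5, noise_cv = 0.1)
  generate_panel(cfg, seed = seed)
}

write_temp_csv <- function(df, na = "") {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = na)
  path
}
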