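test_that("germination rate, energy and index match hand-computed values", {
  counts <- c(2, 5, 8, 9, 10, 10, 10)
  expect_equal(germination_rate(counts, 11), 10 / 11)
  expect_equal(germination_energy(counts, 11), 2 / 11)
  expect_equal(germination_index(counts),
               2 / 1 + 5 / 2 + 8 / 3 + 9 / 4 + 10 / 5 + 10 / 6 + 10 / 7)

  zero <- rep(0, 7)
  expect_equal(germination_rate(zero, 11), 0)
  expect_equal(germination_energy(zero, 11), 0)
  expect_equal(germination_index(zero), 0)

  full <- rep(11, 7)
  expect_equal(germination_rate(full, 11), 1)
  expect_equal(germination_energy(full, 11), 1)
  expect_equal(germination_index(full), 11 * sum(1 / (1:7)))
})

test_that("trait formulas agree with a per-seed brute-force oracle", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    day <- sample(c(1:7, NA), n, replace = TRUE)  # NA = never germinated
    counts <- vapply(1:7, function(t) sum(!is.na(day) & day <= t), integer(1))
    # oracle: iterate seeds and days explicitly
    gr_o <- sum(!is.na(day)) / n
    ge_o <- sum(!is.na(day) & day == 1) / n
    gi_o <- 0
    for (t in 1:7) for (s in seq_len(n))
      if (!is.na(day[s]) && day[s] <= t) gi_o <- gi_o + 1 / t
    expect_equal(germination_rate(counts, n), gr_o)
    expect_equal(germination_energy(counts, n), ge_o)
    expect_equal(germination_index(counts), gi_o)
  }
})

test_that("index bounds and monotonicity hold on random courses", {
  set.seed(7)
  h7 <- sum(1 / (1:7))
  for (i in 1:40) {
    counts <- random_course(11L)
    expect_lte(germination_energy(counts, 11), germination_rate(counts, 11))
    gi <- germination_index(counts)
    expect_gte(gi, 0)
    expect_lte(gi, 11 * h7)
    # bumping any day's cumulative count (keeping validity) never lowers GI
    d <- sample(1:7, 1)
    bumped <- pmax(counts, c(rep(0, d - 1), rep(min(counts[d] + 1, 11), 8 - d)))
    expect_gte(germination_index(bumped), gi)
  }
  expect_equal(germination_index(rep(11, 7)), 11 * h7)  # all germinate day 1
})

test_that("water content and vigor index follow their definitions", {
  expect_equal(water_content(0.50, 0.05), 0.90)
  expect_equal(water_content(0.3, 0.3), 0)
  expect_equal(water_content(0.3, 0), 1)
  expect_true(is.na(water_content(NA, 0.1)))
  expect_error(water_content(0.3, 0.5), "exceeds")

  expect_equal(germination_vigor_index(14.5119, 0.2), 2.90238)
  expect_equal(germination_vigor_index(0, 0.7), 0)
  expect_true(is.na(germination_vigor_index(3, NA)))
})

test_that("trait vectors average per-replicate indices and pool endpoints", {
  g1 <- germ_rows("A", "salt", 1, c(0, 2, 4, 6, 8, 8, 8))
  g2 <- germ_rows("A", "salt", 2, c(1, 3, 5, 6, 6, 7, 8))
  e <- rbind(endpoint_row("A", "salt", 1, rl = 2.0, fw = 0.40, dw = 0.04),
             endpoint_row("A", "salt", 2, rl = 3.0, fw = 0.60, dw = 0.08))
  tv <- compute_trait_vector(rbind(g1, g2), e)

  gr1 <- 8 / 11; gr2 <- 8 / 11
  gi1 <- germination_index(g1$cum_germinated)
  gi2 <- germination_index(g2$cum_germinated)
  expect_equal(tv$GR, mean(c(gr1, gr2)))
  expect_equal(tv$GE, mean(c(0, 1 / 11)))
  expect_equal(tv$GI, mean(c(gi1, gi2)))
  expect_equal(tv$RL, 2.5)
  expect_equal(tv$FW, 0.5)
  # WC from mean weights (ratio of means); GVI = mean GI x AFW
  expect_equal(tv$WC, (0.5 - 0.06) / 0.5)
  expect_equal(tv$GVI, tv$GI * 0.5)

  # two identical replicates equal one (averaging idempotence)
  one <- compute_trait_vector(g1, e[1, ])
  two <- compute_trait_vector(rbind(g1, transform(g1, replicate = 2)),
                              rbind(e[1, ], transform(e[1, ], replicate = 2)))
  expect_equal(two[names(two) != "n_replicates"], one[names(one) != "n_replicates"])
})

test_that("per-replicate averaging equals pooled counts when N is shared", {
  set.seed(11)
  for (i in 1:10) {
    c1 <- random_course(11L); c2 <- random_course(11L)
    g <- rbind(germ_rows("A", "salt", 1, c1), germ_rows("A", "salt", 2, c2))
    tv <- compute_trait_vector(g)
    expect_equal(tv$GR, germination_rate(c1 + c2, 22))
    expect_equal(tv$GI, germination_index(c1 + c2) / 2)
  }
})

test_that("missing endpoints leave biomass traits missing but counts usable", {
  g <- germ_rows("A", "salt", 1, c(0, 1, 2, 3, 3, 3, 3))
  tv <- compute_trait_vector(g, endpoint_row("A", "salt", 1, rl = 0.8))
  expect_false(anyNA(tv[c("GR", "GI", "GE", "RL")]))
  expect_true(all(is.na(tv[c("FW", "WC", "GVI")])))

  expect_error(compute_trait_vector(rbind(g, germ_rows("B", "salt", 1, rep(0, 7)))),
               "mixed germplasm")
  expect_error(compute_trait_vector(g, endpoint_row("A", "control", 1, rl = 1)),
               "do not match")
})
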