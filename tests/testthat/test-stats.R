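# Welch t, Holm-Sidak, chi-square GOF, group summaries.

test_that("welch_t matches the textbook oracle to 1e-10", {
  got <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(got$t, -1.5491933, tolerance = 1e-6)
  expect_equal(got$df, 2.9411765, tolerance = 1e-6)
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(sample(3:15, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:15, 1), mean = runif(1, -2, 2))
    got <- welch_t(a, b)
    want <- oracle_welch(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("welch_t handles degenerate inputs as specified", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  # large shift at n = 20: decisive significance
  set.seed(9)
  a <- rnorm(20); b <- rnorm(20) + 5
  expect_lt(welch_t(a, b)$p, 1e-4)
})

test_that("holm_sidak step-down matches its definition", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04),
               tolerance = 1e-12)
  expect_equal(holm_sidak(0.5), 0.5)
  expect_equal(holm_sidak(rep(0.02, 4)), rep(1 - 0.98^4, 4),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    adj <- holm_sidak(p)
    expect_equal(adj, oracle_holm_sidak(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))           # never below raw
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone step-down
  }
  expect_error(holm_sidak(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("chi-square GOF reproduces the birth-ratio test", {
  # 41% vs 59% of 1560 births against the Mendelian 50:50
  r <- chi_square_gof(c(640, 920), c(0.5, 0.5))
  expect_equal(r$chi_sq, 2 * 140^2 / 780, tolerance = 1e-10)
  expect_equal(r$df, 1)
  expect_lt(r$p, 1e-4)
  exact <- chi_square_gof(c(25, 25), c(0.5, 0.5))
  expect_equal(exact$chi_sq, 0)
  expect_equal(exact$p, 1)
  expect_equal(chi_square_gof(c(10, 0), c(0.5, 0.5))$chi_sq, 10)
  expect_error(chi_square_gof(c(5, 5), c(0.7, 0.2)), "sum to 1")
  expect_error(chi_square_gof(c(5, 5), c(1, 0)), "zero expected")
  # k = 2 equals the squared one-sample proportion z statistic
  set.seed(1)
  for (i in 1:10) {
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    p0 <- runif(1, 0.2, 0.8)
    z <- (n1 / (n1 + n2) - p0) / sqrt(p0 * (1 - p0) / (n1 + n2))
    expect_equal(chi_square_gof(c(n1, n2), c(p0, 1 - p0))$chi_sq, z^2,
                 tolerance = 1e-10)
  }
})

test_that("significance stars use strict open bands", {
  expect_identical(significance_stars(c(0.2, 0.03, 0.005, 5e-4, 5e-5)),
                   c("ns", "*", "**", "***", "****"))
  # boundary values fall to the weaker band
  expect_identical(significance_stars(c(0.05, 0.01, 0.001, 0.0001)),
                   c("ns", "*", "**", "***"))
})

test_that("summarize_groups builds per-cell Welch comparisons", {
  st <- generate_study(n_per_group = 10,
                       effects = list(skull_volume = c(-3, -3),
                                      kyphosis_index = c(-2, 0)),
                       seed = 21)
  sg <- summarize_groups(st)
  expect_equal(nrow(sg), 4L)
  expect_true(all(c("mean_wt", "sem_wt", "t_stat", "df_welch", "p_value",
                    "stars") %in% names(sg)))
  # SEM definition
  wt <- st$value[st$genotype == "WT" & st$measurement_name == "skull_volume"
                 & st$age_weeks == 3]
  expect_equal(sg$sem_wt[sg$measurement_name == "skull_volume" &
                           sg$age_weeks == 3],
               sd(wt) / sqrt(length(wt)))
  # a 3 SD shift at n = 10 is reliably starred
  expect_true(all(sg$stars[sg$measurement_name == "skull_volume"] != "ns"))
})

test_that("summarize_groups warns and skips degenerate cells", {
  df <- data.frame(animal_id = sprintf("a%d", 1:5),
                   genotype = c("WT", "WT", "WT", "WT", "Ach"),
                   sex = "M", age_weeks = 3, measurement_name = "x",
                   value = c(1, 2, 3, 4, 5))
  w <- capture_warnings(sg <- summarize_groups(study_table(df)))
  expect_true(any(grepl("n < 2", w)))
  expect_equal(nrow(sg), 0L)
})

test_that("timeline measurements get Holm-Sidak adjustment across ages", {
  st <- generate_study(n_per_group = 8,
                       effects = list(body_weight = rep(-1, 6)),
                       ages = c(1, 2, 3, 4, 5, 6), seed = 13)
  sg <- summarize_groups(st, adjust_measurements = "body_weight")
  expect_equal(sg$p_adjusted, holm_sidak(sg$p_value), tolerance = 1e-12)
  expect_true(all(sg$p_adjusted >= sg$p_value - 1e-15))
  sg2 <- summarize_groups(st)
  expect_equal(sg2$p_adjusted, sg2$p_value)
})
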