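test_that("two-sample-means sample size reproduces the worked example", {
  # sigma 5, delta 3, rounded quantiles: 2*25*(2.8)^2/9 = 43.56 -> 44
  res <- sample_size_per_group(5, 3, z_alpha = 1.96, z_beta = 0.84)
  expect_equal(res$n, 44L)
  expect_equal(res$n_raw, 50 * 7.84 / 9)
  # exact quantiles give the same ceiling
  expect_equal(sample_size_per_group(5, 3, alpha = 0.05, power = 0.8)$n, 44L)
  # delta = sigma: ceil(2 * (1.96 + 0.8416)^2) = 16
  expect_equal(sample_size_per_group(1, 1)$n, 16L)
  # very large effect floors at 1
  expect_equal(sample_size_per_group(1, 100)$n, 1L)
  expect_error(sample_size_per_group(5, 0), "delta")
})

test_that("sample size is monotone in delta, sigma and power", {
  n_of <- function(delta = 3, sigma = 5, power = 0.8)
    sample_size_per_group(sigma, delta, power = power)$n_raw
  expect_true(all(diff(vapply(c(1, 2, 3, 5), function(d) n_of(delta = d),
                              numeric(1))) < 0))
  expect_true(all(diff(vapply(c(2, 4, 6, 8), function(s) n_of(sigma = s),
                              numeric(1))) > 0))
  expect_true(all(diff(vapply(c(0.5, 0.8, 0.9), function(p) n_of(power = p),
                              numeric(1))) > 0))
})

test_that("enrollment arithmetic: dropout inflation and fixed per-stratum targets", {
  plan <- inflate_for_design(44, 0.15, n_strata = 4, per_stratum_target = 50)
  expect_equal(plan$total_enrollment, 400)
  expect_equal(plan$n_inflated, 52L)       # ceil(44 / 0.85)
  expect_equal(inflate_for_design(44, 0)$n_inflated, 44L)
  expect_error(inflate_for_design(44, 1), "dropout")
})

test_that("GOLD grading applies the FEV1 thresholds with boundary and override rules", {
  expect_equal(as.character(gold_grade(48.3)), "III")
  expect_equal(as.character(gold_grade(80)), "I")     # boundary inclusive
  expect_equal(as.character(gold_grade(25)), "IV")
  expect_equal(as.character(gold_grade(50)), "II")
  expect_equal(as.character(gold_grade(30)), "III")
  expect_equal(as.character(gold_grade(85, respiratory_failure = TRUE)), "IV")
  expect_error(gold_grade(0), "FEV1")
  expect_error(gold_grade(250), "FEV1")
  # exact partition of (0, 200)
  x <- seq(0.5, 199.5, by = 0.5)
  g <- gold_grade(x)
  expect_false(any(is.na(g)))
  expect_equal(sum(table(g)), length(x))
})

test_that("stratified randomization is balanced, seeded and handles odd strata", {
  arm <- stratified_randomize(rep("I", 48), seed = 10)
  expect_equal(unname(table(arm)), c(24L, 24L), ignore_attr = TRUE)

  strata <- rep(c("I", "II", "III", "IV"), c(48, 106, 156, 90))
  a1 <- stratified_randomize(strata, seed = 20)
  a2 <- stratified_randomize(strata, seed = 20)
  expect_identical(a1, a2)
  tab <- table(strata, a1)
  expect_true(all(tab[, 1] == tab[, 2]))   # perfect 1:1 in even strata

  odd <- stratified_randomize(rep("x", 5), seed = 1)
  expect_equal(attr(odd, "odd_strata"), "x")
  expect_lte(abs(diff(table(odd))), 1)
  expect_error(stratified_randomize(character()), "subjects")
})

test_that("BH adjustment matches hand evaluation and the brute-force oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # brute force: q_i = min over j with p_j >= p_i of m p_(j) / rank(j), clipped
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ranked <- m * p[o] / seq_len(m)
    q <- numeric(m)
    for (i in seq_len(m)) q[o[i]] <- min(1, min(ranked[i:m]))
    q
  }
  set.seed(77)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # and against the independent standard implementation
  set.seed(78)
  for (i in 1:50) {
    p <- stats::runif(12)
    expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
})

test_that("correlation matrix recovers a generator-specified association", {
  coh <- simulate_correlated_cohort(n = 500, r = -0.6, seed = 31)
  cm <- correlation_matrix(coh$imaging, coh$functional)
  cell <- cm[cm$imaging == "biomarker" & cm$functional == "outcome", ]
  expect_lt(abs(cell$r - (-0.6)), 0.08)
  expect_lt(cell$q, 0.001)
  # independent columns stay near zero
  null_cell <- cm[cm$imaging == "noise_img" & cm$functional == "noise_fun", ]
  expect_lt(abs(null_cell$r), 0.15)
})

test_that("correlation matrix flags constant columns and self-correlation is 1", {
  df <- data.frame(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2))
  cm <- correlation_matrix(df, data.frame(a2 = c(1, 2, 3, 4)))
  expect_equal(cm$r[cm$imaging == "a"], 1)
  expect_equal(cm$flag[cm$imaging == "b"], "constant_column")
  expect_true(is.na(cm$r[cm$imaging == "b"]))
  # spearman route works on monotone data
  cs <- correlation_matrix(data.frame(x = c(1, 10, 100, 1000)),
                           data.frame(y = c(1, 2, 3, 4)), method = "spearman")
  expect_equal(cs$r, 1)
})
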