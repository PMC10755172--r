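test_that("noiseless balanced data give BLUEs equal to line means", {
  rec <- data.frame(line = rep(c("L1", "L2", "L3"), each = 2),
                    rep = rep(1:2, 3), hue = rep(c(30, 33, 36), each = 2))
  bl <- suppressWarnings(fit_line_blues(rec))
  expect_equal(unname(bl$blues[c("L1", "L2", "L3")]), c(30, 33, 36),
               tolerance = 1e-8)
  expect_lt(bl$avsed, 1e-6)
})

test_that("BLUEs are translation equivariant", {
  sim <- simulate_line_records(n_lines = 60, sigma_g2 = 4, sigma_rep2 = 0.5,
                               sigma_e2 = 1, seed = 8)
  a <- fit_line_blues(sim$records)
  shifted <- sim$records
  shifted$hue <- shifted$hue - 5
  b <- fit_line_blues(shifted)
  expect_equal(unname(a$blues - b$blues), rep(5, length(a$blues)),
               tolerance = 1e-6)
  expect_equal(a$sigma_e2, b$sigma_e2, tolerance = 1e-6)
  expect_equal(a$avsed, b$avsed, tolerance = 1e-6)
})

test_that("REML recovers the line variance component", {
  est <- vapply(seq_len(60), function(i) {
    sim <- simulate_line_records(n_lines = 200, sigma_g2 = 4, sigma_rep2 = 1,
                                 sigma_e2 = 1, prop_two_rep = 1, seed = 500 + i)
    fit_line_blues(sim$records)$sigma_g2
  }, numeric(1))
  expect_lt(abs(mean(est) - 4), 0.4)  # within 10% of the truth
})

test_that("single-replicate data degenerate to flagged line means", {
  rec <- data.frame(line = c("L1", "L1", "L2"), rep = 1, hue = c(30, 32, 35))
  expect_warning(bl <- fit_line_blues(rec), "one replicate")
  expect_true(bl$degenerate)
  expect_equal(unname(bl$blues["L1"]), 31)
})

test_that("Cullis heritability follows its closed form", {
  expect_equal(cullis_h2(2, 0)$h2, 1)
  expect_equal(cullis_h2(1, 1)$h2, 0.5)
  expect_error(cullis_h2(0, 1), "undefined")
  # strictly decreasing in avsed at fixed sigma_g2
  h <- vapply(seq(0, 2, by = 0.25), function(a) cullis_h2(2, a)$h2, numeric(1))
  expect_true(all(diff(h) < 0))
})

test_that("Tukey letters separate what should separate and share otherwise", {
  set.seed(19)
  far <- tukey_groups(c(rnorm(40, 0), rnorm(40, 10)),
                      rep(c("a", "b"), each = 40))
  expect_false(far$letters["a"] == far$letters["b"])

  three <- tukey_groups(c(rnorm(50, 0), rnorm(50, 0), rnorm(50, 5)),
                        rep(c("a", "b", "c"), each = 50))
  expect_equal(three$letters[["a"]], three$letters[["b"]])
  expect_false(three$letters[["c"]] %in% three$letters[c("a", "b")])

  expect_warning(tukey_groups(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "size 1")
})

test_that("Tukey family-wise error is near nominal under the null", {
  set.seed(31)
  share <- vapply(seq_len(300), function(i) {
    g <- rep(c("a", "b"), each = 30)
    tg <- tukey_groups(rnorm(60), g)
    tg$letters[["a"]] == tg$letters[["b"]]
  }, logical(1))
  expect_lt(abs(mean(share) - 0.95), 0.035)
})

test_that("Spearman validation behaves at its extremes and under the null", {
  sv <- spearman_validation(c(40, 38, 36, 34, 32), c(1, 2, 3, 4, 5))
  expect_equal(sv$rho, -1)
  set.seed(5)
  null <- spearman_validation(rnorm(1000), sample(1:5, 1000, replace = TRUE))
  expect_lt(abs(null$rho), 0.1)
  expect_error(spearman_validation(rnorm(10), rep(3, 10)), "constant")
})
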