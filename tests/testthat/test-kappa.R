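test_that("Fleiss kappa is 1 under perfect agreement across mixed subjects", {
  tab <- rbind(c("A", "A", "A"), c("B", "B", "B"), c("A", "A", "A"))
  res <- fleissKappa(tab)
  expect_equal(res@kappa, 1)
  expect_identical(res@category, "almost perfect")
})

test_that("Fleiss kappa matches the hand-computed worked example exactly", {
  tab <- rbind(c("A", "A", "B"), c("A", "B", "B"), c("A", "A", "A"))
  # by hand: Pbar = 5/9 and Pe = (2/3)^2 + (1/3)^2 = 5/9, so kappa = 0
  res <- fleissKappa(tab)
  expect_equal(res@kappa, 0, tolerance = 1e-12)
  expect_equal(res@kappa, fleissOracle(tab), tolerance = 1e-12)
  # pairwise-counting oracle agrees on random tables too
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(sample(letters[1:3], 40 * 4, replace = TRUE), 40, 4)
    expect_equal(fleissKappa(m)@kappa, fleissOracle(m), tolerance = 1e-12)
  }
})

test_that("Fleiss kappa is near zero under rating independence", {
  set.seed(123)
  m <- matrix(sample(c("A", "B", "C"), 1000 * 5, replace = TRUE), 1000, 5)
  expect_lt(abs(fleissKappa(m)@kappa), 0.05)
})

test_that("Fleiss kappa is invariant to category relabeling", {
  set.seed(9)
  m <- matrix(sample(c("A", "B", "C"), 60 * 3, replace = TRUE), 60, 3)
  relab <- matrix(c(A = "z", B = "q", C = "m")[m], nrow(m), ncol(m))
  expect_equal(fleissKappa(m)@kappa, fleissKappa(relab)@kappa,
               tolerance = 1e-12)
})

test_that("degenerate rating tables are rejected", {
  expect_error(fleissKappa(matrix("A", 5, 3)), "undefined kappa")
  expect_error(fleissKappa(matrix("A", 1, 3)), "2 subjects")
  expect_error(fleissKappa(matrix(c("A", NA, "B", "B"), 2, 2)), "missing")
})

test_that("weighted kappa handles identity, worked example and independence", {
  expect_equal(weightedKappa(c(1, 2, 3, 2), c(1, 2, 3, 2))@kappa, 1)
  # hand-computed: a = (1,2,3,3), b = (1,2,3,2), linear weights -> 5/7
  wk <- weightedKappa(c(1, 2, 3, 3), c(1, 2, 3, 2), categories = 1:3,
                      scheme = "linear")
  expect_equal(wk@kappa, 5 / 7, tolerance = 1e-12)
  expect_equal(wk@kappa,
               weightedKappaOracle(c(1, 2, 3, 3), c(1, 2, 3, 2), 1:3,
                                   "linear"),
               tolerance = 1e-12)
  set.seed(31)
  a <- sample(1:4, 1000, replace = TRUE)
  b <- sample(1:4, 1000, replace = TRUE)
  expect_lt(abs(weightedKappa(a, b, scheme = "quadratic")@kappa), 0.05)
  expect_equal(weightedKappa(a, b, scheme = "linear")@kappa,
               weightedKappaOracle(a, b, 1:4, "linear"), tolerance = 1e-12)
})

test_that("linear and quadratic weights coincide for two categories", {
  set.seed(17)
  a <- sample(c("x", "y"), 50, replace = TRUE)
  b <- sample(c("x", "y"), 50, replace = TRUE)
  expect_equal(weightedKappa(a, b, scheme = "linear")@kappa,
               weightedKappa(a, b, scheme = "quadratic")@kappa,
               tolerance = 1e-12)
})

test_that("weighted kappa validates inputs", {
  expect_error(weightedKappa(1:3, 1:4), "equal length")
  expect_error(weightedKappa(c(1, 1), c(1, 1)), "undefined kappa")
  expect_error(weightedKappa(c(1, 5), c(1, 2), categories = 1:3), "outside")
})

test_that("Landis-Koch labels match the printed scale incl. boundaries", {
  expect_identical(landisKochCategory(0.937), "almost perfect")
  expect_identical(landisKochCategory(0.985), "almost perfect")
  expect_identical(landisKochCategory(0.5), "moderate")
  expect_identical(landisKochCategory(-0.1), "none")
  expect_identical(landisKochCategory(0.1), "slight")
  expect_identical(landisKochCategory(0.3), "fair")
  expect_identical(landisKochCategory(0.7), "substantial")
  # boundaries belong to the lower band
  expect_identical(landisKochCategory(0.2), "slight")
  expect_identical(landisKochCategory(0.4), "fair")
  expect_identical(landisKochCategory(0.6), "moderate")
  expect_identical(landisKochCategory(0.8), "substantial")
  expect_identical(landisKochCategory(0), "slight")
  expect_identical(landisKochCategory(1), "almost perfect")
  expect_identical(landisKochCategory(-1), "none")
  expect_error(landisKochCategory(1.2), "\\[-1, 1\\]")
})

test_that("Landis-Koch labeling is a total monotone step function", {
  grid <- seq(-1, 1, by = 0.001)
  labs <- vapply(grid, landisKochCategory, character(1))
  order <- c("none", "slight", "fair", "moderate", "substantial",
             "almost perfect")
  ranks <- match(labs, order)
  expect_false(anyNA(ranks))            # total
  expect_true(all(diff(ranks) >= 0))    # monotone
})

test_that("landmark picks discretize into usable agreement categories", {
  set.seed(5)
  picks <- lapply(1:12, function(i) {
    truth <- rnorm(3, sd = 20)
    p <- lapply(1:5, function(j) truth + rnorm(3, sd = 0.3))
    p[[5]] <- truth + c(8, 0, 0)  # one discordant rater
    p
  })
  tab <- discretizePicks(picks, tolerance = 2)
  expect_identical(dim(tab), c(12L, 5L))
  expect_true(all(tab[, 5] == "disagree"))
  expect_true(all(tab[, 1:4] == "agree"))
  res <- fleissKappa(tab)
  expect_s4_class(res, "AgreementResult")
  expect_error(discretizePicks(picks, tolerance = 0), "tolerance")
})
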