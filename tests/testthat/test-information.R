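# Plug-in information estimators, complete-case handling, and the
# decomposition identities they must satisfy.

test_that("plug-in entropy matches direct evaluation", {
  d <- makeData(X = c(1, 1, 2, 2))
  expect_equal(plugInEntropy(contingencyTable(d, "X")), log(2))
  d2 <- makeData(X = c(1, 1, 1, 1))
  expect_equal(plugInEntropy(contingencyTable(d2, "X")), 0)
  d3 <- makeData(X = c(1, 1, 1, 2))
  expect_equal(plugInEntropy(contingencyTable(d3, "X")),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
})

test_that("contingency tables use complete cases only", {
  df <- data.frame(X = c("1", "1", NA, "2"), Y = c("a", "b", "a", "b"),
                   Z = c("u", NA, "u", "v"), stringsAsFactors = FALSE)
  d <- categoricalData(df)
  expect_equal(contingencyTable(d, c("X", "Y"))@nAvailable, 3L)
  expect_equal(contingencyTable(d, "Y")@nAvailable, 4L)
  # brute-force row-scan oracle on random missingness patterns
  set.seed(42)
  for (rep in 1:20) {
    m <- matrix(sample(c("1", "2", NA), 60, replace = TRUE, prob = c(.4, .4, .2)),
                20, 3, dimnames = list(NULL, c("A", "B", "C")))
    dd <- categoricalData(as.data.frame(m, stringsAsFactors = FALSE))
    vars <- sample(c("A", "B", "C"), sample(1:3, 1))
    expected <- sum(apply(!is.na(m[, vars, drop = FALSE]), 1, all))
    if (expected == 0) {
      expect_error(contingencyTable(dd, vars), "degenerate")
    } else {
      ct <- contingencyTable(dd, vars)
      expect_equal(ct@nAvailable, expected)
      expect_equal(sum(ct@counts), expected)
    }
  }
  expect_error(contingencyTable(d, "nope"), "unknown")
})

test_that("mutual information matches hand evaluation and brute force", {
  # 2x2 counts [[2,1],[1,2]], N = 6: I = (2/3) log(4/3) + (1/3) log(2/3)
  d <- makeData(X = c(1, 1, 1, 2, 2, 2), Y = c(1, 1, 2, 1, 2, 2))
  expect_equal(condMutualInfo(d, "X", "Y")@info,
               (2 / 3) * log(4 / 3) + (1 / 3) * log(2 / 3), tolerance = 1e-12)
  # identical variables: I = H = log 2
  d2 <- makeData(X = c(1, 2, 1, 2), Y = c(1, 2, 1, 2))
  expect_equal(condMutualInfo(d2, "X", "Y")@info, log(2))
  # brute-force probability-table oracle on random tables
  for (s in 1:25) {
    dd <- randomTable(n = 40, p = 3, seed = s)
    cnt <- contingencyTable(dd, c("A", "B"))@counts
    p <- cnt / sum(cnt)
    px <- rowSums(p); py <- colSums(p)
    oracle <- sum(ifelse(p > 0, p * log(p / outer(px, py)), 0))
    expect_equal(condMutualInfo(dd, "A", "B")@info, oracle, tolerance = 1e-9)
  }
})

test_that("information decomposition identity holds on random tables", {
  for (s in 1:200) {
    d <- randomTable(n = 25, p = 3, seed = s)
    ixy <- condMutualInfo(d, "A", "B")@info
    icond <- condMutualInfo(d, "A", "B", "C")@info
    i3 <- multivariateInformation(d, c("A", "B", "C"))
    expect_equal(ixy - icond - i3, 0, tolerance = 1e-12)
    expect_gte(ixy, 0)
    expect_gte(icond, 0)
  }
})

test_that("multivariate information: special cases", {
  for (s in 1:10) {
    d <- randomTable(n = 40, p = 2, seed = s)
    expect_equal(multivariateInformation(d, c("A", "B")),
                 condMutualInfo(d, "A", "B")@info, tolerance = 1e-12)
  }
  # uniform XOR triple: I(X;Y;Z) = -log 2
  g <- expand.grid(X = 0:1, Y = 0:1)
  g <- g[rep(1:4, 10), ]
  g$Z <- (g$X + g$Y) %% 2
  d <- makeData(X = g$X, Y = g$Y, Z = g$Z)
  expect_equal(multivariateInformation(d, c("X", "Y", "Z")), -log(2),
               tolerance = 1e-12)
  # exact product table: exactly zero
  g2 <- expand.grid(X = 0:1, Y = 0:1, Z = 0:2)
  d2 <- makeData(X = g2$X, Y = g2$Y, Z = g2$Z)
  expect_equal(multivariateInformation(d2, c("X", "Y", "Z")), 0, tolerance = 1e-12)
  expect_error(multivariateInformation(d2, "X"), "at least 2")
  expect_error(multivariateInformation(d2, as.character(1:13)), "12")
})

test_that("three-point information: sign semantics and telescoping", {
  # collider with independent roots: I(X;Y) ~ 0 so I3 ~ -I(X;Y|Z) <= 0
  d <- forwardSample(colliderBN(), 4000, seed = 3)
  tp <- threePointInfo(d, "A", "B", "C")
  expect_lt(tp@info, 0)
  expect_equal(tp@info,
               condMutualInfo(d, "A", "B")@info - condMutualInfo(d, "A", "B", "C")@info,
               tolerance = 1e-12)
  # chain: middle node carries positive 3-point information
  d2 <- forwardSample(chainBN(), 4000, seed = 4)
  expect_gt(threePointInfo(d2, "A", "C", "B")@info, 0)
  # telescoping reconstruction of I(X;Y), both contributor orders
  for (s in 1:20) {
    dd <- randomTable(n = 30, p = 4, seed = s)
    ixy <- condMutualInfo(dd, "A", "B")@info
    for (ord in list(c("C", "D"), c("D", "C"))) {
      tele <- threePointInfo(dd, "A", "B", ord[1])@info +
        threePointInfo(dd, "A", "B", ord[2], cond = ord[1])@info +
        condMutualInfo(dd, "A", "B", ord)@info
      expect_equal(tele, ixy, tolerance = 1e-12)
    }
  }
})

test_that("effective-sample override replaces N in shifted values", {
  d <- randomTable(n = 200, p = 2, seed = 9)
  shifted <- vapply(c(50L, 100L, 200L), function(ne) {
    effectiveSamples(d) <- ne
    r <- condMutualInfo(d, "A", "B", mode = "bic")
    expect_identical(r@nUsed, ne)
    expect_equal(r@shifted, r@info - r@complexity / ne)
    r@shifted
  }, 0)
  # larger effective n weakens the penalty: shifted increases
  expect_true(all(diff(shifted) > 0))
})

test_that("degenerate inputs are handled explicitly", {
  d <- categoricalData(data.frame(X = c("a", "a"), Y = c("u", "v")))
  expect_warning(r <- condMutualInfo(d, "X", "Y"), "single-level")
  expect_equal(r@info, 0)
  expect_error(condMutualInfo(d, "X", "X"), "differ")
  expect_error(plugInEntropy(contingencyTable(d, character(0))), "non-empty")
})
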