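test_that("winsorized mean: constants, bounds and the sort/clip oracle", {
  expect_equal(winsorized_mean(rep(3.7, 10)), 3.7)
  expect_error(winsorized_mean(numeric()), "empty")
  expect_error(winsorized_mean(1:5, 0.9, 0.1))

  set.seed(101)
  for (i in 1:100) {
    x <- rnorm(50, sd = runif(1, 0.5, 5))
    w <- winsorized_mean(x, 0.10, 0.90)
    expect_gte(w, min(x))
    expect_lte(w, max(x))
    expect_equal(w, oracle_winsor(x, 0.10, 0.90), tolerance = 1e-12)
  }
})

test_that("winsorized mean ignores inflation of already-clipped values", {
  # n chosen so the 10%/90% quantile positions are exact order statistics,
  # making the clipping bounds themselves immune to the inflation
  set.seed(7)
  x <- rnorm(41)
  hi <- x > quantile(x, 0.90)
  y <- x
  y[hi] <- y[hi] + 1000
  expect_equal(winsorized_mean(x), winsorized_mean(y), tolerance = 1e-12)
})

test_that("transcript filtering applies all three criteria", {
  # 5 genes: g1 ok; g2 constant (CV = 0); g3 all below 5; g4 fails detection;
  # g5 ok
  set.seed(1)
  n <- 20
  vals <- rbind(g1 = rnorm(n, 8, 1), g2 = rep(6, n), g3 = rnorm(n, 3, 0.4),
                g4 = rnorm(n, 8, 1), g5 = rnorm(n, 7, 1))
  vals["g3", ] <- pmin(vals["g3", ], 4.9)
  colnames(vals) <- sprintf("s%02d", 1:n)
  em <- quick_em(vals)
  det <- matrix(TRUE, 5, n, dimnames = dimnames(vals))
  det["g4", 1:15] <- FALSE          # detected in 25% < 50%
  res <- filter_transcripts(list(em), list(det))
  expect_setequal(gene_ids(res$matrices[[1]]), c("g1", "g5"))
  rep <- res$report
  expect_equal(rep$n[rep$criterion == "detection"], 1)
  expect_equal(rep$n[rep$criterion == "cv"], 1)
  expect_equal(rep$n[rep$criterion == "expression"], 1)
  expect_equal(rep$n[rep$criterion == "kept"], 2)
})

test_that("a gene passing in any one region is retained", {
  set.seed(2)
  n <- 10
  v1 <- rbind(gA = rep(6, n), gB = rnorm(n, 8, 1))   # gA constant in region 1
  v2 <- rbind(gA = rnorm(n, 8, 1), gB = rnorm(n, 8, 1))
  colnames(v1) <- sprintf("a%02d", 1:n); colnames(v2) <- sprintf("b%02d", 1:n)
  res <- filter_transcripts(list(quick_em(v1, "R01"), quick_em(v2, "R02")))
  expect_setequal(gene_ids(res$matrices[[1]]), c("gA", "gB"))
})

test_that("filtering is independent of gene order", {
  set.seed(3)
  vals <- matrix(rnorm(200, 7, 1), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  vals[3, ] <- 4          # fails expression
  vals[8, ] <- 7          # constant, fails CV
  perm <- sample(20)
  r1 <- filter_transcripts(list(quick_em(vals)))
  r2 <- filter_transcripts(list(quick_em(vals[perm, ])))
  expect_setequal(gene_ids(r1$matrices[[1]]), gene_ids(r2$matrices[[1]]))
})

test_that("residualize removes planted batch structure exactly", {
  set.seed(4)
  n <- 30
  md <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   batch = rep(c("B1", "B2"), each = n / 2))
  vals <- matrix(rnorm(5 * n, 8, 1), 5, n,
                 dimnames = list(sprintf("g%d", 1:5), md$sample_id))
  vals[, md$batch == "B2"] <- vals[, md$batch == "B2"] + 2
  em <- expression_matrix(vals, metadata = md)
  res <- residualize(em, "batch")
  for (g in 1:5) {
    d <- mean(res$values[g, md$batch == "B1"]) -
      mean(res$values[g, md$batch == "B2"])
    expect_lt(abs(d), 1e-10)
  }
  # means are preserved
  expect_equal(rowMeans(res$values), rowMeans(vals), tolerance = 1e-10)
})

test_that("residualize leaves genes orthogonal to the design unchanged", {
  n <- 20
  md <- data.frame(sample_id = sprintf("s%02d", 1:n), x = rnorm(n))
  g <- rnorm(n)
  # orthogonalize g against [1, x] by explicit projection
  X <- cbind(1, md$x)
  g_orth <- g - X %*% solve(crossprod(X), crossprod(X, g))
  vals <- matrix(g_orth + 5, 1, n, dimnames = list("g1", md$sample_id))
  em <- expression_matrix(vals, metadata = md)
  res <- residualize(em, "x")
  expect_equal(res$values, vals, tolerance = 1e-10)
})

test_that("residualize matches the normal-equations oracle and is idempotent", {
  set.seed(5)
  n <- 10
  md <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   age = runif(n, 20, 80), sex = rep(c("M", "F"), 5))
  vals <- matrix(rnorm(3 * n), 3, n,
                 dimnames = list(paste0("g", 1:3), md$sample_id))
  em <- expression_matrix(vals, metadata = md)
  res <- residualize(em, c("age", "sex"))
  X <- model.matrix(~ age + sex, md)        # 10 x 3 design
  H <- X %*% solve(crossprod(X)) %*% t(X)
  for (g in 1:3) {
    oracle <- vals[g, ] - as.vector(H %*% vals[g, ]) + mean(vals[g, ])
    expect_equal(unname(res$values[g, ]), unname(oracle), tolerance = 1e-10)
  }
  res2 <- residualize(res, c("age", "sex"))
  expect_equal(res2$values, res$values, tolerance = 1e-10)
})

test_that("residualize names collinear covariates", {
  n <- 12
  md <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   a = rep(c("x", "y"), each = 6),
                   b = rep(c("x", "y"), each = 6))
  vals <- matrix(rnorm(n), 1, n, dimnames = list("g1", md$sample_id))
  em <- expression_matrix(vals, metadata = md)
  expect_error(residualize(em, c("a", "b")), "collinear.*b", ignore.case = TRUE)
})

test_that("outlier detection flags a noise sample among correlated ones", {
  set.seed(6)
  n <- 40
  f <- rnorm(200)
  vals <- sapply(seq_len(n), function(i) 0.9 * f + 0.45 * rnorm(200))
  dimnames(vals) <- list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:n))
  vals[, "s07"] <- rnorm(200)              # independent noise sample
  em <- quick_em(vals)
  expect_identical(detect_outlier_samples(em), "s07")
})

test_that("outlier detection: homogeneous data and equality boundary", {
  set.seed(8)
  f <- rnorm(100)
  vals <- sapply(1:10, function(i) f + 0.5 * rnorm(100))
  dimnames(vals) <- list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:10))
  expect_length(detect_outlier_samples(quick_em(vals)), 0)

  # perfectly exchangeable samples: every IAC equals the mean, SD = 0, so the
  # cut equals the mean and the strict "<" flags nothing
  vals2 <- sapply(1:5, function(i) f)
  dimnames(vals2) <- list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:5))
  expect_length(detect_outlier_samples(quick_em(vals2)), 0)

  expect_error(detect_outlier_samples(quick_em(vals2[, 1:2, drop = FALSE])),
               "at least 3")
})

test_that("outlier detection iterates until a fixed point", {
  set.seed(9)
  n <- 40
  f <- rnorm(300)
  vals <- sapply(seq_len(n), function(i) 0.95 * f + 0.3 * rnorm(300))
  dimnames(vals) <- list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:n))
  vals[, "s03"] <- rnorm(300)                       # gross outlier
  vals[, "s11"] <- 0.55 * f + 0.85 * rnorm(300)     # milder outlier
  flagged <- detect_outlier_samples(quick_em(vals))
  expect_true("s03" %in% flagged)
  expect_true("s11" %in% flagged)
})
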