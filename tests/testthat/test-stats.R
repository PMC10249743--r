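test_that("identical counts with equal library sizes give a null result", {
  res <- nb_glm_test(rep(50L, 10), rep(c("a", "b"), each = 5),
                     rep(1000, 10), "b", "a")
  expect_equal(res$coefficient, 0, tolerance = 1e-8)
  expect_gt(res$p_value, 0.99)
})

test_that("all-zero counts return NA rather than an error", {
  res <- nb_glm_test(rep(0L, 10), rep(c("a", "b"), each = 5))
  expect_true(is.na(res$p_value))
  expect_false(res$converged)
})

test_that("input validation catches bad counts and degenerate groups", {
  expect_error(nb_glm_test(c(1, -1, 2, 3), rep(c("a", "b"), 2)),
               "non-negative")
  expect_error(nb_glm_test(c(1.5, 1, 2, 3), rep(c("a", "b"), 2)),
               "non-negative integers")
  expect_error(nb_glm_test(1:4, rep("a", 4)), "two groups")
  expect_error(nb_glm_test(1:4, c("a", "a", "a", "b")), ">= 2 samples")
})

test_that("ML theta with a normal reference reproduces MASS::glm.nb", {
  skip_if_not_installed("MASS")
  set.seed(13)
  for (i in 1:8) {
    grp <- rep(c("a", "b"), each = 5)
    y <- rnbinom(10, mu = 150 * rep(c(1, 1.8), each = 5), size = 8)
    if (all(y == 0)) next
    ls <- sample(800:1200, 10)
    got <- nb_glm_test(y, grp, ls, group_a = "b", group_b = "a",
                       theta_method = "ml", p_reference = "normal")
    fit <- MASS::glm.nb(y ~ factor(grp, levels = c("a", "b")) +
                          offset(log(ls)))
    s <- summary(fit)$coefficients
    expect_equal(got$coefficient, unname(coef(fit)[2]), tolerance = 1e-6)
    expect_equal(got$se, unname(s[2, 2]), tolerance = 1e-6)
    expect_equal(got$p_value, unname(s[2, 4]), tolerance = 1e-6)
    expect_equal(got$theta, fit$theta, tolerance = 1e-4)
  }
})

test_that("near-Poisson data triggers the capped-theta Poisson fallback", {
  set.seed(14)
  y <- rpois(10, 200)
  res <- nb_glm_test(y, rep(c("a", "b"), each = 5))
  expect_false(res$converged)
  expect_gte(res$theta, 1e6)
  # the fallback fit equals a plain Poisson GLM
  pfit <- glm(y ~ rep(c(0, 1), each = 5), family = poisson())
  expect_equal(res$coefficient, unname(coef(pfit)[2]), tolerance = 1e-6)
})

test_that("group-effect bias shrinks and Wald coverage is sane at n=20+20", {
  set.seed(15)
  beta <- log(2)
  est_small <- numeric(150); est_big <- numeric(150); cover <- logical(150)
  for (i in 1:150) {
    y5 <- rnbinom(10, mu = 200 * exp(beta * rep(0:1, each = 5)), size = 10)
    y20 <- rnbinom(40, mu = 200 * exp(beta * rep(0:1, each = 20)), size = 10)
    r5 <- nb_glm_test(y5, rep(c("a", "b"), each = 5), group_a = "b",
                      group_b = "a")
    r20 <- nb_glm_test(y20, rep(c("a", "b"), each = 20), group_a = "b",
                       group_b = "a")
    est_small[i] <- r5$coefficient; est_big[i] <- r20$coefficient
    cover[i] <- abs(r20$coefficient - beta) <= qt(0.975, 38) * r20$se
  }
  expect_lt(abs(mean(est_big) - beta), abs(mean(est_small) - beta) + 0.02)
  expect_lt(abs(mean(est_big) - beta), 0.05)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("nb_glm_table maps rows, keeps raw p by default and supports BH", {
  set.seed(16)
  counts <- matrix(rnbinom(40, mu = 100, size = 10), 4, 10,
                   dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
  pheno <- data.frame(sample = paste0("s", 1:10),
                      group = rep(c("a", "b"), each = 5))
  tab <- nb_glm_table(counts, pheno, "b", "a")
  expect_identical(tab$feature, paste0("f", 1:4))
  expect_false("p_adj" %in% names(tab))
  tab2 <- nb_glm_table(counts, pheno, "b", "a", adjust = "BH")
  expect_equal(tab2$p_adj, p.adjust(tab2$p_value, "BH"))
  expect_equal(tab2$p_value, tab$p_value)
})

test_that("rm_corr equals the dense least-squares oracle on random instances", {
  set.seed(17)
  for (i in 1:40) {
    k <- sample(3:8, 1)
    reps <- sample(2:5, 1)
    subject <- rep(paste0("s", seq_len(k)), each = reps)
    x <- rnorm(k * reps)
    y <- rep(rnorm(k, sd = 3), each = reps) + 0.8 * x + rnorm(k * reps)
    got <- rm_corr(subject, x, y)
    want <- oracle_rmcorr(subject, x, y)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$df, want$df)
  }
})

test_that("points exactly on subject-shifted lines of slope 2 give r = 1", {
  subject <- rep(c("a", "b", "c"), each = 4)
  x <- c(1:4, 2:5, 0:3)
  y <- 2 * x + rep(c(10, -5, 3), each = 4)
  res <- rm_corr(subject, x, y)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 2)
})

test_that("shuffled y within subjects gives small r and a large p on average", {
  set.seed(18)
  subject <- rep(paste0("s", 1:10), each = 10)
  x <- rnorm(100)
  p <- replicate(50, {
    y <- rep(rnorm(10, sd = 3), each = 10) + rnorm(100)
    rm_corr(subject, x, y)$p_value
  })
  expect_gt(mean(p), 0.3)   # roughly uniform null p-values
  expect_lt(mean(p < 0.05), 0.2)
})

test_that("rm_corr rejects degenerate designs", {
  expect_error(rm_corr(rep("a", 4), 1:4, 1:4), "two subjects")
  expect_error(rm_corr(c("a", "a", "b"), 1:3, c(2, 1, 5)), "df")
  expect_error(rm_corr(rep(c("a", "b"), each = 3), rep(c(1, 2), each = 3),
                       rnorm(6)), "constant within every subject")
})

test_that("identical rows merge at distance zero and clusters recover groups", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  hc <- hcluster(m)
  expect_equal(min(hc$tree$height), 0)
  set.seed(19)
  centers <- matrix(rnorm(4 * 6, sd = 1), 4, 6) * 0.3 +
    matrix(c(0, 20, 40, 60), 4, 6)
  m2 <- centers[rep(1:4, each = 5), ] + matrix(rnorm(120, sd = 0.3), 20, 6)
  rownames(m2) <- paste0("r", 1:20)
  hc2 <- hcluster(m2, k = 4)
  # labels constant within each planted group, distinct across groups
  lab <- matrix(hc2$labels, nrow = 5)
  expect_true(all(apply(lab, 2, function(z) length(unique(z)) == 1)))
  expect_equal(length(unique(lab[1, ])), 4)
})

test_that("clustering is permutation-equivariant", {
  set.seed(20)
  m <- matrix(rnorm(60), 12, 5, dimnames = list(paste0("r", 1:12), NULL))
  perm <- sample(12)
  h1 <- hcluster(m, k = 3)
  h2 <- hcluster(m[perm, ], k = 3)
  l1 <- h1$labels[rownames(m)]
  l2 <- h2$labels[rownames(m)]
  # the partitions are identical up to relabelling: same co-membership
  expect_identical(outer(l1, l1, "=="), outer(l2, l2, "=="))
})

test_that("pearson distance is invariant to positive affine row rescaling", {
  set.seed(23)
  m <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("r", 1:8), NULL))
  m2 <- m * 3.7 + 11
  h1 <- hcluster(m, metric = "pearson_distance", k = 3)
  h2 <- hcluster(m2, metric = "pearson_distance", k = 3)
  expect_identical(h1$labels, h2$labels)
  expect_identical(h1$order, h2$order)
})

test_that("zero-variance rows get Pearson distance 1 with a warning", {
  m <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(2, 4, 6))
  expect_warning(h <- hcluster(m, metric = "pearson_distance"),
                 "zero-variance")
  d <- as.matrix(stats::cophenetic(h$tree))
  expect_equal(unname(d["a", "b"]), 1)
})

test_that("proteome normalisation equalises column sums and preserves ratios", {
  m <- matrix(c(40, 60, 100, 200), 2, 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  nm <- normalize_proteome(m)
  expect_equal(unname(colSums(nm)), c(200, 200))
  expect_equal(nm["p1", "s2"] / nm["p2", "s2"], 0.5)
  eq <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_equal(normalize_proteome(eq), eq)
  expect_error(normalize_proteome(matrix(c(-1, 2), 1, 2)), "non-negative")
})
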