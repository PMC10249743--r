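# Statistical layer: negative-binomial GLM differential testing (log link,
# group factor, log library-size offset, theta by maximum likelihood),
# repeated-measures correlation via the common-slope ANCOVA, hierarchical
# clustering, and proteomics column normalisation.

# profile log-likelihood in theta (dropping y-only constants); with X the
# Cox-Reid adjustment -0.5 log det(X'WX) is subtracted, giving the adjusted
# profile likelihood that corrects the small-sample bias of ML dispersion
nb_theta_loglik <- function(theta, y, mu, X = NULL) {
  ll <- sum(lgamma(y + theta) - lgamma(theta) + theta * log(theta) -
              (y + theta) * log(theta + mu) + y * log(mu + 1e-300))
  if (!is.null(X)) {
    w <- mu / (1 + mu / theta)
    ll <- ll - 0.5 * as.numeric(determinant(t(X * w) %*% X)$modulus)
  }
  ll
}

# theta by maximising the Cox-Reid adjusted profile likelihood on log(theta)
nb_theta_apl <- function(y, mu, X, theta_max = 1e6, theta_min = 1e-4) {
  opt <- stats::optimize(function(u) nb_theta_loglik(exp(u), y, mu, X),
                         c(log(theta_min), log(theta_max)), maximum = TRUE,
                         tol = 1e-9)
  # optimize never lands exactly on a boundary; snap diverging theta to the cap
  if (opt$maximum > log(theta_max) - 1e-3 &&
      nb_theta_loglik(theta_max, y, mu, X) >= opt$objective - 1e-9) {
    return(theta_max)
  }
  exp(opt$maximum)
}

# ML update of theta by safeguarded Newton steps on log(theta)
nb_theta_ml <- function(y, mu, theta0 = 1, max_iter = 50L,
                        theta_max = 1e6, theta_min = 1e-4) {
  u <- log(min(max(theta0, theta_min), theta_max))
  for (i in seq_len(max_iter)) {
    t <- exp(u)
    score_t <- sum(digamma(y + t) - digamma(t) + log(t) - log(t + mu) +
                     1 - (y + t) / (t + mu))
    hess_t <- sum(trigamma(y + t) - trigamma(t) + 1 / t - 1 / (t + mu) -
                    (mu - y) / (t + mu)^2)
    g <- t * score_t
    h <- g + t^2 * hess_t
    step <- if (is.finite(h) && h < 0) -g / h else sign(g)
    step <- max(min(step, 2), -2)
    ll_old <- nb_theta_loglik(t, y, mu)
    u_new <- u + step
    # halve until the likelihood does not decrease
    for (j in 1:20) {
      t_new <- exp(min(max(u_new, log(theta_min)), log(theta_max)))
      if (nb_theta_loglik(t_new, y, mu) >= ll_old - 1e-12) break
      u_new <- (u + u_new) / 2
    }
    u_new <- min(max(u_new, log(theta_min)), log(theta_max))
    if (abs(u_new - u) < 1e-10) { u <- u_new; break }
    u <- u_new
  }
  exp(u)
}

# IRLS for a log-link GLM with NB variance mu + mu^2/theta
# (theta = Inf gives the Poisson fit)
nb_irls <- function(y, X, offset, theta, beta0 = NULL, max_iter = 100L) {
  if (is.null(beta0)) {
    beta <- stats::lm.fit(X, log(y + 0.5) - offset)$coefficients
    beta[is.na(beta)] <- 0
  } else beta <- beta0
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmax(exp(eta), 1e-10)
    w <- if (is.finite(theta)) mu / (1 + mu / theta) else mu
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    fit <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(fit)) break
    beta_new <- drop(fit)
    if (max(abs(beta_new - beta)) < 1e-10 * (1 + max(abs(beta)))) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta) + offset
  mu <- pmax(exp(eta), 1e-10)
  w <- if (is.finite(theta)) mu / (1 + mu / theta) else mu
  cov <- tryCatch(solve(t(X * w) %*% X), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  list(beta = beta, se = sqrt(pmax(diag(cov), 0)), mu = mu,
       converged = converged)
}

#' Negative-binomial GLM test for one feature
#'
#' Fits `count ~ group` with a log link and `log(lib_size)` offset,
#' alternating IRLS for the coefficients with updates of the NB size
#' parameter theta. By default theta maximises the Cox-Reid adjusted
#' profile likelihood and the two-sided Wald statistic is referred to a t
#' distribution with `N - p` degrees of freedom — both standard
#' small-sample corrections, chosen because plain ML theta with a normal
#' reference is markedly anti-conservative at five samples per group.
#' `theta_method = "ml"` with `p_reference = "normal"` reproduces
#' `MASS::glm.nb` exactly. The reported coefficient is the natural-log
#' ratio of `group_a` over `group_b` means. When theta diverges
#' (overdispersion vanishing, capped at 1e6) the fit falls back to a
#' Poisson GLM and is flagged `converged = FALSE`. All-zero features return
#' `NA` with `converged = FALSE` rather than an error.
#'
#' @param y non-negative integer counts, one per sample.
#' @param group two-level group label per sample.
#' @param lib_sizes library size per sample (offset), defaults to 1.
#' @param group_a,group_b contrast; defaults to the two observed levels
#'   with `group_a` the second.
#' @param theta_method `"cox_reid"` (adjusted profile likelihood, default)
#'   or `"ml"`.
#' @param p_reference `"t"` (df = N - p, default) or `"normal"`.
#' @param max_outer maximum alternating iterations.
#' @return data frame row: coefficient, se, p_value, theta, converged.
#' @export
nb_glm_test <- function(y, group, lib_sizes = NULL, group_a = NULL,
                        group_b = NULL,
                        theta_method = c("cox_reid", "ml"),
                        p_reference = c("t", "normal"), max_outer = 25L) {
  theta_method <- match.arg(theta_method)
  p_reference <- match.arg(p_reference)
  group <- as.character(group)
  levs <- unique(group)
  if (length(levs) != 2L) stop("exactly two groups are required")
  if (is.null(group_b)) group_b <- levs[1]
  if (is.null(group_a)) group_a <- setdiff(levs, group_b)[1]
  if (min(table(group)) < 2L) stop("each group needs >= 2 samples")
  if (any(y < 0) || any(y != floor(y))) stop("counts must be non-negative integers")
  if (is.null(lib_sizes)) lib_sizes <- rep(1, length(y))
  if (all(y == 0)) {
    return(data.frame(coefficient = NA_real_, se = NA_real_,
                      p_value = NA_real_, theta = NA_real_,
                      converged = FALSE))
  }
  offset <- log(lib_sizes)
  X <- cbind(intercept = 1, groupa = as.numeric(group == group_a))

  theta <- 10
  fit <- nb_irls(y, X, offset, theta)
  for (i in seq_len(max_outer)) {
    theta_new <- if (theta_method == "cox_reid") {
      nb_theta_apl(y, fit$mu, X)
    } else {
      nb_theta_ml(y, fit$mu, theta0 = theta)
    }
    fit_new <- nb_irls(y, X, offset, theta_new, beta0 = fit$beta)
    done <- abs(log(theta_new) - log(theta)) < 1e-8 &&
      max(abs(fit_new$beta - fit$beta)) < 1e-8
    theta <- theta_new; fit <- fit_new
    if (done) break
  }
  poisson_fallback <- theta >= 1e6 * (1 - 1e-9)
  if (poisson_fallback) {
    fit <- nb_irls(y, X, offset, Inf, beta0 = fit$beta)
  }
  z <- fit$beta[2] / fit$se[2]
  p <- if (p_reference == "t") {
    2 * stats::pt(-abs(z), df = length(y) - ncol(X))
  } else {
    2 * stats::pnorm(-abs(z))
  }
  data.frame(coefficient = unname(fit$beta[2]), se = unname(fit$se[2]),
             p_value = unname(p), theta = theta,
             converged = fit$converged && !poisson_fallback)
}

#' Negative-binomial GLM tests across a count matrix
#'
#' Applies [nb_glm_test()] to every row. Following the convention that
#' multimapping ambiguity precludes a per-sequence error model, no multiple
#' testing correction is applied by default; `adjust = "BH"` adds a
#' Benjamini-Hochberg column.
#'
#' @param counts feature x sample integer matrix.
#' @param pheno sample sheet with `sample` and `group` columns.
#' @param group_a,group_b contrast (numerator / denominator).
#' @param lib_sizes per-sample library sizes; defaults to the column sums
#'   of `counts`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data frame: feature, coefficient, se, p_value, theta, converged
#'   (and p_adj when requested).
#' @export
nb_glm_table <- function(counts, pheno, group_a, group_b, lib_sizes = NULL,
                         adjust = c("none", "BH"), ...) {
  adjust <- match.arg(adjust)
  samples <- pheno$sample[pheno$group %in% c(group_a, group_b)]
  group <- pheno$group[match(samples, pheno$sample)]
  m <- counts[, samples, drop = FALSE]
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    nb_glm_test(m[i, ], group, lib_sizes, group_a = group_a,
                group_b = group_b, ...)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(feature = rownames(m), stringsAsFactors = FALSE),
               out)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Repeated-measures correlation
#'
#' The common within-subject correlation from the ANCOVA formulation:
#' `y ~ subject intercepts + common slope * x`. With N observations and k
#' subjects, `r = sign(slope) * sqrt(SS_x / (SS_x + SS_resid))`,
#' `df = N - k - 1`, and the p-value is the F test of the common slope.
#'
#' @param subject subject (participant) identifier per observation.
#' @param x,y numeric observations.
#' @return list of class `rmcorr_result`: r, df, p_value, slope.
#' @export
rm_corr <- function(subject, x, y) {
  subject <- as.factor(subject)
  k <- nlevels(subject)
  N <- length(x)
  stopifnot(length(y) == N, length(subject) == N)
  if (k < 2L) stop("at least two subjects are required")
  if (N - k - 1L < 1L) stop("not enough observations for df = N - k - 1 >= 1")
  full <- stats::lm(y ~ 0 + subject + x)
  if (is.na(stats::coef(full)["x"])) {
    stop("x is constant within every subject; the common slope is undefined")
  }
  reduced <- stats::lm(y ~ 0 + subject)
  rss_full <- sum(stats::residuals(full)^2)
  ss_x <- sum(stats::residuals(reduced)^2) - rss_full
  slope <- unname(stats::coef(full)["x"])
  df <- N - k - 1L
  r <- sign(slope) * sqrt(max(ss_x, 0) / (ss_x + rss_full))
  fstat <- ss_x / (rss_full / df)
  p <- stats::pf(fstat, 1, df, lower.tail = FALSE)
  if (rss_full < 1e-300) { r <- sign(slope); p <- 0 }
  structure(list(r = r, df = df, p_value = p, slope = slope),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("repeated-measures correlation: r = %.4f (df = %d, p = %.3g, slope = %.4g)\n",
              x$r, x$df, x$p_value, x$slope))
  invisible(x)
}

#' Hierarchical clustering of matrix rows
#'
#' Agglomerative complete-linkage clustering with either Euclidean distance
#' or Pearson's distance (1 - Pearson correlation between rows). Rows with
#' zero variance have undefined correlation; their Pearson distance is set
#' to 1 with a warning.
#'
#' @param mat numeric matrix (>= 2 rows).
#' @param metric `"euclidean"` or `"pearson_distance"`.
#' @param k optional number of clusters to cut the tree into.
#' @return list: `order` (dendrogram row order), `labels` (cluster labels,
#'   or NULL), `tree` (the `hclust` object).
#' @export
hcluster <- function(mat, metric = c("euclidean", "pearson_distance"),
                     k = NULL) {
  metric <- match.arg(metric)
  if (nrow(mat) < 2L) stop("at least two rows are required")
  if (metric == "euclidean") {
    d <- stats::dist(mat)
  } else {
    v <- apply(mat, 1, stats::var)
    cm <- suppressWarnings(stats::cor(t(mat)))
    if (any(v == 0)) {
      warning("zero-variance row(s); their Pearson distance is set to 1")
      cm[v == 0, ] <- 0
      cm[, v == 0] <- 0
    }
    d <- stats::as.dist(1 - cm)
  }
  tree <- stats::hclust(d, method = "complete")
  labels <- if (!is.null(k)) stats::cutree(tree, k = k) else NULL
  list(order = tree$order, labels = labels, tree = tree)
}

#' Normalise a proteomics count matrix
#'
#' Scales each sample (column) so its total equals the mean of the original
#' column totals.
#'
#' @param mat protein x sample non-negative matrix.
#' @return normalised matrix; all column sums equal the mean original sum.
#' @export
normalize_proteome <- function(mat) {
  if (any(mat < 0)) stop("protein counts must be non-negative")
  sums <- colSums(mat)
  if (any(sums == 0)) {
    stop("zero-sum column(s): ",
         paste(colnames(mat)[sums == 0], collapse = ", "))
  }
  sweep(mat, 2, sums, "/") * mean(sums)
}
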