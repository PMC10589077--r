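# Differential expression: TMM normalization, moment-based shrunk
# dispersions, per-gene negative-binomial log-linear models fit by IRLS,
# and a df = 1 likelihood-ratio test with BH correction.

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample normalization for compositional bias. The reference is
#' the sample whose 75th-percentile count fraction is closest to the mean
#' of those fractions. For each sample, gene-wise log2 ratios (M) against
#' the reference are trimmed by 30% at each end, jointly with a 5% trim at
#' each end of average log abundance (A), and averaged with inverse
#' asymptotic-variance weights. Factors are rescaled so their geometric
#' mean is 1; effective library size is `library size * factor`.
#'
#' @param counts A [count_matrix()] or numeric matrix with >= 2 samples.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts) {
  m <- as_count_mat(counts)
  if (ncol(m) < 2) stop("TMM needs at least 2 samples", call. = FALSE)
  lib <- colSums(m)
  if (any(lib <= 0)) stop("library sizes must be > 0", call. = FALSE)
  f75 <- apply(m, 2, function(y) stats::quantile(y, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(m)), function(s) {
    tmm_pair(m[, s], m[, ref], lib[s], lib[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

# One sample against the reference; returns the unscaled factor.
tmm_pair <- function(ys, yr, ls, lr, logratio_trim = 0.3, abund_trim = 0.05) {
  keep <- ys > 0 & yr > 0
  if (!any(keep)) {
    warning("sample shares no co-expressed genes with the reference; ",
            "factor set to 1")
    return(1)
  }
  ys <- ys[keep]; yr <- yr[keep]
  M <- log2((ys / ls) / (yr / lr))
  A <- 0.5 * log2((ys / ls) * (yr / lr))
  w <- (ls - ys) / (ls * ys) + (lr - yr) / (lr * yr)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abund_trim) + 1;   hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  trim <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(trim) || sum(1 / w[trim]) == 0) return(1)
  2^(sum(M[trim] / w[trim]) / sum(1 / w[trim]))
}

#' Declare a two-condition contrast
#'
#' @param condition_a,condition_b Condition labels; log fold changes are
#'   reported as `condition_b` over `condition_a`.
#' @param samples Optional character vector restricting the contrast to a
#'   sample subset (e.g. one treatment timepoint plus its control).
#' @param block Optional name of a blocking column in the sample sheet
#'   (e.g. `"block"` for family) entered as a covariate.
#' @return An object of class `de_contrast`.
#' @export
de_contrast <- function(condition_a, condition_b, samples = NULL,
                        block = NULL) {
  if (identical(condition_a, condition_b)) {
    stop("conditions must differ", call. = FALSE)
  }
  structure(list(condition_a = condition_a, condition_b = condition_b,
                 samples = samples, block = block),
            class = "de_contrast")
}

# Restrict a count_matrix to the samples a contrast uses and check the
# >= 2 replicates per condition precondition.
contrast_samples <- function(cm, contrast) {
  meta <- cm$samples
  keep <- meta$condition %in% c(contrast$condition_a, contrast$condition_b)
  if (!is.null(contrast$samples)) keep <- keep & meta$sample %in% contrast$samples
  sub <- subset_samples(cm, meta$sample[keep])
  tab <- table(sub$samples$condition)
  for (cond in c(contrast$condition_a, contrast$condition_b)) {
    if (is.na(tab[cond]) || tab[cond] < 2) {
      stop(sprintf("condition '%s' needs >= 2 samples", cond), call. = FALSE)
    }
  }
  if (!is.null(contrast$block) && !contrast$block %in% names(sub$samples)) {
    stop(sprintf("block column '%s' not in sample sheet", contrast$block),
         call. = FALSE)
  }
  sub
}

#' Per-gene dispersion by moments with shrinkage to the common value
#'
#' Counts are scaled to a common effective library size; within each
#' design cell (condition, or condition x block) with >= 2 samples, a
#' method-of-moments estimate `(var - mean) / mean^2` is formed and cells
#' are pooled with degree-of-freedom weights. Raw values are floored at
#' 1e-6 and shrunk toward a common dispersion with weight
#' `prior_df / (prior_df + residual_df)`. The common value maximizes the
#' cell-total-conditioned NB log-likelihood pooled over all genes (the
#' conditioning removes the per-cell means, so the estimate is not
#' deflated by the fitted-mean degrees of freedom the way a median of
#' few-replicate moment estimates is). Genes with no counts get the
#' common value and are flagged in attribute `allzero`.
#'
#' @param counts A [count_matrix()].
#' @param contrast A [de_contrast()].
#' @param prior_df Shrinkage prior degrees of freedom (default 10).
#' @param norm_factors Optional TMM factors for the full matrix's samples;
#'   computed by [tmm_factors()] on the contrast subset when `NULL`.
#' @return Named numeric vector of dispersions with attributes `common`
#'   (the median raw value) and `allzero` (logical).
#' @export
estimate_dispersions <- function(counts, contrast, prior_df = 10,
                                 norm_factors = NULL) {
  sub <- contrast_samples(counts, contrast)
  m <- sub$counts
  if (is.null(norm_factors)) {
    norm_factors <- tmm_factors(sub)
  } else {
    norm_factors <- norm_factors[sub$samples$sample]
  }
  eff <- colSums(m) * norm_factors
  yn <- sweep(m, 2, exp(mean(log(eff))) / eff, "*")
  cell <- if (is.null(contrast$block)) {
    factor(sub$samples$condition)
  } else {
    interaction(sub$samples$condition, sub$samples[[contrast$block]],
                drop = TRUE)
  }
  groups <- split(seq_len(ncol(m)), cell)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (!length(groups)) stop("no design cell has >= 2 samples", call. = FALSE)
  num <- numeric(nrow(m)); den <- numeric(nrow(m))
  for (idx in groups) {
    g <- yn[, idx, drop = FALSE]
    mu <- rowMeans(g)
    v <- apply(g, 1, stats::var)
    ok <- mu > 0
    df <- length(idx) - 1
    phi_c <- ifelse(ok, (v - mu) / mu^2, 0)
    num <- num + ifelse(ok, df * phi_c, 0)
    den <- den + ifelse(ok, df, 0)
  }
  allzero <- den == 0
  raw <- ifelse(allzero, NA_real_, pmax(num / pmax(den, 1), 1e-6))
  common <- common_dispersion_cml(yn[!allzero, , drop = FALSE], groups)
  if (!is.finite(common)) common <- 0.1
  residual_df <- ncol(m) - nlevels(cell)
  w <- prior_df / (prior_df + max(residual_df, 0))
  disp <- w * common + (1 - w) * raw
  disp[allzero] <- common
  names(disp) <- rownames(m)
  attr(disp, "common") <- common
  attr(disp, "allzero") <- allzero
  disp
}

#' Fit NB log-linear models and test a condition contrast per gene
#'
#' For each gene, the full model `log mu = intercept + condition (+ block)`
#' with a log effective-library-size offset is fit by iteratively
#' reweighted least squares (step halving on deviance increase, ridge
#' 1e-8 on the normal equations, convergence at relative deviance change
#' < 1e-8 within 50 iterations); the reduced model drops condition. The
#' deviance difference is referred to chi-square with 1 df, q-values are
#' BH-adjusted over the tested genes, and the log2 fold change is the
#' fitted condition coefficient on the log2 scale (`condition_b` over
#' `condition_a`). Genes with zero counts in every used sample, or outside
#' `universe`, carry `tested = FALSE` and no p-value.
#'
#' @param counts A [count_matrix()].
#' @param contrast A [de_contrast()].
#' @param dispersions Optional named dispersion vector; estimated with
#'   [estimate_dispersions()] when `NULL`.
#' @param norm_factors Optional TMM factors; computed on the contrast
#'   subset when `NULL`.
#' @param universe Optional character vector restricting testing to the
#'   expression-filtered gene universe.
#' @param q_threshold Significance level used only to set the `direction`
#'   label (default 0.05).
#' @return Data frame: `gene`, `logFC`, `p_value`, `q_value`, `direction`
#'   (`up_in_a` / `up_in_b` / `none`), `tested`.
#' @export
fit_and_test <- function(counts, contrast, dispersions = NULL,
                         norm_factors = NULL, universe = NULL,
                         q_threshold = 0.05) {
  sub <- contrast_samples(counts, contrast)
  m <- sub$counts
  if (is.null(norm_factors)) {
    norm_factors <- tmm_factors(sub)
  } else {
    norm_factors <- norm_factors[sub$samples$sample]
  }
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, contrast,
                                        norm_factors = norm_factors)
  }
  offset <- log(colSums(m) * norm_factors)
  cond <- as.integer(sub$samples$condition == contrast$condition_b)
  X <- cbind(intercept = 1, condition = cond)
  if (!is.null(contrast$block)) {
    blk <- factor(sub$samples[[contrast$block]])
    if (nlevels(blk) > 1) {
      X <- cbind(X, stats::model.matrix(~blk)[, -1, drop = FALSE])
    }
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is not full rank", call. = FALSE)
  }
  genes <- rownames(m)
  testable <- rowSums(m) > 0
  if (!is.null(universe)) testable <- testable & genes %in% universe
  logfc <- rep(NA_real_, length(genes))
  pval <- rep(NA_real_, length(genes))
  phi <- dispersions[genes]
  if (anyNA(phi)) stop("dispersions missing for some genes", call. = FALSE)
  cond_col <- which(colnames(X) == "condition")
  for (i in which(testable)) {
    full <- nb_irls(m[i, ], X, offset, phi[i])
    red <- nb_irls(m[i, ], X[, -cond_col, drop = FALSE], offset, phi[i])
    if (!full$converged || !red$converged) next  # tested stays TRUE -> drop
    stat <- max(red$deviance - full$deviance, 0)
    pval[i] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    logfc[i] <- full$beta[cond_col] / log(2)
  }
  tested <- testable & !is.na(pval)
  qval <- rep(NA_real_, length(genes))
  qval[tested] <- bh_adjust(pval[tested])
  direction <- rep("none", length(genes))
  sig <- tested & !is.na(qval) & qval < q_threshold & logfc != 0
  direction[sig & logfc > 0] <- "up_in_b"
  direction[sig & logfc < 0] <- "up_in_a"
  data.frame(gene = genes, logFC = logfc, p_value = pval, q_value = qval,
             direction = direction, tested = tested,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Significant genes of a DE result
#'
#' @param de Result of [fit_and_test()].
#' @param q_threshold FDR cutoff (default 0.05); a threshold of 1 (or
#'   more) saturates to every tested gene.
#' @return Character vector of DEG ids.
#' @export
deg_set <- function(de, q_threshold = 0.05) {
  if (q_threshold >= 1) return(de$gene[de$tested])
  de$gene[de$tested & !is.na(de$q_value) & de$q_value < q_threshold]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity; `NA` values are
#' passed through and excluded from the family.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# Common dispersion by maximizing the NB log-likelihood conditional on
# each design cell's total count, pooled over genes and cells of size
# >= 2. For equal-size NB observations the cell total is sufficient for
# the mean, so this profile is free of the fitted-mean parameters;
# counts arrive already scaled to a common library size, making the
# equal-size conditioning a good approximation.
common_dispersion_cml <- function(yn, groups) {
  if (!nrow(yn)) return(NA_real_)
  loglik <- function(log_phi) {
    r <- exp(-log_phi)  # size = 1/phi
    total <- 0
    for (idx in groups) {
      g <- yn[, idx, drop = FALSE]
      n <- length(idx)
      total <- total + sum(rowSums(lgamma(g + r)) + lgamma(n * r) -
                             lgamma(rowSums(g) + n * r) - n * lgamma(r))
    }
    total
  }
  opt <- stats::optimize(loglik, c(log(1e-6), log(20)), maximum = TRUE)
  exp(opt$maximum)
}

# Negative-binomial IRLS with log link, fixed dispersion phi and offset.
# Returns beta, deviance and a convergence flag.
nb_irls <- function(y, X, offset, phi, max_iter = 50L, tol = 1e-8,
                    ridge = 1e-8) {
  p <- ncol(X)
  mu <- pmax(y, 1 / 6)
  eta <- log(mu)
  beta <- tryCatch(
    qr.solve(crossprod(X) + ridge * diag(p), crossprod(X, eta - offset)),
    error = function(e) rep(0, p))
  eta <- drop(X %*% beta) + offset
  mu <- exp(eta)
  dev <- nb_deviance(y, mu, phi)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    delta <- tryCatch(
      qr.solve(XtW %*% X + ridge * diag(p), XtW %*% z) - beta,
      error = function(e) NULL)
    if (is.null(delta) || anyNA(delta)) break
    step <- 1
    repeat {
      beta_new <- beta + step * drop(delta)
      eta_new <- drop(X %*% beta_new) + offset
      mu_new <- exp(eta_new)
      dev_new <- nb_deviance(y, mu_new, phi)
      if (is.finite(dev_new) && dev_new <= dev + 1e-12) break
      step <- step / 2
      if (step < 1e-10) { dev_new <- dev; beta_new <- beta
        eta_new <- eta; mu_new <- mu; break }
    }
    done <- abs(dev - dev_new) < tol * (abs(dev_new) + 0.1)
    beta <- beta_new; eta <- eta_new; mu <- mu_new; dev <- dev_new
    if (done) { converged <- TRUE; break }
  }
  list(beta = drop(beta), deviance = dev, converged = converged)
}

# NB deviance (Poisson limit for phi ~ 0); y may contain zeros.
nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-300)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (phi < 1e-10) {
    2 * sum(t1 - (y - mu))
  } else {
    2 * sum(t1 - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  }
}
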