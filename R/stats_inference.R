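#' Pooled two-sample t-test from group summaries
#'
#' Student's pooled-variance t with df = n1 + n2 - 2 and a two-sided p,
#' computed directly from group means/SDs/sizes (the form a summary table
#' supports). If both SDs are zero and the means are equal, t is defined
#' as 0.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return Named numeric vector `t`, `df`, `p`.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- if (se == 0) {
    if (mean1 == mean2) 0 else stop("zero pooled SD with unequal means",
                                    call. = FALSE)
  } else {
    (mean1 - mean2) / se
  }
  c(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Case/control summary table for a feature block
#'
#' Per-feature group means, SDs and the pooled two-sample t test.
#'
#' @param X Numeric matrix, participants x features.
#' @param y Binary labels (1 = case, 0 = control).
#' @return data.frame with one row per feature.
#' @export
group_summary <- function(X, y) {
  X <- as.matrix(X)
  case <- X[y == 1, , drop = FALSE]
  ctrl <- X[y == 0, , drop = FALSE]
  rows <- lapply(seq_len(ncol(X)), function(j) {
    tt <- two_sample_t(mean(case[, j]), stats::sd(case[, j]), nrow(case),
                       mean(ctrl[, j]), stats::sd(ctrl[, j]), nrow(ctrl))
    data.frame(feature = colnames(X)[j],
               case_mean = mean(case[, j]), case_sd = stats::sd(case[, j]),
               control_mean = mean(ctrl[, j]), control_sd = stats::sd(ctrl[, j]),
               t = tt[["t"]], df = tt[["df"]], p = tt[["p"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' PCA reduction at a cumulative-variance threshold
#'
#' Features are z-scored, zero-variance columns dropped with a warning, and
#' the minimal number of principal components whose cumulative explained
#' variance reaches the threshold is retained. Component signs follow a
#' deterministic convention: the largest-magnitude loading of each component
#' is positive.
#'
#' @param X Numeric matrix, participants x features.
#' @param cum_var_threshold Cumulative explained-variance target
#'   (default 0.95).
#' @return List of class `pca_result`: `loadings`, `scores` (all
#'   components), `explained_variance_ratio`, `n_retained`,
#'   `dropped_features`, `center`, `scale`.
#' @export
pca_reduce <- function(X, cum_var_threshold = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA needs >= 2 participants", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped), " zero-variance feature(s) before PCA")
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(ncol(rot)))
  out <- list(loadings = rot, scores = scores,
              explained_variance_ratio = ratio,
              n_retained = which(cumsum(ratio) >= cum_var_threshold)[1],
              dropped_features = dropped,
              center = pc$center, scale = pc$scale)
  class(out) <- "pca_result"
  out
}

#' Retained PC scores of a PCA result
#' @param pca A `pca_result`.
#' @return Score matrix restricted to the retained components.
#' @export
retained_scores <- function(pca) {
  pca$scores[, seq_len(pca$n_retained), drop = FALSE]
}

# IRLS logistic fit on a design matrix (first column should be the
# intercept). Returns coefficients, SEs, log-likelihood and a separation
# flag. Ridge lambda > 0 gives the penalized fallback used under perfect
# separation (intercept unpenalized).
fit_logistic <- function(Xd, y, lambda = 0) {
  p <- ncol(Xd)
  beta <- rep(0, p)
  pen <- c(0, rep(lambda, p - 1))
  for (it in 1:100) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, Xd * w) + diag(pen, p)
    g <- crossprod(Xd, y - mu) - pen * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(Xd %*% beta)
  mu <- 1 / (1 + exp(-eta))
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  w <- pmax(mu * (1 - mu), 1e-10)
  vc <- tryCatch(solve(crossprod(Xd, Xd * w) + diag(pen, p)),
                 error = function(e) matrix(NA_real_, p, p))
  # scale-invariant separation heuristics: a (near-)perfect fit, or a term
  # whose standardized coefficient has diverged
  std_beta <- if (p > 1) {
    abs(beta[-1]) * apply(Xd[, -1, drop = FALSE], 2, stats::sd)
  } else 0
  separated <- ll > -1e-4 * length(y) || any(std_beta > 15)
  list(beta = beta, se = sqrt(diag(vc)), loglik = ll, separated = separated)
}

#' Stepwise forward logistic regression
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' predictor with the smallest entry p-value while that p-value is below
#' `alpha`; the model is refit at every step. The entry test is the
#' likelihood-ratio test by default (Wald optional). The final model is
#' reported with per-term beta, SE, Wald statistic (beta/SE)^2, odds ratio
#' exp(beta), raw Wald p and a multiplicity-corrected p over the final
#' model's terms (Holm by default): selection operates on raw p-values and
#' correction is applied post hoc for reporting, so retained terms may have
#' corrected p above `alpha`.
#'
#' Under perfect separation the reported fit falls back to a weakly
#' ridge-penalized logistic regression and is flagged.
#'
#' @param X Named numeric predictor matrix (no missing values).
#' @param y Binary response (1 = case).
#' @param alpha Entry threshold on the raw entry p-value (default 0.05).
#' @param criterion "lrt" (default) or "wald" entry test.
#' @param correction "holm" (default) or "bonferroni".
#' @param max_terms Optional cap on the number of selected terms.
#' @return List of class `logistic_fit`: `terms` (data.frame with beta, se,
#'   wald, odds_ratio, p_raw, p_corrected), `selected` (in entry order),
#'   `loglik_null`, `loglik_model`, `n`, `nagelkerke_r2`, `separation`.
#' @export
stepwise_logistic <- function(X, y, alpha = 0.05,
                              criterion = c("lrt", "wald"),
                              correction = c("holm", "bonferroni"),
                              max_terms = Inf) {
  criterion <- match.arg(criterion)
  correction <- match.arg(correction)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  y <- as.numeric(y)
  n <- length(y)
  ones <- matrix(1, n, 1)
  null_fit <- fit_logistic(ones, y)
  ll0 <- null_fit$loglik

  selected <- character(0)
  cur_ll <- ll0
  remaining <- colnames(X)
  while (length(remaining) > 0 && length(selected) < max_terms) {
    ps <- vapply(remaining, function(cand) {
      Xd <- cbind(ones, X[, c(selected, cand), drop = FALSE])
      f <- fit_logistic(Xd, y)
      if (criterion == "lrt") {
        stats::pchisq(2 * (f$loglik - cur_ll), df = 1, lower.tail = FALSE)
      } else {
        k <- ncol(Xd)
        stats::pchisq((f$beta[k] / f$se[k])^2, df = 1, lower.tail = FALSE)
      }
    }, numeric(1))
    best <- which.min(ps)
    if (!is.finite(ps[best]) || ps[best] >= alpha) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
    cur_ll <- fit_logistic(cbind(ones, X[, selected, drop = FALSE]), y)$loglik
  }

  Xd <- cbind(ones, X[, selected, drop = FALSE])
  fit <- fit_logistic(Xd, y)
  separation <- fit$separated
  if (separation && length(selected) > 0) {
    warning("perfect separation detected; reporting ridge-penalized fit")
    fit <- fit_logistic(Xd, y, lambda = 1e-2)
  }
  if (length(selected) > 0) {
    b <- fit$beta[-1]; se <- fit$se[-1]
    wald <- (b / se)^2
    p_raw <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
    terms <- data.frame(term = selected, beta = b, se = se, wald = wald,
                        odds_ratio = exp(b), p_raw = p_raw,
                        p_corrected = stats::p.adjust(p_raw, method = correction),
                        stringsAsFactors = FALSE)
    rownames(terms) <- NULL
  } else {
    terms <- data.frame(term = character(), beta = numeric(), se = numeric(),
                        wald = numeric(), odds_ratio = numeric(),
                        p_raw = numeric(), p_corrected = numeric(),
                        stringsAsFactors = FALSE)
  }
  out <- list(terms = terms, selected = selected,
              loglik_null = ll0, loglik_model = fit$loglik, n = n,
              nagelkerke_r2 = nagelkerke_r2(ll0, fit$loglik, n),
              separation = separation)
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n=%d, %d term(s), Nagelkerke R2 = %.4f\n",
              x$n, nrow(x$terms), x$nagelkerke_r2))
  if (nrow(x$terms) > 0) print(x$terms, digits = 3)
  invisible(x)
}

#' Nagelkerke pseudo R-squared
#'
#' The Cox-Snell pseudo R2, 1 - exp(2 (ll0 - ll1) / n), rescaled by its
#' maximum attainable value 1 - exp(2 ll0 / n) so the result lies in [0, 1].
#'
#' @param loglik_null Log-likelihood of the intercept-only model.
#' @param loglik_model Log-likelihood of the fitted model (>= null).
#' @param n Number of observations.
#' @return Scalar in [0, 1].
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_model, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (loglik_null == 0) {
    stop("degenerate null model (log-likelihood 0)", call. = FALSE)
  }
  if (loglik_model < loglik_null - 1e-8) {
    stop("model log-likelihood below null", call. = FALSE)
  }
  r2_cs <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  max_cs <- 1 - exp(2 * loglik_null / n)
  min(1, max(0, r2_cs / max_cs))
}

#' Pearson correlations between retained PCs and original features
#'
#' One row per retained component, one column per original feature; a
#' zero-variance feature yields NA.
#'
#' @param pca A `pca_result`.
#' @param original Numeric matrix of original features (same participants,
#'   same row order as the PCA input).
#' @return Matrix of Pearson r, components x features.
#' @export
pc_feature_correlations <- function(pca, original) {
  original <- as.matrix(original)
  sc <- retained_scores(pca)
  if (nrow(original) != nrow(sc)) {
    stop("participant sets do not match", call. = FALSE)
  }
  out <- suppressWarnings(stats::cor(sc, original))
  sds <- apply(original, 2, stats::sd)
  out[, sds == 0] <- NA_real_
  out
}
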