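#' Generalized estimating equations with slices as clusters
#'
#' Marginal Gaussian-identity regression of a per-ROI outcome on condition
#' terms, with an exchangeable working correlation within slices and
#' cluster-robust (sandwich) standard errors, so each brain slice acts as
#' the independent unit while its ROIs inform the mean and its precision.
#' Inference uses z (normal) reference distributions, the GEE convention.
#'
#' The estimating equations are solved by iterating between (i) generalized
#' least squares given the working correlation and (ii) moment estimation of
#' the common intra-cluster correlation from Pearson residuals. The robust
#' covariance is the usual sandwich
#' \deqn{B^{-1} M B^{-1},\quad B = \sum_i X_i' V_i^{-1} X_i,\quad
#'       M = \sum_i X_i' V_i^{-1} r_i r_i' V_i^{-1} X_i.}
#'
#' @param data Data frame of per-ROI observations (e.g. an effects table).
#' @param outcome Name of the numeric outcome column (default `"delta_r"`).
#' @param terms Character vector of model terms (column names or interaction
#'   expressions like `"neuron_type:phase"`); empty for an intercept-only
#'   model.
#' @param cluster Name of the cluster column (default `"slice_id"`).
#' @param corstr `"exchangeable"` (default) or `"independence"`.
#' @param cov_type Sandwich flavour: `"md"` (default) applies the
#'   Mancl-DeRouen bias correction, which keeps test size near nominal at
#'   realistic cluster counts (10-20 slices); `"robust"` is the classic
#'   uncorrected sandwich (liberal with few clusters); `"cr1"` scales the
#'   classic sandwich by `m/(m-1)`.
#' @param max_iter,tol Iteration controls.
#' @return Object of class `gee_fit` with elements `coefficients`,
#'   `robust_se`, `z`, `p_value`, `rho` (working correlation), `n_clusters`,
#'   `n_obs`, `corstr`, `terms`, `vbeta` (robust covariance).
#' @export
fit_gee <- function(data, outcome = "delta_r", terms = character(),
                    cluster = "slice_id",
                    corstr = c("exchangeable", "independence"),
                    cov_type = c("md", "robust", "cr1"),
                    max_iter = 50L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  cov_type <- match.arg(cov_type)
  stopifnot(outcome %in% names(data), cluster %in% names(data))
  y <- data[[outcome]]
  keep <- is.finite(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  cl <- as.character(data[[cluster]])
  ids <- unique(cl)
  if (length(ids) < 2L)
    stop("single cluster: clustered GEE is not identified; use a t-test instead",
         call. = FALSE)
  rhs <- if (length(terms)) stats::reformulate(terms) else ~1
  for (v in all.vars(rhs)) {
    if (is.character(data[[v]]) || is.factor(data[[v]])) {
      if (length(unique(data[[v]])) < 2L)
        stop(sprintf("term '%s' has a single level in the data", v), call. = FALSE)
    }
  }
  X <- stats::model.matrix(rhs, data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; aliased term(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  p <- ncol(X)
  n <- length(y)

  Xi <- split.data.frame(X, cl)[ids]
  yi <- split(y, factor(cl, levels = ids))

  beta <- qr.coef(qrX, y)            # OLS start
  rho <- 0
  for (iter in seq_len(max_iter)) {
    resid <- y - drop(X %*% beta)
    phi <- sum(resid^2) / (n - p)
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      ri <- split(resid, factor(cl, levels = ids))
      for (r in ri) {
        ni <- length(r)
        if (ni > 1L) {
          num <- num + (sum(r)^2 - sum(r^2)) / 2
          den <- den + ni * (ni - 1) / 2
        }
      }
      rho_new <- if (den > p) num / ((den - p) * phi) else 0
      rho_new <- max(min(rho_new, 0.99), -0.49)
    } else rho_new <- 0
    B <- matrix(0, p, p)
    u <- numeric(p)
    for (i in seq_along(ids)) {
      Xc <- Xi[[i]]; yc <- yi[[i]]; ni <- length(yc)
      Vinv <- .exch_inverse(ni, rho_new) / phi
      XtV <- crossprod(Xc, Vinv)
      B <- B + XtV %*% Xc
      u <- u + XtV %*% yc
    }
    beta_new <- drop(solve(B, u))
    done <- max(abs(beta_new - beta)) < tol && abs(rho_new - rho) < tol
    beta <- beta_new
    rho <- rho_new
    if (done) break
  }

  resid <- y - drop(X %*% beta)
  phi <- sum(resid^2) / (n - p)
  B <- matrix(0, p, p)
  ri <- split(resid, factor(cl, levels = ids))
  XtVs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    Xc <- Xi[[i]]; ni <- nrow(Xc)
    Vinv <- .exch_inverse(ni, rho) / phi
    XtVs[[i]] <- crossprod(Xc, Vinv)
    B <- B + XtVs[[i]] %*% Xc
  }
  Binv <- solve(B)
  M <- matrix(0, p, p)
  for (i in seq_along(ids)) {
    r_i <- ri[[i]]
    if (cov_type == "md") {
      # Mancl-DeRouen: inflate residuals by (I - H_i)^{-1}, H_i the
      # cluster leverage; corrects the downward bias of the plain
      # sandwich with few clusters
      H <- Xi[[i]] %*% Binv %*% XtVs[[i]]
      r_i <- solve(diag(nrow(H)) - H, r_i)
    }
    s <- drop(XtVs[[i]] %*% r_i)
    M <- M + tcrossprod(s)
  }
  m <- length(ids)
  scale <- if (cov_type == "cr1") m / (m - 1) else 1
  vbeta <- scale * Binv %*% M %*% Binv
  se <- sqrt(diag(vbeta))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  names(beta) <- names(se) <- names(z) <- names(pv) <- colnames(X)
  structure(list(coefficients = beta, robust_se = se, z = z, p_value = pv,
                 rho = rho, phi = phi, n_clusters = length(ids), n_obs = n,
                 corstr = corstr, cov_type = cov_type, terms = terms,
                 outcome = outcome, vbeta = vbeta),
            class = "gee_fit")
}

# Inverse of the exchangeable correlation matrix (1-rho) I + rho J, in
# closed form: a I + b J with a = 1/(1-rho), b = -rho / ((1-rho)(1+(n-1)rho)).
.exch_inverse <- function(n, rho) {
  if (n == 1L || rho == 0) return(diag(n))
  a <- 1 / (1 - rho)
  b <- -rho / ((1 - rho) * (1 + (n - 1) * rho))
  diag(a, n) + matrix(b, n, n)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("<gee_fit> %s outcome, %s working correlation (rho = %.3f), %d clusters / %d obs\n",
              x$outcome, x$corstr, x$rho, x$n_clusters, x$n_obs))
  tab <- data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                    z = x$z, p = x$p_value)
  print(format(tab, digits = 4))
  invisible(x)
}

#' Coefficient table of a GEE fit
#' @param fit A `gee_fit`.
#' @return Data frame with term, estimate, robust SE, z, p.
#' @export
gee_table <- function(fit) {
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             robust_se = unname(fit$robust_se),
             z = unname(fit$z), p = unname(fit$p_value),
             stringsAsFactors = FALSE)
}

#' Compare one term between two independently fitted GEE models
#'
#' Used to compare drug effects between the bicarbonate- and HEPES-buffered
#' datasets: the z statistic is the difference of the two estimates divided
#' by the standard error of the difference, and significance is declared
#' against a Bonferroni-adjusted threshold `0.05 / n_comparisons`.
#'
#' @param fit_a,fit_b `gee_fit` objects from disjoint datasets.
#' @param term Coefficient name present in both fits.
#' @param n_comparisons Number of planned cross-model comparisons.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Object of class `cross_model_comparison` with `z`, `p_raw`,
#'   `alpha_adjusted`, `significant`.
#' @export
compare_across_solutions <- function(fit_a, fit_b, term, n_comparisons = 1L,
                                     alpha = 0.05) {
  for (f in list(fit_a, fit_b)) {
    if (!term %in% names(f$coefficients))
      stop(sprintf("term '%s' absent from a fit (has: %s)", term,
                   paste(names(f$coefficients), collapse = ", ")), call. = FALSE)
  }
  d <- fit_a$coefficients[[term]] - fit_b$coefficients[[term]]
  se <- sqrt(fit_a$robust_se[[term]]^2 + fit_b$robust_se[[term]]^2)
  z <- d / se
  p <- 2 * stats::pnorm(-abs(z))
  alpha_adj <- alpha / n_comparisons
  structure(list(term = term, estimate_a = fit_a$coefficients[[term]],
                 estimate_b = fit_b$coefficients[[term]],
                 difference = d, se_difference = se, z = z, p_raw = p,
                 n_comparisons = n_comparisons, alpha_adjusted = alpha_adj,
                 significant = p < alpha_adj),
            class = "cross_model_comparison")
}

#' @export
print.cross_model_comparison <- function(x, ...) {
  cat(sprintf("<cross_model_comparison> '%s': diff %.4g (SE %.3g), z = %.3f, p = %.3g (Bonferroni alpha = %.3g)%s\n",
              x$term, x$difference, x$se_difference, x$z, x$p_raw,
              x$alpha_adjusted,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Paired t-test for electrophysiology summaries
#'
#' Two-sided paired Student's t-test on `post - pre` differences, e.g.
#' reversal potentials before and after a transporter blocker.
#'
#' @param pre,post Equal-length numeric vectors (n >= 2).
#' @return List with `t`, `p`, `mean_diff`, `se_diff`, `df`, `n`, and a
#'   `degenerate` flag set when the differences have zero variance (then `p`
#'   is the limiting value 0 for a nonzero mean difference, 1 otherwise).
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length", call. = FALSE)
  if (length(pre) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- post - pre
  m <- mean(d)
  s <- stats::sd(d)
  n <- length(d)
  if (s == 0) {
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                p = if (m == 0) 1 else 0,
                mean_diff = m, se_diff = 0, df = n - 1L, n = n,
                degenerate = TRUE))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = m,
       se_diff = s / sqrt(n), df = unname(tt$parameter), n = n,
       degenerate = FALSE)
}

#' Serialize inference results to JSON
#'
#' Writes the coefficient table, cluster counts, and optional cross-model
#' comparisons, in the conventional "GEE, p < ..." reporting style.
#'
#' @param fit A `gee_fit`.
#' @param comparisons Optional list of `cross_model_comparison` objects.
#' @param path Output JSON path.
#' @export
write_inference <- function(fit, path, comparisons = NULL) {
  obj <- list(model = list(corstr = fit$corstr, rho = fit$rho,
                           n_clusters = fit$n_clusters, n_obs = fit$n_obs,
                           outcome = fit$outcome),
              coefficients = gee_table(fit))
  if (length(comparisons)) {
    obj$cross_model <- do.call(rbind, lapply(comparisons, function(cmp) {
      data.frame(term = cmp$term, difference = cmp$difference,
                 se = cmp$se_difference, z = cmp$z, p_raw = cmp$p_raw,
                 alpha_adjusted = cmp$alpha_adjusted,
                 significant = cmp$significant, stringsAsFactors = FALSE)
    }))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
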