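#' Transformed estimate and standard error from a reported 95% CI
#'
#' Published penetrance estimates come as a point estimate with a 95%
#' confidence interval on the percentage scale. For pooling, the estimate is
#' moved to a working scale (logit, log, or identity on the proportion) and
#' its standard error recovered from the full CI width:
#' `se = (transform(hi) - transform(lo)) / (2 * 1.96)`. The full-width
#' formula accommodates CIs that are asymmetric around the estimate, as is
#' typical for proportions near the boundary.
#'
#' @param estimate point estimate on the 0-100 scale.
#' @param ci_low,ci_high 95% bounds on the 0-100 scale.
#' @param scale `"logit"` (default), `"log"`, or `"identity"`.
#' @return list with `theta` (transformed estimate) and `se`.
#' @export
se_from_ci <- function(estimate, ci_low, ci_high,
                       scale = c("logit", "log", "identity")) {
  scale <- match.arg(scale)
  if (any(is.na(c(estimate, ci_low, ci_high)))) {
    stop_kinpen("estimate and CI bounds must be present")
  }
  if (ci_low > estimate || estimate > ci_high) {
    stop_kinpen("CI bounds must bracket the estimate")
  }
  if (any(c(estimate, ci_low, ci_high) < 0) ||
      any(c(estimate, ci_low, ci_high) > 100)) {
    stop_kinpen("penetrance values must lie in [0, 100]")
  }
  if (scale != "identity" &&
      (ci_low <= 0 || ci_high >= 100 || estimate <= 0 || estimate >= 100)) {
    stop_kinpen(
      "a bound at 0 or 100 cannot be transformed on the ", scale,
      " scale; apply a continuity adjustment to the study first"
    )
  }
  trans <- switch(scale,
                  logit = function(x) stats::qlogis(x / 100),
                  log = function(x) log(x / 100),
                  identity = function(x) x)
  z <- stats::qnorm(0.975)
  list(
    theta = trans(estimate),
    se = (trans(ci_high) - trans(ci_low)) / (2 * z)
  )
}

.back_transform <- function(theta, scale) {
  switch(scale,
         logit = 100 * stats::plogis(theta),
         log = 100 * exp(theta),
         identity = theta)
}

#' DerSimonian-Laird random-effects pooling of study estimates
#'
#' Pools per-study penetrance estimates (point + 95% CI on the 0-100 scale)
#' with the DerSimonian-Laird moment estimator of between-study variance.
#' On the working scale: fixed-effect weights `w0_i = 1/se_i^2` give the
#' heterogeneity statistic `Q = sum w0_i (theta_i - theta_fixed)^2`;
#' `tau2 = max(0, (Q - (k-1)) / (sum(w0) - sum(w0^2)/sum(w0)))`; random
#' weights `w_i = 1/(se_i^2 + tau2)` give the pooled estimate and its normal
#' CI, which is back-transformed to the percentage scale. Heterogeneity is
#' tested against a chi-squared distribution with `k - 1` degrees of
#' freedom.
#'
#' @param studies data.frame with columns `study`, `estimate`, `ci_low`,
#'   `ci_high` (0-100 scale); other columns are ignored.
#' @param scale working scale passed to [se_from_ci()].
#' @return object of class `meta_result`: pooled `estimate`, `ci_low`,
#'   `ci_high` (0-100 scale), `Q`, `df`, `p_het`, `tau2` (working scale),
#'   normalized `weights`, `k`, `scale`.
#' @export
dl_pool <- function(studies, scale = c("logit", "log", "identity")) {
  scale <- match.arg(scale)
  k <- nrow(studies)
  if (is.null(k) || k < 2L) stop_kinpen("at least two studies are required")
  if (any(studies$ci_low > studies$ci_high)) {
    stop_kinpen("malformed CI: lower bound above upper bound")
  }
  ts <- lapply(seq_len(k), function(i) {
    se_from_ci(studies$estimate[i], studies$ci_low[i], studies$ci_high[i],
               scale)
  })
  theta <- vapply(ts, `[[`, numeric(1), "theta")
  se <- vapply(ts, `[[`, numeric(1), "se")

  if (any(se == 0)) {
    if (length(unique(theta[se == 0])) > 1L ||
        any(theta[se > 0] != theta[se == 0][1L])) {
      stop_kinpen("zero-width CI with discordant estimates cannot be pooled")
    }
    # all information concentrated on one common value
    est <- .back_transform(theta[1L], scale)
    return(structure(
      list(estimate = est, ci_low = est, ci_high = est,
           Q = 0, df = k - 1L, p_het = 1, tau2 = 0,
           weights = ifelse(se == 0, 1 / sum(se == 0), 0),
           k = k, scale = scale),
      class = "meta_result"
    ))
  }

  w0 <- 1 / se^2
  theta_fixed <- sum(w0 * theta) / sum(w0)
  Q <- sum(w0 * (theta - theta_fixed)^2)
  df <- k - 1L
  tau2 <- max(0, (Q - df) / (sum(w0) - sum(w0^2) / sum(w0)))
  w <- 1 / (se^2 + tau2)
  theta_pool <- sum(w * theta) / sum(w)
  se_pool <- 1 / sqrt(sum(w))
  z <- stats::qnorm(0.975)
  structure(
    list(
      estimate = .back_transform(theta_pool, scale),
      ci_low = .back_transform(theta_pool - z * se_pool, scale),
      ci_high = .back_transform(theta_pool + z * se_pool, scale),
      Q = Q, df = df,
      p_het = stats::pchisq(Q, df, lower.tail = FALSE),
      tau2 = tau2,
      weights = w / sum(w),
      k = k, scale = scale
    ),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "DL random-effects pooled estimate (%s scale): %.1f (95%% CI %.1f-%.1f)\n",
    x$scale, x$estimate, x$ci_low, x$ci_high
  ))
  cat(sprintf("  k = %d; Q = %.3f on %d df (p = %.3f); tau2 = %.4g\n",
              x$k, x$Q, x$df, x$p_het, x$tau2))
  invisible(x)
}

#' Read a study-estimates table for meta-analysis
#'
#' Expects a delimited file with columns `study`, `gene`, `age_interval`,
#' `estimate`, `ci_low`, `ci_high` (percentage scale). Lines starting with
#' `#` are ignored.
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame of study estimates.
#' @export
read_study_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop_kinpen("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE,
                          strip.white = TRUE)
  need <- c("study", "gene", "age_interval", "estimate", "ci_low", "ci_high")
  if (!all(need %in% names(df))) {
    stop_kinpen("study table must have columns: ",
                paste(need, collapse = ", "))
  }
  if (any(df$ci_low > df$estimate | df$estimate > df$ci_high)) {
    stop_kinpen("malformed study row: CI does not bracket the estimate")
  }
  df
}
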