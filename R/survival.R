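#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival curve
#' \eqn{\hat S(t) = \prod_{t_k \le t} (1 - d_k / n_k)} over the distinct
#' event times, with censored-only times entering the risk sets but adding no
#' step. The curve starts at \eqn{S(0) = 1} and is right-continuous.
#'
#' @param time Positive follow-up times (months).
#' @param event 0/1 event indicator (1 = event observed).
#' @return A `km_curve` tibble with columns `time`, `n_risk`, `n_event`,
#'   `survival`, beginning with the (0, n, 0, 1) anchor row.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) abort("at least one subject is required")
  if (any(!is.finite(time)) || any(time <= 0)) abort("times must be positive and finite")
  if (!all(event %in% c(0, 1))) abort("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  keep <- fit$n.event > 0
  out <- tibble(
    time = c(0, fit$time[keep]),
    n_risk = c(fit$n, fit$n.risk[keep]),
    n_event = c(0L, as.integer(fit$n.event[keep])),
    survival = c(1, fit$surv[keep])
  )
  class(out) <- c("km_curve", class(out))
  out
}

# ---- log-rank machinery -----------------------------------------------------
# The minimum-p cutoff scan needs the one-degree-of-freedom log-rank statistic
# evaluated over hundreds of candidate dichotomizations (and, for permutation
# calibration, thousands of score permutations), so the statistic is computed
# here directly from the aggregated risk-set counts and vectorized over group
# assignments; survdiff() agrees with the single-assignment path but cannot be
# batched.

# rowsum over all K bins, including empty ones
rowsum_full <- function(M, idx, K) {
  out <- matrix(0, K, ncol(M))
  if (nrow(M)) {
    rs <- rowsum(M, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

# chi2 of the log-rank test for each column of G (n x C membership matrix,
# TRUE = "high" group). Returns list(chi2, observed, expected) per column.
logrank_scan_chi2 <- function(time, event, G) {
  G <- as.matrix(G) * 1
  n <- length(time)
  ut <- sort(unique(time))
  idx <- match(time, ut)
  K <- length(ut)
  d_all <- tabulate(idx[event == 1], K)
  m_all <- tabulate(idx, K)
  n_all <- n - c(0, cumsum(m_all)[-K])
  ev <- event == 1
  m_hi <- rowsum_full(G, idx, K)
  d_hi <- rowsum_full(G[ev, , drop = FALSE], idx[ev], K)
  cum_left <- apply(m_hi, 2, cumsum)
  n_hi <- matrix(colSums(G), K, ncol(G), byrow = TRUE) -
    rbind(0, cum_left[-K, , drop = FALSE])
  frac <- n_hi / n_all
  E <- d_all * frac
  vfac <- d_all * (n_all - d_all) / pmax(n_all - 1, 1)
  vfac[n_all <= 1] <- 0
  V <- vfac * frac * (1 - frac)
  U <- colSums(d_hi - E)
  Vs <- colSums(V)
  chi2 <- ifelse(Vs > 0, U^2 / Vs, 0)
  list(chi2 = chi2, observed = colSums(d_hi), expected = colSums(E), variance = Vs)
}

#' Two-group log-rank test
#'
#' One-degree-of-freedom log-rank test: observed minus expected events summed
#' over distinct event times with the hypergeometric variance; the p-value is
#' the upper tail of \eqn{\chi^2_1}.
#'
#' @inheritParams km_estimate
#' @param group Two-level group assignment (logical, factor or 2-valued
#'   vector); the second sorted level (or `TRUE`) is taken as "high".
#' @return One-row tibble: `statistic`, `df`, `p_value`, `observed_high`,
#'   `expected_high`, `n`, `n_events`.
#' @examples
#' logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
#' @export
logrank_test <- function(time, event, group) {
  if (any(!is.finite(time)) || any(time <= 0)) abort("times must be positive and finite")
  if (!all(event %in% c(0, 1))) abort("event must be 0/1")
  g <- as.factor(group)
  g <- droplevels(g)
  if (nlevels(g) != 2) abort("group must have exactly two non-empty levels")
  if (sum(event) < 1) abort("at least one event is required")
  hi <- g == levels(g)[2]
  st <- logrank_scan_chi2(time, event, matrix(hi, ncol = 1))
  tibble(statistic = st$chi2, df = 1L,
         p_value = pchisq(st$chi2, df = 1, lower.tail = FALSE),
         observed_high = st$observed, expected_high = st$expected,
         n = length(time), n_events = sum(event))
}

# ---- Cox proportional hazards ----------------------------------------------

#' Fit a Cox proportional-hazards model
#'
#' Wraps [survival::coxph()] (partial-likelihood maximization, Efron tie
#' handling by default) and reports per-term hazard ratios with Wald 95%
#' confidence intervals. Complete cases only; the n actually used is
#' reported. A monotone partial likelihood (perfect separation, infinite
#' coefficient) yields a flagged result rather than a silent one.
#'
#' @param design Data frame of covariates (numeric, factor or character;
#'   characters become reference-coded factors).
#' @param time,event Survival outcome (months, 0/1).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit`: list with `terms` (tibble: `term`, `estimate`, `se`,
#'   `hr`, `ci_low`, `ci_high`, `p_value`), `loglik`, `n`, `n_events`,
#'   `flagged`, `ties`.
#' @examples
#' fit_cox(data.frame(x = c(1, 0, 1, 0)), c(1, 2, 3, 4), c(1, 1, 1, 1))
#' @export
fit_cox <- function(design, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  design <- as.data.frame(design)
  if (!nrow(design) || nrow(design) != length(time))
    abort("design must have one row per subject")
  if (!all(event %in% c(0, 1))) abort("event must be 0/1")
  if (sum(event) < 1) abort("at least one event is required")
  cc <- complete.cases(design) & is.finite(time)
  for (nm in names(design)) {
    v <- design[[nm]][cc]
    nuniq <- length(unique(v))
    if (nuniq < 2)
      abort(paste0("covariate '", nm, "' is constant across subjects"))
  }
  dat <- design[cc, , drop = FALSE]
  dat$.time <- time[cc]
  dat$.event <- event[cc]
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(design)), collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite|converged before", msg)) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("did not converge|out of iterations", msg)) {
        abort(paste0("Cox model failed to converge within 100 iterations: ", msg))
      }
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z975 <- qnorm(0.975)
  terms <- tibble(
    term = names(beta),
    estimate = unname(beta),
    se = unname(se),
    hr = exp(unname(beta)),
    ci_low = exp(unname(beta) - z975 * unname(se)),
    ci_high = exp(unname(beta) + z975 * unname(se)),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / unname(se)))
  )
  structure(list(terms = terms, loglik = fit$loglik[2], n = fit$n,
                 n_events = fit$nevent, flagged = flagged, ties = ties,
                 score_test = unname(summary(fit)$sctest["test"]),
                 coxph = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n = ", x$n, ", events = ", x$n_events,
      if (x$flagged) " [flagged: monotone likelihood]", "\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) x$terms

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(loglik = x$loglik, n = x$n, n_events = x$n_events,
         flagged = x$flagged, ties = x$ties)
}

# ---- minimum-p cutoff scan --------------------------------------------------

#' Scan score cutoffs in the interquartile range for the best split
#'
#' Implements minimum-p optimal-cutpoint dichotomization: every distinct
#' score value whose quantile rank lies in `window` (the 25th-75th percentile
#' band by default) and which leaves both groups at least `min_group` strong
#' is a candidate; for each, samples are split at `score > cutoff` ("high")
#' and the two groups compared by log-rank. The cutoff with the smallest
#' p-value wins (ties: smallest cutoff). The selected split is summarized by
#' the Cox hazard ratio of high vs low and both Kaplan-Meier curves.
#'
#' Because the reported p-value is a minimum over many correlated tests it is
#' anti-conservative; set `n_perm > 0` to also estimate a selection-adjusted
#' p-value by permuting the score against the outcomes and recomputing the
#' minimum p each time. Multiple-testing control across signatures or strata
#' (e.g. Benjamini-Hochberg) is a separate, additional step.
#'
#' @param score Numeric score per subject, or a tibble with columns
#'   `sample_id` and `score` aligned to `time`/`event` order.
#' @inheritParams km_estimate
#' @param window Quantile-rank window for candidate cutoffs, default
#'   `c(0.25, 0.75)`.
#' @param min_group Minimum size of each group at any candidate (default 5).
#' @param n_perm Number of score permutations for the selection-adjusted
#'   p-value (0 = skip).
#' @param seed Seed for the permutation stream.
#' @return A `cutoff_scan`: list with `candidates` (tibble: `cutoff`,
#'   `statistic`, `p_value`, `n_low`, `n_high`), `cutoff`, `statistic`,
#'   `p_value` (the unadjusted minimum), `p_permutation` (or NA), `n_perm`,
#'   `n_candidates`, `group` (factor high/low per subject), `fit` (Cox
#'   `cox_fit` of the high indicator), `km` (both groups' curves, stacked),
#'   and `multiplicity_note`.
#' @export
scan_cutoffs <- function(score, time, event, window = c(0.25, 0.75),
                         min_group = 5, n_perm = 0, seed = NULL) {
  if (is.data.frame(score)) score <- score$score
  n <- length(score)
  if (n != length(time)) abort("score and time lengths differ")
  if (any(!is.finite(score))) abort("scores must be finite")
  if (length(window) != 2 || window[1] >= window[2] || window[1] < 0 || window[2] > 1)
    abort("window must be (low, high) within [0, 1]")
  if (n < 2 * min_group) abort("need at least 2 * min_group samples")
  qrank <- ecdf(score)(score)
  cand <- sort(unique(score[qrank >= window[1] & qrank <= window[2]]))
  if (length(cand)) {
    n_high <- vapply(cand, function(v) sum(score > v), integer(1))
    ok <- n_high >= min_group & (n - n_high) >= min_group
    cand <- cand[ok]
    n_high <- n_high[ok]
  }
  if (length(cand) < 2)
    abort("fewer than 2 candidate cutoffs in the quantile window")
  G <- outer(score, cand, `>`)
  st <- logrank_scan_chi2(time, event, G)
  pvals <- pchisq(st$chi2, df = 1, lower.tail = FALSE)
  candidates <- tibble(cutoff = cand, statistic = st$chi2, p_value = pvals,
                       n_high = n_high, n_low = n - n_high)
  best <- which.min(pvals)   # ties resolve to the smallest cutoff
  cutoff <- cand[best]
  group <- factor(ifelse(score > cutoff, "high", "low"), levels = c("low", "high"))
  fit <- fit_cox(data.frame(group = as.integer(group == "high")), time, event)
  km <- bind_rows(
    mutate(km_estimate(time[group == "low"], event[group == "low"]), group = "low"),
    mutate(km_estimate(time[group == "high"], event[group == "high"]), group = "high")
  )
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    p_min_obs <- pvals[best]
    chunk <- max(1L, as.integer(2e7 / (n * length(cand))))
    hits <- 0L
    done <- 0L
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      Gp <- matrix(FALSE, n, length(cand) * b)
      for (j in seq_len(b)) {
        prm <- sample.int(n)
        Gp[, (j - 1) * length(cand) + seq_along(cand)] <- G[prm, ]
      }
      chi <- logrank_scan_chi2(time, event, Gp)$chi2
      chi <- matrix(chi, nrow = length(cand))
      pm <- pchisq(apply(chi, 2, max), df = 1, lower.tail = FALSE)
      hits <- hits + sum(pm <= p_min_obs)
      done <- done + b
    }
    p_perm <- (1 + hits) / (n_perm + 1)
  }
  structure(list(
    candidates = candidates, cutoff = cutoff, statistic = st$chi2[best],
    p_value = pvals[best], p_permutation = p_perm, n_perm = n_perm,
    n_candidates = length(cand), group = group, fit = fit, km = km,
    multiplicity_note = paste0(
      "p_value is the unadjusted minimum over ", length(cand),
      " candidate cutoffs and overstates significance; ",
      if (n_perm > 0) "p_permutation is the selection-adjusted estimate."
      else "set n_perm > 0 for a selection-adjusted estimate.")
  ), class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat("<cutoff_scan> ", x$n_candidates, " candidates; selected cutoff ",
      signif(x$cutoff, 5), " (log-rank p = ", signif(x$p_value, 3), ")\n", sep = "")
  cat("  high vs low HR = ", signif(x$fit$terms$hr, 4), " [",
      signif(x$fit$terms$ci_low, 4), ", ", signif(x$fit$terms$ci_high, 4), "]\n", sep = "")
  if (!is.na(x$p_permutation))
    cat("  selection-adjusted p (", x$n_perm, " permutations) = ",
        signif(x$p_permutation, 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy cutoff_scan
#' @export
tidy.cutoff_scan <- function(x, ...) x$candidates

#' @method glance cutoff_scan
#' @export
glance.cutoff_scan <- function(x, ...) {
  tibble(cutoff = x$cutoff, statistic = x$statistic, p_value = x$p_value,
         p_permutation = x$p_permutation, n_candidates = x$n_candidates,
         n_high = sum(x$group == "high"), n_low = sum(x$group == "low"),
         hr = x$fit$terms$hr, ci_low = x$fit$terms$ci_low,
         ci_high = x$fit$terms$ci_high)
}

# ---- multiple testing and adjusted models -----------------------------------

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j} clipped to 1, returned in the
#' input order. Tests are flagged significant at `fdr` (default 0.10, i.e.
#' FDR below 10%).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param fdr Significance threshold on the q-value.
#' @return Tibble `p_value`, `q_value`, `significant`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p, fdr = 0.10) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    abort("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  tibble(p_value = p, q_value = q, significant = q < fdr)
}

#' Two-variable Cox model: signature plus one clinical covariate
#'
#' Fits `Surv(time, event) ~ signature + covariate` on exactly the samples
#' with a non-missing value for that covariate, so each covariate is assessed
#' on the largest cohort available to it (complete cases per model rather
#' than a single all-covariate complete-case set). Categorical covariates are
#' reference-coded; the signature term's HR/CI/p quantifies its prognostic
#' value adjusted for the covariate.
#'
#' @param clin Clinical tibble with `sample_id`, `time`, `event` and the
#'   covariate column.
#' @param score Numeric signature term per row of `clin` (continuous score or
#'   0/1 high-group indicator), or the name of a column of `clin`.
#' @param covariate Name of the covariate column.
#' @param missing_levels Category labels treated as missing in addition to
#'   `NA` (default `"missing"`, `"other/missing"`, `""`).
#' @return A `cox_fit` with an extra `signature` element: the signature
#'   term's row of the coefficient table, plus `covariate` and `n_used`.
#' @export
two_variable_cox <- function(clin, score, covariate,
                             missing_levels = c("missing", "other/missing", "")) {
  clin <- check_clinical(clin)
  if (is.character(score) && length(score) == 1) score <- clin[[score]]
  if (length(score) != nrow(clin)) abort("score must align with the clinical rows")
  if (!covariate %in% names(clin)) abort(paste0("no covariate column '", covariate, "'"))
  cv <- clin[[covariate]]
  keep <- !is.na(cv) & !is.na(score)
  if (is.character(cv) || is.factor(cv)) keep <- keep & !(as.character(cv) %in% missing_levels)
  if (!any(keep)) abort(paste0("covariate '", covariate, "' has no non-missing values"))
  cv_kept <- cv[keep]
  if (is.character(cv_kept)) cv_kept <- factor(cv_kept)
  if (length(unique(cv_kept)) < 2)
    abort(paste0("covariate '", covariate, "' has fewer than 2 levels among complete cases"))
  if (sum(clin$event[keep]) < 1) abort("no events among complete cases")
  design <- data.frame(signature = score[keep], covariate = cv_kept)
  names(design)[2] <- covariate
  fit <- fit_cox(design, clin$time[keep], clin$event[keep])
  fit$signature <- fit$terms[fit$terms$term == "signature", ]
  fit$covariate <- covariate
  fit$n_used <- sum(keep)
  fit
}
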