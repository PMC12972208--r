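# Shared fixtures: tiny expression tables, null survival draws, and the
# solved censoring design points (240-month horizon; rates solved from
# P(censor < event) so that the expected censoring fraction is 0.30).
CENSOR_RATE_NULL30 <- 0.004841798   # homogeneous arm, lambda0 = 0.012
CENSOR_RATE_ARM30 <- 0.001688286    # two-arm ln HR = -1 design
ADMIN_240 <- 240

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_expr <- function(values, feature_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  feature_ids <- feature_ids %||% sprintf("p%d", seq_len(nrow(m)))
  sample_ids <- sample_ids %||% sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(feature_ids, sample_ids)
  dplyr::bind_cols(tibble::tibble(feature_id = feature_ids), tibble::as_tibble(m))
}

# exponential survival with exponential + administrative censoring
null_surv <- function(n, rate = 0.02, censor_rate = 0.01, admin = 120) {
  t_ev <- stats::rexp(n, rate)
  t_cn <- pmin(stats::rexp(n, censor_rate), admin)
  list(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn))
}

# independent log-rank oracle via survival::survdiff
survdiff_p <- function(time, event, group) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
}

# exhaustive cutoff-scan oracle: candidate rule re-derived from first
# principles, per-candidate p from survdiff
scan_oracle <- function(score, time, event, window = c(0.25, 0.75), min_group = 5) {
  n <- length(score)
  qrank <- vapply(score, function(v) mean(score <= v), numeric(1))
  cand <- sort(unique(score[qrank >= window[1] & qrank <= window[2]]))
  keep <- vapply(cand, function(v) {
    nh <- sum(score > v)
    nh >= min_group && (n - nh) >= min_group
  }, logical(1))
  cand <- cand[keep]
  p <- vapply(cand, function(v) survdiff_p(time, event, score > v), numeric(1))
  list(candidates = cand, p = p, cutoff = cand[which.min(p)], p_min = min(p))
}
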