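#' Configure a synthetic multi-batch survival cohort
#'
#' Builds the configuration object for [generate_cohort()]. The generator
#' emulates the statistical structure of an integrated microarray survival
#' database: per-gene log-normal intensities on a MAS5-like scale, a subset of
#' signature genes whose latent z-scores carry known log-hazard effects,
#' exponential event times under a proportional-hazards model with independent
#' exponential plus administrative censoring, per-batch multiplicative
#' intensity shifts, injected exact-duplicate samples, and injected samples
#' with extreme quality-control metrics.
#'
#' Time is measured in months throughout. Defaults describe a lung-cancer-like
#' cohort: baseline hazard 0.012 events/month (median survival about 58
#' months), random censoring at 0.01/month with a 120-month administrative
#' horizon (roughly half the cohort censored), and histology/sex/smoking
#' covariate frequencies matching a large integrated lung cohort, with zero
#' covariate log-hazards unless requested.
#'
#' @param n_samples Number of base tumor samples.
#' @param n_genes Number of genes on the array.
#' @param n_signature_genes Number of genes carrying survival effects (the
#'   first `n_signature_genes` features).
#' @param beta Per-signature-gene log-hazard per 1 SD of expression; scalar or
#'   vector of length `n_signature_genes`.
#' @param baseline_rate Exponential baseline hazard (events per month), > 0.
#' @param censor_rate Independent exponential censoring rate (per month), > 0.
#' @param admin_time Administrative censoring horizon (months).
#' @param n_batches Number of batches (datasets) with differing mean intensity.
#' @param batch_log_shift_sd SD of the per-batch multiplicative intensity
#'   shift on the natural-log scale.
#' @param n_duplicates Number of exact-copy samples appended to the matrix.
#' @param n_qc_outliers Number of appended samples given QC metrics outside
#'   the central 95% interval of the others.
#' @param covariate_spec Named list of categorical covariates; each element is
#'   `list(levels =, freq =, loghr =)` with `freq` summing to 1. `NULL` uses
#'   the built-in histology/sex/smoking spec with zero log-hazards.
#' @param seed Integer RNG seed; every stochastic component is derived from it
#'   through named substreams (expression, survival, batch, injection, qc) so
#'   that changing one component's inputs leaves the others reproducible.
#' @return A `sim_config` list.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_samples = 300,
                       n_genes = 200,
                       n_signature_genes = min(20L, n_genes),
                       beta = 0,
                       baseline_rate = 0.012,
                       censor_rate = 0.01,
                       admin_time = 120,
                       n_batches = 3,
                       batch_log_shift_sd = 0.2,
                       n_duplicates = 0,
                       n_qc_outliers = 0,
                       covariate_spec = NULL,
                       seed = 1L) {
  if (n_samples < 1 || n_genes < 1) abort("n_samples and n_genes must be positive")
  if (n_signature_genes < 0 || n_signature_genes > n_genes)
    abort("n_signature_genes must lie in [0, n_genes]")
  if (!is.finite(baseline_rate) || baseline_rate <= 0)
    abort("baseline_rate must be a positive rate (events per month)")
  if (!is.finite(censor_rate) || censor_rate <= 0)
    abort("censor_rate must be a positive rate (per month)")
  if (!is.finite(admin_time) || admin_time <= 0) abort("admin_time must be positive")
  if (n_batches < 1) abort("n_batches must be >= 1")
  if (batch_log_shift_sd < 0) abort("batch_log_shift_sd must be >= 0")
  if (n_duplicates < 0 || n_qc_outliers < 0) abort("injection counts must be >= 0")
  if (n_duplicates > n_samples) abort("cannot duplicate more samples than exist")
  beta <- rep_len(as.numeric(beta), max(n_signature_genes, 1L))[seq_len(n_signature_genes)]
  covariate_spec <- covariate_spec %||% default_covariate_spec()
  for (nm in names(covariate_spec)) {
    cv <- covariate_spec[[nm]]
    if (!all(c("levels", "freq", "loghr") %in% names(cv)))
      abort(paste0("covariate '", nm, "' needs levels, freq and loghr"))
    if (length(cv$levels) != length(cv$freq) || length(cv$levels) != length(cv$loghr))
      abort(paste0("covariate '", nm, "': levels, freq and loghr lengths differ"))
    if (abs(sum(cv$freq) - 1) > 1e-8)
      abort(paste0("covariate '", nm, "': frequencies must sum to 1"))
  }
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_signature_genes = as.integer(n_signature_genes), beta = beta,
    baseline_rate = baseline_rate, censor_rate = censor_rate,
    admin_time = admin_time, n_batches = as.integer(n_batches),
    batch_log_shift_sd = batch_log_shift_sd,
    n_duplicates = as.integer(n_duplicates),
    n_qc_outliers = as.integer(n_qc_outliers),
    covariate_spec = covariate_spec, seed = as.integer(seed)
  ), class = "sim_config")
}

# Frequencies follow a large integrated lung cohort's OS arm (fractions of
# the full cohort; unannotated patients fall in the "missing" level).
default_covariate_spec <- function() {
  list(
    histology = list(
      levels = c("LUAD", "LUSC", "large-cell", "LCNEC", "other/missing"),
      freq   = c(0.477, 0.374, 0.037, 0.040, 0.072),
      loghr  = c(0, 0, 0, 0, 0)
    ),
    sex = list(
      levels = c("male", "female", "missing"),
      freq   = c(0.583, 0.339, 0.078),
      loghr  = c(0, 0, 0)
    ),
    smoking = list(
      levels = c("never", "smoker", "missing"),
      freq   = c(0.102, 0.235, 0.663),
      loghr  = c(0, 0, 0)
    )
  )
}

# Named RNG substreams: deterministic sub-seeds below 2^31 - 1.
substream_seed <- function(seed, stream) {
  k <- match(stream, c("expression", "survival", "batch", "injection", "qc"))
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483629)
}

with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a multi-batch expression matrix, a clinical/survival table, per-sample
#' QC metrics and the planted ground truth, deterministically given
#' `config$seed`.
#'
#' Expression for gene \eqn{g} in sample \eqn{i} is
#' \eqn{2^{\mu_g + z_{ig}}} with \eqn{\mu_g \sim U(6,10)} on the log2 scale and
#' \eqn{z_{ig} \sim N(0,1)}. The individual hazard is
#' \deqn{h_i = \lambda_0 \exp\big(\textstyle\sum_g \beta_g z_{ig} +
#'   \sum_c \gamma_{c}\big),}
#' driven by the latent z-scores rather than raw intensities, so batch shifts
#' are pure nuisance. Event times are exponential with rate \eqn{h_i};
#' censoring is the minimum of an independent exponential and the
#' administrative horizon; `event = 1` iff the event time is the smaller.
#' Duplicate samples (exact column copies) and QC-outlier samples are appended
#' after the base samples and recorded in the truth object.
#'
#' @param config A [sim_config()].
#' @return A list of class `senosurv_cohort` with elements `expression` (wide
#'   tibble), `clinical` (tibble: `sample_id`, `time`, `event`, `batch`, one
#'   column per covariate), `qc` (tibble of per-sample QC metrics:
#'   `background`, `noise`, `present_rate`, `ratio_gapdh_3p5p`,
#'   `ratio_actb_3p5p`), `truth` (list: `signature_gene_ids`, `beta_per_gene`,
#'   `batch_factors`, `duplicate_pairs`, `qc_outlier_ids`, plus the latent
#'   per-gene means) and `config`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_samples = 50, n_genes = 30, seed = 7))
#' dim(cohort$expression)
#' table(cohort$clinical$event)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_samples
  n_qc <- config$n_qc_outliers
  n_base <- n + n_qc   # fresh (non-duplicate) samples; outliers appended last
  g <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(g))
  ids_core <- sprintf("S%04d", seq_len(n))
  ids_qc <- if (n_qc) sprintf("S%04d_qcx", n + seq_len(n_qc)) else character()
  sig_ids <- gene_ids[seq_len(config$n_signature_genes)]

  expr <- with_stream(config$seed, "expression", {
    mu <- runif(g, 6, 10)
    z <- matrix(rnorm(g * n_base), nrow = g)
    list(mu = mu, z = z)
  })

  batches <- with_stream(config$seed, "batch", {
    assignment <- sample(rep_len(seq_len(config$n_batches), n_base))
    factors <- exp(rnorm(config$n_batches, 0, config$batch_log_shift_sd))
    list(assignment = assignment, factors = factors)
  })

  surv <- with_stream(config$seed, "survival", {
    covs <- lapply(config$covariate_spec, function(cv)
      cv$levels[sample.int(length(cv$levels), n_base, replace = TRUE, prob = cv$freq)])
    lp <- rep(0, n_base)
    if (config$n_signature_genes > 0)
      lp <- lp + drop(crossprod(expr$z[seq_len(config$n_signature_genes), , drop = FALSE],
                                config$beta))
    for (nm in names(config$covariate_spec)) {
      cv <- config$covariate_spec[[nm]]
      lp <- lp + cv$loghr[match(covs[[nm]], cv$levels)]
    }
    h <- config$baseline_rate * exp(lp)
    t_event <- rexp(n_base, rate = h)
    t_cens <- pmin(rexp(n_base, rate = config$censor_rate), config$admin_time)
    list(covs = covs,
         time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens))
  })

  qc <- with_stream(config$seed, "qc", {
    tibble(
      background = rnorm(n_base, 55, 6),
      noise = rnorm(n_base, 2.2, 0.25),
      present_rate = pmin(pmax(rnorm(n_base, 0.45, 0.04), 0.01), 0.99),
      ratio_gapdh_3p5p = exp(rnorm(n_base, log(1.1), 0.12)),
      ratio_actb_3p5p = exp(rnorm(n_base, log(1.2), 0.12))
    )
  })
  if (n_qc) {
    # push appended outliers far outside the central 95% interval of the rest
    out_rows <- n + seq_len(n_qc)
    core <- qc[seq_len(n), , drop = FALSE]
    qc$background[out_rows] <- max(core$background) + 12 * sd(core$background)
    qc$present_rate[out_rows] <- pmax(min(core$present_rate) / 10, 1e-4)
  }

  intens <- 2^(expr$mu + expr$z) *
    rep(batches$factors[batches$assignment], each = g)
  dimnames(intens) <- list(gene_ids, c(ids_core, ids_qc))

  dup <- with_stream(config$seed, "injection", {
    if (config$n_duplicates == 0) {
      tibble(original = character(), copy = character())
    } else {
      orig <- sort(sample(ids_core, config$n_duplicates))
      tibble(original = orig, copy = paste0(orig, "_dup"))
    }
  })

  order_cols <- c(ids_core, dup$copy, ids_qc)
  full <- cbind(intens[, ids_core, drop = FALSE],
                intens[, dup$original, drop = FALSE],
                intens[, ids_qc, drop = FALSE])
  colnames(full) <- order_cols

  idx_base <- c(seq_len(n), match(dup$original, ids_core), n + seq_len(n_qc))
  clinical <- tibble(
    sample_id = order_cols,
    time = surv$time[idx_base],
    event = surv$event[idx_base],
    batch = paste0("batch", batches$assignment[idx_base])
  )
  for (nm in names(surv$covs)) clinical[[nm]] <- surv$covs[[nm]][idx_base]

  qc_out <- bind_cols(tibble(sample_id = order_cols), qc[idx_base, , drop = FALSE])

  truth <- structure(list(
    signature_gene_ids = sig_ids,
    beta_per_gene = setNames(config$beta, sig_ids),
    batch_factors = setNames(batches$factors, paste0("batch", seq_len(config$n_batches))),
    duplicate_pairs = dup,
    qc_outlier_ids = ids_qc,
    gene_log2_means = setNames(expr$mu, gene_ids),
    baseline_rate = config$baseline_rate,
    censor_rate = config$censor_rate,
    admin_time = config$admin_time
  ), class = "sim_truth")

  structure(list(expression = expr_tibble(full), clinical = clinical,
                 qc = qc_out, truth = truth, config = config),
            class = "senosurv_cohort")
}

#' Write a synthetic cohort to a directory
#'
#' Emits `expression.tsv`, `clinical.tsv`, `qc.tsv`, `truth.json` and
#' `config.json` into `dir`.
#'
#' @param cohort A `senosurv_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "senosurv_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_qc_metrics(cohort$qc, file.path(dir, "qc.tsv"))
  truth <- cohort$truth
  truth$duplicate_pairs <- as.data.frame(truth$duplicate_pairs)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.senosurv_cohort <- function(x, ...) {
  cat("<senosurv_cohort> ", ncol(x$expression) - 1L, " samples x ",
      nrow(x$expression), " genes (",
      length(x$truth$signature_gene_ids), " signature genes, ",
      nrow(x$truth$duplicate_pairs), " duplicates, ",
      length(x$truth$qc_outlier_ids), " QC outliers)\n", sep = "")
  invisible(x)
}
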