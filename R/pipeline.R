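#' Dataset registry bookkeeping
#'
#' A dataset registry lists the cohorts feeding an integrated expression
#' database: one row per dataset with its accession, array platform label and
#' sample size. `total_samples()` sums the sizes, reproducing the database
#' total quoted from such a table.
#'
#' @param path TSV with columns `accession`, `platform`, `n`.
#' @return `read_registry()`: tibble (`accession`, `platform`, `n`);
#'   `total_samples()`: integer.
#' @export
read_registry <- function(path) {
  reg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("accession", "platform", "n")
  miss <- setdiff(need, names(reg))
  if (length(miss)) abort(paste0("registry missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(reg$accession)) abort("registry accessions must be unique")
  if (any(!is.finite(reg$n)) || any(reg$n <= 0) || any(reg$n != round(reg$n)))
    abort("registry sample sizes must be positive integers")
  reg$n <- as.integer(reg$n)
  as_tibble(reg)
}

#' @rdname read_registry
#' @param registry Tibble from [read_registry()] (or any tibble with `n`).
#' @export
total_samples <- function(registry) {
  if (!nrow(registry)) return(0L)
  sum(as.integer(registry$n))
}

#' Summarize a clinical cohort's categorical composition
#'
#' Counts and percentages per level of each categorical covariate. With
#' `denominator = "full"` percentages use the whole cohort size (main-text
#' convention); with `"annotated"` they use only the patients with a
#' non-missing value for that variable (figure convention). Percentages are
#' rounded half-up to one decimal so that published count tables recompute
#' exactly.
#'
#' @param clin Clinical tibble (`sample_id`, `time`, `event`, covariates).
#' @param denominator `"full"` or `"annotated"`.
#' @param variables Covariate columns to tabulate (default: every column that
#'   is not `sample_id`, `time`, `event` or `batch`).
#' @param missing_levels Labels counted as missing for the annotated
#'   denominator.
#' @return Tibble `variable`, `level`, `count`, `denominator`, `percent`.
#' @export
summarize_cohort <- function(clin, denominator = c("full", "annotated"),
                             variables = NULL,
                             missing_levels = c("missing", "other/missing", "")) {
  denominator <- match.arg(denominator)
  clin <- as_tibble(clin)
  if (!nrow(clin)) abort("clinical table is empty")
  variables <- variables %||%
    setdiff(names(clin), c("sample_id", "time", "event", "batch"))
  rows <- lapply(variables, function(v) {
    x <- as.character(clin[[v]])
    x[is.na(x)] <- "missing"
    tab <- table(x)
    is_missing <- names(tab) %in% c(missing_levels, "missing")
    denom <- if (denominator == "full") nrow(clin) else sum(tab[!is_missing])
    tibble(variable = v, level = names(tab), count = as.integer(tab),
           denominator = as.integer(denom),
           percent = round_half_up(100 * as.integer(tab) / denom, 1))
  })
  bind_rows(rows)
}

#' Assemble an analysis configuration
#'
#' Gathers every input and tuning parameter of [run_analysis()]. Expression,
#' clinical, QC and signature inputs may be given in-memory (tibbles /
#' `gene_signature` objects) or as file paths in the formats of
#' [senosurv_io] and [read_signature()].
#'
#' @param expression Wide expression tibble or TSV path (probe- or
#'   gene-level, linear intensities).
#' @param clinical Named list of clinical tibbles or TSV paths, one per
#'   endpoint (e.g. `list(OS = ..., FP = ...)`); a bare tibble is treated as
#'   endpoint `"OS"`.
#' @param signatures Named list of `gene_signature` objects, character
#'   vectors, or signature file paths.
#' @param qc Optional QC metrics tibble or TSV path.
#' @param probe_map Optional probe-gene map tibble or TSV path (collapse to
#'   gene level when given).
#' @param shared_probes Optional probe universe (character vector or path).
#' @param strata Histology strata to analyze; `"all"` means no restriction
#'   (default `"all"` only).
#' @param stratum_variable Clinical column holding the strata (default
#'   `"histology"`).
#' @param weight_mode,expression_mode See [derive_weights()] and
#'   [compute_score()].
#' @param window,min_group See [scan_cutoffs()].
#' @param fdr Benjamini-Hochberg threshold (default 0.10).
#' @param score_term `"indicator"` (default) uses the selected high/low split
#'   in the two-variable models; `"continuous"` uses the score itself.
#' @param n_perm Permutations for selection-adjusted p (0 = skip).
#' @param cv_folds If > 0, score samples out-of-fold with [crossfit_scores()]
#'   (k = `cv_folds`) instead of the in-sample default, removing the
#'   weight-derivation optimism from downstream p-values.
#' @param target Mean-scaling target intensity (default 1000).
#' @param seed Integer seed for every stochastic step.
#' @param output_dir Directory for the report bundle.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(expression, clinical, signatures,
                            qc = NULL, probe_map = NULL, shared_probes = NULL,
                            strata = "all", stratum_variable = "histology",
                            weight_mode = c("loghr", "sign_only"),
                            expression_mode = c("zscore", "raw"),
                            window = c(0.25, 0.75), min_group = 5,
                            fdr = 0.10, score_term = c("indicator", "continuous"),
                            n_perm = 0, cv_folds = 0, target = 1000, seed = 1L,
                            output_dir = tempfile("senosurv_run_")) {
  if (fdr <= 0 || fdr >= 1) abort("fdr must lie in (0, 1)")
  if (window[1] >= window[2] || window[1] <= 0 || window[2] >= 1)
    abort("window must satisfy 0 < low < high < 1")
  structure(list(
    expression = expression, clinical = clinical, signatures = signatures,
    qc = qc, probe_map = probe_map, shared_probes = shared_probes,
    strata = strata, stratum_variable = stratum_variable,
    weight_mode = match.arg(weight_mode),
    expression_mode = match.arg(expression_mode),
    window = window, min_group = min_group, fdr = fdr,
    score_term = match.arg(score_term), n_perm = n_perm,
    cv_folds = as.integer(cv_folds), target = target,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "analysis_config")
}

#' Load an analysis configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [analysis_config()];
#' path-valued entries (`expression`, `clinical`, `signatures`, `qc`,
#' `probe_map`, `shared_probes`) are resolved relative to the YAML file.
#'
#' @param path YAML configuration file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (is.character(p)) file.path(base, p) else p
  for (k in c("expression", "qc", "probe_map", "shared_probes"))
    if (!is.null(raw[[k]])) raw[[k]] <- rel(raw[[k]])
  if (!is.null(raw$clinical)) raw$clinical <- lapply(raw$clinical, rel)
  if (!is.null(raw$signatures)) raw$signatures <- lapply(raw$signatures, rel)
  if (!is.null(raw$window)) raw$window <- as.numeric(raw$window)
  do.call(analysis_config, raw)
}

resolve_input <- function(x, reader) if (is.character(x) && length(x) == 1) reader(x) else x

resolve_signature <- function(x, name) {
  if (inherits(x, "gene_signature")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    sig <- read_signature(x)
    if (!is.null(name) && nzchar(name)) sig$name <- name
    return(sig)
  }
  gene_signature(x, name = name %||% "signature")
}

#' Run the full prognostic analysis
#'
#' Orchestrates harmonization, signature matching, hazard-ratio weight
#' derivation, score computation, the minimum-p cutoff scan, Kaplan-Meier
#' export, Benjamini-Hochberg control across every (signature, stratum,
#' endpoint) test, and two-variable adjusted Cox models — then writes the
#' report bundle (results, weights, KM curves, manifest, log) to
#' `config$output_dir`. Deterministic given `config$seed`.
#'
#' Strata with fewer than 30 samples are analyzed but flagged underpowered.
#'
#' @param config An [analysis_config()] (or YAML path, via
#'   [read_analysis_config()]).
#' @return Invisibly, a list with `results` (one row per signature x stratum
#'   x endpoint), `adjusted` (results joined with q-values), `two_variable`
#'   (adjusted-model table), `scans` (the `cutoff_scan` objects), `weights`,
#'   `harmonization_log` and `manifest`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }

  x <- resolve_input(config$expression, read_expression)
  qc <- resolve_input(config$qc, read_qc_metrics)
  map <- resolve_input(config$probe_map, read_probe_map)
  shared <- resolve_input(config$shared_probes, read_shared_probes)
  clin_list <- config$clinical
  if (is.data.frame(clin_list)) clin_list <- list(OS = clin_list)
  clin_list <- lapply(clin_list, resolve_input, reader = read_clinical)
  sig_names <- names(config$signatures) %||% rep("", length(config$signatures))
  sigs <- purrr::map2(config$signatures, sig_names, resolve_signature)
  names(sigs) <- map_chr(sigs, "name")

  note("input: ", ncol(x) - 1L, " samples x ", nrow(x), " features")
  h <- harmonize(x, qc = qc, map = map, shared = shared, target = config$target)
  xg <- h$expression
  for (i in seq_len(nrow(h$log)))
    note("harmonize/", h$log$stage[i], ": ", h$log$n_samples[i], " samples, ",
         h$log$n_features[i], " features")

  results <- list()
  weights_out <- list()
  scans <- list()
  two_var <- list()
  for (ep in names(clin_list)) {
    clin <- clin_list[[ep]]
    ids <- intersect(sample_ids(xg), clin$sample_id)
    orphans <- setdiff(clin$sample_id, sample_ids(xg))
    note("endpoint ", ep, ": ", length(ids), " samples with expression (",
         length(orphans), " clinical-only ids)")
    if (!length(ids)) abort(paste0("endpoint ", ep, ": no overlap between clinical and expression ids"))
    clin <- clin[match(ids, clin$sample_id), ]
    for (stratum in config$strata) {
      in_str <- if (identical(stratum, "all")) rep(TRUE, nrow(clin))
                else clin[[config$stratum_variable]] == stratum & !is.na(clin[[config$stratum_variable]])
      clin_s <- clin[in_str, ]
      underpowered <- nrow(clin_s) < 30
      xs <- xg[, c("feature_id", clin_s$sample_id), drop = FALSE]
      for (sg in names(sigs)) {
        key <- paste(sg, stratum, ep, sep = "|")
        mt <- match_signature(sigs[[sg]], xs)
        xm <- xs[match(mt$matched, xs$feature_id), , drop = FALSE]
        recs <- univariate_gene_hrs(xm, clin_s)
        w <- derive_weights(recs, mode = config$weight_mode)
        sc <- if (config$cv_folds > 0)
          crossfit_scores(xm, clin_s, k = config$cv_folds,
                          weight_mode = config$weight_mode,
                          seed = substream_seed(config$seed, "expression"))
        else compute_score(xm, w, expression_mode = config$expression_mode)
        scan <- scan_cutoffs(sc$score, clin_s$time, clin_s$event,
                             window = config$window, min_group = config$min_group,
                             n_perm = config$n_perm,
                             seed = substream_seed(config$seed, "survival"))
        scans[[key]] <- scan
        weights_out[[key]] <- mutate(w, signature = sg, stratum = stratum, endpoint = ep)
        g <- glance(scan)
        results[[key]] <- bind_cols(
          tibble(signature = sg, stratum = stratum, endpoint = ep,
                 n = nrow(clin_s), n_events = sum(clin_s$event),
                 n_matched = mt$n_matched, n_signature = mt$n_total,
                 underpowered = underpowered),
          g)
        note("scan ", key, ": n=", nrow(clin_s), ", matched ", mt$n_matched, "/",
             mt$n_total, ", cutoff ", signif(g$cutoff, 5), ", p=", signif(g$p_value, 4),
             if (underpowered) " [underpowered]")
        if (identical(stratum, "all")) {
          term <- if (config$score_term == "indicator")
            as.integer(scan$group == "high") else sc$score
          covs <- setdiff(names(clin_s),
                          c("sample_id", "time", "event", "batch"))
          for (cv in covs) {
            tv <- tryCatch(two_variable_cox(clin_s, term, cv), error = function(e) NULL)
            if (is.null(tv)) {
              note("two-variable model ", key, " + ", cv, ": skipped (degenerate covariate)")
              next
            }
            two_var[[paste(key, cv, sep = "|")]] <- bind_cols(
              tibble(signature = sg, endpoint = ep, covariate = cv,
                     n_used = tv$n_used, score_term = config$score_term),
              tv$signature[, c("hr", "ci_low", "ci_high", "p_value")])
          }
        }
      }
    }
  }
  results <- bind_rows(results)
  adj <- bh_adjust(results$p_value, fdr = config$fdr)
  adjusted <- bind_cols(results, adj[, c("q_value", "significant")])
  two_var <- bind_rows(two_var)
  weights_tbl <- bind_rows(weights_out)

  out <- config$output_dir
  readr::write_tsv(adjusted, file.path(out, "results.tsv"), progress = FALSE)
  readr::write_tsv(weights_tbl, file.path(out, "weights.tsv"), progress = FALSE)
  if (nrow(two_var)) readr::write_tsv(two_var, file.path(out, "two_variable_models.tsv"),
                                      progress = FALSE)
  km_files <- character()
  for (key in names(scans)) {
    fn <- paste0("km_", gsub("[^A-Za-z0-9]+", "_", key), ".csv")
    readr::write_csv(scans[[key]]$km, file.path(out, fn), progress = FALSE)
    km_files <- c(km_files, fn)
  }
  manifest <- list(
    seed = config$seed,
    fdr = config$fdr,
    weight_mode = config$weight_mode,
    expression_mode = config$expression_mode,
    harmonization = as.data.frame(h$log),
    n_tests = nrow(adjusted),
    n_significant = sum(adjusted$significant),
    files = c("results.tsv", "weights.tsv",
              if (nrow(two_var)) "two_variable_models.tsv", km_files, "run.log")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(list(results = results, adjusted = adjusted, two_variable = two_var,
                 scans = scans, weights = weights_tbl, harmonization_log = h$log,
                 manifest = manifest, output_dir = out))
}

#' Reconstruct a categorical clinical table from published counts
#'
#' Expands a per-level count table (columns `endpoint`, `variable`, `level`,
#' `count`, with a `total` row per endpoint) into a skeleton clinical tibble
#' in which each variable's levels are assigned to the right number of
#' patients and the unannotated remainder is `missing`. The joint
#' distribution across variables is not reconstructed (it is not published);
#' the table is exact for the marginal summaries that
#' [summarize_cohort()] computes. Survival columns are placeholders.
#'
#' @param counts Tibble as in `inst/extdata/cohort_counts.tsv`.
#' @param endpoint Which endpoint's counts to expand (e.g. `"OS"`).
#' @return A clinical tibble with `sample_id`, `time`, `event` placeholders
#'   and one column per tabulated variable.
#' @export
cohort_from_counts <- function(counts, endpoint) {
  counts <- as_tibble(counts)
  counts <- counts[counts$endpoint == endpoint, ]
  if (!nrow(counts)) abort(paste0("no counts for endpoint ", endpoint))
  total <- counts$count[counts$variable == "total"]
  if (length(total) != 1) abort("counts need exactly one 'total' row per endpoint")
  clin <- tibble(sample_id = sprintf("P%04d", seq_len(total)), time = 1, event = 0L)
  for (v in setdiff(unique(counts$variable), "total")) {
    sub <- counts[counts$variable == v, ]
    if (sum(sub$count) > total)
      abort(paste0("counts for '", v, "' exceed the cohort total"))
    lev <- rep("missing", total)
    lev[seq_len(sum(sub$count))] <- rep(sub$level, sub$count)
    clin[[v]] <- lev
  }
  clin
}
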