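#' Scale every sample to a uniform mean intensity
#'
#' Secondary scaling normalization for cross-dataset integration: each
#' sample's intensities are multiplied by `target / mean(sample)` so that the
#' per-sample mean over the retained probes equals `target` (1000 by default,
#' the conventional value for MAS5-scale arrays). Operates on linear-scale
#' intensities; feature and sample order are preserved, and the operation is
#' idempotent.
#'
#' @param x Wide expression tibble (`feature_id` + one numeric column per
#'   sample).
#' @param target Positive target mean intensity.
#' @return The rescaled expression tibble.
#' @examples
#' x <- tibble::tibble(feature_id = c("p1", "p2", "p3"), s1 = c(1, 2, 3))
#' scale_normalize(x)$s1
#' @export
scale_normalize <- function(x, target = 1000) {
  x <- check_expression(x)
  if (!is.finite(target) || target <= 0) abort("target must be a positive number")
  m <- expr_values(x)
  mu <- colMeans(m)
  bad <- names(mu)[mu <= 0]
  if (length(bad))
    abort(paste0("sample(s) with nonpositive mean intensity: ",
                 paste(bad, collapse = ", ")))
  expr_tibble(sweep(m, 2, target / mu, `*`))
}

#' Restrict an expression matrix to a shared probe universe
#'
#' Keeps only the features present in `shared` (e.g. the probe set common to
#' all array platforms in an integrated database), in the matrix's own order.
#'
#' @inheritParams scale_normalize
#' @param shared Character vector of feature ids to retain.
#' @return The restricted expression tibble.
#' @export
restrict_to_shared_probes <- function(x, shared) {
  x <- check_expression(x)
  if (!length(shared)) abort("shared probe list must be non-empty")
  keep <- x$feature_id %in% shared
  if (!any(keep)) abort("no features of the matrix are in the shared probe list")
  x[keep, , drop = FALSE]
}

#' Drop samples with identical expression profiles
#'
#' Samples whose full expression vector equals an earlier sample's (after
#' rounding to `digits` decimals, so floating-point round-off cannot defeat
#' the comparison) are removed, keeping the first occurrence in column order.
#'
#' @inheritParams scale_normalize
#' @param digits Decimals used for the equality comparison.
#' @return The deduplicated expression tibble, with attribute
#'   `removed_samples` listing the dropped sample ids.
#' @export
remove_duplicate_samples <- function(x, digits = 4) {
  x <- check_expression(x)
  m <- round(expr_values(x), digits)
  dup <- duplicated(t(m))
  out <- x[, c(TRUE, !dup), drop = FALSE]
  attr(out, "removed_samples") <- sample_ids(x)[dup]
  out
}

#' Filter samples by central-interval quality-control metrics
#'
#' A sample is kept iff, for every metric column, its value lies within the
#' central `keep_interval` interval of that metric across all input samples.
#' Intervals are computed once on the full input and applied once (no
#' iteration). The default interval is the 2.5th-97.5th percentile band;
#' `method = "parametric"` uses mean +/- z*SD instead.
#'
#' @param metrics Tibble of per-sample QC metrics; first column `sample_id`,
#'   remaining columns numeric (e.g. `background`, `noise`, `present_rate`,
#'   `ratio_gapdh_3p5p`, `ratio_actb_3p5p`).
#' @param keep_interval Central probability mass to keep (default 0.95).
#' @param method `"percentile"` (robust, default) or `"parametric"`.
#' @return Character vector of kept sample ids, with attribute `bounds` (a
#'   tibble of the per-metric interval) and `excluded` (dropped ids).
#' @export
filter_samples_by_qc <- function(metrics, keep_interval = 0.95,
                                 method = c("percentile", "parametric")) {
  method <- match.arg(method)
  metrics <- as_tibble(metrics)
  if (names(metrics)[1] != "sample_id") abort("first column of metrics must be sample_id")
  if (nrow(metrics) < 20)
    abort("QC interval filtering needs at least 20 samples")
  if (keep_interval <= 0 || keep_interval >= 1) abort("keep_interval must be in (0, 1)")
  vals <- metrics[, -1, drop = FALSE]
  for (nm in names(vals)) {
    nf <- !is.finite(vals[[nm]])
    if (any(nf))
      abort(paste0("non-finite value in metric '", nm, "' for sample(s) ",
                   paste(metrics$sample_id[nf], collapse = ", ")))
  }
  alpha <- (1 - keep_interval) / 2
  bounds <- purrr::imap(vals, function(v, nm) {
    if (method == "percentile") {
      q <- quantile(v, c(alpha, 1 - alpha), names = FALSE, type = 7)
    } else {
      z <- qnorm(1 - alpha)
      q <- mean(v) + c(-1, 1) * z * sd(v)
    }
    tibble(metric = nm, lower = q[1], upper = q[2])
  })
  bounds <- bind_rows(bounds)
  inside <- rep(TRUE, nrow(metrics))
  for (i in seq_len(nrow(bounds))) {
    v <- vals[[bounds$metric[i]]]
    inside <- inside & v >= bounds$lower[i] & v <= bounds$upper[i]
  }
  kept <- metrics$sample_id[inside]
  attr(kept, "bounds") <- bounds
  attr(kept, "excluded") <- metrics$sample_id[!inside]
  kept
}

#' Collapse probe-level rows to one row per gene
#'
#' For each gene with at least one mapped probe in the matrix, the probe with
#' the largest interquartile range across samples is retained (a deterministic
#' best-probe selector standing in for annotation-database-driven choices such
#' as JetSet; supply a curated map to reproduce those instead). Ties are
#' broken by the lexicographically smallest probe id; unmapped probes are
#' dropped.
#'
#' @inheritParams scale_normalize
#' @param map Tibble with columns `probe_id`, `gene_symbol` (many probes may
#'   map to one gene; each probe maps to at most one gene).
#' @return Gene-level expression tibble (`feature_id` now holds gene symbols,
#'   rows ordered by gene symbol) with attribute `selection`: a tibble of
#'   (gene, probe, n_candidates).
#' @export
collapse_probes_to_genes <- function(x, map) {
  x <- check_expression(x)
  map <- as_tibble(map)
  if (!all(c("probe_id", "gene_symbol") %in% names(map)))
    abort("map needs columns probe_id and gene_symbol")
  if (anyDuplicated(map$probe_id)) abort("probe ids must be unique in the map")
  present <- map[map$probe_id %in% x$feature_id, ]
  if (nrow(present) == 0) abort("no probe of the matrix appears in the map")
  m <- expr_values(x)
  iqr <- apply(m[present$probe_id, , drop = FALSE], 1, IQR)
  sel <- present |>
    mutate(iqr = iqr[.data$probe_id]) |>
    arrange(.data$gene_symbol, dplyr::desc(.data$iqr), .data$probe_id) |>
    group_by(.data$gene_symbol) |>
    summarise(probe = dplyr::first(.data$probe_id), n_candidates = n(),
              .groups = "drop")
  out <- expr_tibble(m[sel$probe, , drop = FALSE])
  out$feature_id <- sel$gene_symbol
  attr(out, "selection") <- sel |> rename(gene = "gene_symbol")
  out
}

#' Run the full harmonization chain
#'
#' Applies, in order: mean-target scaling, shared-probe restriction (if a
#' probe universe is given), duplicate-sample removal, QC interval filtering
#' (if metrics are given) and probe-to-gene collapse (if a map is given).
#' Every stage's sample/feature counts are logged.
#'
#' @inheritParams scale_normalize
#' @param qc Optional tibble of per-sample QC metrics (see
#'   [filter_samples_by_qc()]).
#' @param map Optional probe-gene map (see [collapse_probes_to_genes()]).
#' @param shared Optional shared probe universe.
#' @param keep_interval Central QC interval (default 0.95).
#' @return List with `expression` (harmonized tibble), `log` (tibble of
#'   per-stage sample and feature counts), `removed_duplicates`,
#'   `qc_excluded`, and `probe_selection`.
#' @export
harmonize <- function(x, qc = NULL, map = NULL, shared = NULL,
                      target = 1000, keep_interval = 0.95) {
  x <- check_expression(x)
  log <- list(tibble(stage = "input", n_samples = ncol(x) - 1L, n_features = nrow(x)))
  x <- scale_normalize(x, target = target)
  log <- c(log, list(tibble(stage = "scale_normalize", n_samples = ncol(x) - 1L,
                            n_features = nrow(x))))
  if (!is.null(shared)) {
    x <- restrict_to_shared_probes(x, shared)
    log <- c(log, list(tibble(stage = "restrict_shared", n_samples = ncol(x) - 1L,
                              n_features = nrow(x))))
  }
  x <- remove_duplicate_samples(x)
  removed <- attr(x, "removed_samples")
  log <- c(log, list(tibble(stage = "remove_duplicates", n_samples = ncol(x) - 1L,
                            n_features = nrow(x))))
  qc_excluded <- character()
  if (!is.null(qc)) {
    qc <- qc[qc$sample_id %in% sample_ids(x), , drop = FALSE]
    kept <- filter_samples_by_qc(qc, keep_interval = keep_interval)
    qc_excluded <- attr(kept, "excluded")
    x <- x[, c("feature_id", intersect(sample_ids(x), kept)), drop = FALSE]
    log <- c(log, list(tibble(stage = "qc_filter", n_samples = ncol(x) - 1L,
                              n_features = nrow(x))))
  }
  selection <- NULL
  if (!is.null(map)) {
    x <- collapse_probes_to_genes(x, map)
    selection <- attr(x, "selection")
    log <- c(log, list(tibble(stage = "collapse_probes", n_samples = ncol(x) - 1L,
                              n_features = nrow(x))))
  }
  list(expression = x, log = bind_rows(log), removed_duplicates = removed,
       qc_excluded = qc_excluded, probe_selection = selection)
}
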