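#' Read a gene signature from GMT or plain-list text
#'
#' Plain-list format: one gene symbol per line (blank lines ignored); the
#' signature is named after the file unless `name` is given. GMT format: tab
#' separated, first field the set name, second a description (ignored), the
#' rest gene symbols; with several GMT lines, use [read_signatures()] and
#' pick. Symbols are de-duplicated preserving first occurrence.
#'
#' @param path Path to the signature file.
#' @param format `"auto"` (by extension), `"gmt"` or `"list"`.
#' @param name Optional signature name override.
#' @return A `gene_signature`: list with `name` and `genes`.
#' @export
read_signature <- function(path, format = c("auto", "gmt", "list"), name = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "list"
  if (format == "gmt") {
    sigs <- read_signatures(path)
    if (length(sigs) != 1)
      abort(paste0("GMT file holds ", length(sigs),
                   " signatures; use read_signatures() and select one"))
    sig <- sigs[[1]]
    if (!is.null(name)) sig$name <- name
    sig
  } else {
    genes <- readr::read_lines(path, progress = FALSE)
    genes <- trimws(genes)
    genes <- genes[nzchar(genes)]
    new_signature(name %||% tools::file_path_sans_ext(basename(path)), genes)
  }
}

#' @rdname read_signature
#' @export
read_signatures <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty GMT file")
  sigs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      abort(paste0("malformed GMT line ", i,
                   ": expected name, description and at least one gene"))
    new_signature(fields[1], fields[-(1:2)])
  })
  setNames(sigs, map_chr(sigs, "name"))
}

new_signature <- function(name, genes) {
  genes <- genes[nzchar(genes)]
  genes <- genes[!duplicated(genes)]
  if (!length(genes)) abort(paste0("signature '", name, "' has an empty gene list"))
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' Build a gene signature from a character vector
#'
#' @param genes Character vector of gene symbols (de-duplicated, order kept).
#' @param name Signature name.
#' @return A `gene_signature`.
#' @export
gene_signature <- function(genes, name = "signature") new_signature(name, genes)

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Match signature genes against a gene-level expression matrix
#'
#' Case-sensitive exact symbol matching; `matched` keeps the signature's
#' order, and `matched` plus `missing` partition the signature.
#'
#' @param sig A `gene_signature` (or character vector of symbols).
#' @param x Gene-level wide expression tibble.
#' @return List with `matched`, `missing`, `n_matched`, `n_total`.
#' @examples
#' x <- tibble::tibble(feature_id = c("A", "B", "C"), s1 = 1:3, s2 = 3:1)
#' match_signature(gene_signature(c("A", "B", "Z")), x)
#' @export
match_signature <- function(sig, x) {
  if (is.character(sig)) sig <- gene_signature(sig)
  x <- check_expression(x)
  matched <- sig$genes[sig$genes %in% x$feature_id]
  if (!length(matched))
    abort(paste0("no gene of signature '", sig$name, "' is present in the matrix"))
  list(matched = matched,
       missing = setdiff(sig$genes, matched),
       n_matched = length(matched),
       n_total = length(sig$genes))
}

#' Per-gene univariate Cox hazard ratios
#'
#' Fits one single-covariate Cox proportional-hazards model per gene on the
#' per-gene z-scored log2 expression (so hazard ratios are per 1 SD), and
#' records HR, Wald 95% CI and p. Genes with zero expression variance cannot
#' be z-scored; they are reported with HR = 1 and flagged rather than dropped,
#' so the record set always aligns with the matched gene list.
#'
#' @param x Gene-level wide expression tibble restricted to the genes of
#'   interest (linear-scale intensities).
#' @param clin Clinical tibble with `sample_id`, `time`, `event` covering the
#'   matrix samples.
#' @param genes Optional subset of genes to fit (default: all matrix rows).
#' @param log2_transform Apply `log2(x + 1)` before z-scoring (default TRUE;
#'   set FALSE when the matrix is already on log scale).
#' @return Tibble with one row per gene: `gene`, `hr`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `n_events`, `flag` (`NA` or `"zero_variance"`).
#' @export
univariate_gene_hrs <- function(x, clin, genes = NULL, log2_transform = TRUE) {
  x <- check_expression(x)
  clin <- check_clinical(clin)
  genes <- genes %||% x$feature_id
  miss <- setdiff(genes, x$feature_id)
  if (length(miss)) abort(paste0("genes absent from matrix: ", paste(miss, collapse = ", ")))
  ids <- intersect(sample_ids(x), clin$sample_id)
  if (!length(ids)) abort("no overlap between matrix samples and clinical table")
  clin <- clin[match(ids, clin$sample_id), ]
  if (sum(clin$event) < 10)
    abort("need at least 10 events to derive per-gene hazard ratios")
  m <- expr_values(x)[genes, ids, drop = FALSE]
  if (log2_transform) m <- log2(m + 1)
  rows <- lapply(genes, function(gid) {
    v <- m[gid, ]
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      return(tibble(gene = gid, hr = 1, ci_low = NA_real_, ci_high = NA_real_,
                    p_value = NA_real_, n = length(v), n_events = sum(clin$event),
                    flag = "zero_variance"))
    }
    z <- (v - mean(v)) / s
    fit <- fit_cox(tibble(expr_z = z), clin$time, clin$event)
    td <- fit$terms
    tibble(gene = gid, hr = td$hr, ci_low = td$ci_low, ci_high = td$ci_high,
           p_value = td$p_value, n = length(v), n_events = sum(clin$event),
           flag = NA_character_)
  })
  bind_rows(rows)
}

#' Turn hazard-ratio records into signature weights
#'
#' Implements the hazard-ratio sign rule: genes with HR > 1 (risk-associated)
#' get negative weights, genes with HR < 1 (protective) get positive weights,
#' HR = 1 gives weight 0. The default magnitude is `-ln(HR)`; `"sign_only"`
#' keeps only the sign. Flagged zero-variance genes get weight 0.
#'
#' @param records Tibble from [univariate_gene_hrs()] (needs `gene`, `hr`;
#'   other columns are carried along).
#' @param mode `"loghr"` (default, w = -ln HR) or `"sign_only"` (w in
#'   \{-1, 0, 1\}).
#' @return A `signature_weights` tibble: the records plus a `weight` column.
#' @examples
#' derive_weights(tibble::tibble(gene = c("A", "B"), hr = c(2, 0.5)))$weight
#' @export
derive_weights <- function(records, mode = c("loghr", "sign_only")) {
  mode <- match.arg(mode)
  records <- as_tibble(records)
  if (!all(c("gene", "hr") %in% names(records))) abort("records need gene and hr columns")
  if (any(!is.finite(records$hr)) || any(records$hr <= 0))
    abort("hazard ratios must be finite and > 0")
  w <- -log(records$hr)
  if (mode == "sign_only") w <- sign(w)
  if ("flag" %in% names(records)) w[!is.na(records$flag)] <- 0
  out <- mutate(records, weight = w)
  attr(out, "mode") <- mode
  class(out) <- c("signature_weights", class(out))
  out
}

#' Compute the weighted-average signature score per sample
#'
#' The score of sample \eqn{i} is
#' \deqn{S_i = \sum_g w_g e_{ig} \Big/ \sum_g |w_g|,}
#' a weighted average of gene expression. In `"zscore"` mode (default)
#' \eqn{e_{ig}} is the per-gene z-score of `log2(intensity + 1)`, making the
#' score invariant to positive rescaling of the matrix and comparable across
#' genes; `"raw"` mode uses the normalized linear intensities directly.
#'
#' @param x Gene-level wide expression tibble containing every weighted gene.
#' @param weights A `signature_weights` tibble (columns `gene`, `weight`).
#' @param expression_mode `"zscore"` (default) or `"raw"`.
#' @return Tibble `sample_id`, `score`, with attributes `signature` (if the
#'   weights carry one) and `expression_mode`.
#' @export
compute_score <- function(x, weights, expression_mode = c("zscore", "raw")) {
  expression_mode <- match.arg(expression_mode)
  x <- check_expression(x)
  weights <- as_tibble(weights)
  if (!all(c("gene", "weight") %in% names(weights)))
    abort("weights need gene and weight columns")
  miss <- setdiff(weights$gene, x$feature_id)
  if (length(miss))
    abort(paste0("weighted genes absent from matrix: ", paste(miss, collapse = ", ")))
  w <- weights$weight
  if (all(w == 0)) abort("all weights are zero; no score can be formed")
  m <- expr_values(x)[weights$gene, , drop = FALSE]
  if (expression_mode == "zscore") {
    m <- log2(m + 1)
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    s[s == 0] <- 1   # zero-variance genes carry weight 0 anyway
    m <- (m - mu) / s
  }
  score <- drop(crossprod(m, w)) / sum(abs(w))
  out <- tibble(sample_id = colnames(m), score = unname(score))
  attr(out, "expression_mode") <- expression_mode
  out
}

#' Cross-fitted signature scores
#'
#' In-sample weight derivation (weights and scores from the same cohort, the
#' default single-cohort procedure) overfits: even null gene sets acquire
#' outcome-correlated scores, biasing downstream p-values. This k-fold
#' alternative derives the hazard-ratio weights on k-1 folds and scores only
#' the held-out fold (per-gene log2 z-score parameters are likewise estimated
#' on the training folds), so each sample's score is independent of its own
#' outcome.
#'
#' @inheritParams univariate_gene_hrs
#' @param k Number of folds (default 5).
#' @param weight_mode See [derive_weights()].
#' @param seed Seed for the fold assignment.
#' @return Tibble `sample_id`, `score`, `fold`, in the matrix's sample order.
#' @export
crossfit_scores <- function(x, clin, genes = NULL, k = 5,
                            weight_mode = c("loghr", "sign_only"),
                            log2_transform = TRUE, seed = 1L) {
  weight_mode <- match.arg(weight_mode)
  x <- check_expression(x)
  clin <- check_clinical(clin)
  genes <- genes %||% x$feature_id
  ids <- intersect(sample_ids(x), clin$sample_id)
  if (length(ids) < 2 * k) abort("too few samples for the requested fold count")
  clin <- clin[match(ids, clin$sample_id), ]
  m <- expr_values(x)[genes, ids, drop = FALSE]
  if (log2_transform) m <- log2(m + 1)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(ids)))
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  score <- rep(NA_real_, length(ids))
  for (f in seq_len(k)) {
    tr <- fold != f
    xtr <- x[match(genes, x$feature_id), c("feature_id", ids[tr]), drop = FALSE]
    rec <- univariate_gene_hrs(xtr, clin[tr, ], log2_transform = log2_transform)
    w <- derive_weights(rec, mode = weight_mode)
    if (all(w$weight == 0)) abort("all cross-fitted weights are zero")
    mu <- rowMeans(m[, tr, drop = FALSE])
    sdv <- apply(m[, tr, drop = FALSE], 1, sd)
    sdv[sdv == 0] <- 1
    e <- (m[, !tr, drop = FALSE] - mu) / sdv
    score[!tr] <- drop(crossprod(e, w$weight)) / sum(abs(w$weight))
  }
  tibble(sample_id = ids, score = score, fold = fold)
}
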