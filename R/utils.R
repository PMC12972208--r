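#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange left_join group_by summarise
#'   ungroup bind_rows bind_cols rename n all_of across pull distinct slice
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl map2 imap
#' @importFrom stats quantile rnorm rexp runif setNames sd var median
#'   pchisq qnorm complete.cases IQR ecdf integrate uniroot rbinom ks.test
NULL

# Round half up (away from zero for .5), unlike base round()'s
# round-half-even; cohort percentages are defined with this rule so that
# count-derived tables recompute exactly.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Validate a wide expression table
#'
#' An expression table is a tibble whose first column (`feature_id`) holds
#' unique probe or gene identifiers and whose remaining columns are numeric
#' per-sample intensity vectors (linear scale, nonnegative, finite).
#'
#' @param x A data frame in the wide expression layout.
#' @param require_nonnegative Check that all intensities are >= 0.
#' @return `x` as a tibble, invisibly usable downstream.
#' @keywords internal
check_expression <- function(x, require_nonnegative = TRUE) {
  if (!is.data.frame(x) || ncol(x) < 2)
    abort("expression table must be a data frame with a feature-id column and at least one sample column")
  ids <- x[[1]]
  if (!is.character(ids)) ids <- as.character(ids)
  if (anyDuplicated(ids))
    abort(paste0("duplicate feature ids: ",
                 paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", ")))
  smp <- names(x)[-1]
  if (anyDuplicated(smp))
    abort(paste0("duplicate sample ids: ",
                 paste(unique(smp[duplicated(smp)]), collapse = ", ")))
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("sample columns must be numeric")
  if (any(!is.finite(vals))) abort("expression values must be finite")
  if (require_nonnegative && any(vals < 0)) abort("expression values must be nonnegative")
  x <- as_tibble(x)
  names(x)[1] <- "feature_id"
  x$feature_id <- ids
  x
}

# Wide tibble -> numeric matrix (features x samples)
expr_values <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}

# Numeric matrix -> wide tibble
expr_tibble <- function(m) {
  bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
}

sample_ids <- function(x) names(x)[-1]

check_clinical <- function(clin) {
  if (!is.data.frame(clin) || nrow(clin) == 0) abort("clinical table must be a non-empty data frame")
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(clin))
  if (length(miss)) abort(paste0("clinical table missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(clin$sample_id)) abort("clinical sample ids must be unique")
  if (any(!is.finite(clin$time)) || any(clin$time <= 0)) abort("survival times must be positive and finite")
  if (!all(clin$event %in% c(0, 1))) abort("event indicator must be 0/1")
  as_tibble(clin)
}
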