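test_that("plain-list signatures are read order-preserving and de-duplicated", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("CDKN1A", "IL6", "CDKN1A"), f)
  sig <- read_signature(f)
  expect_identical(sig$genes, c("CDKN1A", "IL6"))
  writeLines(character(), f)
  expect_error(read_signature(f), "empty gene list")
})

test_that("GMT lines parse into named signatures, with line numbers on failure", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SIG\tdesc\tA\tB"), f)
  sig <- read_signature(f)
  expect_identical(sig$name, "SIG")
  expect_identical(sig$genes, c("A", "B"))
  writeLines(c("SIG1\tdesc\tA\tB", "BROKEN\tonly-two-fields"), f)
  expect_error(read_signatures(f), "line 2")
  writeLines(c("SIG1\td\tA", "SIG2\td\tB\tC"), f)
  sigs <- read_signatures(f)
  expect_named(sigs, c("SIG1", "SIG2"))
})

test_that("signature matching partitions symbols and mirrors published match counts", {
  x <- tiny_expr(matrix(1:6, ncol = 2), feature_ids = c("A", "B", "C"))
  mt <- match_signature(gene_signature(c("A", "B", "Z")), x)
  expect_identical(mt$matched, c("A", "B"))
  expect_identical(mt$missing, "Z")
  expect_identical(match_signature(gene_signature(c("B", "A")), x)$missing, character())
  expect_error(match_signature(gene_signature(c("X", "Y")), x), "no gene")

  # a 125-gene set with 3 symbols absent matches 122; a 32-gene set with 2
  # absent matches 30 (the senescence-signature bookkeeping cases)
  universe <- sprintf("GENE%03d", 1:200)
  xg <- tiny_expr(matrix(runif(400), ncol = 2), feature_ids = universe)
  sen <- gene_signature(c(universe[1:122], "ABS1", "ABS2", "ABS3"), "senmayo_like")
  expect_identical(match_signature(sen, xg)$n_matched, 122L)
  li <- gene_signature(c(universe[50:79], "NOPE1", "NOPE2"), "li_like")
  expect_identical(match_signature(li, xg)$n_matched, 30L)
})

test_that("null genes yield near-unit hazard ratios at the expected rate", {
  set.seed(17)
  ok <- logical(200)
  for (r in seq_along(ok)) {
    n <- 1000
    sv <- null_surv(n)
    z <- rnorm(n)
    hr <- fit_cox(data.frame(z = z), sv$time, sv$event)$terms$hr
    ok[r] <- hr >= 0.85 && hr <= 1.18
  }
  expect_gte(mean(ok), 0.95)
})

test_that("per-gene hazard ratios recover a planted log-hazard of 0.7 on average", {
  lnhr <- numeric(100)
  for (r in seq_along(lnhr)) {
    co <- generate_cohort(sim_config(n_samples = 800, n_genes = 3,
                                     n_signature_genes = 1, beta = 0.7,
                                     n_batches = 1, seed = 1700 + r))
    rec <- univariate_gene_hrs(co$expression, co$clinical, genes = "G0001")
    lnhr[r] <- log(rec$hr)
  }
  expect_lt(abs(mean(lnhr) - 0.7), 0.1)
})

test_that("zero-variance genes are flagged with HR = 1 and weight 0", {
  sv <- null_surv(60, rate = 0.05)
  x <- tiny_expr(rbind(rep(100, 60), runif(60, 50, 150)),
                 feature_ids = c("FLAT", "VAR"))
  clin <- tibble::tibble(sample_id = names(x)[-1], time = sv$time, event = sv$event)
  rec <- univariate_gene_hrs(x, clin)
  expect_identical(rec$flag[rec$gene == "FLAT"], "zero_variance")
  expect_identical(rec$hr[rec$gene == "FLAT"], 1)
  w <- derive_weights(rec)
  expect_identical(w$weight[w$gene == "FLAT"], 0)
})

test_that("hazard-ratio weights follow the sign rule with -ln(HR) magnitude", {
  rec <- tibble::tibble(gene = c("R", "N", "P"), hr = c(2, 1, 0.5))
  w <- derive_weights(rec)
  expect_lt(w$weight[1], 0)
  expect_identical(w$weight[2], 0)
  expect_gt(w$weight[3], 0)
  expect_equal(w$weight[1], -log(2), tolerance = 1e-12)
  ws <- derive_weights(rec, mode = "sign_only")
  expect_identical(ws$weight, c(-1, 0, 1))
  expect_error(derive_weights(tibble::tibble(gene = "X", hr = -1)), "finite and > 0")
})

test_that("inverting every hazard ratio negates weights and scores (antisymmetry)", {
  set.seed(23)
  x <- tiny_expr(matrix(runif(60, 50, 500), nrow = 3),
                 feature_ids = c("A", "B", "C"))
  rec <- tibble::tibble(gene = c("A", "B", "C"), hr = c(1.8, 0.6, 1.2))
  w1 <- derive_weights(rec)
  w2 <- derive_weights(dplyr::mutate(rec, hr = 1 / hr))
  expect_equal(w2$weight, -w1$weight, tolerance = 1e-12)
  s1 <- compute_score(x, w1)
  s2 <- compute_score(x, w2)
  expect_equal(s2$score, -s1$score, tolerance = 1e-12)
})

test_that("the score reduces to the expected closed forms", {
  set.seed(29)
  m <- matrix(2^runif(40, 5, 9), nrow = 4)
  x <- tiny_expr(m, feature_ids = c("A", "B", "C", "D"))
  lz <- t(scale(t(log2(m + 1))))
  # uniform +1 weights: mean of the z-scores
  w <- tibble::tibble(gene = c("A", "B", "C", "D"), weight = 1)
  expect_equal(compute_score(x, w)$score, unname(colMeans(lz)), tolerance = 1e-10)
  # single gene with weight -1: minus that gene's z
  w1 <- tibble::tibble(gene = "B", weight = -1)
  expect_equal(compute_score(x, w1)$score, unname(-lz[2, ]), tolerance = 1e-10)
  # symmetric weights on equal z cancel
  x2 <- tiny_expr(rbind(m[1, ], m[1, ]), feature_ids = c("U", "V"))
  w2 <- tibble::tibble(gene = c("U", "V"), weight = c(0.69, -0.69))
  expect_equal(compute_score(x2, w2)$score, rep(0, ncol(m)), tolerance = 1e-10)
  expect_error(compute_score(x, tibble::tibble(gene = "A", weight = 0)), "all weights")
})

test_that("z-scored scores are invariant to positive rescaling of intensities", {
  set.seed(31)
  m <- matrix(2^runif(50, 8, 13), nrow = 5)   # MAS5-like post-scaling range
  x <- tiny_expr(m)
  w <- tibble::tibble(gene = x$feature_id, weight = c(0.4, -0.2, 0.9, -0.5, 0.1))
  s1 <- compute_score(x, w)$score
  s2 <- compute_score(tiny_expr(m * 7.3), w)$score
  expect_equal(s1, s2, tolerance = 1e-2)
  # raw mode is, by design, scale-dependent
  r1 <- compute_score(x, w, expression_mode = "raw")$score
  r2 <- compute_score(tiny_expr(m * 2), w, expression_mode = "raw")$score
  expect_equal(r2, 2 * r1, tolerance = 1e-10)
})

test_that("planted weight signs are recovered and scores point the right way", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    co <- generate_cohort(sim_config(n_samples = 500, n_genes = 20,
                                     n_signature_genes = 10,
                                     beta = c(rep(0.6, 5), rep(-0.6, 5)),
                                     seed = 2400 + s))
    rec <- univariate_gene_hrs(co$expression, co$clinical,
                               genes = co$truth$signature_gene_ids)
    w <- derive_weights(rec)
    planted <- co$truth$beta_per_gene
    hits <- hits + sum(sign(w$weight) == -sign(planted[w$gene]))
    total <- total + length(planted)
  }
  expect_gte(hits / total, 0.9)

  # all-protective signature: the upper-half score group outlives the lower
  co <- generate_cohort(sim_config(n_samples = 400, n_genes = 12,
                                   n_signature_genes = 6, beta = -0.8, seed = 77))
  rec <- univariate_gene_hrs(co$expression, co$clinical,
                             genes = co$truth$signature_gene_ids)
  sc <- compute_score(co$expression[1:6, ], derive_weights(rec))
  hi <- sc$score > median(sc$score)
  km_hi <- km_estimate(co$clinical$time[hi], co$clinical$event[hi])
  km_lo <- km_estimate(co$clinical$time[!hi], co$clinical$event[!hi])
  med_surv <- function(km) min(c(km$time[km$survival <= 0.5], Inf))
  expect_gt(med_surv(km_hi), med_surv(km_lo))
})
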