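make_expr <- function(ng = 12, ns = 8, seed = 2) {
  set.seed(seed)
  matrix(rnorm(ng * ns), nrow = ng,
         dimnames = list(sprintf("GENE%02d", seq_len(ng)),
                         sprintf("S%02d", seq_len(ns))))
}

test_that("GMT parsing, sidecar modes and mode counts", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("ModA\tdesc\tGENE01\tGENE02\tGENE03",
               "ModB\tdesc\tGENE04\tGENE05"), gmt)
  reg <- read_module_registry(gmt)
  expect_length(reg, 2)
  expect_true(all(vapply(reg, `[[`, "", "mode") == "median"))

  side <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(ModB = list(mode = "first_pc")), side,
                       auto_unbox = TRUE)
  reg2 <- read_module_registry(gmt, side)
  counts <- registry_mode_counts(reg2)
  expect_equal(counts[["median"]], 1L)
  expect_equal(counts[["first_pc"]], 1L)

  ## format errors carry the line number / unknown name
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("ModA\tdesc\tG1", "ModA\tdesc\tG2"), bad)
  expect_error(read_module_registry(bad), "line 2.*duplicate")
  writeLines("short\tonly", bad)
  expect_error(read_module_registry(bad), "line 1")
  side2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(Nope = list(mode = "median")), side2,
                       auto_unbox = TRUE)
  expect_error(read_module_registry(gmt, side2), "Nope")
})

test_that("a four-route registry reaches the full published collection size", {
  mods <- c(
    lapply(1:221, function(i) module_definition(paste0("med", i), "G1")),
    lapply(1:77, function(i) {
      module_definition(paste0("pc", i), c("G1", "G2"), mode = "first_pc")
    }),
    lapply(1:22, function(i) {
      module_definition(paste0("cen", i), c("G1", "G2"),
                        mode = "centroid_corr",
                        centroids = list(A = c(G1 = 1, G2 = 0)))
    }),
    lapply(1:3, function(i) {
      module_definition(paste0("pub", i), "G1", mode = "published_model",
                        weights = c(G1 = 1))
    }))
  reg <- module_registry(mods)
  expect_length(reg, 323)
  expect_equal(unname(registry_mode_counts(reg)), c(221L, 77L, 22L, 3L))
  ## published exclusion lists: 4 signatures -> 319, 5 -> 318
  expect_length(exclude_modules(reg, c("pc1", "pub1", "pub2", "pub3")), 319)
  expect_length(exclude_modules(reg, c("pc1", "pub1", "pub2", "pub3",
                                       "med1")), 318)
  expect_identical(exclude_modules(reg, character()), reg)
  expect_error(exclude_modules(reg, "missing_module"), "Valid names")
})

test_that("gene matching is case-insensitive and enforces the threshold", {
  expr <- make_expr()
  rownames(expr)[1] <- "Erbb2"
  m <- module_definition("m", c("ERBB2", "GENE02"))
  mg <- match_genes(expr, m)
  expect_equal(mg$n_matched, 2)
  expect_equal(mg$fraction, 1.0)

  m2 <- module_definition("m2", c("GENE02", "GENE03", paste0("NOPE", 1:8)))
  mg2 <- match_genes(expr, m2, min_fraction = 0.5)
  expect_equal(mg2$fraction, 0.2)
  expect_false(mg2$scoreable)

  m3 <- module_definition("m3", c("ZZZ1", "ZZZ2"))
  expect_warning(mg3 <- match_genes(expr, m3), "no genes matched")
  expect_false(mg3$scoreable)
})

test_that("median scoring centers genes by cohort median then takes the gene median", {
  expr <- matrix(c(1, 2, 7,
                   1, 2, 7,
                   1, 2, 7), nrow = 3, byrow = TRUE,
                 dimnames = list(c("G1", "G2", "G3"), c("S1", "S2", "S3")))
  m <- module_definition("m", c("G1", "G2", "G3"))
  ## after median-centering each gene becomes (-1, 0, 5); median over genes
  res <- score_median(expr, m)
  expect_equal(unname(res$score), c(-1, 0, 5))

  ## hand-constructed per-sample values (1, 2, 7) -> median 2
  expr2 <- matrix(c(1, 2, 7), nrow = 3,
                  dimnames = list(c("G1", "G2", "G3"), "S1"))
  res2 <- score_median(expr2, m, center = FALSE)
  expect_equal(unname(res2$score), 2)

  ## single-gene module: score equals the centered gene row
  m1 <- module_definition("m1", "G1")
  res1 <- score_median(expr, m1)
  expect_equal(unname(res1$score), expr["G1", ] - median(expr["G1", ]),
               ignore_attr = TRUE)

  ## order of genes within the module is irrelevant
  m_rev <- module_definition("mr", c("G3", "G1", "G2"))
  expect_equal(score_median(expr, m_rev)$score, res$score)
})

test_that("first-PC scores match an independent eigendecomposition", {
  expr <- make_expr(ng = 6, ns = 10, seed = 5)
  m <- module_definition("pc", rownames(expr)[1:3], mode = "first_pc")
  res <- score_first_pc(expr, m)

  ## oracle: z-score, dense eigensolver on the gene-gene covariance
  x <- expr[1:3, ]
  z <- t(scale(t(x)))
  ev <- eigen(cov(t(z)), symmetric = TRUE)
  proj <- drop(t(z) %*% ev$vectors[, 1])
  if (cor(proj, colMeans(z)) < 0) proj <- -proj
  proj <- proj / sd(proj)
  expect_equal(unname(res$score), unname(proj), tolerance = 1e-8)
  expect_equal(sd(res$score), 1, tolerance = 1e-12)

  ## rank-1 case: two identical standardized profiles across 3 samples
  e2 <- matrix(c(-1, 0, 1, -2, 0, 2), nrow = 2, byrow = TRUE,
               dimnames = list(c("G1", "G2"), c("S1", "S2", "S3")))
  m2 <- module_definition("r1", c("G1", "G2"), mode = "first_pc")
  r2 <- score_first_pc(e2, m2)
  expect_equal(cor(r2$score, c(-1, 0, 1)), 1, tolerance = 1e-12)

  ## orientation rule: global sign flip of the input leaves the score
  ## correlated >= 0 with the (new) mean member profile
  r_neg <- score_first_pc(-expr, m)
  expect_gte(cor(r_neg$score, colMeans(t(scale(t(-expr[1:3, ]))))), 0)
  expect_gte(cor(res$score, colMeans(z)), 0)
})

test_that("first-PC training constants transfer to unseen samples", {
  expr <- make_expr(ng = 8, ns = 20, seed = 6)
  m <- module_definition("pc", rownames(expr)[1:4], mode = "first_pc")
  tr <- score_first_pc(expr[, 1:12], m)
  te <- score_first_pc(expr[, 13:20], m, constants = tr$constants)
  ## applying train constants to the training samples reproduces the score
  again <- score_first_pc(expr[, 1:12], m, constants = tr$constants)
  expect_equal(again$score, tr$score, tolerance = 1e-10)
  expect_length(te$score, 8)
})

test_that("centroid-correlation scores agree with hand-ranked tables", {
  cen <- c(G1 = 0.1, G2 = 0.4, G3 = 0.9, G4 = 0.2, G5 = 0.6)
  m <- module_definition("sub", names(cen), mode = "centroid_corr",
                         centroids = list(C1 = cen))
  expr <- matrix(c(5, 1, 2, 4, 3,       # sample equal-ranked vs reversed
                   0.9, 0.6, 0.4, 0.2, 0.1), ncol = 2,
                 dimnames = list(names(cen), c("S1", "S2")))
  res <- score_centroid_correlation(expr, m)
  ## S1 ranks (5,1,2,4,3) vs centroid ranks (1,3,5,2,4):
  ## hand Spearman = 1 - 6*sum(d^2)/(n(n^2-1)), d = (4,-2,-3,2,-1)
  d <- c(4, -2, -3, 2, -1)
  expect_equal(res$score["sub.C1", "S1"],
               1 - 6 * sum(d^2) / (5 * 24), tolerance = 1e-12)

  ## profile equal to the centroid -> 1; reversed order -> -1
  expr2 <- cbind(S1 = cen, S2 = rev(unname(cen)))
  rownames(expr2) <- names(cen)
  r2 <- score_centroid_correlation(expr2, m)
  expect_equal(unname(r2$score["sub.C1", "S1"]), 1)
  m_rev <- module_definition("rev", names(cen), mode = "centroid_corr",
                             centroids = list(C1 = rev(cen)))
  ## constant sample profile -> NA with a warning
  expr3 <- cbind(S1 = rep(1, 5))
  rownames(expr3) <- names(cen)
  expect_warning(r3 <- score_centroid_correlation(expr3, m), "constant")
  expect_true(is.na(r3$score["sub.C1", "S1"]))
})

test_that("published-model scores are exact dot products", {
  expr <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                 dimnames = list(c("G1", "G2", "G3"), c("S1", "S2")))
  w <- c(G1 = 0.5, G2 = -1, G3 = 2)
  m <- module_definition("pub", names(w), mode = "published_model",
                         weights = w, offset = 0.25)
  res <- score_published_model(expr, m)
  expect_equal(unname(res$score),
               0.25 + c(sum(w * expr[, 1]), sum(w * expr[, 2])),
               tolerance = 1e-12)

  ## zero weights -> all scores equal the offset; missing genes contribute 0
  m0 <- module_definition("z", names(w), mode = "published_model",
                          weights = w * 0)
  expect_equal(unname(score_published_model(expr, m0)$score), c(0, 0))
  m_part <- module_definition("p", c("G1", "MISSING1"),
                              mode = "published_model",
                              weights = c(G1 = 1, MISSING1 = 100))
  rp <- score_published_model(expr, m_part)
  expect_equal(unname(rp$score), unname(expr["G1", ]))
  expect_equal(rp$missing_genes, "MISSING1")
})

test_that("compute_all_scores keeps registry order and is permutation-equivariant", {
  expr <- make_expr(ng = 12, ns = 10, seed = 9)
  reg <- module_registry(list(
    module_definition("med", rownames(expr)[1:3]),
    module_definition("pc", rownames(expr)[4:7], mode = "first_pc"),
    module_definition("cen", rownames(expr)[8:10], mode = "centroid_corr",
                      centroids = list(A = setNames(c(1, 2, 3),
                                                    rownames(expr)[8:10]),
                                       B = setNames(c(3, 1, 2),
                                                    rownames(expr)[8:10]))),
    module_definition("unmatchable", c("NOPE1", "NOPE2"))))
  ms <- suppressWarnings(compute_all_scores(expr, reg))
  expect_equal(rownames(ms$scores), c("med", "pc", "cen.A", "cen.B"))
  expect_false(ms$report$scoreable[ms$report$module == "unmatchable"])

  perm <- sample(ncol(expr))
  ms_p <- suppressWarnings(compute_all_scores(expr[, perm], reg))
  expect_equal(abs(ms_p$scores), abs(ms$scores[, perm]), tolerance = 1e-8)
  ## all modules unscoreable -> error
  reg_bad <- module_registry(list(module_definition("x", "NOPE")))
  expect_error(suppressWarnings(compute_all_scores(expr, reg_bad)),
               "no module")
})

test_that("registries round-trip through GMT + sidecar exactly", {
  reg <- module_registry(list(
    module_definition("med", c("G1", "G2"), note = "plain"),
    module_definition("pc", c("G1", "G3"), mode = "first_pc",
                      direction_hint = -1),
    module_definition("cen", c("G1", "G2"), mode = "centroid_corr",
                      centroids = list(A = c(G1 = 0.5, G2 = -0.5))),
    module_definition("pub", c("G1",  "G2"), mode = "published_model",
                      weights = c(G1 = 1.5, G2 = -2), offset = 0.1)))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  side <- withr::local_tempfile(fileext = ".json")
  write_module_registry(reg, gmt, side)
  reg2 <- read_module_registry(gmt, side)
  for (nm in names(reg)) {
    expect_equal(reg2[[nm]]$mode, reg[[nm]]$mode)
    expect_equal(reg2[[nm]]$genes, reg[[nm]]$genes)
  }
  expect_equal(unlist(reg2$pub$weights), unlist(reg$pub$weights))
  expect_equal(reg2$pub$offset, reg$pub$offset)
  expect_equal(unlist(reg2$cen$centroids$A), unlist(reg$cen$centroids$A))
  expect_equal(reg2$pc$direction_hint, reg$pc$direction_hint)
})
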