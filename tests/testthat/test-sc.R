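test_that("high-expression flags use the strict non-zero median rule", {
  counts <- matrix(0, 2, 5, dimnames = list(c("C3", "G1"), paste0("c", 1:5)))
  counts["C3", ] <- c(0, 0, 1, 2, 3)
  counts["G1", ] <- 1
  cm <- makeCells(Matrix::Matrix(counts, sparse = TRUE),
                  subject = rep(c("D1", "D2"), c(3, 2)),
                  arm = rep(c("naive", "NAT"), c(3, 2)))
  fl <- flagHighExpression(cm, "C3", assay = "counts")
  expect_equal(fl$cutoff, 2)
  expect_identical(unname(fl$flags), c(FALSE, FALSE, FALSE, FALSE, TRUE))

  # all non-zero equal -> no flags (strict inequality)
  counts["C3", ] <- c(0, 2, 2, 2, 0)
  cm2 <- makeCells(Matrix::Matrix(counts, sparse = TRUE),
                   subject = "D1", arm = "naive")
  expect_false(any(flagHighExpression(cm2, "C3", assay = "counts")$flags))

  # single non-zero cell is its own median, not flagged
  counts["C3", ] <- c(0, 0, 7, 0, 0)
  cm3 <- makeCells(Matrix::Matrix(counts, sparse = TRUE),
                   subject = "D1", arm = "naive")
  expect_false(any(flagHighExpression(cm3, "C3", assay = "counts")$flags))

  # all-zero gene errors
  counts["C3", ] <- 0
  cm4 <- makeCells(Matrix::Matrix(counts, sparse = TRUE),
                   subject = "D1", arm = "naive")
  expect_error(flagHighExpression(cm4, "C3", assay = "counts"), "non-zero")
})

test_that("flags are order-invariant and monotone in the values", {
  set.seed(31)
  counts <- matrix(rpois(300, 1), 3, 100,
                   dimnames = list(c("C3", "G1", "G2"), sprintf("c%03d", 1:100)))
  cm <- makeCells(Matrix::Matrix(counts, sparse = TRUE),
                  subject = "D1", arm = "naive")
  fl <- flagHighExpression(cm, "C3", assay = "counts")
  perm <- sample(100)
  cmp <- makeCells(Matrix::Matrix(counts[, perm], sparse = TRUE),
                   subject = "D1", arm = "naive")
  flp <- flagHighExpression(cmp, "C3", assay = "counts")
  expect_identical(flp$flags[names(fl$flags)], fl$flags)

  # raising a flagged cell's own value keeps it flagged and can only move
  # the cutoff up
  counts2 <- counts
  j <- which(fl$flags)[1]
  counts2["C3", j] <- counts2["C3", j] + 50
  fl2 <- flagHighExpression(
    makeCells(Matrix::Matrix(counts2, sparse = TRUE), "D1", "naive"),
    "C3", assay = "counts")
  expect_true(fl2$flags[j])
  expect_gte(fl2$cutoff, fl$cutoff)
})

test_that("background genes are the rank-adjacent non-signature genes", {
  # hand-ordered means: A1 2nd, A2 4th; candidates B1..B4 at ranks 1,3,5,6
  counts <- matrix(c(10, 30, 5, 20, 40, 50), 6, 1,
                   dimnames = list(c("A1", "A2", "B1", "B2", "B3", "B4"),
                                   "c1"))
  counts <- cbind(c1 = counts[, 1], c2 = counts[, 1])
  cm <- makeCells(Matrix::Matrix(counts, sparse = TRUE),
                  subject = c("D1", "D2"), arm = c("naive", "NAT"))
  sig <- list(GeneSignature("st", c("A1", "A2")))
  asg <- assignSubtypes(cm, sig, assay = "counts")
  # means: B1=5 (r1), A1=10 (r2), B2=20 (r3), A2=30 (r4), B3=40 (r5), B4=50 (r6)
  # A1 (rank 2): B1 and B2 equidistant -> lower rank B1; A2 (rank 4): B2 (r3)
  # and B3 (r5) equidistant -> lower rank B2
  expect_identical(asg$background$st, c("B1", "B2"))
  # never selects signature genes, deterministic
  expect_identical(assignSubtypes(cm, sig, assay = "counts")$background$st,
                   c("B1", "B2"))

  # zero-expression cell gets no label
  counts0 <- counts; counts0[, "c2"] <- 0
  cm0 <- makeCells(Matrix::Matrix(counts0, sparse = TRUE),
                   subject = c("D1", "D2"), arm = c("naive", "NAT"))
  asg0 <- assignSubtypes(cm0, sig, assay = "counts")
  expect_false(asg0$assigned["c2", "st"])

  # fewer candidates than signature genes errors
  sig_big <- list(GeneSignature("big", c("A1", "A2", "B1", "B2", "B3")))
  expect_error(assignSubtypes(cm, sig_big, assay = "counts"),
               "fewer candidate background genes")
})

test_that("planted subtype signatures are recovered above background", {
  sim <- generateCells(cellSimConfig(seed = 41, cells_per_subject = 120))
  cm <- normalizeCells(sim$cells)
  caf <- sim$truth$cell_manifest[sim$truth$cell_manifest$cell_type == "CAF", ]
  asg <- assignSubtypes(cm, sim$signatures,
                        cell_subset = function(md) md$cell_type == "CAF")
  idx <- cbind(match(caf$cell_id, rownames(asg$assigned)),
               match(caf$subtype, colnames(asg$assigned)))
  on_target <- mean(asg$assigned[idx])
  off_target <- mean(vapply(colnames(asg$assigned), function(st)
    mean(asg$assigned[caf$cell_id[caf$subtype != st], st]), numeric(1)))
  expect_gte(on_target, 0.75)
  expect_lt(off_target, on_target - 0.3)

  # single-label mode returns one label or NA
  asg1 <- assignSubtypes(cm, sim$signatures, mode = "single",
                         cell_subset = function(md) md$cell_type == "CAF")
  expect_true(all(is.na(asg1$labels) |
                    asg1$labels %in% names(sim$signatures)))
})

test_that("the linear mixed model degenerates to the subject-mean t-test", {
  # zero within-subject variance: every cell of a subject has the same value
  subj <- rep(sprintf("D%d", 1:6), each = 10)
  arm <- rep(c("naive", "NAT"), each = 30)
  mu <- rep(c(1, 2, 1.5, 3, 2.5, 3.5), each = 10)
  counts <- matrix(0, 2, 60, dimnames = list(c("C3", "G1"),
                                             sprintf("c%02d", 1:60)))
  counts["C3", ] <- mu
  cm <- makeCells(Matrix::Matrix(counts, sparse = TRUE), subj, arm)
  res <- lmmExpressionTest(cm, "C3", assay = "counts")
  sm <- tapply(mu, subj, mean)
  tt <- t.test(sm[4:6], sm[1:3], var.equal = TRUE)
  expect_identical(res$method, "subject-mean t-test")
  expect_equal(res$estimate, unname(tt$estimate[1] - tt$estimate[2]))
  expect_equal(res$p_two_tailed, tt$p.value)
  expect_equal(res$p_one_tailed, tt$p.value / 2)   # estimate is positive

  # single subject per arm is confounded
  cm2 <- makeCells(Matrix::Matrix(counts[, 1:20], sparse = TRUE),
                   subject = rep(c("D1", "D2"), each = 10),
                   arm = rep(c("naive", "NAT"), each = 10))
  expect_error(lmmExpressionTest(cm2, "C3", assay = "counts"),
               "two subjects per arm")
})

test_that("the mixed model detects planted subject-level expression shifts", {
  hits <- 0L
  for (seed in 1:12) {
    set.seed(seed)
    n_subj <- 10; n_cells <- 60
    subj <- rep(sprintf("D%02d", 1:(2 * n_subj)), each = n_cells)
    arm <- rep(c("naive", "NAT"), each = n_subj * n_cells)
    shift <- ifelse(arm == "NAT", 1, 0)
    y <- rnorm(2 * n_subj * n_cells, 3, 1) +
      rep(rnorm(2 * n_subj, 0, 0.3), each = n_cells) + shift
    counts <- matrix(pmax(y, 0), 1, length(y),
                     dimnames = list("C3", sprintf("c%05d", seq_along(y))))
    cm <- makeCells(Matrix::Matrix(counts, sparse = TRUE), subj, arm)
    res <- lmmExpressionTest(cm, "C3", assay = "counts")
    hits <- hits + (res$p_one_tailed < 0.05)
  }
  expect_gte(hits, 10L)
})

test_that("proportion test reports exact per-arm percentages and null behavior", {
  set.seed(33)
  n <- 4000
  subj <- rep(sprintf("D%02d", 1:20), each = n / 20)
  arm <- rep(c("naive", "NAT"), each = n / 2)
  flags <- setNames(runif(n) < 0.08, sprintf("c%04d", 1:n))
  meta <- data.frame(subject = subj, arm = arm,
                     row.names = names(flags))
  res <- glmmProportionTest(flags, meta)
  expect_equal(unname(res$pct["naive"]),
               100 * mean(flags[arm == "naive"]), tolerance = 1e-12)
  expect_equal(unname(res$pct["NAT"]),
               100 * mean(flags[arm == "NAT"]), tolerance = 1e-12)
  expect_lt(abs(res$estimate), 0.8)
  expect_false(res$separation)

  # separation: one arm all-unflagged is still reported
  flags2 <- flags
  flags2[arm == "naive"] <- FALSE
  res2 <- glmmProportionTest(flags2, meta)
  expect_true(res2$separation)
  expect_equal(unname(res2$pct["naive"]), 0)
})
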