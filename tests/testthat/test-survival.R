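test_that("complement subject scores are TME means per panel gene", {
  panel <- complementPanel()
  vals <- matrix(5, length(panel) + 1, 5,
                 dimnames = list(c(panel, "OTHER"), paste0("S", 1:5)))
  vals["C3", ] <- c(2, 6, 9, 1, 1)
  seg <- toySegTable(colnames(vals),
                     compartment = c("TME", "TME", "TME", "carcinoma",
                                     "carcinoma"),
                     subject = c("P1", "P1", "P2", "P2", "P3"),
                     arm = "NAT")
  em <- makeExprSet(vals, compartment = seg$compartment,
                    subject = seg$subject_id, arm = seg$arm)
  expect_warning(css <- complementSubjectScore(em), "P3")
  expect_equal(unname(css$panel_matrix["P1", "C3"]), 4)    # mean of 2, 6
  expect_equal(unname(css$panel_matrix["P2", "C3"]), 9)    # single TME segment
  expect_equal(unname(css$panel_matrix["P2", "C7"]), 5)

  expect_error(complementSubjectScore(em[setdiff(rownames(em), "C4B"), ]),
               "C4B")
})

test_that("stratification recovers planted clusters and labels by mean", {
  set.seed(21)
  for (i in 1:10) {
    n_hi <- sample(3:6, 1); n_lo <- sample(4:8, 1)
    pm <- rbind(
      matrix(2 ^ (5 + rnorm(n_hi * 5, 0, 0.25)), n_hi),
      matrix(2 ^ (4 + rnorm(n_lo * 5, 0, 0.25)), n_lo))  # 1 log2 = 4 x 0.25sd
    rownames(pm) <- sprintf("P%02d", seq_len(n_hi + n_lo))
    colnames(pm) <- complementPanel()
    st <- stratifyComplement(pm)
    expect_identical(unname(st$labels),
                     rep(c("high", "low"), c(n_hi, n_lo)))
    # invariance to subject permutation
    perm <- sample(nrow(pm))
    st2 <- stratifyComplement(pm[perm, ])
    expect_identical(st2$labels[rownames(pm)], st$labels)
  }
  # degenerate input
  flat <- matrix(3, 5, 5, dimnames = list(paste0("P", 1:5),
                                          complementPanel()))
  expect_error(stratifyComplement(flat), "degenerate")
  expect_error(stratifyComplement(flat[1:3, ]), "at least 4")
})

test_that("log-rank statistic equals the hand risk-table oracle", {
  sv <- data.frame(subject_id = paste0("s", 1:6), time_months = 1:6,
                   event = 1)
  groups <- setNames(rep(c("A", "B"), each = 3), sv$subject_id)
  km <- kmLogrank(sv, groups)
  orc <- oracleLogrank(sv$time_months, sv$event, unname(groups))
  expect_equal(km$chisq, orc$chisq, tolerance = 1e-10)
  expect_equal(km$p, pchisq(orc$chisq, 1, lower.tail = FALSE))

  # identical groups: duplicate the same data under two labels
  sv2 <- data.frame(subject_id = paste0("s", 1:8),
                    time_months = rep(c(2, 4, 6, 8), 2),
                    event = rep(c(1, 0, 1, 1), 2))
  g2 <- setNames(rep(c("A", "B"), each = 4), sv2$subject_id)
  km2 <- kmLogrank(sv2, g2)
  expect_equal(km2$chisq, 0, tolerance = 1e-12)
  expect_equal(km2$p, 1, tolerance = 1e-10)

  # all censored
  sv3 <- sv; sv3$event <- 0
  expect_equal(kmLogrank(sv3, groups)$chisq, 0)

  expect_error(kmLogrank(sv, groups[1:5]), "missing")
})

test_that("Cox fit matches grid-maximized partial likelihood and flags issues", {
  set.seed(22)
  valid <- 0
  while (valid < 15) {
    n <- sample(4:8, 1)
    sv <- data.frame(subject_id = paste0("s", 1:n),
                     time_months = sample(seq(1, 60, by = 1), n),
                     event = rbinom(n, 1, 0.8),
                     x = rep_len(c(0, 1), n))
    if (sum(sv$event) < 2) next
    fit <- tryCatch(suppressWarnings(coxPH(sv, covariates = "x")),
                    error = function(e) NULL)
    if (is.null(fit) || fit$table$flagged) next
    b_grid <- oracleCoxGrid(sv$time_months, sv$event, sv$x)
    if (abs(b_grid) > 4.5) next
    expect_lt(abs(log(fit$table$hr) - b_grid), 2e-3)
    valid <- valid + 1
  }
})

test_that("Cox estimates are invariant to time rescaling and covariate shifts", {
  set.seed(23)
  n <- 40
  x <- rbinom(n, 1, 0.5)
  sv <- data.frame(subject_id = paste0("s", 1:n),
                   time_months = rexp(n, 0.05 * exp(-1 * x)),
                   event = rbinom(n, 1, 0.8), x = x, age = rnorm(n, 65, 8))
  f1 <- coxPH(sv, covariates = c("x", "age"))
  sv2 <- sv; sv2$time_months <- sv2$time_months * 12
  f2 <- coxPH(sv2, covariates = c("x", "age"))
  expect_equal(f1$table$hr, f2$table$hr, tolerance = 1e-8)
  sv3 <- sv; sv3$age <- sv3$age + 100
  f3 <- coxPH(sv3, covariates = c("x", "age"))
  expect_equal(f1$table$hr, f3$table$hr, tolerance = 1e-6)

  sv$k <- 1
  expect_error(coxPH(sv, covariates = "k"), "constant")
})

test_that("perfect separation is flagged with an unbounded CI", {
  sv <- data.frame(subject_id = paste0("s", 1:8),
                   time_months = c(1, 2, 3, 4, 30, 40, 50, 60),
                   event = c(rep(1, 4), rep(0, 4)),
                   x = c(rep(1, 4), rep(0, 4)))
  ws <- capture_warnings(fit <- coxPH(sv, covariates = "x"))
  expect_true(any(grepl("monotone", ws)))
  expect_true(fit$table$flagged)
  expect_identical(fit$table$hi, Inf)
})

test_that("paired pre/post deltas classify planted increases", {
  genes <- c("C3", "OTHER")
  segs <- sprintf("S%02d", 1:12)
  vals <- matrix(8, 2, 12, dimnames = list(genes, segs))
  seg <- toySegTable(segs, compartment = "TME",
                     subject = rep(c("P1", "P2"), each = 6), arm = "NAT")
  pairs <- list(P1 = list(pre = segs[1:3], post = segs[4:6]),
                P2 = list(pre = segs[7:9], post = segs[10:12]))

  # pre = post -> delta 0, not-increased
  em <- makeExprSet(vals, compartment = seg$compartment,
                    subject = seg$subject_id, arm = seg$arm)
  res <- pairedPrePostDelta(em, pairs = pairs)
  expect_equal(res$delta, c(0, 0))
  expect_identical(res$classification, c("not-increased", "not-increased"))

  # planted 2-fold increase with modest noise -> increased
  set.seed(24)
  ok <- 0L
  for (i in 1:10) {
    v2 <- vals
    v2["C3", ] <- 8 * 2 ^ rnorm(12, 0, 0.25)
    v2["C3", c(segs[4:6], segs[10:12])] <-
      v2["C3", c(segs[4:6], segs[10:12])] * 2
    em2 <- makeExprSet(v2, compartment = seg$compartment,
                       subject = seg$subject_id, arm = seg$arm)
    r2 <- pairedPrePostDelta(em2, pairs = pairs)
    ok <- ok + sum(r2$classification == "increased")
  }
  expect_gte(ok, 18L)   # 20 subject-sides, >=95% expected power

  # single segment per side: delta reported, test skipped
  pairs1 <- list(P1 = list(pre = segs[1], post = segs[4]))
  v3 <- vals; v3["C3", segs[4]] <- 32
  em3 <- makeExprSet(v3, compartment = seg$compartment,
                     subject = seg$subject_id, arm = seg$arm)
  expect_warning(r3 <- pairedPrePostDelta(em3, pairs = pairs1), "single segment")
  expect_equal(r3$delta, 2)
  expect_true(is.na(r3$p_value))

  # incomplete pair skipped with warning
  expect_warning(r4 <- pairedPrePostDelta(em, pairs = list(
    P1 = list(pre = segs[1:3], post = character(0)))), "incomplete")
  expect_identical(nrow(r4), 0L)
})
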