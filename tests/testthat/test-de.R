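test_that("subject averaging is linear mean then log2 with floor", {
  vals <- matrix(c(8, 4, 16, 0), 1, 4,
                 dimnames = list("G1", paste0("S", 1:4)))
  seg <- toySegTable(colnames(vals),
                     compartment = c("TME", "TME", "TME", "TME"),
                     subject = c("P1", "P2", "P2", "P3"),
                     arm = c("naive", "naive", "naive", "NAT"))
  sp <- subjectAverage(makeExprSet(vals, subject = seg$subject_id,
                                   compartment = seg$compartment,
                                   arm = seg$arm),
                       compartment = "TME")
  expect_equal(unname(sp@exprs["G1", "P1"]), 3)               # log2(8)
  expect_equal(unname(sp@exprs["G1", "P2"]), log2(10))        # mean before log
  expect_equal(unname(sp@exprs["G1", "P3"]), -1)              # floor 0.5

  # subject with no qualifying segments is excluded with a warning
  seg2 <- toySegTable(colnames(vals),
                      compartment = c("carcinoma", "TME", "TME", "TME"),
                      subject = c("P1", "P2", "P2", "P3"),
                      arm = "naive")
  expect_warning(
    sp2 <- subjectAverage(makeExprSet(vals, subject = seg2$subject_id,
                                      compartment = seg2$compartment,
                                      arm = seg2$arm),
                          compartment = "TME"),
    "P1")
  expect_identical(colnames(sp2@exprs), c("P2", "P3"))
})

test_that("treatment DE recovers the closed-form OLS estimate", {
  Y <- matrix(c(1, 1, 2, 2), 1, 4,
              dimnames = list("G1", paste0("P", 1:4)))
  sp <- makeProfile(Y, arm = c("naive", "naive", "NAT", "NAT"))
  de <- fitTreatmentDE(sp, covariates = character(0))
  expect_equal(de$estimate, 1)
  expect_identical(de$direction, "up")

  # identical values in both arms
  Y2 <- matrix(c(3, 3, 3, 3), 1, 4, dimnames = dimnames(Y))
  de2 <- fitTreatmentDE(makeProfile(Y2, arm = c("naive", "naive", "NAT", "NAT")),
                        covariates = character(0))
  expect_equal(de2$estimate, 0)
  expect_equal(de2$p_value, 1)
})

test_that("treatment DE matches the normal-equations oracle with covariates", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(8:14, 1)
    arm <- rep(c("naive", "NAT"), length.out = n)
    covs <- data.frame(age = rnorm(n, 65, 8),
                       sex = sample(c("M", "F"), n, replace = TRUE),
                       grade = sample(c("G1", "G2"), n, replace = TRUE),
                       stage = sample(1:3, n, replace = TRUE))
    Y <- matrix(rnorm(5 * n), 5, n,
                dimnames = list(paste0("G", 1:5), paste0("P", 1:n)))
    sp <- makeProfile(Y, arm, covs)
    de <- fitTreatmentDE(sp)
    X <- cbind(1, as.numeric(arm == "NAT"), covs$age - mean(covs$age),
               as.numeric(covs$sex == "M"), as.numeric(covs$grade == "G2"),
               covs$stage)
    for (g in 1:5)
      expect_equal(de$estimate[g], unname(oracleOLS(X, Y[g, ])[2]),
                   tolerance = 1e-8)
  }
})

test_that("shifting one arm shifts only the treatment estimate by that amount", {
  set.seed(11)
  Y <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("G", 1:4), paste0("P", 1:10)))
  arm <- rep(c("naive", "NAT"), 5)
  de0 <- fitTreatmentDE(makeProfile(Y, arm), covariates = character(0))
  Y1 <- Y
  Y1[, arm == "NAT"] <- Y1[, arm == "NAT"] + 0.7
  de1 <- fitTreatmentDE(makeProfile(Y1, arm), covariates = character(0))
  expect_equal(de1$estimate, de0$estimate + 0.7, tolerance = 1e-12)
})

test_that("rank-deficient designs fail with the collinear column named", {
  Y <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("G1", "G2"), paste0("P", 1:4)))
  covs <- data.frame(age = c(60, 60, 70, 70))   # collinear with treatment
  sp <- makeProfile(Y, arm = c("naive", "naive", "NAT", "NAT"), covs)
  expect_error(fitTreatmentDE(sp, covariates = "age"), "collinear")
})

test_that("compartment markers split planted genes by sign", {
  set.seed(5)
  n_subj <- 6
  segs <- sprintf("S%02d", 1:(2 * n_subj))
  compartment <- rep(c("carcinoma", "TME"), n_subj)
  subject <- rep(sprintf("P%d", 1:n_subj), each = 2)
  vals <- matrix(rlnorm(20 * 2 * n_subj, 3, 0.2), 20,
                 dimnames = list(sprintf("G%02d", 1:20), segs))
  vals["G01", compartment == "carcinoma"] <-
    vals["G01", compartment == "carcinoma"] * 4
  vals["G02", compartment == "TME"] <- vals["G02", compartment == "TME"] * 4
  em <- makeExprSet(vals, compartment = compartment, subject = subject,
                    arm = "NAT")
  mk <- compartmentMarkers(em, arm = "NAT")
  expect_true("G01" %in% mk$carcinoma_high)
  expect_true("G02" %in% mk$tme_high)
  expect_false("G01" %in% mk$tme_high)

  # single subject: no residual degrees of freedom
  em1 <- em[, 1:2]
  expect_error(compartmentMarkers(em1, arm = "NAT"), "residual")
})

test_that("permuted compartment labels yield about nominal marker rates", {
  set.seed(6)
  n_subj <- 10
  compartment <- rep(c("carcinoma", "TME"), n_subj)
  subject <- rep(sprintf("P%02d", 1:n_subj), each = 2)
  hits <- 0L; total <- 0L
  for (i in 1:10) {
    vals <- matrix(rlnorm(100 * 2 * n_subj, 3, 0.3), 100,
                   dimnames = list(sprintf("G%03d", 1:100),
                                   sprintf("S%02d", 1:(2 * n_subj))))
    em <- makeExprSet(vals, compartment = sample(compartment),
                      subject = subject, arm = "NAT")
    mk <- compartmentMarkers(em, arm = "NAT")
    hits <- hits + length(mk$carcinoma_high) + length(mk$tme_high)
    total <- total + 100L
  }
  ci <- qbinom(c(0.005, 0.995), total, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("highly variable gene selection ranks by CV with symbol tie-break", {
  cvs <- c(GA = 0.5, GB = 0.1, GC = 0.3, GD = 0.2, GE = 0.05)
  mu <- 10
  vals <- t(vapply(cvs, function(cv) mu * c(1 + cv / sqrt(2), 1 - cv / sqrt(2)),
                   numeric(2)))
  colnames(vals) <- c("S1", "S2")
  em <- makeExprSet(vals)
  expect_identical(highlyVariableGenes(em, top_fraction = 0.4),
                   c("GA", "GC"))
  expect_length(highlyVariableGenes(em, top_fraction = 0.2), 1L)

  # 10 genes at 20% -> 2; constant gene never selected
  vals10 <- rbind(vals, vals + 1, matrix(5, 1, 2))
  rownames(vals10) <- c(names(cvs), paste0(names(cvs), "2"), "CONST")
  sel <- highlyVariableGenes(makeExprSet(vals10), top_fraction = 0.2)
  expect_length(sel, ceiling(0.2 * 11))
  expect_false("CONST" %in% sel)

  expect_error(highlyVariableGenes(em[1:3, ]), "at least 5")
  valsz <- vals; valsz[5, ] <- 0
  expect_warning(highlyVariableGenes(makeExprSet(valsz), 0.4), "zero mean")
})
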