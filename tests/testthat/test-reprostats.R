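# long-format table from a patients x readers matrix
make_table <- function(wide, method = "M") {
  data.frame(patient = rep(rownames(wide), ncol(wide)),
             reader = rep(colnames(wide), each = nrow(wide)),
             method = method, percent_lv = as.vector(wide),
             stringsAsFactors = FALSE)
}

wide_mat <- function(values, n, k)
  matrix(values, n, k, dimnames = list(paste0("P", seq_len(n)),
                                       paste0("R", seq_len(k))))

test_that("per-patient differences average the reader pairs", {
  wide <- wide_mat(c(10, 20, 12, 20, 14, 26), 2, 3)
  tab <- make_table(wide)
  d <- per_patient_diffs(tab, "M")
  expect_equal(unname(d$per_patient), c(8 / 3, 4))
  expect_equal(d$mean, mean(c(8 / 3, 4)))
  expect_equal(d$sd, sd(c(8 / 3, 4)))

  # translation invariance
  tab2 <- tab; tab2$percent_lv <- tab2$percent_lv + 7
  expect_equal(per_patient_diffs(tab2, "M")$per_patient, d$per_patient)

  # perfect agreement
  tab3 <- make_table(wide_mat(rep(c(10, 20), 3), 2, 3))
  expect_equal(per_patient_diffs(tab3, "M")$sd, 0)
})

test_that("CV divides the SD of averaged differences by the method mean", {
  wide <- wide_mat(c(10, 20, 12, 20, 14, 26), 2, 3)
  tab <- make_table(wide)
  expect_equal(cv(tab, "M"), 100 * sd(c(8 / 3, 4)) / 17, tolerance = 1e-12)
  expect_equal(round(cv(tab, "M"), 2), 5.55)

  tab2 <- tab; tab2$percent_lv <- tab2$percent_lv * 3
  expect_equal(cv(tab2, "M"), cv(tab, "M"))

  tab3 <- make_table(wide_mat(rep(c(10, 20), 3), 2, 3))
  expect_equal(cv(tab3, "M"), 0)
})

test_that("incomplete reader crossings are rejected by name", {
  tab <- make_table(wide_mat(1:6, 2, 3))
  tab <- tab[-2, ]
  expect_error(cv(tab, "M"), "P2")
})

test_that("ICC(2,1) matches an independent mean-squares oracle", {
  icc_oracle <- function(wide) {
    n <- nrow(wide); k <- ncol(wide)
    gm <- mean(wide)
    rm <- rowMeans(wide); cm <- colMeans(wide)
    msr <- k * sum((rm - gm)^2) / (n - 1)
    msc <- n * sum((cm - gm)^2) / (k - 1)
    sse <- sum((wide - outer(rm, rep(1, k)) -
                  outer(rep(1, n), cm) + gm)^2)
    mse <- sse / ((n - 1) * (k - 1))
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  set.seed(11)
  for (dims in list(c(4, 3), c(6, 4), c(5, 2), c(6, 3))) {
    wide <- wide_mat(rnorm(prod(dims), 20, 8), dims[1], dims[2])
    tab <- make_table(wide)
    expect_equal(icc(tab, "M")$icc, icc_oracle(wide), tolerance = 1e-10)
  }
})

test_that("ICC is 1 for identical readers and near 0 for pure noise", {
  wide <- wide_mat(rep(c(5, 10, 20, 40), 3), 4, 3)
  expect_equal(icc(make_table(wide), "M")$icc, 1)

  set.seed(13)
  wide2 <- wide_mat(rnorm(1500), 500, 3)    # no patient effect
  r <- icc(make_table(wide2), "M")
  expect_lt(abs(r$icc), 0.1)
  expect_lt(r$lower, r$icc)
  expect_gt(r$upper, r$icc)
})

test_that("ICC confidence interval brackets strong agreement plausibly", {
  set.seed(14)
  truth <- rnorm(30, 20, 10)
  wide <- wide_mat(rep(truth, 3) + rnorm(90, 0, 2), 30, 3)
  r <- icc(make_table(wide), "M")
  expect_gt(r$icc, 0.85)
  expect_true(r$lower < r$icc && r$icc < r$upper)
  expect_gt(r$upper - r$lower, 0)
})

test_that("Bland-Altman bias, limits and t-test match hand arithmetic", {
  wide <- wide_mat(c(0, 1, 2, 5, 1, 1, 1, 1), 4, 2)  # d = (-1, 0, 1, 4)
  tab <- make_table(wide)
  ba <- bland_altman(tab, "M", c("R1", "R2"))
  expect_equal(ba$bias, 1)
  expect_equal(ba$sd, sd(c(-1, 0, 1, 4)))
  expect_equal(ba$loa, 1 + c(-1.96, 1.96) * sd(c(-1, 0, 1, 4)))
  expect_equal(ba$p, t.test(c(-1, 0, 1, 4))$p.value)

  ident <- make_table(wide_mat(rep(c(3, 7), 2), 2, 2))
  bi <- bland_altman(ident, "M", c("R1", "R2"))
  expect_equal(bi$bias, 0); expect_equal(bi$sd, 0)
  expect_equal(bi$loa, c(0, 0))

  off <- make_table(wide_mat(c(5, 9, 3, 7), 2, 2))
  bo <- bland_altman(off, "M", c("R1", "R2"))
  expect_equal(bo$bias, 2); expect_equal(bo$sd, 0)
})

test_that("variance components recover injected effects", {
  # degenerate: identical readers per patient
  wide <- wide_mat(rep(c(10, 20, 30), 3), 3, 3)
  vc <- variance_components(make_table(wide), "M")
  expect_equal(vc$sigma_e2, 0)
  expect_equal(vc$within_share, 0)

  # constant table
  vc0 <- variance_components(make_table(wide_mat(rep(5, 6), 2, 3)), "M")
  expect_equal(vc0$sigma_T2 + vc0$sigma_e2, 0)
  expect_equal(vc0$within_share, 0)

  # parameter recovery at n = 2000, k = 3
  set.seed(19)
  truth <- rnorm(2000, 20, 10)
  wide2 <- wide_mat(rep(truth, 3) + rnorm(6000, 0, 2), 2000, 3)
  vc2 <- variance_components(make_table(wide2), "M")
  expect_lt(abs(sqrt(vc2$sigma_T2) - 10), 1)
  expect_lt(abs(sqrt(vc2$sigma_e2) - 2), 0.2)
  expect_lt(vc2$within_share, 0.1)
})

test_that("sample size follows the two-arm normal-approximation formula", {
  oracle <- function(sigma, delta, alpha = 0.05, beta = 0.2)
    2 * sigma^2 * (qnorm(1 - alpha / 2) + qnorm(1 - beta))^2 / delta^2
  expect_equal(sample_size(5, sigma = 10), 63L)
  expect_equal(sample_size(5, sigma = 10), as.integer(ceiling(oracle(10, 5))))
  # delta-scaling law holds exactly before rounding
  expect_equal(oracle(10, 2.5) / oracle(10, 5), 4)
  expect_equal(sample_size(2.5, sigma = 10), as.integer(ceiling(oracle(10, 2.5))))
  # component form
  expect_equal(sample_size(5, sigma_T = 8, sigma_e = 6),
               sample_size(5, sigma = 10))
  expect_warning(n0 <- sample_size(5, sigma = 0), "sigma")
  expect_equal(n0, 0L)
  expect_error(sample_size(0, sigma = 10), "delta")
  # monotone in sigma, anti-monotone in delta
  expect_gt(sample_size(5, sigma = 12), sample_size(5, sigma = 10))
  expect_lt(sample_size(7, sigma = 10), sample_size(5, sigma = 10))
})

test_that("quality correlation is Pearson r with the least-squares fit", {
  x <- c(1, 2, 3, 4, 5)
  q <- quality_correlation(2 * x, x)
  expect_equal(q$r, 1)
  expect_equal(q$slope, 2)
  expect_equal(q$intercept, 0)

  set.seed(23)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(quality_correlation(a, b)$r), 0.1)

  # affine invariance of |r|
  expect_equal(abs(quality_correlation(3 * a + 2, -b / 4 + 1)$r),
               abs(quality_correlation(a, b)$r))

  expect_error(quality_correlation(rep(1, 5), x), "zero variance")
})

test_that("the assembled report covers every method and reader pair", {
  set.seed(29)
  truth <- rnorm(12, 20, 8)
  tabs <- lapply(c("A", "B"), function(m)
    make_table(wide_mat(rep(truth, 3) + rnorm(36, 0, 2), 12, 3), method = m))
  tab <- do.call(rbind, tabs)
  # method B duplicates method A's values
  tab$percent_lv[tab$method == "B"] <- tab$percent_lv[tab$method == "A"]
  rep_ <- run_reproducibility(tab)
  expect_named(rep_$methods, c("A", "B"))
  a <- rep_$methods$A; b <- rep_$methods$B
  expect_equal(a$cv, b$cv)
  expect_equal(a$icc, b$icc)
  expect_length(a$bland_altman, 3L)
  expect_equal(nrow(rep_$sample_sizes), 2L)
  expect_named(rep_$sample_sizes, c("method", "delta_3", "delta_5", "delta_7"))
  expect_output(print(rep_), "Sample size per arm")
})

test_that("higher reader noise raises CV and lowers ICC", {
  set.seed(31)
  truth <- rnorm(40, 20, 10)
  tab <- do.call(rbind, lapply(c(1, 3, 6), function(s)
    make_table(wide_mat(rep(truth, 3) + rnorm(120, 0, s), 40, 3),
               method = paste0("S", s))))
  cvs <- vapply(c("S1", "S3", "S6"), function(m) cv(tab, m), numeric(1))
  iccs <- vapply(c("S1", "S3", "S6"), function(m) icc(tab, m)$icc, numeric(1))
  vcs <- vapply(c("S1", "S3", "S6"), function(m)
    variance_components(tab, m)$within_share, numeric(1))
  expect_true(all(diff(cvs) > 0))
  expect_true(all(diff(iccs) < 0))
  expect_true(all(diff(vcs) > 0))
})
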