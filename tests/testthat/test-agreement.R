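test_that("percent error matches hand arithmetic and guards zero manual", {
  expect_equal(percent_error(0.77, -0.07), 109.090909, tolerance = 1e-6)
  expect_equal(percent_error(1.3, 1.3), 0)
  expect_equal(percent_error(-2, -2), 0)
  # rounded Table SURs give 3.896..., not a printed 4.80 from unrounded data
  expect_equal(percent_error(0.77, 0.80), 3.8961039, tolerance = 1e-6)
  expect_error(percent_error(0, 1), "nonzero")
})

test_that("variability is the absolute difference over the pair mean", {
  expect_equal(variability(0.5, 0.5), 0)
  expect_equal(variability(0.77, 0.75), 0.02 / 0.76, tolerance = 1e-12)
  expect_equal(variability(1, 3), 1)
  expect_error(variability(1, -1), "zero")
})

test_that("percent error and variability are scale invariant", {
  set.seed(5)
  m <- runif(20, 0.2, 2); a <- runif(20, 0.2, 2)
  for (c_ in c(0.1, 3, 1000)) {
    expect_equal(percent_error(c_ * m, c_ * a), percent_error(m, a),
                 tolerance = 1e-12)
    expect_equal(variability(c_ * m, c_ * a), variability(m, a),
                 tolerance = 1e-12)
  }
})

test_that("one-way ICC reproduces hand ANOVA cases exactly", {
  perfect <- icc_oneway(c(1, 2, 3), c(1, 2, 3))
  expect_identical(perfect$icc, 1)
  expect_identical(perfect$components$msws, 0)
  crossed <- icc_oneway(c(1, 2), c(2, 1))
  expect_identical(crossed$icc, -1)
  expect_identical(crossed$components$msbs, 0)
  expect_equal(crossed$components$msws, 0.5)
  expect_error(icc_oneway(1, 1), "at least 2")
})

test_that("ICC agrees with the independent aov oracle and stays in [-1, 1]", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 3))
    y <- x * runif(1, -1, 2) + rnorm(n, sd = runif(1, 0.01, 2))
    res <- icc_oneway(x, y)
    expect_lt(abs(res$icc - icc_oracle_aov(x, y)), 1e-10)
    expect_gte(res$icc, -1); expect_lte(res$icc, 1)
  }
})

test_that("Pearson correlation matches the brute-force formula", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  set.seed(2)
  a <- rnorm(100); b <- rnorm(100)
  brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_lt(abs(pearson(a, b) - brute), 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

test_that("Bland-Altman bias, limits, and sign convention", {
  x <- c(1, 2, 3, 4)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  ba <- bland_altman(x, x + 0.5)
  expect_equal(ba$mean_diff, -0.5)
  expect_equal(ba$sd_diff, 0)
  # automatic systematically larger => manual - automatic < 0
  set.seed(3)
  m <- runif(15); a <- m + runif(15, 0.1, 0.4)
  expect_lt(bland_altman(m, a)$mean_diff, 0)
  flipped <- bland_altman(m, a, direction = "automatic_minus_manual")
  expect_equal(flipped$mean_diff, -bland_altman(m, a)$mean_diff)
  # limits bracket the mean difference symmetrically
  ba2 <- bland_altman(m, a)
  expect_equal(ba2$loa_high - ba2$mean_diff, ba2$mean_diff - ba2$loa_low)
})

test_that("pooled t test matches textbook formula; degenerate convention", {
  same <- ttest_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_identical(ttest_two_sample(c(2, 2), c(2, 2)),
                   list(t = 0, p = 1, df = 2))
  sep <- ttest_two_sample(c(1, 2, 3), c(101, 102, 103))
  expect_lt(sep$p, 0.01)
  set.seed(9)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_lt(abs(ttest_two_sample(a, b)$t - t_hand), 1e-10)
  expect_false(isTRUE(all.equal(ttest_two_sample(a, b, welch = TRUE)$t,
                                NULL)))
})

test_that("agreement statistics match brute-force implementations broadly", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    m <- runif(n, 0.1, 3); a <- m + rnorm(n, 0, 0.3)
    tab <- data.frame(subject_id = as.character(seq_len(n)),
                      sur_manual = m, sur_X = a)
    rp <- agreement_report(tab, "X")
    expect_lt(abs(rp$pearson_r - cor(m, a)), 1e-12)
    d <- m - a
    expect_lt(abs(rp$bland_altman$mean_diff - mean(d)), 1e-12)
    expect_lt(abs(rp$bland_altman$loa_high - (mean(d) + 1.96 * sd(d))), 1e-12)
    v <- abs(d) / ((m + a) / 2)
    expect_lt(abs(rp$variability_mean - mean(v)), 1e-12)
    expect_lt(abs(rp$variability_sd - sd(v)), 1e-12)
    expect_lt(abs(rp$icc$icc - icc_oracle_aov(m, a)), 1e-10)
  }
})

test_that("agreement report: perfect agreement and row-order invariance", {
  tab <- data.frame(subject_id = letters[1:6],
                    sur_manual = c(0.4, 0.9, 1.3, 1.8, 0.7, 1.1))
  tab$sur_MBT <- tab$sur_manual
  rp <- agreement_report(tab, "MBT")
  expect_equal(rp$variability_mean, 0)
  expect_equal(rp$icc$icc, 1)
  expect_equal(rp$bland_altman$mean_diff, 0)

  tab$sur_MBT <- tab$sur_manual + rnorm(6, 0, 0.2)
  shuffled <- tab[sample(nrow(tab)), ]
  r1 <- agreement_report(tab, "MBT"); r2 <- agreement_report(shuffled, "MBT")
  expect_equal(r1$pearson_r, r2$pearson_r)
  expect_equal(r1$icc$icc, r2$icc$icc)
  expect_error(agreement_report(tab, "HBT"), "not found")
})

test_that("SUR tables read from CSV and XLSX give identical reports", {
  set.seed(8)
  tab <- data.frame(Subject = sprintf("P%02d", 1:12),
                    Manual = runif(12, 0.2, 1.5),
                    MBT = runif(12, 0.2, 1.5),
                    HBT = runif(12, 0.2, 1.5),
                    HMPAO = runif(12, -0.5, 1.5))
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, csv, row.names = FALSE)
  got <- read_sur_table(csv)
  expect_named(got, c("subject_id", "sur_manual", "sur_MBT", "sur_HBT",
                      "sur_HMPAO"))
  expect_equal(got$sur_manual, tab$Manual)

  xlsx <- withr::local_tempfile(fileext = ".xlsx")
  wrote <- system2("python", c("-c", shQuote(paste0(
    "import openpyxl,csv,sys\n",
    "wb=openpyxl.Workbook(); ws=wb.active\n",
    "rows=list(csv.reader(open('", csv, "')))\n",
    "ws.append(rows[0])\n",
    "for r in rows[1:]: ws.append([r[0]]+[float(x) for x in r[1:]])\n",
    "wb.save('", xlsx, "')"))), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(xlsx))
  got_x <- read_sur_table(xlsx)
  expect_equal(got_x$sur_MBT, got$sur_MBT, tolerance = 1e-12)
  r_csv <- agreement_report(got, "HMPAO")
  r_xlsx <- agreement_report(got_x, "HMPAO")
  expect_equal(r_csv$icc$icc, r_xlsx$icc$icc, tolerance = 1e-12)

  # explicit mapping override for nonstandard headers
  tab2 <- data.frame(`Pat code` = 1:5, `SUR hand` = runif(5, .2, 2),
                     Auto = runif(5, .2, 2), check.names = FALSE)
  csv2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab2, csv2, row.names = FALSE)
  got2 <- read_sur_table(csv2, mapping = c(subject_id = "Pat code",
                                           manual = "SUR hand"))
  expect_equal(got2$sur_manual, tab2$`SUR hand`)
  expect_error(read_sur_table(withr::local_tempfile(fileext = ".txt")),
               "unsupported")
})
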