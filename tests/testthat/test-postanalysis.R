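test_that("differential effects summarize constructed posterior draws exactly", {
  # draws where condition 2 always has twice the fitness of condition 1 for
  # amino acid 1, identical profiles elsewhere
  nd <- 40
  F <- array(1 / 20, c(nd, 2, 2, 20))
  F[, 1, 2, 1] <- 2 / 20
  fit <- fake_ds_fit(F)
  eff <- differential_effects(fit, cond_from = 0, cond_to = 1)
  e11 <- eff[eff$site == 1 & eff$aa == "A", ]
  expect_equal(e11$mean_D, log(2))
  expect_equal(e11$pp_pos, 1)
  expect_equal(e11$call, "+")
  # identical profiles: D = 0 everywhere, no calls
  e2 <- eff[eff$site == 2, ]
  expect_true(all(e2$mean_D == 0))
  expect_true(all(e2$call == ""))
  expect_error(differential_effects(fake_om_fit(array(1, c(5, 2, 1)))),
               "DS")
})

test_that("differential effects are antisymmetric in the condition pair", {
  set.seed(71)
  F <- array(rgamma(30 * 3 * 2 * 20, 1), c(30, 3, 2, 20))
  fit <- fake_ds_fit(F)
  ab <- differential_effects(fit, cond_from = 0, cond_to = 1)
  ba <- differential_effects(fit, cond_from = 1, cond_to = 0)
  expect_equal(ab$mean_D, -ba$mean_D)
  expect_equal(ab$pp_pos, ba$pp_neg)
})

test_that("calls are monotone in the threshold", {
  set.seed(72)
  F <- array(rgamma(60 * 4 * 2 * 20, 1), c(60, 4, 2, 20))
  fit <- fake_ds_fit(F)
  lo <- differential_effects(fit, 0, 1, threshold = 0.90)
  hi <- differential_effects(fit, 0, 1, threshold = 0.95)
  called_lo <- paste(lo$site, lo$aa)[lo$call != ""]
  called_hi <- paste(hi$site, hi$aa)[hi$call != ""]
  expect_true(all(called_hi %in% called_lo))
})

test_that("omega site calls count tail draws exactly", {
  om <- array(0.5, c(40, 3, 1))
  om[1:38, 2, 1] <- 1.5  # 95% of draws above 1 at site 2
  fit <- fake_om_fit(om)
  calls <- omega_site_calls(fit)
  expect_equal(calls$pp_gt1[calls$site == 1], 0)
  expect_false(calls$call[calls$site == 1])
  expect_equal(calls$pp_gt1[calls$site == 2], 0.95)
  expect_true(calls$call[calls$site == 2])
  expect_error(omega_site_calls(fake_ds_fit(array(1, c(5, 2, 2, 20)))), "OM")
})

test_that("site report takes the union of called sites and keeps inputs", {
  om <- array(0.5, c(40, 5, 1))
  om[, 4, 1] <- 2  # site 4 always above 1
  om1 <- omega_site_calls(fake_om_fit(om))

  F <- array(1 / 20, c(40, 5, 2, 20))
  F[, 2, 2, 3] <- 5 / 20  # site 2: amino acid D favoured under cond 2
  ds <- differential_effects(fake_ds_fit(F), 0, 1)

  rep_tab <- site_report(ds = ds, om1 = om1)
  expect_equal(rep_tab$site, c(2, 4))
  # row for the DS-only site keeps OM columns filled but unflagged
  expect_equal(rep_tab$omega_om1[rep_tab$site == 2], 0.5)
  expect_equal(rep_tab$ds_calls[rep_tab$site == 2], "+D")
  expect_equal(rep_tab$ds_calls[rep_tab$site == 4], "-")
  # values reproduce the inputs exactly (no recomputation drift)
  expect_equal(rep_tab$pp_om1[rep_tab$site == 4],
               round(om1$pp_gt1[om1$site == 4], 2))

  # empty when nothing is called
  quiet <- omega_site_calls(fake_om_fit(array(0.5, c(10, 3, 1))))
  expect_equal(nrow(site_report(om1 = quiet)), 0)
  # coordinate offset mismatch is an error
  ds_off <- differential_effects(fake_ds_fit(F), 0, 1, offset = 21)
  expect_error(site_report(ds = ds_off, om1 = om1), "offset")
})

test_that("logo matrices export posterior means in the documented layout", {
  F <- array(1 / 20, c(20, 3, 2, 20))
  fit <- fake_ds_fit(F)
  lg <- logo_matrices(fit, cond_from = 0, cond_to = 1)
  expect_equal(dim(lg$absolute), c(3L, 21L))
  expect_true(all(abs(as.matrix(lg$absolute[, -1]) - 0.05) < 1e-12))
  # differential of identical conditions is identically zero
  expect_true(all(as.matrix(lg$differential[, -1]) == 0))
  f <- tempfile(fileext = ".tsv")
  write_site_tsv(lg$absolute, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), 3)
})

test_that("tidy and glance methods return the documented shapes", {
  F <- array(1 / 20, c(10, 2, 2, 20))
  fit <- fake_ds_fit(F)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("site", "aa", "mean_D") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$model, "DS")
})

test_that("plots build without error", {
  set.seed(81)
  F <- array(rgamma(20 * 3 * 2 * 20, 1), c(20, 3, 2, 20))
  fit <- fake_ds_fit(F)
  p1 <- autoplot(differential_effects(fit, 0, 1, threshold = 0.6))
  expect_s3_class(p1, "ggplot")
  om <- fake_om_fit(array(rgamma(20 * 3 * 1, 2, 1), c(20, 3, 1)))
  p2 <- autoplot(omega_site_calls(om))
  expect_s3_class(p2, "ggplot")
})
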