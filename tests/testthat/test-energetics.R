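# MM/GBSA bookkeeping.

table3 <- list(
  # published per-complex component and derived means (kcal/mol)
  "PN1/b-CD"    = c(dE_vdW = -51.70, dE_ele = -10.41, dE_MM = -62.11,
                    dG_GB = 26.68, dG_nonpolar = -5.44, dG_solvation = 21.24,
                    dH = -40.87, TdS = -20.43, dG_binding = -20.43),
  "PN2/b-CD"    = c(dE_vdW = -50.79, dE_ele = -9.66, dE_MM = -60.45,
                    dG_GB = 25.31, dG_nonpolar = -5.33, dG_solvation = 19.99,
                    dH = -40.47, TdS = -19.93, dG_binding = -20.53),
  "PN/DM-b-CD"  = c(dE_vdW = -51.16, dE_ele = -11.09, dE_MM = -62.25,
                    dG_GB = 26.43, dG_nonpolar = -5.49, dG_solvation = 20.93,
                    dH = -41.31, TdS = -16.51, dG_binding = -24.80),
  "PN/TM-b-CD"  = c(dE_vdW = -53.41, dE_ele = -6.43, dE_MM = -59.84,
                    dG_GB = 27.16, dG_nonpolar = -5.37, dG_solvation = 21.78,
                    dH = -38.06, TdS = -17.61, dG_binding = -20.45),
  "PN1/HP-b-CD" = c(dE_vdW = -27.15, dE_ele = -5.79, dE_MM = -32.94,
                    dG_GB = 23.64, dG_nonpolar = -3.28, dG_solvation = 20.35,
                    dH = -12.58, TdS = -15.63, dG_binding = 3.04),
  "PN2/HP-b-CD" = c(dE_vdW = -26.23, dE_ele = -7.00, dE_MM = -33.27,
                    dG_GB = 25.43, dG_nonpolar = -3.29, dG_solvation = 22.16,
                    dH = -11.11, TdS = -16.31, dG_binding = 5.20))

test_that("nonpolar term is linear in SASA", {
  expect_equal(nonpolar_from_sasa(c(100, 200), nonpolar_params(0, -1)),
               c(-1, -1))
  expect_equal(nonpolar_from_sasa(500, nonpolar_params(0.0072, 0)), 3.6)
  expect_equal(nonpolar_from_sasa(0, nonpolar_params(0.0072, -1.2)), -1.2)
  expect_error(nonpolar_from_sasa(-1, nonpolar_params()), "non-negative")
})

test_that("combine_frames averages per-frame sums", {
  z <- as.data.frame(matrix(0, 10, 4,
                            dimnames = list(NULL, c("dE_vdW", "dE_ele",
                                                    "dG_GB", "dG_nonpolar"))))
  bz <- combine_frames(z)
  expect_true(all(bz$mean == 0))
  expect_true(all(bz$sd == 0))

  # two frames, hand arithmetic
  two <- data.frame(dE_vdW = c(-50, -52), dE_ele = c(-10, -12),
                    dG_GB = c(20, 20), dG_nonpolar = c(-5, -5))
  b2 <- combine_frames(two)
  g <- function(q) b2$mean[match(q, b2$quantity)]
  s <- function(q) b2$sd[match(q, b2$quantity)]
  expect_equal(g("dE_MM"), -62)
  # per-frame sums are -60 and -64: sample SD 2*sqrt(2) (the components
  # here are perfectly correlated, so quadrature sqrt(2+2) = 2 would be
  # wrong - exactly the distinction the per-frame convention preserves)
  expect_equal(s("dE_MM"), 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(g("dH"), -47)

  expect_error(combine_frames(two[, -1]), "dE_vdW")
})

test_that("generator tables reproduce their specified moments exactly", {
  sp <- energy_gen_spec(n_frames = 400, correlation = 0.4, seed = 10)
  ge <- gen_energy_frames(sp)
  for (j in seq_along(sp$means)) {
    expect_equal(mean(ge$table[[names(sp$means)[j]]]), unname(sp$means[j]),
                 tolerance = 1e-9)
    expect_equal(stats::sd(ge$table[[names(sp$means)[j]]]), unname(sp$sds[j]),
                 tolerance = 1e-9)
  }
  b <- combine_frames(ge$table, tds = -20.43)
  g <- function(q) b$mean[match(q, b$quantity)]
  expect_equal(g("dE_MM"), sum(sp$means[c("dE_vdW", "dE_ele")]),
               tolerance = 1e-9)
  expect_equal(g("dG_solvation"), sum(sp$means[c("dG_GB", "dG_nonpolar")]),
               tolerance = 1e-9)
})

test_that("additive identities hold exactly on every combined table", {
  set.seed(14)
  for (i in 1:10) {
    tab <- data.frame(dE_vdW = rnorm(50, -50, 4), dE_ele = rnorm(50, -10, 4),
                      dG_GB = rnorm(50, 25, 4), dG_nonpolar = rnorm(50, -5, 1))
    b <- combine_frames(tab, tds = rnorm(1, -18, 2))
    g <- function(q) b$mean[match(q, b$quantity)]
    expect_lt(abs(g("dE_MM") - g("dE_vdW") - g("dE_ele")), 1e-9)
    expect_lt(abs(g("dG_solvation") - g("dG_GB") - g("dG_nonpolar")), 1e-9)
    expect_lt(abs(g("dH") - g("dE_MM") - g("dG_solvation")), 1e-9)
    expect_lt(abs(g("dG_binding") - g("dH") + g("TdS")), 1e-9)
  }
})

test_that("summed-component SD matches quadrature only when uncorrelated", {
  quad <- sqrt(4.08^2 + 4.64^2)
  devs <- vapply(1:10, function(s) {
    ge <- gen_energy_frames(energy_gen_spec(n_frames = 10000,
                                            correlation = 0, seed = s))
    b <- combine_frames(ge$table)
    b$sd[match("dE_MM", b$quantity)] - quad
  }, numeric(1))
  # sampling error of the residual covariance term: ~sd1*sd2/sqrt(n)/quad
  se <- 4.08 * 4.64 / sqrt(10000) / quad
  expect_lt(max(abs(devs)), 3 * se * 3)   # 3 SE with head-room across 10 runs

  # strongly correlated components push the sum SD well away from quadrature
  gc <- gen_energy_frames(energy_gen_spec(n_frames = 10000,
                                          correlation = 0.6, seed = 1))
  bc <- combine_frames(gc$table)
  expect_gt(bc$sd[match("dE_MM", bc$quantity)], quad + 0.5)
})

test_that("summarize_means reproduces the published derived rows", {
  col <- table3[["PN1/b-CD"]]
  s <- summarize_means(col[c("dE_vdW", "dE_ele", "dG_GB", "dG_nonpolar",
                             "TdS")])
  g <- function(q) s$mean[match(q, s$quantity)]
  expect_equal(g("dE_MM"), -62.11, tolerance = 1e-9)
  expect_equal(g("dH"), -40.87, tolerance = 0.005)
  # chained rounding leaves dG_binding 0.01 from the printed -20.43
  expect_equal(g("dG_binding"), -20.44, tolerance = 0.005)

  dm <- summarize_means(table3[["PN/DM-b-CD"]][c("dE_vdW", "dE_ele", "dG_GB",
                                                 "dG_nonpolar", "TdS")])
  expect_equal(dm$mean[match("dG_binding", dm$quantity)], -24.80,
               tolerance = 0.005)

  zz <- summarize_means(c(dE_vdW = 0, dE_ele = 0, dG_GB = 0,
                          dG_nonpolar = 0, TdS = 0))
  expect_true(all(zz$mean == 0))
})

test_that("consistency_check validates published tables and flags errors", {
  cc <- consistency_check(table3[["PN/TM-b-CD"]])
  expect_true(all(cc$pass))
  expect_true(all(abs(cc$residual) <= 0.01))
  # dH identity for this column is exact: -59.84 + 21.78 = -38.06
  expect_equal(cc$residual[match("dH = dE_MM + dG_solvation", cc$identity)],
               0, tolerance = 1e-9)

  bad <- table3[["PN1/b-CD"]]
  bad["dE_MM"] <- bad["dE_MM"] + 1
  ccb <- consistency_check(bad)
  expect_false(ccb$pass[match("dE_MM = dE_vdW + dE_ele", ccb$identity)])
})

test_that("dropping the entropy term only removes the binding rows", {
  tab <- data.frame(dE_vdW = rnorm(20, -50, 2), dE_ele = rnorm(20, -9, 2),
                    dG_GB = rnorm(20, 24, 2), dG_nonpolar = rnorm(20, -5, 1))
  with_s <- combine_frames(tab, tds = -17)
  without <- combine_frames(tab)
  expect_false(any(c("TdS", "dG_binding") %in% without$quantity))
  shared <- intersect(with_s$quantity, without$quantity)
  expect_equal(with_s$mean[match(shared, with_s$quantity)],
               without$mean[match(shared, without$quantity)])
  # no-entropy binding estimate equals the enthalpy
  expect_equal(without$mean[match("dG_binding_no_entropy", without$quantity)],
               without$mean[match("dH", without$quantity)])
})

test_that("SASA input and per-frame TdS columns are accepted", {
  tab <- data.frame(dE_vdW = c(-50, -51), dE_ele = c(-10, -9),
                    dG_GB = c(25, 26), SASA = c(500, 520),
                    TdS = c(-17, -18))
  ef <- energy_frames(tab, gamma = 0.0072, b = 0)
  expect_equal(ef$dG_nonpolar, c(3.6, 3.744))
  b <- combine_frames(ef)
  expect_equal(b$mean[match("TdS", b$quantity)], -17.5)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(tab, p, row.names = FALSE)
  expect_equal(read_energy_csv(p)$dG_nonpolar, c(3.6, 3.744))
})
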