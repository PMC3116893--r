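test_that("energy tables parse, validate and round-trip", {
  df <- random_energy_df(10, seed = 1)
  es <- energy_series(df, "WT")
  expect_equal(nrow(es), 10L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_energy_table(es, f)
  back <- parse_energy_table(f, "WT")
  expect_equal(as.data.frame(back), as.data.frame(es), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(energy_series(df[, setdiff(names(df), "E_ele")]), "E_ele")
  bad <- df; bad$bogus <- 1
  expect_error(energy_series(bad), "unknown column")
  nonmono <- df; nonmono$time_ps[5] <- nonmono$time_ps[4]
  expect_error(energy_series(nonmono), "increasing")
  # entropy columns may be absent or sparse; enthalpy gaps are rejected
  noTS <- df[, c("time_ps", "E_int", "E_ele", "E_vdw", "G_gb", "G_sa")]
  expect_s3_class(energy_series(noTS), "energy_series")
  gap <- df; gap$E_vdw[3] <- NA
  expect_error(energy_series(gap), "enthalpy")
})

test_that("free-energy summation follows the component bookkeeping", {
  df <- data.frame(time_ps = 1, E_int = 10, E_ele = -20, E_vdw = 5,
                   G_gb = -3, G_sa = 1, TS_trans = 1, TS_rot = 1, TS_vib = 2)
  tot <- total_free_energy(energy_series(df))
  expect_equal(tot$E_gas, -5)
  expect_equal(tot$H, -7)
  expect_equal(tot$TS, 4)
  expect_equal(tot$G, -11)
  zero <- data.frame(time_ps = 1:3, E_int = 0, E_ele = 0, E_vdw = 0,
                     G_gb = 0, G_sa = 0, TS_trans = 0, TS_rot = 0, TS_vib = 0)
  expect_equal(total_free_energy(energy_series(zero))$G, rep(0, 3))
  rnd <- total_free_energy(energy_series(random_energy_df(50, seed = 2)))
  expect_lt(max(abs(rnd$G + rnd$TS - rnd$H)), 1e-12)
})

test_that("Straatsma errors track the closed-form standard error of correlated means", {
  x_iid <- make_ar1_series(0, 1, 0, 1e5, seed = 21)
  e_iid <- estimate_with_error(x_iid)
  expect_lt(abs(e_iid$error - ar1_true_se(1, 0, 1e5)) / ar1_true_se(1, 0, 1e5),
            0.10)
  x_ar <- make_ar1_series(0, 2, 0.9, 1e5, seed = 22)
  e_ar <- estimate_with_error(x_ar)
  truth <- ar1_true_se(2, 0.9, 1e5)
  expect_lt(abs(e_ar$error - truth) / truth, 0.20)
  # positively autocorrelated series inflate the naive error
  naive <- sd(x_ar) / sqrt(length(x_ar))
  expect_gt(e_ar$error, naive)
  expect_gt(e_ar$tau, 1)
  const <- estimate_with_error(rep(3.5, 100))
  expect_identical(const$error, 0)
  expect_identical(const$tau, 0)
  expect_error(estimate_with_error(1:5), "short")
})

test_that("stability differences combine errors in quadrature", {
  mk_est <- function(mean_shift, seed) {
    df <- random_energy_df(40, seed = seed)
    df$E_ele <- df$E_ele + mean_shift
    estimate_free_energy(energy_series(df))
  }
  a <- mk_est(0, 1)
  same <- stability_change(a, a)
  expect_equal(same$delta, rep(0, 3))
  expect_equal(same$error, sqrt(2) * c(a$G$error, a$H$error, a$TS$error))
  # 3-4-5 quadrature on hand-built estimates
  fake <- function(m, e) structure(
    list(G = structure(list(mean = m, error = e), class = "fe_estimate"),
         H = structure(list(mean = m, error = e), class = "fe_estimate"),
         TS = structure(list(mean = 0, error = 0), class = "fe_estimate")),
    class = "free_energy_estimate")
  sc <- stability_change(fake(-100, 3), fake(-110, 4))
  expect_equal(sc$delta[sc$quantity == "G"], 10)
  expect_equal(sc$error[sc$quantity == "G"], 5)
  # antisymmetry
  b <- mk_est(-8, 2)
  ab <- stability_change(a, b); ba <- stability_change(b, a)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$error, ba$error)
})

test_that("binding cycles satisfy additivity and match a spreadsheet recomputation", {
  legs <- function(seed) energy_series(random_energy_df(30, seed = seed))
  # complex components exactly equal receptor + ligand: zero binding energy
  r <- random_energy_df(30, seed = 5); l <- random_energy_df(30, seed = 6)
  cpx <- r; for (cc in setdiff(names(r), "time_ps")) cpx[[cc]] <- r[[cc]] + l[[cc]]
  wt <- list(complex = energy_series(cpx), receptor = energy_series(r),
             ligand = energy_series(l))
  bc0 <- binding_cycle(wt, wt)
  expect_lt(max(abs(bc0$binding$value)), 1e-9)
  expect_lt(max(abs(bc0$difference$value)), 1e-9)
  # random six-leg cycle vs direct recomputation from the means
  wt2 <- list(complex = legs(11), receptor = legs(12), ligand = legs(13))
  mu2 <- list(complex = legs(14), receptor = legs(15), ligand = legs(16))
  bc <- binding_cycle(wt2, mu2)
  mean_G <- function(s) {
    tot <- total_free_energy(s); mean(tot$H) - mean(tot$TS)
  }
  ddG <- (mean_G(mu2$complex) - mean_G(mu2$receptor) - mean_G(mu2$ligand)) -
         (mean_G(wt2$complex) - mean_G(wt2$receptor) - mean_G(wt2$ligand))
  expect_equal(bc$difference$value[bc$difference$quantity == "G"], ddG,
               tolerance = 1e-12)
  # delta-delta-H decomposes exactly into gas + gb + sa parts
  d <- bc$difference
  expect_equal(d$value[d$quantity == "H"],
               sum(d$value[d$quantity %in% c("E_gas", "G_gb", "G_sa")]),
               tolerance = 1e-12)
  # single-point legs are allowed
  single <- function(seed) energy_series(random_energy_df(1, seed = seed))
  bs <- binding_cycle(list(complex = single(1), receptor = single(2),
                           ligand = single(3)),
                      list(complex = single(4), receptor = single(5),
                           ligand = single(6)))
  expect_true(all(bs$difference$error == 0))
  expect_error(binding_cycle(wt2[c("complex", "ligand")], mu2), "receptor")
})

test_that("fragment free-energy differences sum to the whole-region difference", {
  # two fragment series summing component-wise to the whole series,
  # with a null receptor so the cycle is a pure decomposition
  f1w <- random_energy_df(25, seed = 31); f2w <- random_energy_df(25, seed = 32)
  f1m <- random_energy_df(25, seed = 33); f2m <- random_energy_df(25, seed = 34)
  add <- function(a, b) {
    o <- a; for (cc in setdiff(names(a), "time_ps")) o[[cc]] <- a[[cc]] + b[[cc]]
    o
  }
  null_leg <- random_energy_df(25, seed = 1)
  null_leg[setdiff(names(null_leg), "time_ps")] <- 0
  cyc <- function(lig_w, lig_m) {
    binding_cycle(list(complex = energy_series(lig_w),
                       receptor = energy_series(null_leg),
                       ligand = energy_series(null_leg)),
                  list(complex = energy_series(lig_m),
                       receptor = energy_series(null_leg),
                       ligand = energy_series(null_leg)))
  }
  dd <- function(bc) bc$difference$value[bc$difference$quantity == "G"]
  whole <- cyc(add(f1w, f2w), add(f1m, f2m))
  expect_equal(dd(cyc(f1w, f1m)) + dd(cyc(f2w, f2m)), dd(whole),
               tolerance = 1e-10)
})
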