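adsc_window <- function() cell_sensing_window(1, 10, 100)

# small three-regime calibration table built from lumped parameters
demo_table <- function() {
  calibration_table(data.frame(
    agarose_mg_ml = c(5, 5, 5, 5),
    dextran_mg_ml = c(0, 20, 30, 40),
    E0_Pa = 3000, E1_Pa = 2000,
    # eta_eff/E1 gives tau_rel = 150, 30, 20, 1 s
    eta1_Pa_s = c(3e5, 6e4, 4e4, 2e3),
    eta2_Pa_s = 0, phi = 0,
    E_app_Pa = 4000))
}

test_that("deborah_number reproduces the canonical worked values", {
  expect_equal(deborah_number(1, 100), 0.01)
  expect_equal(deborah_number(20, 100), 0.2)
  expect_equal(deborah_number(30, 100), 0.3)
  expect_equal(deborah_number(5, 5), 1)
  expect_identical(deborah_number(Inf, 100), Inf)
  expect_error(deborah_number(1, 0), "tau_L")
  expect_error(deborah_number(-1, 10), "tau_rel")
})

test_that("deborah_number is homogeneous of degree zero", {
  set.seed(19)
  for (i in 1:20) {
    tr <- runif(1, 0.1, 500); tl <- runif(1, 1, 200); a <- runif(1, 0.01, 50)
    expect_equal(deborah_number(a * tr, a * tl), deborah_number(tr, tl),
                 tolerance = 1e-12)
  }
})

test_that("classify_regime matches the three-condition logic", {
  w <- adsc_window()
  expect_equal(as.character(classify_regime(1, w)), "below_one")
  expect_equal(as.character(classify_regime(20, w)), "near_one")
  expect_equal(as.character(classify_regime(30, w)), "near_one")
  expect_equal(as.character(classify_regime(Inf, w)), "above_one")
  # boundary ties go to the lower regime
  expect_equal(as.character(classify_regime(w$tau_b, w)), "below_one")
  expect_equal(as.character(classify_regime(w$tau_L_max, w)), "near_one")
  expect_error(classify_regime(-1, w), "tau_rel")
})

test_that("band mode reproduces the structural assignments", {
  w <- adsc_window()
  taus <- c(1, 20, 30, 1e6)
  expect_equal(classify_regime(taus, w, mode = "band"),
               classify_regime(taus, w, mode = "structural"))
})

test_that("regime partition is total and monotone in tau_rel", {
  w <- adsc_window()
  taus <- c(0, 10^seq(-3, 5, length.out = 60), Inf)
  reg <- classify_regime(taus, w)
  expect_false(any(is.na(reg)))
  expect_true(all(diff(as.integer(reg)) >= 0))
})

test_that("select_agarose_concentration filters and interpolates", {
  tab <- calibration_table(data.frame(
    agarose_mg_ml = 1:10, dextran_mg_ml = 0,
    E_eq_Pa = seq(1000, 10000, by = 1000),
    E_inst_Pa = seq(1500, 10500, by = 1000),
    tau_rel_s = 20,
    E_app_Pa = seq(1000, 10000, by = 1000)))
  target <- tissue_target(2000, 6000, "adipose")
  res <- select_agarose_concentration(tab, target)
  # exhaustive-scan oracle
  oracle <- tab$agarose_mg_ml[tab$E_app_Pa >= 2000 & tab$E_app_Pa <= 6000]
  expect_equal(res$selected, sort(oracle))
  expect_false(res$interpolated)
  # single matching row
  one <- calibration_table(data.frame(agarose_mg_ml = 5, dextran_mg_ml = 0,
                                      E_eq_Pa = 4000, E_inst_Pa = 5000,
                                      tau_rel_s = 10, E_app_Pa = 4000))
  expect_equal(select_agarose_concentration(one, target)$selected, 5)
  # all rows outside: empty + interpolated suggestion
  out <- calibration_table(data.frame(
    agarose_mg_ml = c(1, 2), dextran_mg_ml = 0,
    E_eq_Pa = c(10000, 20000), E_inst_Pa = c(11000, 21000),
    tau_rel_s = 20, E_app_Pa = c(10000, 20000)))
  res2 <- select_agarose_concentration(out, target)
  expect_length(res2$selected, 0)
  expect_true(res2$interpolated)
})

test_that("select_dextran_concentration returns regime-matched rows", {
  tab <- demo_table()
  w <- adsc_window()
  expect_equal(select_dextran_concentration(tab, 5, w, "below_one"), 40)
  expect_equal(select_dextran_concentration(tab, 5, w, "near_one"), c(20, 30))
  expect_equal(select_dextran_concentration(tab, 5, w, "above_one"), 0)
  # brute-force re-verification of every returned row
  for (reg in c("below_one", "near_one", "above_one")) {
    sel <- select_dextran_concentration(tab, 5, w, reg)
    for (d in sel) {
      tau <- tab$tau_rel_s[tab$dextran_mg_ml == d]
      expect_equal(as.character(classify_regime(tau, w)), reg)
    }
  }
  # all tau_rel <= 100 s: no above_one rows
  low <- calibration_table(data.frame(
    agarose_mg_ml = 5, dextran_mg_ml = c(10, 20),
    E_eq_Pa = 3000, E_inst_Pa = 5000, tau_rel_s = c(50, 80)))
  expect_length(select_dextran_concentration(low, 5, w, "above_one"), 0)
  expect_error(select_dextran_concentration(tab, 99, w, "near_one"),
               "no rows")
})

test_that("design_report partitions formulations exactly as classify_regime", {
  tab <- demo_table()
  rep <- design_report(tab, tissue_target(2000, 6000), adsc_window())
  expect_s3_class(rep, "design_report")
  expect_length(rep$formulations, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    f <- rep$formulations[[i]]
    expect_equal(f$regime,
                 as.character(classify_regime(tab$tau_rel_s[i], adsc_window())))
    expect_equal(f$De_point, tab$tau_rel_s[i] / 100)
    expect_equal(f$De_range, c(tab$tau_rel_s[i] / 100, tab$tau_rel_s[i] / 10))
  }
  sel <- rep$dextran_selection[["5"]]
  expect_equal(sel$below_one, 40)
  expect_equal(sel$near_one, c(20, 30))
  # single-formulation table still yields a complete report
  one <- calibration_table(demo_table()[2, ])
  rep1 <- design_report(one, tissue_target(2000, 6000), adsc_window())
  expect_length(rep1$formulations, 1)
  expect_true(all(c("De_point", "De_range", "regime") %in%
                    names(rep1$formulations[[1]])))
})

test_that("empty or malformed calibration tables are rejected", {
  expect_error(calibration_table(data.frame()), "empty")
  expect_error(calibration_table(data.frame(agarose_mg_ml = 1)), "missing")
  expect_error(calibration_table(data.frame(
    agarose_mg_ml = c(5, 5), dextran_mg_ml = c(0, 0),
    E_eq_Pa = 1, E_inst_Pa = 2, tau_rel_s = 1)), "duplicate")
  expect_error(cell_sensing_window(2, 1, 100), "tau_b")
  expect_error(tissue_target(0, 100), "E_low")
})
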