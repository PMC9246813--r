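test_that("significant-figure rounding rounds halves away from zero", {
  expect_equal(signif_half_up(6.805), 6.81)     # mean(6.86, 6.75)
  expect_equal(signif_half_up(3.915), 3.92)
  expect_equal(signif_half_up(18.95), 19.0)
  expect_equal(signif_half_up(7.325), 7.33)
  expect_equal(signif_half_up(1.5645), 1.56)
  expect_equal(signif_half_up(-6.805), -6.81)
  expect_equal(signif_half_up(0.69768), 0.698)
  expect_equal(signif_half_up(1234.5, 2), 1200)
})

test_that("representative parameters are rounded means of literature values", {
  expect_equal(derive_mean_parameter(c(5.58, 2.25)), 3.92)   # CNS1 %MV
  expect_equal(derive_mean_parameter(c(6.87, 7.16)), 7.02)   # CNS1 ECF pH
  expect_equal(derive_mean_parameter(c(6.86, 6.75)), 6.81)   # patients C/D
  expect_equal(derive_mean_parameter(42.3), 42.3)            # singleton
  expect_error(derive_mean_parameter(numeric(0)), "non-empty")
})

test_that("scaled means cover vascularization multipliers", {
  expect_equal(derive_scaled_parameter(c(4.40, 5.61), 4), 20.0)  # SF188/V+
  expect_equal(derive_scaled_parameter(c(4.40, 5.61), 1),
               derive_mean_parameter(c(4.40, 5.61)))
  expect_equal(derive_scaled_parameter(c(1, 3), 2), 4.00)
  expect_error(derive_scaled_parameter(c(1), -2), "positive")
})

test_that("relative blood-flow values scale against healthy brain", {
  expect_equal(absolute_from_relative_cbf(1, 1.53), 1.53)
  expect_equal(signif_half_up(absolute_from_relative_cbf(0.456, 1.53)), 0.698)
  expect_equal(absolute_from_relative_cbf(2, 0.527), 1.054)
  expect_error(absolute_from_relative_cbf(-1, 1), "positive")
})

test_that("BTB surface area scales with the microvascular volume ratio", {
  expect_equal(btb_surface_area(263, 0.054, 0.054), 263)
  expect_equal(btb_surface_area(100, 0.05, 1), 5)
  # C6 tumor (0.03 mL x 2.25% MV) vs healthy rat (1.8 mL x 3.00%)
  ratio <- (0.03 * 2.25 / 100) / (1.8 * 3.00 / 100)
  expect_equal(ratio, 0.0125)
  expect_equal(btb_surface_area(263, 0.03 * 0.0225, 1.8 * 0.03), 263 * 0.0125)
  # linear in tumor MV volume
  expect_equal(btb_surface_area(263, 2 * 0.001, 0.054),
               2 * btb_surface_area(263, 0.001, 0.054))
  expect_error(btb_surface_area(263, 0.01, 0), "positive")
})

test_that("re-deriving footnoted tumor parameters reproduces the bundled table", {
  tab <- load_tumor_table()
  row <- function(m) tab[tab$model_name == m, ]
  # CNS1: averages of the RG-2 and C6 rat glioma rows
  expect_equal(derive_mean_parameter(c(row("RG-2")$f_mv_pct, row("C6")$f_mv_pct)),
               row("CNS1")$f_mv_pct)
  expect_equal(derive_mean_parameter(c(row("RG-2")$f_ecf_pct, row("C6")$f_ecf_pct)),
               row("CNS1")$f_ecf_pct)
  expect_equal(derive_mean_parameter(c(row("RG-2")$ph_ecf, row("C6")$ph_ecf)),
               row("CNS1")$ph_ecf)
  expect_equal(derive_mean_parameter(c(row("RG-2")$cbf_ml_min_g, row("C6")$cbf_ml_min_g)),
               row("CNS1")$cbf_ml_min_g)
  # intracellular pH: average of C6 and the generic rat-glioma value (7.37)
  expect_equal(derive_mean_parameter(c(row("C6")$ph_icf, 7.37)),
               row("CNS1")$ph_icf)
  expect_equal(row("BT4C")$f_ecf_pct, row("CNS1")$f_ecf_pct)
  expect_equal(row("BT4C")$ph_ecf, row("CNS1")$ph_ecf)
  # SF188/V+: 4 x average of U251 and U87-MG microvascular fractions
  expect_equal(derive_scaled_parameter(c(row("U251")$f_mv_pct, row("U87-MG")$f_mv_pct), 4),
               row("SF188/V+")$f_mv_pct)
  # patients C/D: average of the glioblastoma and anaplastic astrocytoma pH
  expect_equal(derive_mean_parameter(c(row("patient_A")$ph_ecf, row("patient_B")$ph_ecf)),
               row("patient_C_D")$ph_ecf)
  # R-6 carries the 9L gliosarcoma values
  expect_equal(row("R-6")[, c("f_mv_pct", "f_ecf_pct", "ph_ecf", "ph_icf", "cbf_ml_min_g")],
               row("9L")[, c("f_mv_pct", "f_ecf_pct", "ph_ecf", "ph_icf", "cbf_ml_min_g")],
               ignore_attr = TRUE)
})

test_that("healthy physiology rows match the pinned species values", {
  rat <- default_physiology("rat")
  expect_equal(c(rat$f_mv, rat$f_ecf, rat$ph_ecf, rat$ph_icf, rat$cbf),
               c(3.00, 20.0, 7.30, 7.00, 1.53))
  hum <- default_physiology("human")
  expect_equal(c(hum$f_mv, hum$f_ecf, hum$cbf), c(3.67, 20.0, 0.527))
  expect_error(cns_physiology("rat", brain_volume = -1, f_mv = 3, f_ecf = 20,
                              f_mem = 0.33, f_lyso = 1, cbf = 1.53,
                              q_ecf_bulk_per_ml = 1e-4, q_csf = 0.002,
                              sa_bbb = 263, sa_bcsfb = 25, bbb_width = 5e-5,
                              pore_fraction_base = 1e-4, pore_radius_base = 0.7,
                              ph_mv = 7.4, ph_ecf = 7.3, ph_icf = 7, ph_lyso = 5,
                              cell_radius = 5e-4, lyso_sa_factor = 1,
                              v_lv = 0.05, v_tfv = 0.05, v_cm = 0.017,
                              v_sas = 0.18),
               "positive")
})

test_that("tumor records inherit unspecified fields from healthy physiology", {
  rat <- rat_phys()
  bare <- tumor_pathophysiology("t", 0.1, f_mv = 3.00, f_ecf = 20.0,
                                ph_ecf = 7.30, ph_icf = 7.00, cbf = 1.53)
  full <- fill_healthy_defaults(bare, rat)
  for (f in c("ph_mv", "ph_lyso", "f_mem", "f_lyso", "q_ecf_bulk_per_ml",
              "cell_radius", "lyso_sa_factor"))
    expect_equal(full[[f]], rat[[f]], label = f)
  # specified fields untouched, inheritance idempotent
  over <- tumor_pathophysiology("t", 0.1, f_mv = 2, f_ecf = 24, ph_ecf = 7.16,
                                ph_icf = 7.28, cbf = 2.43, ph_lyso = 4.5)
  filled <- fill_healthy_defaults(over, rat)
  expect_equal(filled$ph_lyso, 4.5)
  expect_identical(fill_healthy_defaults(filled, rat), filled)
  # bundled C6 row inherits the healthy microvascular/lysosomal environment
  c6 <- load_tumor_model("C6")
  expect_equal(c6$ph_mv, rat$ph_mv)
  expect_equal(c6$ph_lyso, rat$ph_lyso)
  expect_equal(c6$q_ecf_bulk_per_ml, rat$q_ecf_bulk_per_ml)
  expect_error(tumor_pathophysiology("t", 0.1, f_mv = 2, f_ecf = 24,
                                     ph_ecf = 7.2, ph_icf = 7.3, cbf = 1,
                                     nonsense = 1), "unknown tumor fields")
})
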