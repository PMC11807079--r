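test_that("prediction error is the symmetrized relative difference", {
  expect_equal(prediction_error(5, 5), 0)
  expect_equal(prediction_error(2, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(round(abs(prediction_error(2, 1)), 2), 0.67)
  expect_equal(prediction_error(1, 2), -2 / 3, tolerance = 1e-12)
  expect_error(prediction_error(-1, 2), ">= 0")
  expect_error(prediction_error(0, 0), "undefined")
})

test_that("prediction error is antisymmetric and bounded over random inputs", {
  set.seed(101)
  n <- 10000
  a <- rlnorm(n, 0, 2)
  b <- rlnorm(n, 0, 2)
  pe_ab <- prediction_error(a, b)
  pe_ba <- prediction_error(b, a)
  expect_equal(pe_ab, -pe_ba, tolerance = 1e-12)
  expect_true(all(pe_ab > -2 & pe_ab < 2))
  # the bound is approached only in the extreme-ratio limit
  expect_gt(prediction_error(1e12, 1), 1.999)
  expect_lt(prediction_error(1e-12, 1), -1.999)
})

test_that("fold thresholds map fold levels to PE magnitudes", {
  expect_equal(fold_threshold(1), 0)
  expect_equal(fold_threshold(2), 2 / 3, tolerance = 1e-12)
  expect_equal(round(fold_threshold(2), 2), 0.67)
  expect_equal(fold_threshold(3), 1)
  expect_equal(fold_threshold(5), 4 / 3, tolerance = 1e-12)
  expect_error(fold_threshold(0.5), ">= 1")
  ks <- seq(1, 50, by = 0.5)
  expect_true(all(diff(fold_threshold(ks)) > 0))
  # a constant k-fold prediction series has median PE exactly 2(k-1)/(k+1)
  obs <- observation_series(data.frame(animal_id = 1, time_min = 1:9,
                                       conc_ng_per_mL = (1:9) / 3))
  for (k in c(1.5, 2, 3)) {
    pred <- data.frame(time = 1:9, conc = k * (1:9) / 3)
    expect_equal(median_pe(pred, obs), fold_threshold(k), tolerance = 1e-12)
  }
})

test_that("median PE pools across animals, with a per-animal option", {
  pred <- data.frame(time = c(10, 20, 30), conc = c(1, 1, 1))
  obs <- observation_series(data.frame(
    animal_id = rep(1:2, each = 3), time_min = rep(c(10, 20, 30), 2),
    conc_ng_per_mL = c(1, 1, 1, 2, 2, 2)))
  expect_equal(median_pe(pred, obs), (0 - 2 / 3) / 2, tolerance = 1e-12)
  pa <- median_pe(pred, obs, per_animal = TRUE)
  expect_equal(unname(pa[["1"]]), 0)
  expect_equal(unname(pa[["2"]]), -2 / 3, tolerance = 1e-12)
  # PEs {-0.2, 0.1, 0.6} -> median 0.1
  expect_equal(median(c(-0.2, 0.1, 0.6)), 0.1)
  # evaluation requires predictions at the exact observation times
  expect_error(median_pe(data.frame(time = c(10, 20), conc = c(1, 1)), obs),
               "missing at observation times")
})

test_that("fold classification uses half-open intervals", {
  t2 <- fold_threshold(2); t3 <- fold_threshold(3); t5 <- fold_threshold(5)
  expect_equal(as.character(fold_class(c(0, t2 - 1e-9, t2, -t2, 1.1, t5, 1.9))),
               c("<2-fold", "<2-fold", "2-3-fold", "2-3-fold", "3-5-fold",
                 ">5-fold", ">5-fold"))
})

test_that("within-twofold summaries stratify and count correctly", {
  mk <- function(med, drug, cell) {
    structure(list(pe = med, median_pe = med,
                   fold_class = as.character(fold_class(med)), n = 1,
                   keys = list(drug = drug, cell_line = cell)),
              class = "pe_report")
  }
  reports <- list(mk(0, "a", "x"), mk(0.5, "a", "x"), mk(0.9, "a", "y"),
                  mk(-0.7, "b", "x"))
  tab <- summarize_within_twofold(reports, "drug")
  expect_equal(tab$pct_within[tab$drug == "a"], 100 * 2 / 3)
  expect_equal(tab$pct_within[tab$drug == "b"], 0)
  expect_equal(sum(tab$n_total), length(reports))
  tab2 <- summarize_within_twofold(reports, c("drug", "cell_line"))
  expect_equal(sum(tab2$n_total), length(reports))   # partition, no overlap
  expect_error(summarize_within_twofold(reports, "regimen"), "unknown")
})

test_that("expression bandwidths order by in vitro expression and degenerate to one curve", {
  b <- test_bundle()
  grid <- seq(0, 360, by = 6)
  rec <- resolve_record(b, "quinidine", "MDCKII-MDR1", "Feng2008")
  ex <- b$expression[b$expression$cell_line == "MDCKII-MDR1", ]
  spec <- quinidine_spec("average")
  band <- bandwidth_predictions(spec, rec, ex,
                                b$constants$pgp_expression_in_vivo, grid)
  expect_true(all(band$lower <= band$central + 1e-12))
  expect_true(all(band$central <= band$upper + 1e-12))
  # highest expression -> lowest REF -> lowest CL_Pgp -> upper curve
  hi <- band$simulations[[which(band$levels$level == "highest")]]$series$c_ecf
  expect_equal(hi, band$upper, tolerance = 1e-12)

  # LLC-PK1-MDR1 has a single reported expression value: degenerate band
  rec2 <- resolve_record(b, "quinidine", "LLC-PK1-MDR1", "Nagaya2020")
  ex2 <- b$expression[b$expression$cell_line == "LLC-PK1-MDR1", ]
  expect_equal(nrow(ex2), 1L)
  spec2 <- spec_from_bundle(b, "quinidine", "continuous", "LLC-PK1-MDR1",
                            "Nagaya2020", "lowest")
  band2 <- bandwidth_predictions(spec2, rec2, ex2,
                                 b$constants$pgp_expression_in_vivo, grid)
  expect_identical(band2$lower, band2$upper)
  expect_identical(band2$lower, band2$central)

  # the no-REF scenario ignores expression records entirely
  band3 <- bandwidth_predictions(spec, rec, ex,
                                 b$constants$pgp_expression_in_vivo, grid,
                                 no_ref = TRUE)
  expect_equal(band3$levels$ref, 1)
  expect_identical(band3$lower, band3$upper)
})
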