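simple_layout <- function() {
  plate_layout(data.frame(
    well = c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2"),
    condition = c("ctrlP", "ctrlP", "drugA", "drugA", "drugB", "drugB",
                  "ctrlD", "ctrlD"),
    solvent = c("PBS", "PBS", "PBS", "PBS", "DMSO", "DMSO", "DMSO", "DMSO"),
    is_control = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE))
}

row_for <- function(well, n_beads, value, assay = 1) {
  r <- measurement_row(well, n_beads = n_beads, n_sprouts = value)
  r$well <- well
  r$assay <- assay
  r
}

test_that("bead-count weighting reproduces hand-computed means", {
  lay <- simple_layout()
  # two wells, values 10 and 20, bead counts 1 and 3 -> (10*1 + 20*3)/4 = 17.5
  rows <- rbind(row_for("A1", 1, 10), row_for("A2", 3, 20))
  agg <- aggregate_wells(rows, lay)
  expect_equal(agg$value[agg$measurement == "n_sprouts"], 17.5)

  # equal bead counts reduce to the simple mean, exactly
  rows2 <- rbind(row_for("A1", 4, 11), row_for("A2", 4, 25))
  agg2 <- aggregate_wells(rows2, lay)
  expect_identical(agg2$value[agg2$measurement == "n_sprouts"], 18)

  # a single well is its own mean
  agg3 <- aggregate_wells(row_for("A1", 7, 42), lay)
  expect_equal(agg3$value[agg3$measurement == "n_sprouts"], 42)
})

test_that("zero-bead wells are excluded with a warning; unmapped wells error", {
  lay <- simple_layout()
  rows <- rbind(row_for("A1", 0, 99), row_for("A2", 3, 20))
  expect_warning(agg <- aggregate_wells(rows, lay), "zero beads")
  expect_equal(agg$value[agg$measurement == "n_sprouts"], 20)
  expect_error(aggregate_wells(row_for("Z9", 3, 1), lay),
               class = "sproutr_config_error")
})

test_that("normalization uses the solvent-matched control and self-normalizes to 1", {
  lay <- simple_layout()
  rows <- rbind(row_for("A1", 2, 20), row_for("A2", 2, 20),   # PBS control 20
                row_for("B1", 2, 30), row_for("B2", 2, 30),   # drugA (PBS)  30
                row_for("C1", 2, 10), row_for("C2", 2, 10),   # drugB (DMSO) 10
                row_for("D1", 2, 40), row_for("D2", 2, 40))   # DMSO control 40
  norm <- normalize_to_control(aggregate_wells(rows, lay), lay)
  f <- function(cond) norm$fold[norm$condition == cond &
                                  norm$measurement == "n_sprouts"]
  expect_equal(f("ctrlP"), 1)                # control normalizes to exactly 1
  expect_equal(f("ctrlD"), 1)
  expect_equal(f("drugA"), 1.5)              # 30 / 20, hand arithmetic
  expect_equal(f("drugB"), 0.25)             # 10 / 40: DMSO control, never PBS
})

test_that("the one-sample t-test matches its closed form and stats::t.test", {
  vals <- c(1.5, 1.6, 1.4)
  got <- test_condition(vals)
  t_hand <- (mean(vals) - 1) / (sd(vals) / sqrt(3))
  p_hand <- 2 * pt(-abs(t_hand), df = 2)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$p, p_hand, tolerance = 1e-12)
  ref <- stats::t.test(vals, mu = 1)          # independent oracle
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(got$direction, "increase")

  # all values at the null: t = 0, p = 1, ns
  null <- test_condition(c(1, 1, 1))
  expect_equal(null$t, 0)
  expect_equal(null$p, 1)
  expect_equal(null$direction, "ns")

  # two low values: decrease iff p < alpha
  two <- test_condition(c(0.5, 0.6))
  ref2 <- stats::t.test(c(0.5, 0.6), mu = 1)
  expect_equal(two$p, ref2$p.value, tolerance = 1e-12)
  expect_equal(two$direction, if (two$p < 0.05) "decrease" else "ns")

  # fewer than two assays: skipped and flagged
  one <- test_condition(1.2)
  expect_false(one$tested)
  expect_true(is.na(one$p))
})

test_that("a condition identical to its control tests as p = 1", {
  lay <- simple_layout()
  rows <- do.call(rbind, lapply(1:3, function(a)
    rbind(row_for("A1", 2, 20, a), row_for("A2", 2, 20, a),
          row_for("B1", 2, 20, a), row_for("B2", 2, 20, a))))
  summ <- summarize_conditions(
    normalize_to_control(aggregate_wells(rows, lay), lay))
  drugA <- summ[summ$condition == "drugA" & summ$measurement == "n_sprouts", ]
  expect_equal(drugA$p_value, 1)
  expect_equal(drugA$direction, "ns")
})

test_that("missing measurements propagate as missing, never as zero", {
  lay <- simple_layout()
  r1 <- row_for("A1", 2, 10); r2 <- row_for("A2", 3, 20)
  r2$n_sprouts <- NA_real_
  agg <- aggregate_wells(rbind(r1, r2), lay)
  # the NA well drops out; weights renormalize over the remaining well
  expect_equal(agg$value[agg$measurement == "n_sprouts"], 10)
  expect_true(is.na(agg$value[agg$measurement == "pericyte_coverage"][1]))
})

test_that("run_stats chains the full table end to end", {
  lay_df <- data.frame(well = c("A1", "B1"), condition = c("ctrl", "drug"),
                       solvent = "PBS", is_control = c(TRUE, FALSE))
  rows <- do.call(rbind, lapply(1:3, function(a) {
    r <- rbind(row_for("A1", 2, 20, a), row_for("B1", 2, 20 * c(1.4, 1.5, 1.6)[a], a))
    r
  }))
  summ <- run_stats(rows, lay_df)
  drug <- summ[summ$condition == "drug" & summ$measurement == "n_sprouts", ]
  expect_equal(drug$normalized_mean, 1.5, tolerance = 1e-12)
  expect_equal(drug$n_assays, 3)
  expect_equal(drug$direction, "increase")
  expect_true(drug$sig_05)
})
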