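test_that("plate table write/read round-trip is the identity on values", {
  d <- tiny_design()
  tr <- default_ground_truth(d, noise_sd = 0.01, seed = 2)
  plate <- simulate_plate(d, tr)
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_table(plate, f)
  back <- read_plate_table(f)
  back <- back[order(match(back$well_id, plate$well_id), back$day), ]
  rownames(back) <- NULL
  expect_equal(back, plate[order(match(plate$well_id, plate$well_id), plate$day), ],
               tolerance = 0)
})

test_that("malformed plate tables are rejected with informative errors", {
  d <- plate_design(0, 7, 25, 1, "x", days = 5)
  plate <- simulate_plate(d, default_ground_truth(d, seed = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_table(rbind(plate, plate[1, ]), f)
  expect_error(read_plate_table(f), "duplicated")
  bad <- plate
  bad$od630 <- as.character(bad$od630)
  bad$od630[3] <- "oops"
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_plate_table(f), "od630")
  write.csv(plate[, -1], f, row.names = FALSE)
  expect_error(read_plate_table(f), "well_id")
})

test_that("blank subtraction removes the per-day mean control signal", {
  # two controls at 0.08 and 0.12 against an inoculated OD of 0.50
  days <- 0:4
  mk <- function(id, role, od) data.frame(
    well_id = id, organism = if (role == "control") "none" else "f",
    salinity = 0, pH = 7, temperature = 25, replicate = 1, role = role,
    day = days, od630 = od)
  plate <- rbind(mk("w1", "inoculated", rep(0.50, 5)),
                 mk("c1", "control", rep(0.08, 5)),
                 mk("c2", "control", rep(0.12, 5)))
  bs <- blank_subtract(plate)
  expect_true(all(bs$od630 == 0.40))
  expect_true(all(bs$role == "blank_subtracted"))
  # identity: inoculated equal to the control mean gives an all-zero series
  plate2 <- rbind(mk("w1", "inoculated", rep(0.10, 5)),
                  mk("c1", "control", rep(0.08, 5)),
                  mk("c2", "control", rep(0.12, 5)))
  expect_true(all(blank_subtract(plate2)$od630 == 0))
  # missing control day
  plate3 <- rbind(mk("w1", "inoculated", rep(0.5, 5)),
                  mk("c1", "control", rep(0.1, 5))[-2, ])
  expect_error(blank_subtract(plate3), "control|grid")
  # unmatched treatment
  plate4 <- plate
  plate4$pH[plate4$role == "control"] <- 9
  expect_error(blank_subtract(plate4), "no matching control")
})

test_that("blank subtraction commutes with replicate averaging (linearity)", {
  d <- tiny_design(replicates = 4)
  tr <- default_ground_truth(d, noise_sd = 0.02, seed = 8)
  plate <- simulate_plate(d, tr)
  bs <- blank_subtract(plate)
  key <- function(df) paste(df$salinity, df$pH, df$temperature, df$day, sep = "/")
  sub_then_avg <- tapply(bs$od630, key(bs), mean)
  inoc <- plate[plate$role == "inoculated", ]
  ctrl <- plate[plate$role == "control", ]
  avg_inoc <- tapply(inoc$od630, key(inoc), mean)
  avg_ctrl <- tapply(ctrl$od630, key(ctrl), mean)
  avg_then_sub <- avg_inoc - avg_ctrl[names(avg_inoc)]
  expect_equal(sub_then_avg[names(avg_then_sub)], avg_then_sub, tolerance = 1e-12)
})

test_that("negative blank-subtracted values are retained, not clamped", {
  days <- 0:5
  plate <- rbind(
    data.frame(well_id = "w", organism = "f", salinity = 0, pH = 7,
               temperature = 25, replicate = 1, role = "inoculated",
               day = days, od630 = 0.04),
    data.frame(well_id = "c", organism = "none", salinity = 0, pH = 7,
               temperature = 25, replicate = 1, role = "control",
               day = days, od630 = 0.05))
  expect_equal(blank_subtract(plate)$od630, rep(-0.01, 6))
})

test_that("rate table round-trips at full precision and keeps conventions", {
  d <- tiny_design(days = 20)
  tr <- default_ground_truth(d, noise_sd = 0.005, seed = 4)
  rates <- fit_plate(simulate_plate(d, tr))
  f <- withr::local_tempfile(fileext = ".csv")
  write_rate_table(rates, f)
  back <- read_rate_table(f)
  expect_equal(back, rates, tolerance = 0)
  # no-growth convention: flag FALSE and rate exactly 0
  ng <- rates[!rates$growth_flag, ]
  expect_gt(nrow(ng), 0)
  expect_true(all(ng$rate == 0))
  # growth rows satisfy rate = k/(2(d+1)) of their own parameters
  g <- rates[rates$growth_flag, ]
  expect_gt(nrow(g), 0)
  expect_equal(g$rate, g$k / (2 * (g$d + 1)))
  # header-only output for an empty table
  write_rate_table(rates[0, ], f)
  expect_equal(nrow(read_rate_table(f)), 0)
})

test_that("fit_plate recovers ground truth on a noiseless plate", {
  d <- plate_design(0, 7, 25, replicates = 2, organisms = "demo", days = 30)
  params <- data.frame(organism = "demo", salinity = 0, pH = 7,
                       temperature = 25, growth = TRUE, a = 0.8, k = 0.5,
                       d = 3, xc = 12)
  tr <- ground_truth(d, params, noise_sd = 0, baseline = 0.05, seed = 1)
  rates <- fit_plate(simulate_plate(d, tr))
  expect_true(all(rates$growth_flag))
  expect_equal(rates$a, rep(0.8, 2), tolerance = 1e-4)
  expect_equal(rates$k, rep(0.5, 2), tolerance = 1e-4)
  expect_equal(rates$d, rep(3, 2), tolerance = 1e-3)
  expect_equal(rates$xc, rep(12, 2), tolerance = 1e-4)
})
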