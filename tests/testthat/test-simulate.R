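test_that("design enumeration equals the product of level counts and replicates", {
  d <- plate_design(salinities = c(0, 30), phs = c(1, 3, 5, 7, 9),
                    temperatures = c(15, 25, 37, 45), replicates = 8,
                    organisms = c("f1", "f2"))
  expect_identical(n_wells(d), 320L)
  per_org <- table(d$wells$organism[d$wells$role == "inoculated"])
  expect_true(all(per_org == 320))
  # one control set per treatment, shared across organisms
  ctrl <- d$wells[d$wells$role == "control", ]
  expect_equal(nrow(ctrl), 2 * 5 * 4 * 8)
  # degenerate single-cell design
  d1 <- plate_design(0, 7, 25, 1, "x", days = 5, include_controls = FALSE)
  expect_identical(n_wells(d1), 1L)
  expect_output(print(d), "320")
})

test_that("invalid designs are rejected", {
  expect_error(plate_design(salinities = numeric(0)), "salinities")
  expect_error(plate_design(replicates = 0), "replicates")
  expect_error(plate_design(days = 1), "days")
  expect_error(plate_design(phs = c(7, 7)), "duplicated")
})

test_that("ground truth must cover every design cell and have valid parameters", {
  d <- tiny_design()
  tr <- default_ground_truth(d, seed = 3)
  expect_s3_class(tr, "ground_truth")
  short <- tr$params[-1, ]
  expect_error(ground_truth(d, short), "cover")
  bad <- tr$params
  bad$d[bad$growth][1] <- 0.5
  expect_error(ground_truth(d, bad), "d")
  expect_error(ground_truth(d, tr$params, noise_sd = -1), "noise_sd")
})

test_that("simulated wells follow curve + baseline exactly when noise is off", {
  d <- plate_design(0, 7, 25, 1, "demo", days = 21, include_controls = TRUE)
  params <- data.frame(organism = "demo", salinity = 0, pH = 7,
                       temperature = 25, growth = TRUE,
                       a = 1.0, k = 0.6, d = 2, xc = 10)
  tr <- ground_truth(d, params, noise_sd = 0, baseline = 0.05, seed = 1)
  pl <- simulate_plate(d, tr)
  inoc <- pl[pl$role == "inoculated", ]
  expect_equal(inoc$od630[inoc$day == 10], 0.55)  # a/2 + baseline at inflection
  expect_true(all(pl$od630[pl$role == "control"] == 0.05))
  # no-growth cell: blank-subtracted trace identically zero
  params$growth <- FALSE
  tr0 <- ground_truth(d, params, noise_sd = 0, baseline = 0.05, seed = 1)
  bs <- blank_subtract(simulate_plate(d, tr0))
  expect_true(all(bs$od630 == 0))
})

test_that("simulation is bit-for-bit reproducible and per-well noise survives subsetting", {
  d <- tiny_design()
  tr <- default_ground_truth(d, noise_sd = 0.02, seed = 9)
  p1 <- simulate_plate(d, tr)
  p2 <- simulate_plate(d, tr)
  expect_identical(p1, p2)
  # restricting the design to one treatment leaves that treatment's noise unchanged
  dsub <- plate_design(0, 7, 25, replicates = 2, organisms = "demo", days = 12)
  trsub <- ground_truth(dsub, tr$params[tr$params$salinity == 0 &
                                        tr$params$pH == 7 &
                                        tr$params$temperature == 25, ],
                        noise_sd = 0.02, seed = 9)
  psub <- simulate_plate(dsub, trsub)
  shared <- intersect(unique(psub$well_id), unique(p1$well_id))
  expect_true(length(shared) > 0)
  for (w in shared) {
    expect_identical(psub$od630[psub$well_id == w], p1$od630[p1$well_id == w])
  }
  expect_true(all(p1$od630 >= 0))  # truncated noise keeps absorbance non-negative
})

test_that("default truth encodes the assay's qualitative structure", {
  d <- plate_design(organisms = c("thermo", "other"))
  tr <- default_ground_truth(d, thermotolerant_organism = "thermo")
  p <- tr$params
  expect_true(all(!p$growth[p$pH == 1]))
  expect_true(all(!p$growth[p$temperature == 45 & p$organism == "other"]))
  expect_true(all(p$growth[p$temperature == 45 & p$organism == "thermo" & p$pH > 1]))
})

test_that("simulated rate tables are balanced with the requested effect structure", {
  tab <- simulate_rate_table(c(0, 2), c(0, 0), n_per_cell = 50, sd = 0.1,
                             seed = 21)
  expect_equal(nrow(tab), 2 * 2 * 50)
  expect_true(all(table(tab$A, tab$B) == 50))
  truth <- attr(tab, "truth")
  expect_equal(sum(truth$a), 0)  # effects are centred
  # empirical A contrast tracks the injected effect
  est <- diff(tapply(tab$y, tab$A, mean))
  expect_equal(unname(est), 2, tolerance = 0.15)
  # zero noise + zero effects gives a constant response
  flat <- simulate_rate_table(c(0, 0), c(0, 0), n_per_cell = 3, sd = 0, seed = 1)
  expect_true(all(flat$y == flat$y[1]))
  expect_error(simulate_rate_table(c(0, 1), c(0, 1), n_per_cell = 1), "n_per_cell")
  expect_error(simulate_rate_table(0, c(0, 1)), "2 levels")
})
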