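test_that("aggregate_wells gives mean and sample SD over replicate wells", {
  ds <- tiny_dataset()
  cv <- aggregate_wells(ds$readings, ds$layout)
  iso1 <- cv[cv$isolate_id == "iso1", ]
  expect_equal(iso1$n_wells, 3)
  expect_equal(iso1$mean_od, mean(c(0.30, 0.32, 0.34)))
  expect_equal(iso1$sd_od, sd(c(0.30, 0.32, 0.34)))
  # hand-derived case {0.1, 0.2, 0.3}: mean 0.2, sample SD 0.1
  ds$readings$absorbance[ds$readings$stage == "growth_endpoint"][1:3] <-
    c(0.1, 0.2, 0.3)
  cv2 <- aggregate_wells(ds$readings, ds$layout)
  expect_equal(cv2$mean_od[cv2$isolate_id == "iso1"], 0.2)
  expect_equal(cv2$sd_od[cv2$isolate_id == "iso1"], 0.1)
})

test_that("a single well yields sd 0 and n_wells 1, and n is conserved", {
  ds <- tiny_dataset()
  keep <- !(ds$readings$well %in% c("A2", "A3"))
  rd <- ds$readings[keep, ]
  lay <- ds$layout[!(ds$layout$well %in% c("A2", "A3")), ]
  cv <- aggregate_wells(rd, lay)
  iso1 <- cv[cv$isolate_id == "iso1", ]
  expect_equal(iso1$n_wells, 1)
  expect_equal(iso1$sd_od, 0)
  expect_equal(iso1$mean_od, 0.30)
  n_sample_wells <- sum(lay$role == "sample")
  expect_equal(sum(cv$n_wells), n_sample_wells)
})

test_that("Ro is the ratio of sterility-well channel means at baseline", {
  ds <- tiny_dataset()
  ro <- compute_Ro(ds$readings, ds$layout)
  expect_equal(ro$ro, 1.25)
  # two wells (0.4/0.4, 0.6/0.4): mean(0.4,0.6)/mean(0.4,0.4) = 1.25
  rd <- ds$readings
  sel570 <- rd$stage == "rz_baseline" & rd$channel == "OD570" &
    rd$well %in% c("H11", "H12")
  rd$absorbance[sel570] <- c(0.4, 0.6)
  expect_equal(compute_Ro(rd, ds$layout)$ro, 1.25)
  # equal channels give the identity ratio
  rd$absorbance[sel570] <- 0.4
  expect_equal(compute_Ro(rd, ds$layout)$ro, 1)
  # degenerate oxidized read
  sel600 <- rd$stage == "rz_baseline" & rd$channel == "OD600" &
    rd$well %in% c("H11", "H12")
  rd$absorbance[sel600] <- 0
  expect_error(compute_Ro(rd, ds$layout), "Ro undefined")
})

test_that("AR570 follows the corrected-reduction formula with clamp and flag", {
  expect_equal(compute_AR570(0.9, 0.4, 1.25),
               data.frame(ar570 = 40, detectable = TRUE))
  z <- compute_AR570(0.5, 0.4, 1.25)      # exactly oxidized
  expect_equal(z$ar570, 0)
  expect_false(z$detectable)
  neg <- compute_AR570(0.3, 0.4, 1.25)    # below oxidized baseline
  expect_equal(neg$ar570, 0)
  expect_false(neg$detectable)
})

test_that("AR570 is homogeneous under joint channel rescaling", {
  set.seed(21)
  a <- runif(50, 0.2, 1.5)
  b <- runif(50, 0.2, 0.8)
  ro <- 1.3
  for (c_scale in c(0.5, 2, 7)) {
    expect_equal(compute_AR570(c_scale * a, c_scale * b, ro)$ar570,
                 pmax(0, c_scale * ((a - b * ro) * 100)))
  }
})

test_that("sterility wells evaluated against their own plate Ro give AR570 = 0", {
  sim <- simulate_experiment(default_study_design(seed = 9))
  ro <- compute_Ro(sim$readings, sim$layout)
  ctrl <- sim$layout[sim$layout$role == "sterility_control", ]
  base <- sim$readings[sim$readings$stage == "rz_baseline", ]
  mg <- merge(base, ctrl[, c("plate_id", "well")], by = c("plate_id", "well"))
  w <- reshape(mg[, c("plate_id", "well", "timepoint_h", "channel",
                      "absorbance")],
               idvar = c("plate_id", "well", "timepoint_h"),
               timevar = "channel", direction = "wide")
  w <- merge(w, ro, by = "plate_id")
  ar <- compute_AR570(w$absorbance.OD570, w$absorbance.OD600, w$ro)
  expect_true(all(abs(ar$ar570) < 1e-9))
})

test_that("viability_table averages plate-level AR570 over biological days", {
  ds <- tiny_dataset()
  vt <- viability_table(ds$readings, ds$layout)
  # iso1 rz_final OD570 mean = 1.25*0.4 + mean(0.2,0.22,0.21); Ro = 1.25
  expect_equal(vt$ar570[vt$isolate_id == "iso1"],
               mean(c(0.2, 0.22, 0.21)) * 100)
  expect_true(all(vt$detectable))
  expect_equal(nrow(vt), 2)
  # dropping the OD600 channel at rz_final is an error naming the key
  rd <- ds$readings[!(ds$readings$stage == "rz_final" &
                        ds$readings$channel == "OD600"), ]
  expect_error(viability_table(rd, ds$layout), "rz_final")
})
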