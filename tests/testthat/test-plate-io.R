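test_that("long readings round-trip through CSV with row count preserved", {
  ds <- tiny_dataset()
  paths <- write_dataset_csv(ds)
  rd <- read_plate_long(paths$readings)
  expect_equal(nrow(rd), nrow(ds$readings))
  expect_equal(rd$absorbance, ds$readings$absorbance)
  lay <- read_layout(paths$layout)
  expect_equal(nrow(lay), nrow(ds$layout))
  expect_setequal(unique(lay$isolate_id[lay$role == "sample"]),
                  c("iso1", "iso2"))
})

test_that("reader rejects duplicate keys and malformed rows by line number", {
  ds <- tiny_dataset()
  ds$readings <- rbind(ds$readings, ds$readings[1, ])
  paths <- write_dataset_csv(ds)
  expect_error(read_plate_long(paths$readings), "duplicate reading key")

  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")
  writeLines(c("plate_id,well,channel,timepoint_h,stage,absorbance",
               "p1,A1,OD570,24,growth_endpoint,0.4",
               "p1,Z9,OD570,24,growth_endpoint,0.4"), f)
  expect_error(read_plate_long(f), "line 3")
})

test_that("an empty readings file with a valid header parses to zero rows", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "empty.csv")
  writeLines("plate_id,well,channel,timepoint_h,stage,absorbance", f)
  rd <- read_plate_long(f)
  expect_equal(nrow(rd), 0)
  expect_named(rd, c("plate_id", "well", "channel", "timepoint_h", "stage",
                     "absorbance"))
})

test_that("negative blanked absorbances are preserved, not clamped", {
  ds <- tiny_dataset()
  ds$readings$absorbance[1] <- -0.013
  paths <- write_dataset_csv(ds)
  rd <- read_plate_long(paths$readings)
  expect_equal(min(rd$absorbance), -0.013)
})

test_that("layout invariants: sterility control required, sample wells named", {
  ds <- tiny_dataset()
  lay_no_ctrl <- ds$layout[ds$layout$role == "sample", ]
  paths <- write_dataset_csv(list(readings = ds$readings,
                                  layout = lay_no_ctrl))
  expect_error(read_layout(paths$layout), "sterility control required")

  lay_anon <- ds$layout
  lay_anon$isolate_id[1] <- ""
  paths2 <- write_dataset_csv(list(readings = ds$readings,
                                   layout = lay_anon))
  expect_error(read_layout(paths2$layout), "isolate_id")
})

test_that("layout recovers all isolate ids from a 10-isolate plate map", {
  sim <- simulate_experiment(default_study_design(seed = 3))
  paths <- write_dataset_csv(sim)
  lay <- read_layout(paths$layout)
  expect_length(unique(lay$isolate_id[lay$role == "sample"]), 10)
})

test_that("validation reports orphans and missing stages without throwing", {
  ds <- tiny_dataset()
  expect_equal(nrow(validate_plate_data(ds$readings, ds$layout)), 0)

  orphan <- ds$readings
  orphan$well[1] <- "C5"        # not in layout
  rep <- validate_plate_data(orphan, ds$layout)
  expect_equal(sum(rep$severity == "error" &
                     grepl("absent from the layout", rep$message)), 1)

  no_base <- ds$readings[ds$readings$stage != "rz_baseline", ]
  rep2 <- validate_plate_data(no_base, ds$layout)
  expect_true(any(rep2$severity == "warning" &
                    grepl("rz_baseline", rep2$message)))
  # idempotent and side-effect free
  expect_identical(rep2, validate_plate_data(no_base, ds$layout))
})

test_that("write_tidy/read_tidy round-trips a table field-by-field", {
  df <- data.frame(id = c("a", "b"), x = c(0.1 + 0.2, -1.5e-7),
                   n = c(3L, 1L), flag = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  f <- file.path(withr::local_tempdir(), "t.tsv")
  write_tidy(df, f)
  back <- read_tidy(f)
  expect_identical(back$x, df$x)   # 17 significant digits: exact doubles
  expect_identical(back$id, df$id)
  expect_identical(back$n, df$n)
  expect_identical(back$flag, df$flag)
  expect_error(write_tidy(df, file.path("no", "such", "dir", "t.tsv")),
               "cannot write")
})

test_that("grid_to_long maps an 8x12 grid onto SBS well coordinates", {
  g <- matrix(NA_real_, 8, 12)
  g[1, 1] <- 0.5   # A1
  g[8, 12] <- 0.7  # H12
  out <- grid_to_long(g, "p1", "OD570", 24, "growth_endpoint")
  expect_equal(out$well, c("A1", "H12"))
  expect_equal(out$absorbance, c(0.5, 0.7))
})
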