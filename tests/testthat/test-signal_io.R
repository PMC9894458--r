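test_that("emg_recording validates its inputs", {
  expect_s3_class(suppressWarnings(emg_recording(rnorm(400), "T-1")),
                  "emg_recording")
  expect_error(emg_recording(numeric(0), "T1"), "empty")
  expect_error(emg_recording(c(rnorm(399), NA), "T1"), "non-finite")
  expect_error(emg_recording(rnorm(399), "T1"), "at least 400")
  expect_error(emg_recording(rnorm(400), "T9"), "unknown stage")
  expect_warning(emg_recording(rnorm(500), "T2"), "< 2 min")
})

test_that("leg_dataset enforces one recording per stage and shared identity", {
  r1 <- suppressWarnings(emg_recording(rnorm(400), "T-1"))
  r2 <- suppressWarnings(emg_recording(rnorm(400), "T1"))
  d <- leg_dataset(list(r2, r1))
  expect_named(d$recordings, c("T-1", "T1"))  # protocol order, not input order
  expect_error(leg_dataset(list(r1, r1)), "duplicate")
  r3 <- suppressWarnings(emg_recording(rnorm(400), "T2", pig_id = "P9"))
  expect_error(leg_dataset(list(r1, r3)), "mix")
})

test_that("read_stage_table parses the wide stage layout", {
  n <- 600
  set.seed(42)
  df <- as.data.frame(stats::setNames(
    lapply(STAGES, function(s) rnorm(n)), STAGES), check.names = FALSE)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  d <- suppressWarnings(read_stage_table(p, pig_id = "P1", leg = "L"))
  expect_length(d$recordings, 9)
  expect_equal(d$recordings[["T3"]]$samples, df[["T3"]])
  expect_equal(length(d$recordings[["T8"]]$samples), n)
})

test_that("stage identity follows the header label, not column position", {
  set.seed(7)
  df <- data.frame(`T1` = rnorm(450), `T-1` = rnorm(450),
                   check.names = FALSE)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  d <- suppressWarnings(read_stage_table(p))
  expect_length(d$recordings, 2)
  expect_equal(d$recordings[["T-1"]]$samples, df[["T-1"]])
  # reorder the columns: identical datasets
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(df[, c("T-1", "T1")], p2, row.names = FALSE)
  d2 <- suppressWarnings(read_stage_table(p2))
  expect_equal(d$recordings[["T1"]]$samples, d2$recordings[["T1"]]$samples)
})

test_that("read_stage_table trims trailing blanks, rejects mid-column NA", {
  df <- data.frame(`T-1` = as.character(rnorm(500)),
                   `T3` = c(as.character(rnorm(450)), rep("", 50)),
                   check.names = FALSE)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  d <- suppressWarnings(read_stage_table(p))
  expect_length(d$recordings[["T3"]]$samples, 450)

  df$T3[200] <- "NA"
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(suppressWarnings(read_stage_table(p)), "T3")
})

test_that("read_stage_table error cases", {
  expect_error(read_stage_table(tempfile()), "no such file")
  p <- tempfile(fileext = ".csv")
  writeLines(c("A,B", "1,2"), p)
  expect_error(read_stage_table(p), "no admissible stage")
  # duplicate stage header
  writeLines(c("T1,T1", paste(rep("0,0", 500), collapse = "\n")), p)
  expect_error(read_stage_table(p), "duplicate")
  # too-short column
  writeLines(c("T-1", as.character(rnorm(100))), p)
  expect_error(read_stage_table(p), "only 100")
})

test_that("long-format CSV round-trips a leg", {
  leg <- tiny_leg(duration_s = 1, seed = 5)
  rows <- do.call(rbind, lapply(leg$recordings, function(r) {
    data.frame(pig_id = r$pig_id, leg = r$leg, stage = r$stage,
               sample_index = seq_along(r$samples), value = r$samples)
  }))
  p <- tempfile(fileext = ".csv")
  utils::write.csv(rows, p, row.names = FALSE)
  d <- suppressWarnings(read_stage_table(p))
  expect_length(d$recordings, 9)
  expect_equal(d$recordings[["T5"]]$samples, leg$recordings[["T5"]]$samples)
})

test_that("wide CSV writer inverts the reader", {
  leg <- tiny_leg(duration_s = 1, seed = 9)
  p <- write_tmp_stage_csv(leg)
  back <- suppressWarnings(read_stage_table(p, pig_id = leg$pig_id,
                                            leg = leg$leg))
  for (s in STAGES) {
    expect_equal(back$recordings[[s]]$samples, leg$recordings[[s]]$samples,
                 tolerance = 1e-12)
  }
})

test_that("metrics serialization round-trips a cv_result losslessly", {
  set.seed(3)
  conf <- matrix(c(57, 3, 2, 58), 2, 2)
  res <- cv_result("binary_10fold", accuracies = runif(10, 90, 100),
                   unit_names = sprintf("fold%02d", 1:10),
                   confusion = conf, class_labels = c("T-1", "T1"))
  p <- tempfile(fileext = ".json")
  write_metrics(res, p)
  back <- read_metrics(p)
  expect_equal(back$accuracies, res$accuracies)
  expect_equal(back$mean, res$mean)
  expect_equal(back$std, res$std)
  expect_equal(unname(back$confusion), unname(res$confusion))
  expect_identical(back$protocol, res$protocol)
  # count conservation survives the round trip
  expect_equal(sum(back$confusion), 120)
  # confusion CSV carries labels
  pc <- tempfile(fileext = ".csv")
  write_confusion_csv(res, pc)
  m <- utils::read.csv(pc, row.names = 1, check.names = FALSE)
  expect_equal(colnames(m), c("T-1", "T1"))
  expect_equal(sum(m), 120)
})

test_that("write_metrics refuses an unwritable path", {
  res <- cv_result("binary_10fold", 100, "fold01", matrix(c(1, 0, 0, 1), 2),
                   c("a", "b"))
  expect_error(write_metrics(res, file.path(tempdir(), "no", "such", "dir",
                                            "x.json")))
})

test_that("xlsx stage tables are read when readxl is installed", {
  skip_if_not_installed("readxl")
  # readxl cannot write xlsx; exercise the extension dispatch error path
  # plus CSV equivalence through a real xlsx only if writable support
  # exists. Here: only the unreadable-file error path.
  expect_error(read_stage_table("missing.xlsx"), "no such file")
})
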