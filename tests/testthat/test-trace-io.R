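test_that("a minimal trace file parses to a validated trace", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,o2_uM", "0,180", "2,179.8", "4,179.6"), f)
  tr <- readTrace(f)
  expect_s4_class(tr, "OxygraphTrace")
  expect_length(tr, 3)
  expect_equal(diff(range(timeS(tr))), 4)
  expect_equal(o2Conc(tr), c(180, 179.8, 179.6))
})

test_that("write-read round trip is the identity on canonical files", {
  tr <- linearTrace(run_id = "rt", norm_basis = "cell_count_per_mL",
                    norm_value = 1e6,
                    events = data.frame(time_s = 100, label = "1PM"),
                    open_intervals = matrix(c(200, 260), ncol = 2))
  f1 <- withr::local_tempfile(fileext = ".csv")
  writeTrace(tr, f1)
  tr2 <- readTrace(f1)
  expect_equal(timeS(tr2), timeS(tr))
  expect_equal(o2Conc(tr2), o2Conc(tr))
  expect_equal(events(tr2), events(tr))
  expect_equal(unname(openIntervals(tr2)), unname(openIntervals(tr)))
  expect_equal(normalization(tr2), normalization(tr))
  # byte-identical re-write
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeTrace(tr2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("parse and validation errors name the offending input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,o2_uM", "0,180", "2,179.8", "2,179.6"), f)
  expect_error(readTrace(f), "row 3")

  writeLines(c("seconds,o2_uM", "0,180"), f)
  expect_error(readTrace(f), "time_s.*missing")

  writeLines(c("time_s,o2_uM,time_s", "0,180,0"), f)
  expect_error(readTrace(f), "duplicate column")

  writeLines(c("time_s,o2_uM", "0,180", "x,179"), f)
  expect_error(readTrace(f), "non-numeric time")
})

test_that("rows inside declared open intervals are retained, not dropped", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# open_interval: 2,6", "time_s,o2_uM",
               "0,180", "2,181", "4,183", "6,180", "8,179.8"), f)
  tr <- readTrace(f)
  expect_length(tr, 5)
  expect_equal(nrow(openIntervals(tr)), 1)
})

test_that("marks are linked to protocol steps and sorted", {
  p <- builtinProtocol("RP1")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,t_start_s,t_end_s,role",
               "2D,500,600,state",
               "1PM,200,300,state",
               "3U2.5,700,760,state"), f)
  mk <- readMarks(f, p)
  expect_equal(mk$label, c("1PM", "2D", "3U2.5"))
  expect_equal(mk$step, c("1PM", "2D", "3U"))
})

test_that("mark files violating the protocol are rejected", {
  p <- builtinProtocol("RP1")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,t_start_s,t_end_s,role", "9Zz,0,10,state"), f)
  expect_error(readMarks(f, p), "unknown mark label '9Zz'.*1PM")

  # protocol order violated in time: ADP before substrate
  writeLines(c("label,t_start_s,t_end_s,role",
               "2D,100,200,state", "1PM,300,400,state"), f)
  expect_error(readMarks(f, p), "order")

  writeLines(c("label,t_start_s,t_end_s,role",
               "1PM,100,250,state", "2D,200,300,state"), f)
  expect_error(readMarks(f, p), "overlap")

  writeLines("label,t_start_s,t_end_s,role", f)
  expect_warning(mk <- readMarks(f, p), "empty")
  expect_equal(nrow(mk), 0)
})

test_that("state tables round-trip through TSV + sidecar at full precision", {
  tab <- rp1TableFixture()
  tab@rows$rate_total <- tab@rows$rate_total + pi * 1e-8
  tab <- baselineCorrectRox(tab)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeStateTable(tab, f)
  expect_true(file.exists(paste0(f, ".json")))
  tab2 <- readStateTable(f)
  expect_identical(tab2@rows$rate_total, tab@rows$rate_total)
  expect_identical(tab2@rows$rate_corrected, tab@rows$rate_corrected)
  expect_equal(protocolId(tab2), "RP1")
  expect_true(isRoxCorrected(tab2))
})

test_that("writing an uncorrected table warns that rates are totals", {
  tab <- tableFixture(c("2D" = 100), "P")
  f <- withr::local_tempfile(fileext = ".tsv")
  expect_warning(writeStateTable(tab, f), "totals")
  expect_true(file.exists(f))
})
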