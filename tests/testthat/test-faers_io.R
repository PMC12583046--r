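# Quarterly-file parsing, deduplication rules, age conversion,
# reporter classification and cohort selection.

test_that("read_quarter round-trips a fixture quarter and flags corruption", {
  q <- fixture_quarter(
    demo = data.frame(primaryid = paste0(101:105, "1"), caseid = 101:105,
                      age = 70, age_cod = "YR", sex = "F",
                      fda_dt = "20240105"),
    drug = data.frame(primaryid = "1011", caseid = "101", drug_seq = "1",
                      role_cod = "PS", drugname = "PROZAC"),
    reac = data.frame(primaryid = "1011", caseid = "101",
                      pt = "Serotonin syndrome"))
  dir <- withr::local_tempdir()
  write_faers_ascii(q, dir)
  back <- read_quarter(dir, "2024Q1")
  expect_equal(nrow(back$demo), 5L)
  for (tab in c("demo", "drug", "reac", "outc", "ther"))
    expect_equal(as.data.frame(back[[tab]]), as.data.frame(q[[tab]]),
                 ignore_attr = TRUE)

  # header-only files parse to an empty quarter
  empty <- fixture_quarter()
  dir2 <- withr::local_tempdir()
  write_faers_ascii(empty, dir2)
  back2 <- read_quarter(dir2, "2024Q1")
  expect_equal(nrow(back2$demo), 0L)
  expect_equal(nrow(back2$drug), 0L)

  # one malformed DRUG row (missing delimiter) is skipped and counted
  drug_file <- file.path(dir, "DRUG24Q1.txt")
  lines <- readLines(drug_file)
  many <- c(lines, replicate(200, lines[2]))  # keep skip fraction < 1%
  many[2] <- gsub("\\$PS\\$", "PS$", many[2])
  writeLines(many, drug_file)
  back3 <- read_quarter(dir, "2024Q1")
  expect_equal(unname(back3$skipped["drug"]), 1L)
  expect_equal(nrow(back3$drug), 200L)

  # missing mandatory file is fatal and names the file
  file.remove(file.path(dir, "REAC24Q1.txt"))
  expect_error(read_quarter(dir, "2024Q1"), "REAC")
})

test_that("read_quarter fails when more than 1% of rows are malformed", {
  dir <- withr::local_tempdir()
  q <- fixture_quarter(demo = data.frame(primaryid = "11", caseid = "1"))
  write_faers_ascii(q, dir)
  writeLines(c("primaryid$caseid$drug_seq", "11$1", "11$1$1"),
             file.path(dir, "DRUG24Q1.txt"))
  expect_error(read_quarter(dir, "2024Q1"), "malformed")
})

test_that("deduplication keeps the latest receipt, breaks ties by id, and is idempotent", {
  # case 100: two receipt dates -> later one kept
  q1 <- fixture_quarter(quarter = "2023Q1",
    demo = data.frame(primaryid = "1001", caseid = "100", age = "70",
                      age_cod = "YR", fda_dt = "20230101"),
    reac = data.frame(primaryid = "1001", caseid = "100", pt = "Nausea"))
  q2 <- fixture_quarter(quarter = "2023Q3",
    demo = data.frame(primaryid = "1002", caseid = "100", age = "70",
                      age_cod = "YR", fda_dt = "20230601"),
    reac = data.frame(primaryid = "1002", caseid = "100", pt = "Rash"))
  cases <- deduplicate_cases(list(q1, q2))
  expect_equal(cases$demo$report_id, "1002")
  expect_equal(cases$reactions$pt, "Rash")  # joins retained version only

  # equal dates -> largest numeric report id wins
  q3 <- fixture_quarter(
    demo = data.frame(primaryid = c("1001", "1002"), caseid = "100",
                      fda_dt = "20230601"))
  cases3 <- deduplicate_cases(list(q3))
  expect_equal(cases3$demo$report_id, "1002")

  # 10 raw versions of 6 cases across 3 quarters -> 6 cases
  mk <- function(quarter, primaryid, caseid, fda)
    fixture_quarter(quarter = quarter,
                    demo = data.frame(primaryid = primaryid, caseid = caseid,
                                      fda_dt = fda))
  qa <- mk("2023Q1", c("11", "21", "31", "41"), c("1", "2", "3", "4"),
           "20230110")
  qb <- mk("2023Q2", c("12", "22", "51"), c("1", "2", "5"), "20230420")
  qc <- mk("2023Q3", c("13", "61", "62"), c("1", "6", "6"), "20230805")
  all6 <- deduplicate_cases(list(qa, qb, qc))
  expect_equal(nrow(all6$demo), 6L)
  expect_setequal(all6$demo$case_id, as.character(1:6))
  expect_true("13" %in% all6$demo$report_id)   # latest version of case 1
  expect_true("62" %in% all6$demo$report_id)   # tie broken upward

  # idempotence: re-deduplicating only the retained versions is a no-op
  kept <- fixture_quarter(quarter = "2023Q3",
    demo = data.frame(primaryid = all6$demo$report_id,
                      caseid = all6$demo$case_id,
                      fda_dt = format(all6$demo$receipt_date, "%Y%m%d")))
  again <- deduplicate_cases(list(kept))
  expect_setequal(again$demo$report_id, all6$demo$report_id)
  expect_equal(nrow(deduplicate_cases(list())$demo), 0L)
})

test_that("partial receipt dates fall back to the quarter end", {
  q <- fixture_quarter(quarter = "2023Q2",
    demo = data.frame(primaryid = "11", caseid = "1", fda_dt = "202305"))
  cases <- deduplicate_cases(list(q))
  expect_equal(cases$demo$receipt_date, as.Date("2023-06-30"))
})

test_that("age conversion follows the unit table and rejects absurd values", {
  expect_equal(parse_age_to_years(70, "YR"), 70)
  expect_equal(parse_age_to_years(7, "DEC"), 70)
  expect_equal(parse_age_to_years(26298, "DY"), 72)
  expect_equal(parse_age_to_years(840, "MON"), 70)
  expect_equal(parse_age_to_years(70, ""), 70)      # missing unit = years
  expect_equal(parse_age_to_years(70, "XX"), 70)    # unknown unit = years
  expect_true(is.na(parse_age_to_years(-5, "YR")))
  expect_true(is.na(parse_age_to_years(130, "YR")))
  expect_true(is.na(parse_age_to_years(NA, "YR")))

  # monotone in value for a fixed unit
  for (u in c("YR", "DEC", "MON", "WK", "DY", "HR")) {
    v <- sort(runif(20, 1, 100))
    y <- parse_age_to_years(v, u)
    ok <- !is.na(y)
    expect_true(all(diff(y[ok]) >= 0))
  }
})

test_that("reporter occupation codes classify as stated", {
  expect_equal(classify_reporter(c("MD", "PH", "HP", "OT")),
               rep("healthcare", 4))
  expect_equal(classify_reporter(c("CN", "LW")), rep("non-healthcare", 2))
  expect_true(all(is.na(classify_reporter(c("", "ZZ", NA)))))
})

test_that("cohort selection partitions the elderly background", {
  demo <- data.frame(report_id = as.character(1:4),
                     age_years = c(60, 65, 80, NA),
                     stringsAsFactors = FALSE)
  reac <- data.frame(report_id = "3", pt = "Serotonin syndrome",
                     stringsAsFactors = FALSE)
  cases <- fixture_cases(demo, reactions = reac)
  sel <- select_cohort(cases)
  expect_equal(nrow(sel$background$demo), 2L)
  expect_equal(nrow(sel$cohort$demo), 1L)
  expect_equal(sel$cohort$demo$report_id, "3")
  expect_true(all(sel$cohort$demo$report_id %in% sel$background$demo$report_id))
  expect_true(all(sel$background$demo$age_years >= 65))

  # boundary age 65 with the PT is in both; matching is case-insensitive
  cases65 <- fixture_cases(
    data.frame(report_id = "9", age_years = 65, stringsAsFactors = FALSE),
    reactions = data.frame(report_id = "9", pt = " SEROTONIN SYNDROME ",
                           stringsAsFactors = FALSE))
  sel65 <- select_cohort(cases65)
  expect_equal(nrow(sel65$cohort$demo), 1L)

  # absent PT leaves the background unchanged, empty cohort
  sel_none <- select_cohort(cases, target_pt = "Absent term")
  expect_equal(nrow(sel_none$cohort$demo), 0L)
  expect_equal(nrow(sel_none$background$demo), 2L)

  # no elderly reports is an error
  young <- fixture_cases(data.frame(report_id = "1", age_years = 40,
                                    stringsAsFactors = FALSE))
  expect_error(select_cohort(young), "no elderly")
})
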