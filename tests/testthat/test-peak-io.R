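test_that("formula parsing yields atom counts and rejects garbage", {
  expect_equal(parse_formula("C16H31O2"), c(C = 16L, H = 31L, O = 2L))
  expect_equal(parse_formula("CH4"), c(C = 1L, H = 4L))
  expect_equal(count_element("C16H31O2", "H"), 31L)
  expect_equal(count_element("C16H31O2", "N"), 0L)
  expect_error(parse_formula("16CH"), "cannot parse")
  expect_error(parse_formula("C0H4"), "non-positive")
  expect_error(parse_formula(""), "non-empty")
})

test_that("a long CSV reads to one validated record per row", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(make_c2_peaks(), path)
  rec <- read_peak_table(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$isotopologue_index, 0:2)
  expect_equal(rec$intensity, c(900, 90, 10))
})

test_that("schema and invariant violations are reported with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- make_c2_peaks()
  write.csv(bad[setdiff(names(bad), "formula")], path, row.names = FALSE)
  expect_error(read_peak_table(path), "missing column.*formula")

  over <- data.frame(sample_id = "s1", metabolite = "palmitate",
                     formula = "C16H31O2", tracer_element = "C",
                     isotopologue_index = 17L, intensity = 10)
  expect_error(validate_peak_records(over), "exceeds the 16 C atoms")

  neg <- make_c2_peaks(intensities = c(900, -1, 10))
  expect_error(validate_peak_records(neg), "negative or missing intensity")

  notrace <- make_c2_peaks()
  notrace$tracer_element <- "S"
  expect_error(validate_peak_records(notrace), "absent from formula")
})

test_that("write-then-read round-trips the generator's peak table", {
  cohort <- simulate_dnl_cohort(synthetic_design(n_per_group = 2, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(cohort$peaks, path)
  back <- read_peak_table(path)
  expect_equal(back$sample_id, cohort$peaks$sample_id)
  expect_equal(back$isotopologue_index, cohort$peaks$isotopologue_index)
  expect_equal(back$intensity, cohort$peaks$intensity, tolerance = 1e-12)
})

test_that("assemble_mids builds zero-filled vectors of length n_atoms + 1", {
  mids <- assemble_mids(make_c2_peaks())
  expect_length(mids, 1L)
  expect_equal(mids[[1]]$intensities, c(900, 90, 10))
  expect_equal(mids[[1]]$n_atoms, 2L)

  c3 <- data.frame(sample_id = "s1", metabolite = "propionate",
                   formula = "C3H5O2", tracer_element = "C",
                   isotopologue_index = 0L, intensity = 100)
  expect_warning(m3 <- assemble_mids(c3), "3 missing isotopologue")
  expect_equal(m3[[1]]$intensities, c(100, 0, 0, 0))
})

test_that("duplicate isotopologue rows are an error naming the index", {
  dup <- rbind(make_c2_peaks(), make_c2_peaks()[2, ])
  expect_error(assemble_mids(dup), "duplicate isotopologue\\(s\\) 1")
})

test_that("assembly conserves total intensity across generated tables", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    intens <- stats::runif(n + 1, 0, 1000)
    rec <- data.frame(sample_id = "s", metabolite = "m",
                      formula = paste0("C", n, "H4"), tracer_element = "C",
                      isotopologue_index = 0:n, intensity = intens)
    m <- assemble_mids(rec)[[1]]
    expect_length(m$intensities, n + 1)
    expect_equal(sum(m$intensities), sum(intens))
  }
})
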