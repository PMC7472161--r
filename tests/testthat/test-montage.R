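test_that("default montage has the expected symmetric structure", {
  m <- default_montage()
  expect_length(m$all_channels, 32)
  expect_equal(m$midline, c("Fz", "Cz", "Pz", "Oz"))
  expect_equal(nrow(m$pairs), 14)
  expect_false(anyDuplicated(m$all_channels) > 0)
})

test_that("channel labels are matched case-insensitively and trimmed", {
  m <- default_montage()
  cs <- channel_set(c(" f7 ", "F8", "fz"), m, check_symmetry = FALSE)
  expect_true(all(c("F7", "F8", "Fz") %in% as.character(cs)))
  expect_error(channel_set("XX", m), "not in montage")
})

test_that("symmetry predicate accepts pairs and midline, rejects orphans", {
  m <- default_montage()
  expect_true(is_symmetric_set(c("F7", "F8"), m))
  expect_true(is_symmetric_set(c("Fz", "Pz"), m))
  expect_true(is_symmetric_set(c("F7", "F8", "Cz", "Oz"), m))
  expect_false(is_symmetric_set(c("F7", "Pz"), m))
  expect_error(channel_set(c("F7", "Pz"), m), "F7")
})

test_that("interhemispheric pairs are exactly the fully contained pairs", {
  m <- default_montage()
  expect_equal(nrow(interhemispheric_pairs(channel_set(c("F7", "F8"), m),
                                           m)), 1)
  expect_equal(nrow(interhemispheric_pairs(channel_set(c("Fz", "Pz"), m),
                                           m)), 0)
  expect_equal(nrow(interhemispheric_pairs(
    channel_set(m$all_channels, m), m)), 14)
  expect_error(interhemispheric_pairs(c("F7", "Cz"), m), "F7")
})

test_that("enumeration matches the brute-force subset oracle", {
  m <- default_montage()
  for (k in c(2, 4)) {
    oracle <- sort(brute_force_symmetric(m, k))
    enum <- sort(vapply(enumerate_symmetric_configs(m, k),
                        function(cs) paste(sort(as.character(cs)),
                                           collapse = "+"),
                        character(1)))
    expect_equal(enum, oracle)
  }
  # reduced montage keeps larger k affordable for the brute force
  mr <- montage(midline = c("Fz", "Cz", "Pz"),
                pairs = list(c("F7", "F8"), c("F3", "F4"), c("C3", "C4"),
                             c("P3", "P4"), c("O1", "O2")))
  for (k in c(2, 4, 6, 8)) {
    oracle <- sort(brute_force_symmetric(mr, k))
    enum <- sort(vapply(enumerate_symmetric_configs(mr, k),
                        function(cs) paste(sort(as.character(cs)),
                                           collapse = "+"),
                        character(1)))
    expect_equal(enum, oracle)
  }
})

test_that("enumeration counts follow the pair/midline closed form", {
  m <- default_montage()
  closed_form <- function(k) {
    sum(vapply(0:(k %/% 2), function(p) {
      mm <- k - 2 * p
      if (mm > 4 || p > 14) return(0)
      choose(14, p) * choose(4, mm)
    }, numeric(1)))
  }
  for (k in c(2, 4, 6, 8)) {
    expect_length(enumerate_symmetric_configs(m, k), closed_form(k))
  }
  expect_length(enumerate_symmetric_configs(m, 2), 20)
  expect_length(enumerate_symmetric_configs(m, 8), 3276)
})

test_that("enumeration order is deterministic with pairs first", {
  m <- default_montage()
  cfgs <- enumerate_symmetric_configs(m, 2)
  expect_equal(as.character(cfgs[[1]]), c("Fp1", "Fp2"))
  expect_equal(as.character(cfgs[[15]]), c("Fz", "Cz"))
  expect_error(enumerate_symmetric_configs(m, 3), "even")
  expect_error(enumerate_symmetric_configs(m, 40), "exceeds")
})

test_that("feature counting reproduces the battery identities", {
  m <- default_montage()
  expect_equal(count_features(channel_set(m$all_channels, m)), 632)
  expect_equal(count_features(
    channel_set(c("CP1", "CP2", "O1", "O2", "F7", "F8"), m)), 162)
  expect_equal(count_features(channel_set(c("F7", "F8"), m)), 86)
})

test_that("feature count grows with channels; CSP part is constant", {
  m <- default_montage()
  cfgs <- list(channel_set(c("Fz", "Cz"), m),
               channel_set(c("F7", "F8", "Fz", "Cz"), m),
               channel_set(c("F7", "F8", "C3", "C4", "Fz", "Cz"), m))
  counts <- vapply(cfgs, count_features, numeric(1))
  expect_true(all(diff(counts) > 0))
  no_csp <- feature_count_rule(n_csp_per_class = 1, n_classes = 1)
  delta <- vapply(cfgs, count_features, numeric(1), rule = no_csp) -
    counts
  expect_true(all(delta == delta[1]))   # only the CSP block differs
})

test_that("custom montage files round-trip through the YAML reader", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("midline: [Cz]",
               "pairs:", "  - [C3, C4]", "  - [O1, O2]"), path)
  m <- read_montage(path)
  expect_equal(m$all_channels, c("C3", "C4", "O1", "O2", "Cz"))
  expect_length(enumerate_symmetric_configs(m, 2), 2)
  expect_error(montage("Cz", list(c("C3", "C3"))), "duplicated")
})
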