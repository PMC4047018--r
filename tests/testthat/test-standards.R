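# Interval partitions, boundary rule, side mapping, classification.

test_that("specimen means feed the per-attribute dataset", {
  tab <- measurement_table(
    taxon = c("a", "a", "b", "c"),
    attribute = rep("MA1", 4),
    specimen = c("s1", "s2", "s1", "s1"),
    value = c(0.2, 0.4, 16, 7))
  v <- build_attribute_dataset(tab, "MA1")
  expect_equal(v[["a"]], 0.3)
  expect_equal(v[["b"]], 16)
  expect_error(build_attribute_dataset(tab, "MA9"), "no observations")
  # focal exclusion
  v2 <- build_attribute_dataset(tab, "MA1", exclude = "a")
  expect_false("a" %in% names(v2))
  # brute-force mean oracle on a random table
  set.seed(5)
  tax <- sprintf("t%02d", 1:30)
  rows <- do.call(rbind, lapply(tax, function(t) {
    ns <- sample(1:3, 1)
    data.frame(taxon = t, attribute = "A", specimen = paste0("s", 1:ns),
               value = runif(ns))
  }))
  tabr <- measurement_table(rows$taxon, rows$attribute, rows$specimen,
                            rows$value)
  vr <- build_attribute_dataset(tabr, "A")
  for (t in tax) {
    vals <- rows$value[rows$taxon == t]
    expect_equal(vr[[t]], sum(vals) / length(vals))
  }
})

test_that("MAP partition yields ordered, labeled component intervals", {
  x <- c(a = 0, b = 0.1, c = 5, d = 5.1)
  m <- fit_gmm1d(x, G = 2)
  p <- partition_to_intervals(m, x, attribute = "MA")
  expect_equal(p$components$component, c("C01", "C02"))
  expect_equal(p$components$lower, c(0, 5))
  expect_equal(p$components$upper, c(0.1, 5.1))
  # MAP oracle: assignment by direct density comparison
  dens <- sapply(1:2, function(g)
    m$weights[g] * dnorm(x, m$means[g], sqrt(m$variances[g])))
  ord <- order(m$means)
  expect_equal(p$assignments$component,
               c("C01", "C02")[match(max.col(dens), ord)])
  # single component: one interval spanning the data
  m1 <- fit_gmm1d(x, G = 1)
  p1 <- partition_to_intervals(m1, x)
  expect_equal(nrow(p1$components), 1L)
  expect_equal(p1$components$lower, 0)
  expect_equal(p1$components$upper, 5.1)
  # ordering invariant on random fits
  set.seed(9)
  for (i in 1:10) {
    xx <- rnorm(40, sample(0:5, 1), runif(1, 0.5, 2))
    pp <- partition_to_intervals(fit_gmm1d(xx, sample(1:3, 1)), xx)
    expect_true(!is.unsorted(pp$components$lower))
  }
})

test_that("the boundary is the midpoint of the adjacent extremes", {
  expect_identical(boundary_between(c(0.38, 0.58), c(0.60, 0.76)), 0.59)
  expect_equal(boundary_between(c(0.10, 0.18), c(0.21, 0.60)), 0.195)
  # limit: as the gap closes the boundary tends to the shared endpoint
  expect_equal(boundary_between(c(0, 1), c(1 + 1e-12, 2)), 1,
               tolerance = 1e-9)
  expect_error(boundary_between(c(0, 0.5), c(0.4, 1)), "overlap")
})

test_that("components map to sides with merging, polarity and alignment", {
  mk_part <- function(values, comps, taxa) {
    structure(list(
      attribute = "MA",
      assignments = data.frame(taxon = taxa, value = values,
                               component = comps),
      components = do.call(rbind, lapply(sort(unique(comps)), function(cc)
        data.frame(component = cc, mean = mean(values[comps == cc]),
                   lower = min(values[comps == cc]),
                   upper = max(values[comps == cc]),
                   n = sum(comps == cc))))),
      class = "component_partition")
  }
  taxa <- sprintf("t%02d", 1:12)
  labels <- setNames(rep(c("basal_hadrosauroid", "hadrosaurine"), each = 6),
                     taxa)
  # three components: C01 basal, C02 + C03 hadrosaurid -> merged interval
  vals <- c(1, 2, 3, 4, 5, 6, 11, 12, 13, 21, 22, 23)
  comps <- rep(c("C01", "C02", "C03"), c(6, 3, 3))
  std <- components_to_sides(mk_part(vals, comps, taxa), labels)
  expect_true(std$diagnostic)
  expect_equal(std$polarity, "basal")
  expect_equal(unname(std$basal[1, ]), c(1, 6))
  expect_equal(nrow(std$hadrosaurid), 1L)       # merged C02 + C03
  expect_equal(unname(std$hadrosaurid[1, ]), c(11, 23))
  expect_equal(std$boundary, (6 + 11) / 2)
  expect_equal(std$alignment, 1)
  # swapped labels exchange sides but preserve alignment
  swapped <- setNames(rep(c("lambeosaurine", "basal_iguanodontian"),
                          each = 6), taxa)
  std2 <- components_to_sides(mk_part(vals, comps, taxa), swapped)
  expect_equal(std2$alignment, 1)
  expect_equal(std2$polarity, "hadrosaurid")
  expect_equal(unname(std2$hadrosaurid[1, ]), c(1, 6))
  # one mislabeled taxon in twenty
  taxa20 <- sprintf("u%02d", 1:20)
  lab20 <- setNames(rep(c("basal_hadrosauroid", "hadrosaurine"), each = 10),
                    taxa20)
  lab20[1] <- "hadrosaurine"
  v20 <- c(1:10, 101:110)
  std3 <- components_to_sides(
    mk_part(v20, rep(c("C01", "C02"), each = 10), taxa20), lab20)
  expect_equal(std3$alignment, 0.95)
  # interleaved arrangement is flagged non-diagnostic
  comps_bad <- rep(c("C01", "C02", "C03"), each = 4)
  lab_bad <- setNames(rep(c("basal_hadrosauroid", "hadrosaurine",
                            "basal_hadrosauroid"), each = 4), taxa)
  expect_warning(
    stdb <- components_to_sides(mk_part(vals, comps_bad, taxa), lab_bad),
    "non-contiguous")
  expect_false(stdb$diagnostic)
})

test_that("diagnostic attribute selection applies all three filters", {
  good <- attribute_standard("MA2", c(0, 1), c(2, 3), alignment = 1)
  weak <- attribute_standard("MA3", c(0, 1), c(2, 3), alignment = 0.55)
  single <- attribute_standard("MA1", c(0, 3), NULL, alignment = 1,
                               diagnostic = FALSE)
  expect_equal(select_diagnostic_attributes(list(good, weak, single), 0.9),
               "MA2")
  expect_equal(select_diagnostic_attributes(list(weak), 0.9), character(0))
  expect_equal(select_diagnostic_attributes(list(good, weak), 0.5),
               c("MA2", "MA3"))
})

test_that("values classify by interval membership then boundary", {
  fx <- published_standards()
  expect_equal(classify_value(0.37, fx$standards$MA1), "hadrosaurid")
  expect_equal(classify_value(16, fx$standards$MA3), "basal")
  # a value exactly on the boundary goes to the low-value side
  s <- attribute_standard("X", c(0, 1), c(3, 4))  # boundary 2, low = basal
  expect_equal(classify_value(2, s), "basal")
  expect_equal(classify_value(2 + 1e-12, s), "hadrosaurid")
  # monotone: once low-side, everything smaller is low-side
  for (std in fx$standards) {
    low <- std$polarity
    vgrid <- seq(min(std$basal[, 1], std$hadrosaurid[, 1]) - 1,
                 max(std$basal[, 2], std$hadrosaurid[, 2]) + 1,
                 length.out = 60)
    sides <- vapply(vgrid, classify_value, character(1), standard = std)
    firsthigh <- match(setdiff(c("basal", "hadrosaurid"), low), sides)
    if (!is.na(firsthigh))
      expect_true(all(sides[seq_len(firsthigh - 1)] == low))
  }
})

test_that("mosaic summary counts sides and flags straddling", {
  ms <- mosaic_summary(c(A = "basal", B = "hadrosaurid", C = "basal"))
  expect_equal(unname(ms$counts), c(2, 1))
  expect_true(ms$straddle)
  expect_equal(sum(ms$counts), 3)
  one <- mosaic_summary(c(A = "basal", B = "basal"))
  expect_false(one$straddle)
  expect_error(mosaic_summary(character(0)), "no classified")
})

test_that("standards round-trip through their delimited form", {
  fx <- published_standards()
  f <- tempfile(fileext = ".tsv")
  write_standards(fx$standards, f)
  back <- read_standards(f)
  expect_setequal(names(back), names(fx$standards))
  for (a in names(back)) {
    expect_equal(back[[a]]$basal, fx$standards[[a]]$basal,
                 ignore_attr = TRUE)
    expect_equal(back[[a]]$boundary, fx$standards[[a]]$boundary)
    expect_equal(back[[a]]$polarity, fx$standards[[a]]$polarity)
  }
})
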