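test_that("the default rule table reads the patterns as expected", {
  rt <- default_rule_table()
  lookup <- function(cirr, wash, pat) {
    hit <- rt$cirrhotic == cirr & rt$washout == wash & rt$pattern == pat
    if (any(hit)) rt$type[hit][1] else "indeterminate"
  }
  expect_equal(lookup(TRUE, TRUE, "hyper-enhancement"), "HCC")
  expect_equal(lookup(FALSE, TRUE, "hyper-enhancement"), "HCC")
  expect_equal(lookup(FALSE, TRUE, "rim enhancement"), "metastasis")
  expect_equal(lookup(TRUE, TRUE, "rim-like with central hypo-enhancement"),
               "cholangiocarcinoma")
  expect_equal(lookup(FALSE, FALSE, "peripheral nodular enhancement"),
               "haemangioma")
  expect_equal(lookup(FALSE, FALSE, "centrifugal hyper-enhancement"), "FNH")
  expect_equal(lookup(FALSE, FALSE, "peripheral enhancement with septa"),
               "abscess")
  expect_equal(lookup(TRUE, FALSE, "iso-enhancement"), "regenerative nodule")
  expect_equal(lookup(FALSE, FALSE, "iso-enhancement"),
               "focal fatty alteration")
  # only the seven canonical pattern labels appear
  expect_true(all(rt$pattern %in% enhancement_patterns()$pattern))
})

test_that("the three-step classification follows the tree", {
  r <- bdtc_classify(TRUE, -25, "hyper-enhancement")
  expect_true(r$predicted_malignant)
  expect_equal(r$predicted_type, "HCC")
  expect_equal(r$path, c("fibrosis:F4", "tic:washout",
                         "pattern:hyper-enhancement"))

  r <- bdtc_classify(FALSE, -25, "rim enhancement")
  expect_true(r$predicted_malignant)
  expect_equal(r$predicted_type, "metastasis")

  r <- bdtc_classify(FALSE, -5, "peripheral nodular enhancement")
  expect_false(r$predicted_malignant)
  expect_equal(r$predicted_type, "haemangioma")

  # no pattern: malignancy still called, type indeterminate, path length 2
  r <- bdtc_classify(FALSE, -5, NA)
  expect_false(r$predicted_malignant)
  expect_equal(r$predicted_type, "indeterminate")
  expect_length(r$path, 2)

  # key absent from the table
  r <- bdtc_classify(TRUE, -25, "iso-enhancement")
  expect_true(r$predicted_malignant)
  expect_equal(r$predicted_type, "indeterminate")
  expect_length(r$path, 3)

  expect_error(bdtc_classify(TRUE, -25, "mosaic"), "invalid")
})

test_that("classification is deterministic and washout-consistent", {
  set.seed(42)
  for (i in 1:25) {
    cirr <- runif(1) < 0.5
    area <- runif(1, -60, 20)
    pat <- sample(c(enhancement_patterns()$pattern, NA), 1)
    r1 <- bdtc_classify(cirr, area, pat)
    r2 <- bdtc_classify(cirr, area, pat)
    expect_identical(r1, r2)
    # malignancy call is the washout call
    expect_identical(r1$predicted_malignant, r1$washout)
    expect_identical(r1$washout, washout_flag(area))
    expect_true(length(r1$path) == ifelse(is.na(pat), 2, 3))
    expect_match(r1$path[1], "^fibrosis:")
    expect_match(r1$path[2], "^tic:")
  }
})

test_that("the boundary AREA value counts as washout", {
  expect_true(washout_flag(-19.3))
  expect_true(washout_flag(-25.08))
  expect_false(washout_flag(-7.08))
  expect_false(washout_flag(-19.2999))
})

test_that("the screening OR rule is high-sensitivity by construction", {
  expect_true(mpus_malignancy(TRUE, -5))    # cirrhosis arm alone
  expect_true(mpus_malignancy(FALSE, -25))  # washout arm alone
  expect_false(mpus_malignancy(FALSE, -5))  # neither
  # OR rule can only raise sensitivity over the washout rule alone
  areas <- runif(50, -40, 0)
  cirr <- rep(c(TRUE, FALSE), 25)
  expect_true(all(mpus_malignancy(cirr, areas) >= washout_flag(areas)))
})

test_that("a noise-free separable cohort is classified perfectly", {
  co <- sample_cohort(separable_config(), seed = 21)
  results <- classify_cohort(co)
  report <- evaluate_results(results, co$lesions)
  expect_equal(report$confusion$accuracy, 1)

  # lesion types with an unambiguous pattern are all typed correctly
  merged <- merge(results, co$lesions, by = "lesion_id")
  unique_types <- c("HCC", "metastasis", "cholangiocarcinoma",
                    "haemangioma", "abscess")
  for (ty in unique_types) {
    sel <- merged$true_type == ty
    expect_true(all(merged$predicted_type[sel] == ty),
                label = paste("all", ty, "typed correctly"))
  }
  # cirrhotic regenerative nodules read as regenerative nodules
  sel <- merged$true_type == "regenerative nodule" & merged$cirrhotic
  expect_true(all(merged$predicted_type[sel] == "regenerative nodule"))
})

test_that("an alternative rule table is honoured as data", {
  rt <- default_rule_table()
  rt$type[!rt$cirrhotic & rt$washout &
            rt$pattern == "hyper-enhancement"] <- "adenoma"
  r <- bdtc_classify(FALSE, -25, "hyper-enhancement", rule_table = rt)
  expect_equal(r$predicted_type, "adenoma")
  r <- bdtc_classify(TRUE, -25, "hyper-enhancement", rule_table = rt)
  expect_equal(r$predicted_type, "HCC")
})
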