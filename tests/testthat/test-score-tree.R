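test_that("T1 reference tree reproduces its defining leaves", {
  t1 <- ks_tree_t1()
  f <- data.frame(
    root_sign = c("no", "yes", "no"),
    curve_type = c("persistent", "washout", "washout"),
    margin = c("circumscribed", "not_circumscribed", "circumscribed"),
    internal_enhancement = c("homogeneous", "homogeneous", "inhomogeneous"),
    edema = c("no", "yes", "no"))
  expect_identical(assign_kaiser_score(f, t1), c(1L, 11L, 7L))
  # root sign + edema dominates regardless of the other features
  combos <- feature_combinations()
  re <- combos[combos$root_sign == "yes" & combos$edema == "yes", ]
  expect_true(all(assign_kaiser_score(re, t1) == 11L))
})

test_that("every one of the 48 combinations matches the traversal oracle", {
  t1 <- ks_tree_t1()
  combos <- feature_combinations()
  got <- assign_kaiser_score(combos, t1)
  want <- mapply(t1_oracle, combos$root_sign, combos$curve_type,
                 combos$margin, combos$internal_enhancement, combos$edema)
  expect_identical(got, as.integer(want))
  expect_setequal(unique(got), 1:11)  # all scores reachable in T1
})

test_that("validation reports uncovered, conflicting and out-of-range paths", {
  t1 <- ks_tree_t1()
  expect_true(validate_tree(t1)$valid)

  # drop one path -> its (unique) combination set becomes uncovered
  broken <- score_tree(t1$paths[-1L, ], name = "broken")
  v <- validate_tree(broken)
  expect_false(v$valid)
  expect_gt(nrow(v$uncovered), 0L)
  expect_true(all(v$uncovered$root_sign == "yes" & v$uncovered$edema == "yes"))
  expect_error(assign_kaiser_score(feature_combinations()[1L, ], broken),
               "not total")

  # out-of-range leaf
  p12 <- t1$paths; p12$score[1L] <- 12L
  v12 <- validate_tree(score_tree(p12))
  expect_false(v12$valid)
  expect_equal(nrow(v12$out_of_range), 1L)

  # conflicting overlap: a wildcard path disagreeing with an existing leaf
  pc <- rbind(t1$paths,
              data.frame(root_sign = "yes", curve_type = "*", margin = "*",
                         internal_enhancement = "*", edema = "yes",
                         score = 9L))
  vc <- validate_tree(score_tree(pc))
  expect_false(vc$valid)
  expect_gt(nrow(vc$conflicts), 0L)
})

test_that("the synthetic Kaiser tree honours the published worked examples", {
  tk <- ks_tree_kaiser_synthetic()
  expect_true(validate_tree(tk)$valid)
  score1 <- function(...) assign_kaiser_score(data.frame(...), tk)
  # irregular margin, persistent enhancement -> 3
  expect_equal(score1(root_sign = "no", curve_type = "persistent",
                      margin = "irregular",
                      internal_enhancement = "homogeneous", edema = "no"), 3L)
  # irregular margin, plateau enhancement -> 5
  expect_equal(score1(root_sign = "no", curve_type = "plateau",
                      margin = "irregular",
                      internal_enhancement = "homogeneous", edema = "no"), 5L)
  # root sign without edema -> 7
  expect_equal(score1(root_sign = "yes", curve_type = "persistent",
                      margin = "circumscribed",
                      internal_enhancement = "homogeneous", edema = "no"), 7L)
  # persistent non-mass enhancement -> 6
  expect_equal(score1(root_sign = "no", curve_type = "persistent",
                      margin = "not_circumscribed",
                      internal_enhancement = "inhomogeneous", edema = "no"), 6L)
})

test_that("feature ingest is case-insensitive and maps margin synonyms", {
  t1 <- ks_tree_t1()
  f <- data.frame(root_sign = "NO", curve_type = "Washout",
                  margin = "SPICULATED", internal_enhancement = "Homogeneous",
                  edema = "No")
  fn <- normalize_features(f)
  expect_identical(fn$margin, "not_circumscribed")
  expect_identical(assign_kaiser_score(f, t1), 9L)
  expect_error(normalize_features(data.frame(
    root_sign = "maybe", curve_type = "washout", margin = "circumscribed",
    internal_enhancement = "homogeneous", edema = "no")), "root_sign")
})

test_that("trees round-trip through YAML and JSON", {
  t1 <- ks_tree_t1()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_score_tree(t1, path)
    back <- read_score_tree(path)
    expect_identical(back$paths, t1$paths)
    expect_identical(back$name, t1$name)
  }
  # the loader refuses an invalid tree file
  bad <- score_tree(t1$paths[-1L, ])
  path <- withr::local_tempfile(fileext = ".yaml")
  write_score_tree(bad, path)
  expect_error(read_score_tree(path), "not total")
})

test_that("preimage sampling round-trips through the tree", {
  t1 <- ks_tree_t1()
  set.seed(11)
  for (i in 1:200) {
    s <- sample(1:11, 1)
    f <- sample_features_for_score(s, t1, n = 5L)
    expect_true(all(assign_kaiser_score(f, t1) == s))
  }
  # unique preimages named by the T1 definition
  f11 <- sample_features_for_score(11L, t1, n = 20L)
  expect_true(all(f11$root_sign == "yes" & f11$edema == "yes"))
  f1 <- sample_features_for_score(1L, t1, n = 20L)
  expect_true(all(f1$root_sign == "no" & f1$curve_type == "persistent" &
                    f1$margin == "circumscribed"))
  # a score must be reachable
  two_leaf <- score_tree(data.frame(
    root_sign = c("yes", "no"), curve_type = "*", margin = "*",
    internal_enhancement = "*", edema = "*", score = c(8L, 1L)))
  expect_error(sample_features_for_score(5L, two_leaf), "unreachable")
})
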