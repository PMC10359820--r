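# Shared fixtures and independent oracles for the test suite.

# Independent traversal oracle for the T1 reference tree: a literal nested
# rule, written separately from the package's path-matching lookup.
t1_oracle <- function(root_sign, curve_type, margin, internal_enhancement,
                      edema) {
  if (root_sign == "yes") {
    if (edema == "yes") 11L else 8L
  } else if (curve_type == "washout") {
    if (margin == "not_circumscribed") {
      if (edema == "yes") 10L else 9L
    } else if (internal_enhancement == "inhomogeneous") 7L else 5L
  } else if (curve_type == "plateau") {
    if (margin == "not_circumscribed") 6L
    else if (internal_enhancement == "inhomogeneous") 4L else 3L
  } else {
    if (margin == "not_circumscribed") 2L else 1L
  }
}

# Brute-force pairwise AUC oracle: psi-summation over all (malignant, benign)
# pairs, independent of the rank-based implementation.
auc_brute_force <- function(scores, truth) {
  x <- scores[truth]; y <- scores[!truth]
  s <- 0
  for (xi in x) for (yj in y) {
    s <- s + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  s / (length(x) * length(y))
}

# A small fully specified cohort data frame for I/O and scoring tests.
tiny_cohort <- function() {
  data.frame(
    id = c("a1", "a2", "a3", "a4"),
    truth = c("malignant", "benign", "malignant", "benign"),
    lesion_type = c("mass", "mass", "non_mass", "non_mass"),
    root_sign = c("no", "no", "yes", "no"),
    curve_type = c("washout", "persistent", "plateau", "plateau"),
    margin = c("circumscribed", "circumscribed", "circumscribed",
               "circumscribed"),
    internal_enhancement = c("inhomogeneous", "homogeneous", "homogeneous",
                             "inhomogeneous"),
    edema = c("no", "no", "yes", "no"),
    ipsi_vessels = c(5L, 1L, 4L, 2L),
    contra_vessels = c(1L, 1L, 2L, 2L),
    avs_present = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

expect_scores_valid <- function(ks) {
  expect_true(all(ks %in% 1:11))
}
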