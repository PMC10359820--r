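# Seeded synthetic lesion cohorts with the statistical structure of a
# diagnostic breast-MRI reader study.

#' Specify a synthetic lesion cohort
#'
#' A `cohort_spec` fully parameterizes the generator: cohort size, the
#' mass/non-mass mix, class prevalence conditional on lesion type, the
#' per-class joint distribution of the two vascular signs (given as the two
#' marginals and the conjunction probability), the per-class distribution of
#' the drawn Kaiser score, the contralateral qualifying-vessel-count
#' distribution, simulated second-reader disagreement rates, an optional
#' latent-severity coupling between score and vascular signs, and the root
#' seed.
#'
#' @param n Cohort size.
#' @param p_mass Probability that a lesion is mass-type.
#' @param p_malignant_given_mass,p_malignant_given_nonmass Class prevalence
#'   conditional on lesion type.
#' @param sign_joint Named list with elements `benign` and `malignant`, each
#'   a numeric triple `c(p_v, p_a, p_both)`: the marginal probability of
#'   increased ipsilateral vascularity, of a positive adjacent vessel sign,
#'   and of both simultaneously. Each triple must satisfy the Frechet bounds
#'   `max(0, p_v + p_a - 1) <= p_both <= min(p_v, p_a)`.
#' @param ks_pmf Named list with elements `benign` and `malignant`, each a
#'   probability vector over scores 1..11 summing to 1 (tolerance 1e-12).
#' @param contralateral_pmf Probability vector over contralateral
#'   qualifying-vessel counts `0, 1, 2, ...`.
#' @param reader_flip Named numeric `c(vascularity=, avs=, features=)`:
#'   probability that the simulated second reading disagrees with the first
#'   on each assessment.
#' @param coupling Gaussian-copula correlation in \[0, 1) between the latent
#'   severity driving the drawn score and the one driving the vascular-sign
#'   category. 0 (default) gives conditional independence given truth class.
#' @param seed Root seed; all draws derive from it.
#' @return A validated object of class `cohort_spec`.
#' @seealso [default_cohort_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(n, p_mass, p_malignant_given_mass,
                        p_malignant_given_nonmass, sign_joint, ks_pmf,
                        contralateral_pmf, reader_flip, coupling = 0,
                        seed = 1L) {
  spec <- structure(
    list(n = as.integer(n), p_mass = p_mass,
         p_malignant_given_mass = p_malignant_given_mass,
         p_malignant_given_nonmass = p_malignant_given_nonmass,
         sign_joint = sign_joint, ks_pmf = ks_pmf,
         contralateral_pmf = contralateral_pmf, reader_flip = reader_flip,
         coupling = coupling, seed = as.integer(seed)),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @param spec Object to validate.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  probs <- c(spec$p_mass, spec$p_malignant_given_mass,
             spec$p_malignant_given_nonmass, unlist(spec$sign_joint),
             unlist(spec$ks_pmf), spec$contralateral_pmf, spec$reader_flip)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (spec$n < 0L) stop("n must be non-negative", call. = FALSE)
  if (spec$coupling < 0 || spec$coupling >= 1) {
    stop("coupling must lie in [0, 1)", call. = FALSE)
  }
  for (cls in c("benign", "malignant")) {
    pmf <- spec$ks_pmf[[cls]]
    if (length(pmf) != 11L || abs(sum(pmf) - 1) > 1e-12) {
      stop(sprintf("ks_pmf$%s must have 11 entries summing to 1", cls),
           call. = FALSE)
    }
    j <- spec$sign_joint[[cls]]
    if (length(j) != 3L) {
      stop(sprintf("sign_joint$%s must be c(p_v, p_a, p_both)", cls),
           call. = FALSE)
    }
    lo <- max(0, j[1] + j[2] - 1); hi <- min(j[1], j[2])
    if (j[3] < lo - 1e-12 || j[3] > hi + 1e-12) {
      stop(sprintf(paste0(
        "sign_joint$%s violates the Frechet bounds: p_both = %.4g must lie ",
        "in [max(0, p_v + p_a - 1), min(p_v, p_a)] = [%.4g, %.4g]"),
        cls, j[3], lo, hi), call. = FALSE)
    }
  }
  if (abs(sum(spec$contralateral_pmf) - 1) > 1e-12) {
    stop("contralateral_pmf must sum to 1", call. = FALSE)
  }
  need <- c("vascularity", "avs", "features")
  if (!all(need %in% names(spec$reader_flip))) {
    stop("reader_flip needs entries: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  invisible(spec)
}

#' Study-calibrated default cohort specification
#'
#' Defaults emulate a 223-lesion reader study: 164 mass / 59 non-mass
#' lesions, 85/164 of mass and 19/59 of non-mass lesions malignant (104
#' malignant overall); per-class vascular-sign joints taken from the
#' published counts (malignant: 72/104 increased vascularity, 86/104 positive
#' AVS, 64/104 both; benign: 28/119, 28/119, 16/119); and per-class Kaiser
#' score distributions calibrated so that the dichotomization "score > 4"
#' has sensitivity 0.942 and specificity 0.588 and the population AUC of the
#' raw score is 0.858 (0.877 after the KS* adjustment). The score pmfs are a
#' committed calibration, not the study's observed histograms (which were not
#' published). Second-reader disagreement rates are anchored to inter-reader
#' kappas of about 0.90 (vascularity) and 0.964 (AVS).
#'
#' @param n Cohort size (default 223).
#' @param seed Root seed.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n = 223L, seed = 20230706L) {
  cohort_spec(
    n = n,
    p_mass = 164 / 223,
    p_malignant_given_mass = 85 / 164,
    p_malignant_given_nonmass = 19 / 59,
    sign_joint = list(
      malignant = c(p_v = 72 / 104, p_a = 86 / 104, p_both = 64 / 104),
      benign    = c(p_v = 28 / 119, p_a = 28 / 119, p_both = 16 / 119)
    ),
    ks_pmf = list(
      benign    = c(0.1570, 0.1503, 0.1427, 0.1380, 0.0898, 0.0801, 0.0661,
                    0.0523, 0.0448, 0.0406, 0.0383),
      malignant = c(0.0137, 0.0142, 0.0148, 0.0153, 0.0483, 0.0563, 0.0754,
                    0.1175, 0.1692, 0.2200, 0.2553)
    ),
    contralateral_pmf = c(`0` = 0.30, `1` = 0.35, `2` = 0.20, `3` = 0.10,
                          `4` = 0.05),
    reader_flip = c(vascularity = 0.05, avs = 0.018, features = 0.05),
    coupling = 0,
    seed = seed
  )
}

# Draw from a categorical pmf through the probability-integral transform so a
# shared latent normal can couple two draws.
#' @keywords internal
.quantile_categorical <- function(u, pmf) {
  pmin(findInterval(u, cumsum(pmf), left.open = TRUE) + 1L, length(pmf))
}

#' Materialize vessel counts consistent with a vascularity flag
#'
#' Draws the contralateral qualifying-vessel count from `pmf`; when the flag
#' is positive the ipsilateral count is `contralateral + 2 + extra` with a
#' small Poisson excess, otherwise the signed difference is at most 1 (never
#' below zero vessels). [assess_increased_vascularity()] on the returned pair
#' always reproduces the flag.
#'
#' @param increased Logical vector of vascularity flags.
#' @param pmf Probability vector over counts `0, 1, 2, ...`.
#' @param extra_lambda Poisson mean of the excess beyond the minimum
#'   difference of 2 for positive lesions.
#' @return Data frame with integer columns `ipsi_vessels`, `contra_vessels`.
#' @export
materialize_vessel_counts <- function(increased, pmf, extra_lambda = 0.7) {
  n <- length(increased)
  vals <- seq_along(pmf) - 1L
  contra <- vals[.quantile_categorical(stats::runif(n), pmf)]
  delta <- sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  ipsi <- ifelse(increased,
                 contra + 2L + stats::rpois(n, extra_lambda),
                 pmax(0L, contra + delta))
  data.frame(ipsi_vessels = as.integer(ipsi),
             contra_vessels = as.integer(contra))
}

#' Simulate a second reading of a cohort
#'
#' Each assessment of the first reading is independently contradicted with
#' its configured probability: the binary vascularity and AVS flags are
#' flipped, binary Kaiser features are flipped, and the curve type moves to
#' one of the other two levels uniformly.
#'
#' @param cohort A cohort data frame (scored or not) containing the feature
#'   columns, vessel counts and `avs_present`.
#' @param reader_flip Named numeric `c(vascularity=, avs=, features=)`.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return `cohort` with `reader2_*` columns filled.
#' @export
simulate_second_reader <- function(cohort, reader_flip, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  flip <- function(p) stats::runif(n) < p
  v1 <- assess_increased_vascularity(cohort$ipsi_vessels, cohort$contra_vessels)
  cohort$reader2_increased_vascularity <- xor(v1, flip(reader_flip[["vascularity"]]))
  cohort$reader2_avs_present <- xor(as.logical(cohort$avs_present),
                                    flip(reader_flip[["avs"]]))
  fl <- reader_flip[["features"]]
  swap_binary <- function(x, vocab) ifelse(flip(fl), vocab[3L - match(x, vocab)], x)
  cohort$reader2_root_sign <- swap_binary(cohort$root_sign, .ks_vocab$root_sign)
  cohort$reader2_margin <- swap_binary(cohort$margin, .ks_vocab$margin)
  cohort$reader2_internal_enhancement <-
    swap_binary(cohort$internal_enhancement, .ks_vocab$internal_enhancement)
  cohort$reader2_edema <- swap_binary(cohort$edema, .ks_vocab$edema)
  other <- vapply(cohort$curve_type, function(ct) {
    sample(setdiff(.ks_vocab$curve_type, ct), 1L)
  }, character(1), USE.NAMES = FALSE)
  cohort$reader2_curve_type <- ifelse(flip(fl), other, cohort$curve_type)
  cohort
}

#' Generate a synthetic lesion cohort
#'
#' Draws, per lesion: the lesion type, the truth class given type, the
#' vascular-sign pair from the class joint, the Kaiser score from the class
#' pmf (optionally coupled to the sign draw through a Gaussian copula on a
#' shared latent severity), Kaiser features sampled uniformly from the tree
#' preimage of the drawn score, vessel counts consistent with the vascularity
#' flag, and a simulated second reading. Fully reproducible given the seed.
#'
#' @param spec A [cohort_spec()].
#' @param tree A valid [score_tree()] used to materialize features (and, by
#'   construction, to reproduce `ks_drawn` when the cohort is scored with the
#'   same tree).
#' @param seed Seed override; defaults to `spec$seed`.
#' @return Data frame, one row per lesion, in the cohort schema of
#'   [read_cohort_csv()] plus the generator column `ks_drawn`.
#' @export
generate_cohort <- function(spec, tree = ks_tree_kaiser_synthetic(),
                            seed = spec$seed) {
  validate_cohort_spec(spec)
  tv <- validate_tree(tree)
  if (!tv$valid) .stop_invalid_tree(tree, tv)
  set.seed(seed)
  n <- spec$n
  empty <- data.frame(
    id = character(), truth = character(), lesion_type = character(),
    root_sign = character(), curve_type = character(), margin = character(),
    internal_enhancement = character(), edema = character(),
    ipsi_vessels = integer(), contra_vessels = integer(),
    avs_present = logical(), ks_drawn = integer(),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(empty)

  lesion_type <- ifelse(stats::runif(n) < spec$p_mass, "mass", "non_mass")
  p_mal <- ifelse(lesion_type == "mass", spec$p_malignant_given_mass,
                  spec$p_malignant_given_nonmass)
  truth <- ifelse(stats::runif(n) < p_mal, "malignant", "benign")

  # Latent severities: z_ks drives the score draw, z_sign the sign-pair
  # category; coupling = 0 makes them independent given the class.
  z1 <- stats::rnorm(n)
  z2 <- spec$coupling * z1 + sqrt(1 - spec$coupling^2) * stats::rnorm(n)
  u_ks <- stats::pnorm(z1); u_sign <- stats::pnorm(z2)

  ks_drawn <- integer(n)
  sign_cat <- character(n)
  for (cls in c("benign", "malignant")) {
    idx <- truth == cls
    if (!any(idx)) next
    ks_drawn[idx] <- .quantile_categorical(u_ks[idx], spec$ks_pmf[[cls]])
    j <- spec$sign_joint[[cls]]
    # ordered none < v_only < a_only < both so higher latent severity means
    # more vascular involvement
    cells <- c(none = 1 - j[[1]] - j[[2]] + j[[3]], v_only = j[[1]] - j[[3]],
               a_only = j[[2]] - j[[3]], both = j[[3]])
    sign_cat[idx] <- names(cells)[.quantile_categorical(u_sign[idx], cells)]
  }
  increased <- sign_cat %in% c("v_only", "both")
  avs <- sign_cat %in% c("a_only", "both")

  # uniform draw from the tree preimage of each drawn score, vectorized over
  # the cohort (the expanded lookup table is computed once)
  tab <- .tree_table(tree)
  if (!all(ks_drawn %in% tab$score)) {
    stop(sprintf("score(s) %s unreachable in tree '%s'",
                 paste(setdiff(ks_drawn, tab$score), collapse = ", "),
                 tree$name), call. = FALSE)
  }
  rows <- integer(n)
  for (s in unique(ks_drawn)) {
    pre <- which(tab$score == s)
    idx <- ks_drawn == s
    rows[idx] <- pre[sample.int(length(pre), sum(idx), replace = TRUE)]
  }
  features <- tab[rows, .ks_feature_names, drop = FALSE]
  counts <- materialize_vessel_counts(increased, spec$contralateral_pmf)

  cohort <- data.frame(
    id = sprintf("L%04d", seq_len(n)), truth = truth,
    lesion_type = lesion_type, features, counts,
    avs_present = avs, ks_drawn = as.integer(ks_drawn),
    stringsAsFactors = FALSE, row.names = NULL
  )
  simulate_second_reader(cohort, spec$reader_flip)
}
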