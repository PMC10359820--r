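# End-to-end orchestration: cohort I/O, dichotomization, evaluation report
# mirroring a reader-study layout, and seeded replication studies.

#' @keywords internal
.cohort_required_cols <- function() {
  c("id", "truth", "lesion_type", .ks_feature_names,
    "ipsi_vessels", "contra_vessels", "avs_present")
}

#' @keywords internal
.yesno_to_logical <- function(x, col) {
  v <- trimws(tolower(as.character(x)))
  out <- ifelse(v %in% c("yes", "true", "1"), TRUE,
                ifelse(v %in% c("no", "false", "0"), FALSE, NA))
  if (anyNA(out)) {
    stop(sprintf("invalid value(s) for '%s' (row %s): expected yes/no", col,
                 paste(utils::head(which(is.na(out)), 5L), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Read and write lesion cohorts as CSV
#'
#' The on-disk schema is one row per lesion with columns `id`, `truth`
#' (benign/malignant), `lesion_type` (mass/non_mass), the five Kaiser feature
#' columns (`root_sign`, `curve_type`, `margin`, `internal_enhancement`,
#' `edema`), `ipsi_vessels`, `contra_vessels` (integers) and `avs_present`
#' (yes/no); optional columns `ks_drawn` and `reader2_*` duplicates are
#' carried through when present. Ingest is case-insensitive and accepts the
#' margin synonyms `irregular`/`spiculated`; flags are serialized as
#' `yes`/`no`. Missing columns raise a schema error naming them; duplicate
#' ids and unknown enumeration values raise row-level errors.
#'
#' @param path CSV file path (UTF-8, comma-delimited, header required).
#' @return `read_cohort_csv()` returns a validated cohort data frame with
#'   logical flag columns; `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(.cohort_required_cols(), names(raw))
  if (length(missing) > 0L) {
    stop("cohort file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$id)) {
    dup <- unique(raw$id[duplicated(raw$id)])
    stop("duplicate lesion id(s): ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  check_enum <- function(x, legal, col) {
    v <- trimws(tolower(x))
    bad <- which(!v %in% legal)
    if (length(bad) > 0L) {
      stop(sprintf("invalid value(s) for '%s': %s (row %s)", col,
                   paste(unique(v[bad]), collapse = ", "),
                   paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
    v
  }
  out <- raw
  out$truth <- check_enum(raw$truth, c("benign", "malignant"), "truth")
  out$lesion_type <- check_enum(raw$lesion_type, c("mass", "non_mass"),
                                "lesion_type")
  out <- normalize_features(out)
  for (col in c("ipsi_vessels", "contra_vessels")) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    if (anyNA(v) || any(v < 0)) {
      stop(sprintf("'%s' must be non-negative integers (row %s)", col,
                   paste(utils::head(which(is.na(v) | v < 0), 5L),
                         collapse = ", ")), call. = FALSE)
    }
    out[[col]] <- v
  }
  out$avs_present <- .yesno_to_logical(raw$avs_present, "avs_present")
  if ("ks_drawn" %in% names(raw)) out$ks_drawn <- as.integer(raw$ks_drawn)
  for (col in grep("^reader2_", names(raw), value = TRUE)) {
    if (col %in% c("reader2_increased_vascularity", "reader2_avs_present",
                   "reader2_root_sign", "reader2_edema")) {
      lg <- .yesno_to_logical(raw[[col]], col)
      out[[col]] <- if (col %in% c("reader2_root_sign", "reader2_edema")) {
        ifelse(lg, "yes", "no")
      } else {
        lg
      }
    } else {
      out[[col]] <- trimws(tolower(raw[[col]]))
    }
  }
  out
}

#' @rdname read_cohort_csv
#' @param cohort Cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as.data.frame(cohort, stringsAsFactors = FALSE)
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- ifelse(out[[col]], "yes", "no")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dichotomize an ordinal score
#'
#' Positive iff `score > cutoff` (strict); the conventional biopsy threshold
#' is `cutoff = 4`, i.e. scores of 5 and above are called malignant.
#'
#' @param scores Integer scores in 1..11.
#' @param cutoff Integer in 0..11.
#' @return Logical vector.
#' @export
dichotomize <- function(scores, cutoff = 4L) {
  stopifnot(cutoff >= 0, cutoff <= 11)
  scores > cutoff
}

#' Audit the lesions upgraded by the vascular adjustment
#'
#' @param scored A cohort scored by [score_cohort()].
#' @param cutoff Active dichotomization cutoff (for the subset whose upgrade
#'   crosses it).
#' @return List with `total` upgraded count, `by_class_type` cross-tab
#'   (truth x lesion type), and `crossed_cutoff` counts by truth of upgrades
#'   from `ks <= cutoff` to `ks_star > cutoff`.
#' @export
upgrade_audit <- function(scored, cutoff = 4L) {
  up <- scored$ks_star != scored$ks
  tab <- table(truth = factor(scored$truth, c("benign", "malignant")),
               lesion_type = factor(scored$lesion_type, c("mass", "non_mass")))
  tab[] <- 0L
  if (any(up)) {
    t2 <- table(truth = factor(scored$truth[up], c("benign", "malignant")),
                lesion_type = factor(scored$lesion_type[up],
                                     c("mass", "non_mass")))
    tab <- t2
  }
  crossed <- up & scored$ks <= cutoff & scored$ks_star > cutoff
  list(
    total = sum(up),
    by_class_type = tab,
    crossed_cutoff = c(
      benign = sum(crossed & scored$truth == "benign"),
      malignant = sum(crossed & scored$truth == "malignant")
    )
  )
}

#' @keywords internal
.sign_flags <- function(scored) {
  list(vascularity = scored$increased_vascularity,
       avs = as.logical(scored$avs_present),
       both = scored$increased_vascularity & as.logical(scored$avs_present))
}

# chi-square comparing one metric of one sign between mass and non-mass:
# successes/failures among the metric's denominator group.
#' @keywords internal
.metric_comparison <- function(ct_mass, ct_nonmass, metric) {
  cells <- function(ct) switch(metric,
    sensitivity = c(ct$tp, ct$fn),
    specificity = c(ct$tn, ct$fp),
    accuracy = c(ct$tp + ct$tn, ct$fp + ct$fn),
    ppv = c(ct$tp, ct$fp),
    npv = c(ct$tn, ct$fn))
  tab <- rbind(cells(ct_mass), cells(ct_nonmass))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_))
  }
  chi2_2x2(tab)
}

#' Evaluate a scored cohort into a report bundle
#'
#' Produces the full reader-study report: inter-reader kappa for the two
#' vascular assessments (when a second reading is present), per-subgroup
#' (all / mass / non-mass) diagnostic metrics of increased vascularity, AVS
#' and their conjunction with exact fractions, chi-square comparisons of each
#' metric between mass and non-mass lesions, AUC with confidence interval for
#' KS and KS* per subgroup with the paired DeLong comparison, and the
#' upgrade audit. Subgroups containing a single truth class are skipped from
#' the AUC table with a warning.
#'
#' @param scored A cohort scored by [score_cohort()].
#' @param cutoff Dichotomization cutoff (strict `>`).
#' @return A list of class `report_bundle`.
#' @export
evaluate_cohort <- function(scored, cutoff = 4L) {
  stopifnot(all(c("ks", "ks_star", "increased_vascularity") %in% names(scored)))
  truth <- scored$truth == "malignant"
  subgroups <- list(all = rep(TRUE, nrow(scored)),
                    mass = scored$lesion_type == "mass",
                    non_mass = scored$lesion_type == "non_mass")

  agreement <- NULL
  if (all(c("reader2_increased_vascularity", "reader2_avs_present")
          %in% names(scored))) {
    rows <- lapply(c(vascularity = "reader2_increased_vascularity",
                     avs = "reader2_avs_present"), function(col) {
      r1 <- if (col == "reader2_avs_present") as.logical(scored$avs_present)
            else scored$increased_vascularity
      k <- cohen_kappa(r1, scored[[col]])
      data.frame(kappa = k$kappa, ci_low = k$ci[1], ci_high = k$ci[2],
                 band = k$band, stringsAsFactors = FALSE)
    })
    agreement <- cbind(assessment = names(rows),
                       do.call(rbind, rows), row.names = NULL)
  }

  # per-subgroup, per-sign metric tables
  perf <- list(); confusions <- list()
  for (sg in names(subgroups)) {
    idx <- subgroups[[sg]]
    flags <- .sign_flags(scored[idx, , drop = FALSE])
    for (sign in names(flags)) {
      ct <- build_confusion(flags[[sign]], truth[idx])
      confusions[[paste(sg, sign, sep = ".")]] <- ct
      ms <- confusion_metrics(ct)
      ms$subgroup <- sg; ms$sign <- sign
      perf[[paste(sg, sign, sep = ".")]] <- ms
    }
  }
  sign_performance <- do.call(rbind, perf)
  row.names(sign_performance) <- NULL
  class(sign_performance) <- "data.frame"

  comparisons <- do.call(rbind, lapply(c("vascularity", "avs", "both"),
                                       function(sign) {
    do.call(rbind, lapply(c("sensitivity", "specificity", "accuracy",
                            "ppv", "npv"), function(metric) {
      cmp <- .metric_comparison(confusions[[paste0("mass.", sign)]],
                                confusions[[paste0("non_mass.", sign)]],
                                metric)
      data.frame(sign = sign, metric = metric, chi2 = cmp$chi2, p = cmp$p,
                 stringsAsFactors = FALSE)
    }))
  }))

  auc_rows <- list(); delong_rows <- list()
  for (sg in names(subgroups)) {
    idx <- subgroups[[sg]]
    t_sg <- truth[idx]
    if (sum(t_sg) < 2L || sum(!t_sg) < 2L) {
      warning(sprintf("subgroup '%s' lacks two lesions per class; skipped", sg))
      next
    }
    a1 <- auc_estimate(scored$ks[idx], t_sg)
    a2 <- auc_estimate(scored$ks_star[idx], t_sg)
    dl <- delong_paired_test(scored$ks_star[idx], scored$ks[idx], t_sg)
    auc_rows[[sg]] <- data.frame(
      subgroup = sg, score = c("ks", "ks_star"),
      auc = c(a1$auc, a2$auc), se = c(a1$se, a2$se),
      ci_low = c(a1$ci[1], a2$ci[1]), ci_high = c(a1$ci[2], a2$ci[2]),
      stringsAsFactors = FALSE)
    delong_rows[[sg]] <- data.frame(subgroup = sg, auc_ks_star = dl$auc1,
                                    auc_ks = dl$auc2, z = dl$z, p = dl$p,
                                    stringsAsFactors = FALSE)
  }

  ops <- list()
  for (score in c("ks", "ks_star")) {
    ct <- build_confusion(dichotomize(scored[[score]], cutoff), truth)
    ms <- confusion_metrics(ct)
    ms$score <- score
    ops[[score]] <- ms
  }
  operating_point <- do.call(rbind, ops)
  row.names(operating_point) <- NULL
  class(operating_point) <- "data.frame"

  structure(
    list(
      meta = list(n = nrow(scored), cutoff = as.integer(cutoff),
                  n_malignant = sum(truth), n_benign = sum(!truth)),
      agreement = agreement,
      sign_performance = sign_performance,
      sign_comparisons = comparisons,
      operating_point = operating_point,
      auc = do.call(rbind, c(auc_rows, list(make.row.names = FALSE))),
      delong = do.call(rbind, c(delong_rows, list(make.row.names = FALSE))),
      upgrade_audit = upgrade_audit(scored, cutoff)
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Report bundle: %d lesions (%d malignant / %d benign), cutoff > %d\n",
              x$meta$n, x$meta$n_malignant, x$meta$n_benign, x$meta$cutoff))
  if (!is.null(x$agreement)) {
    cat("\nInter-reader agreement:\n"); print(x$agreement, row.names = FALSE)
  }
  cat("\nVascular-sign performance (percent by subgroup):\n")
  wide <- stats::reshape(
    x$sign_performance[, c("subgroup", "sign", "metric", "percent")],
    idvar = c("sign", "metric"), timevar = "subgroup", direction = "wide")
  print(wide, row.names = FALSE)
  cat("\nAUC (DeLong CI) and paired comparison:\n")
  print(x$auc, row.names = FALSE)
  print(x$delong, row.names = FALSE)
  cat(sprintf("\nUpgraded lesions: %d (%d malignant crossing the cutoff)\n",
              x$upgrade_audit$total, x$upgrade_audit$crossed_cutoff[["malignant"]]))
  invisible(x)
}

#' Serialize a report bundle
#'
#' Writes `report.json` (the full bundle, machine readable) plus CSV tables
#' `sign_performance.csv`, `sign_comparisons.csv`, `auc.csv` and, when
#' present, `agreement.csv` into a directory. Serialization is deterministic:
#' identical bundles give byte-identical files.
#'
#' @param bundle A `report_bundle` from [evaluate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- bundle
  json$upgrade_audit$by_class_type <-
    as.data.frame(bundle$upgrade_audit$by_class_type)
  json$upgrade_audit$crossed_cutoff <-
    as.list(bundle$upgrade_audit$crossed_cutoff)
  jsonlite::write_json(unclass(json), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.csv(bundle$sign_performance,
                   file.path(dir, "sign_performance.csv"), row.names = FALSE)
  utils::write.csv(bundle$sign_comparisons,
                   file.path(dir, "sign_comparisons.csv"), row.names = FALSE)
  utils::write.csv(bundle$auc, file.path(dir, "auc.csv"), row.names = FALSE)
  utils::write.csv(bundle$delong, file.path(dir, "delong.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$agreement)) {
    utils::write.csv(bundle$agreement, file.path(dir, "agreement.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Run the full pipeline
#'
#' Reads a cohort CSV or simulates one from a [cohort_spec()], scores it
#' (KS, KS*, BI-RADS), evaluates it into a [evaluate_cohort()] report bundle
#' and optionally writes the bundle to disk. Deterministic under a fixed
#' seed.
#'
#' @param config A list (or path to a YAML/JSON file encoding one) with
#'   fields: `input` (cohort CSV path, or `NULL` to simulate), `spec` (a
#'   [cohort_spec()], used when simulating; default [default_cohort_spec()]),
#'   `tree` (a [score_tree()] or tree file path; default
#'   [ks_tree_kaiser_synthetic()]), `cutoff` (default 4), `seed` (overrides
#'   the spec seed) and `out_dir` (optional output directory).
#' @return The `report_bundle`, invisibly; the scored cohort is attached as
#'   attribute `"cohort"`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyDataFrame = FALSE)
    }
  }
  tree <- config$tree
  if (is.null(tree)) tree <- ks_tree_kaiser_synthetic()
  if (is.character(tree)) tree <- read_score_tree(tree)
  cutoff <- if (is.null(config$cutoff)) 4L else as.integer(config$cutoff)
  stopifnot(cutoff >= 0L, cutoff <= 11L)

  if (!is.null(config$input)) {
    cohort <- read_cohort_csv(config$input)
  } else {
    spec <- if (is.null(config$spec)) default_cohort_spec() else config$spec
    seed <- if (is.null(config$seed)) spec$seed else as.integer(config$seed)
    cohort <- generate_cohort(spec, tree, seed = seed)
  }
  scored <- score_cohort(cohort, tree)
  bundle <- evaluate_cohort(scored, cutoff)
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  attr(bundle, "cohort") <- scored
  invisible(bundle)
}

#' Replicate a simulation study over seeds
#'
#' Generates `replicates` cohorts (replicate `k` uses `base_seed + k`),
#' scores each, and records the AUC of KS and KS*, the paired DeLong
#' comparison and the upgrade counts.
#'
#' @param spec A [cohort_spec()].
#' @param tree A valid [score_tree()].
#' @param replicates Number of replicates.
#' @param base_seed Root seed; replicate `k` uses `base_seed + k`.
#' @return Data frame with one row per replicate: `replicate`, `seed`,
#'   `auc_ks`, `auc_ks_star`, `delta`, `p`, `upgrades`,
#'   `upgrades_malignant`.
#' @export
replicate_study <- function(spec = default_cohort_spec(),
                            tree = ks_tree_kaiser_synthetic(),
                            replicates = 200L, base_seed = spec$seed) {
  rows <- lapply(seq_len(replicates), function(k) {
    cohort <- generate_cohort(spec, tree, seed = base_seed + k)
    scored <- score_cohort(cohort, tree)
    truth <- scored$truth == "malignant"
    if (sum(truth) < 2L || sum(!truth) < 2L) return(NULL)
    dl <- delong_paired_test(scored$ks_star, scored$ks, truth)
    up <- scored$ks_star != scored$ks
    data.frame(replicate = k, seed = base_seed + k, auc_ks = dl$auc2,
               auc_ks_star = dl$auc1, delta = dl$auc1 - dl$auc2, p = dl$p,
               upgrades = sum(up), upgrades_malignant = sum(up & truth))
  })
  do.call(rbind, rows)
}
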