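# Kaiser diagnostic features and the decision tree mapping them to scores.

#' @keywords internal
.ks_feature_names <- c("root_sign", "curve_type", "margin",
                       "internal_enhancement", "edema")

#' @keywords internal
.ks_vocab <- list(
  root_sign            = c("no", "yes"),
  curve_type           = c("persistent", "plateau", "washout"),
  margin               = c("circumscribed", "not_circumscribed"),
  internal_enhancement = c("homogeneous", "inhomogeneous"),
  edema                = c("no", "yes")
)

# Synonyms accepted on ingest (after lower-casing). "irregular" and
# "spiculated" margins both mean not circumscribed; the root sign is carried
# separately. Logical-looking tokens map onto yes/no for the binary features.
#' @keywords internal
.ks_synonyms <- list(
  root_sign            = c("true" = "yes", "false" = "no", "1" = "yes", "0" = "no"),
  curve_type           = character(),
  margin               = c(irregular = "not_circumscribed",
                           spiculated = "not_circumscribed"),
  internal_enhancement = c(heterogeneous = "inhomogeneous"),
  edema                = c("true" = "yes", "false" = "no", "1" = "yes", "0" = "no")
)

#' Normalize Kaiser feature values to the canonical vocabulary
#'
#' Values are lower-cased and trimmed; accepted synonyms (e.g. `"irregular"`
#' or `"spiculated"` margins, logical tokens for the binary features) are
#' mapped to the canonical lower-case vocabulary. Unknown values raise an
#' error naming the column and the offending values.
#'
#' @param features A data frame (or coercible list) holding the five feature
#'   columns `root_sign`, `curve_type`, `margin`, `internal_enhancement`,
#'   `edema`. Extra columns are passed through untouched.
#' @param allow_wildcard Accept `"*"` as a value (used for tree path records).
#' @return The input with the five feature columns in canonical form.
#' @export
normalize_features <- function(features, allow_wildcard = FALSE) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  missing <- setdiff(.ks_feature_names, names(features))
  if (length(missing) > 0L) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in .ks_feature_names) {
    x <- trimws(tolower(as.character(features[[f]])))
    syn <- .ks_synonyms[[f]]
    hit <- match(x, names(syn))
    x[!is.na(hit)] <- unname(syn[hit[!is.na(hit)]])
    legal <- .ks_vocab[[f]]
    if (allow_wildcard) legal <- c(legal, "*")
    bad <- setdiff(unique(x[!is.na(x)]), legal)
    if (length(bad) > 0L || anyNA(x)) {
      rows <- which(is.na(x) | x %in% bad)
      stop(sprintf("invalid value(s) for '%s': %s (row %s)", f,
                   paste(unique(c(bad, if (anyNA(x)) NA)), collapse = ", "),
                   paste(utils::head(rows, 5L), collapse = ", ")),
           call. = FALSE)
    }
    features[[f]] <- x
  }
  features
}

#' All 48 legal Kaiser feature combinations
#'
#' @return A data frame with one row per combination of the five features
#'   (2 x 3 x 2 x 2 x 2 = 48 rows).
#' @export
feature_combinations <- function() {
  g <- expand.grid(.ks_vocab, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, .ks_feature_names]
}

#' Construct a Kaiser score tree
#'
#' A score tree is a declarative decision rule: a set of path records, each
#' constraining some of the five Kaiser features (with `"*"` as a wildcard)
#' and assigning an integer score. A valid tree covers every one of the 48
#' feature combinations exactly once (overlapping paths that agree on the
#' score are tolerated) with all scores in 1..11.
#'
#' Construction performs structural checks only; use [validate_tree()] for
#' the full totality/determinism report. [assign_kaiser_score()] refuses to
#' score with an invalid tree.
#'
#' @param paths Data frame with columns `root_sign`, `curve_type`, `margin`,
#'   `internal_enhancement`, `edema` (wildcard `"*"` allowed) and `score`.
#' @param name,version Identification strings carried on the object.
#' @return An object of class `score_tree`.
#' @seealso [read_score_tree()], [validate_tree()], [ks_tree_t1()]
#' @export
score_tree <- function(paths, name = "unnamed", version = "0") {
  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  if (!"score" %in% names(paths)) stop("paths must have a 'score' column", call. = FALSE)
  paths <- normalize_features(paths, allow_wildcard = TRUE)
  score <- suppressWarnings(as.numeric(paths$score))
  if (anyNA(score) || any(score != round(score))) {
    stop("tree scores must be integers", call. = FALSE)
  }
  paths$score <- as.integer(score)
  structure(
    list(name = as.character(name), version = as.character(version),
         paths = paths[, c(.ks_feature_names, "score")]),
    class = "score_tree"
  )
}

#' @export
print.score_tree <- function(x, ...) {
  v <- validate_tree(x)
  cat(sprintf("Kaiser score tree '%s' (version %s): %d paths, %s\n",
              x$name, x$version, nrow(x$paths),
              if (v$valid) "valid" else "INVALID"))
  print(x$paths, row.names = FALSE)
  invisible(x)
}

# Expand a tree's paths over the 48 combinations. Returns the combination
# table with, per combination, the set of distinct scores reached.
#' @keywords internal
.tree_cover <- function(tree) {
  combos <- feature_combinations()
  p <- tree$paths
  scores <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    m <- rep(TRUE, nrow(p))
    for (f in .ks_feature_names) {
      m <- m & (p[[f]] == "*" | p[[f]] == combos[[f]][i])
    }
    scores[[i]] <- unique(p$score[m])
  }
  combos$scores <- scores
  combos
}

#' Validate a score tree for totality, determinism and score range
#'
#' @param tree A [score_tree()].
#' @return An object of class `tree_validation`: a list with data frames
#'   `uncovered` (combinations reaching no leaf), `conflicts` (combinations
#'   reaching two different scores), `out_of_range` (path records whose score
#'   is outside 1..11) and a logical `valid`, true iff all three are empty.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "score_tree"))
  cover <- .tree_cover(tree)
  k <- lengths(cover$scores)
  uncovered <- cover[k == 0L, .ks_feature_names, drop = FALSE]
  conflicts <- cover[k > 1L, .ks_feature_names, drop = FALSE]
  oor <- tree$paths[tree$paths$score < 1L | tree$paths$score > 11L, , drop = FALSE]
  structure(
    list(uncovered = uncovered, conflicts = conflicts, out_of_range = oor,
         valid = nrow(uncovered) == 0L && nrow(conflicts) == 0L && nrow(oor) == 0L),
    class = "tree_validation"
  )
}

#' @export
print.tree_validation <- function(x, ...) {
  if (x$valid) {
    cat("score tree is total, deterministic, scores within 1..11\n")
  } else {
    if (nrow(x$uncovered) > 0L) {
      cat(nrow(x$uncovered), "uncovered feature combination(s):\n")
      print(x$uncovered, row.names = FALSE)
    }
    if (nrow(x$conflicts) > 0L) {
      cat(nrow(x$conflicts), "combination(s) reaching conflicting scores:\n")
      print(x$conflicts, row.names = FALSE)
    }
    if (nrow(x$out_of_range) > 0L) {
      cat(nrow(x$out_of_range), "path(s) with score outside 1..11:\n")
      print(x$out_of_range, row.names = FALSE)
    }
  }
  invisible(x)
}

#' @keywords internal
.stop_invalid_tree <- function(tree, v) {
  if (nrow(v$uncovered) > 0L) {
    u <- v$uncovered[1L, ]
    stop(sprintf(
      "tree '%s' is not total; e.g. combination (%s) reaches no leaf",
      tree$name, paste(unlist(u), collapse = ", ")), call. = FALSE)
  }
  if (nrow(v$conflicts) > 0L) {
    u <- v$conflicts[1L, ]
    stop(sprintf(
      "tree '%s' is nondeterministic; e.g. combination (%s) reaches two scores",
      tree$name, paste(unlist(u), collapse = ", ")), call. = FALSE)
  }
  stop(sprintf("tree '%s' has leaf score(s) outside 1..11", tree$name),
       call. = FALSE)
}

# Full 48-row lookup table combo -> score for a valid tree.
#' @keywords internal
.tree_table <- function(tree) {
  v <- validate_tree(tree)
  if (!v$valid) .stop_invalid_tree(tree, v)
  cover <- .tree_cover(tree)
  cover$score <- vapply(cover$scores, `[[`, integer(1), 1L)
  cover$scores <- NULL
  cover
}

#' Assign Kaiser scores to lesions
#'
#' Traverses a validated score tree for each row of feature values and
#' returns the unique leaf score (an integer in 1..11).
#'
#' @param features Data frame (one row per lesion) with the five Kaiser
#'   feature columns; values are normalized with [normalize_features()].
#' @param tree A valid [score_tree()].
#' @return Integer vector of Kaiser scores, one per row of `features`.
#' @examples
#' tree <- ks_tree_t1()
#' assign_kaiser_score(
#'   data.frame(root_sign = "no", curve_type = "washout",
#'              margin = "circumscribed",
#'              internal_enhancement = "inhomogeneous", edema = "no"),
#'   tree)
#' @export
assign_kaiser_score <- function(features, tree) {
  tab <- .tree_table(tree)
  features <- normalize_features(features)
  key <- function(d) do.call(paste, c(d[.ks_feature_names], sep = "\r"))
  idx <- match(key(features), key(tab))
  tab$score[idx]
}

#' Draw feature combinations from the preimage of a score
#'
#' Samples uniformly among the feature combinations that a tree maps to the
#' requested score. Used by the synthetic-cohort generator to materialize
#' Kaiser features consistent with a drawn score.
#'
#' @param score Integer scalar, a leaf value of `tree`.
#' @param tree A valid [score_tree()].
#' @param n Number of combinations to draw.
#' @return Data frame of `n` feature rows; `assign_kaiser_score()` on the
#'   result returns `score` for every row.
#' @export
sample_features_for_score <- function(score, tree, n = 1L) {
  stopifnot(length(score) == 1L, n >= 0L)
  tab <- .tree_table(tree)
  pre <- tab[tab$score == score, .ks_feature_names, drop = FALSE]
  if (nrow(pre) == 0L) {
    stop(sprintf("score %s is unreachable in tree '%s'", score, tree$name),
         call. = FALSE)
  }
  pre[sample.int(nrow(pre), n, replace = TRUE), , drop = FALSE]
}

#' Read or write a score tree (YAML or JSON)
#'
#' The on-disk form is a mapping with `name`, `version` and `paths`, the
#' latter a list of records over the five features (wildcard `"*"`) plus
#' `score`. The loader expands wildcards and re-validates; an invalid file is
#' refused.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_score_tree()` returns a valid [score_tree()];
#'   `write_score_tree()` returns `path` invisibly.
#' @export
read_score_tree <- function(path) {
  if (!file.exists(path)) stop("no such tree file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  if (is.null(raw$paths)) stop("tree file has no 'paths' entry", call. = FALSE)
  paths <- do.call(rbind, lapply(raw$paths, function(r) {
    as.data.frame(lapply(r, as.character), stringsAsFactors = FALSE)
  }))
  tree <- score_tree(paths,
                     name = if (is.null(raw$name)) basename(path) else raw$name,
                     version = if (is.null(raw$version)) "0" else raw$version)
  v <- validate_tree(tree)
  if (!v$valid) .stop_invalid_tree(tree, v)
  tree
}

#' @rdname read_score_tree
#' @param tree A [score_tree()] to serialize.
#' @export
write_score_tree <- function(tree, path) {
  stopifnot(inherits(tree, "score_tree"))
  recs <- lapply(seq_len(nrow(tree$paths)), function(i) {
    r <- as.list(tree$paths[i, ])
    r$score <- as.integer(r$score)
    r
  })
  obj <- list(name = tree$name, version = tree$version, paths = recs)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Bundled score trees
#'
#' `ks_tree_t1()` is the fully specified reference tree used throughout the
#' test suite; it is total, deterministic and reaches all eleven scores.
#' `ks_tree_kaiser_synthetic()` is a synthetic reconstruction of the Kaiser
#' flowchart: the published decision rule is not redistributed, so this tree
#' is only constrained to reproduce four published worked examples (irregular
#' margin with persistent enhancement scoring 3, irregular margin with
#' plateau scoring 5, root sign without edema scoring 7, persistent non-mass
#' enhancement scoring 6). It is the pipeline default but should be replaced
#' by a transcription of the published flowchart for clinical use.
#'
#' @return A valid [score_tree()].
#' @export
ks_tree_t1 <- function() {
  read_score_tree(system.file("extdata", "tree_fixture_t1.yaml",
                              package = "ksvasc", mustWork = TRUE))
}

#' @rdname ks_tree_t1
#' @export
ks_tree_kaiser_synthetic <- function() {
  read_score_tree(system.file("extdata", "tree_kaiser_synthetic.yaml",
                              package = "ksvasc", mustWork = TRUE))
}
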