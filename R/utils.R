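# Internal helpers: seeded evaluation, argument checks, id parsing.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded sub-computations
#' (fold draws, subsamples, decoy permutations) do not perturb each other.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one parent seed; keeps values < 2^31.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647L)
}

stopifnot_scalar_count <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    stop(sprintf("`%s` must be a single %s integer, got %s",
                 name, if (positive) "positive" else "non-negative",
                 deparse(substitute(x))), call. = FALSE)
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# glmnet wrapper muffling its small-class advisory warning, which is
# expected (and harmless) in the small inner folds and subsamples used here.
quiet_glmnet <- function(...) {
  withCallingHandlers(
    glmnet::glmnet(...),
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

# Canonical feature id is "stratum|cell_type|marker"; frequency features use
# the pseudo-marker "frequency".
make_feature_id <- function(stratum, cell_type, marker) {
  paste(stratum, cell_type, marker, sep = "|")
}

parse_feature_id <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("malformed feature id(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    feature   = ids,
    stratum   = vapply(parts, `[[`, "", 1L),
    cell_type = vapply(parts, `[[`, "", 2L),
    marker    = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

# Feature tables are data.frames whose first column is sample_id; internally
# models work on the numeric matrix.
feature_matrix <- function(table) {
  if (is.matrix(table)) {
    storage.mode(table) <- "double"
    return(table)
  }
  stopifnot(is.data.frame(table))
  if (!identical(names(table)[1L], "sample_id")) {
    stop("a feature table's first column must be `sample_id`", call. = FALSE)
  }
  x <- as.matrix(table[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- as.character(table$sample_id)
  x
}

as_feature_table <- function(x, sample_ids = rownames(x)) {
  stopifnot(is.matrix(x))
  out <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(x, optional = TRUE))
  rownames(out) <- NULL
  out
}

# Binary outcome coercion: accepts 0/1, logical, or a factor/character with
# levels control/case.
as_binary_outcome <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    lv <- sort(unique(y))
    if (length(lv) > 2L) stop("outcome has more than two levels", call. = FALSE)
    y <- as.integer(y == if ("case" %in% lv) "case" else lv[length(lv)])
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary", call. = FALSE)
  y
}

# Stratified fold assignment: every sample appears in exactly one fold and
# both classes are spread as evenly as possible across folds.
stratified_folds <- function(y, k, seed) {
  y <- as_binary_outcome(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  folds
}
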