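# Derivation of per-sample immune features from gated event tables:
# population frequencies, endogenous signaling, stimulation responses, and
# the prior-knowledge penalization step.

#' Arcsinh transform with cofactor
#'
#' The standard mass-cytometry variance-stabilizing transform
#' `asinh(x / cofactor)`; the conventional cofactor is 5.
#'
#' @param x intensities (any real; strictly increasing map).
#' @param cofactor positive scale (default 5).
#' @return transformed values.
#' @export
#' @examples
#' arcsinh_transform(5)          # asinh(1) = log(1 + sqrt(2))
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0) {
    stop("cofactor must be a positive scalar", call. = FALSE)
  }
  asinh(x / cofactor)
}

#' Feature derivation settings
#'
#' @param cofactor arcsinh cofactor (> 0, default 5).
#' @param mononuclear_types,granulocyte_types disjoint population sets;
#'   mononuclear frequencies are a percentage of mononuclear events,
#'   granulocyte frequencies a percentage of all singlet leukocytes.
#' @param min_cells minimum events per (sample, cell type, condition) for a
#'   valid median (default 3; medians of fewer events are unstable).
#' @param conditions stimulation conditions expected per sample; the first
#'   entry is the unstimulated reference aliquot.
#' @return a `feature_derivation_config` list.
#' @export
feature_derivation_config <- function(cofactor = 5,
                                      mononuclear_types =
                                        setdiff(default_cell_types(),
                                                default_granulocyte_types()),
                                      granulocyte_types =
                                        default_granulocyte_types(),
                                      min_cells = 3L,
                                      conditions = default_conditions()) {
  if (cofactor <= 0) stop("cofactor must be > 0", call. = FALSE)
  if (length(intersect(mononuclear_types, granulocyte_types)) > 0L) {
    stop("mononuclear and granulocyte sets must be disjoint", call. = FALSE)
  }
  min_cells <- stopifnot_scalar_count(min_cells, "min_cells")
  structure(list(cofactor = cofactor,
                 mononuclear_types = mononuclear_types,
                 granulocyte_types = granulocyte_types,
                 min_cells = min_cells,
                 conditions = conditions),
            class = "feature_derivation_config")
}

event_marker_columns <- function(events) {
  setdiff(names(events), c("sample_id", "condition", "cell_type"))
}

check_event_table <- function(events, config) {
  required <- c("sample_id", "condition", "cell_type")
  if (!all(required %in% names(events))) {
    stop("event table must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  known <- c(config$mononuclear_types, config$granulocyte_types)
  unknown <- setdiff(unique(events$cell_type), known)
  if (length(unknown) > 0L) {
    stop("unknown cell type label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(events)
}

#' Cell-population frequency features
#'
#' Frequencies are computed from the unstimulated aliquot: mononuclear
#' subsets as a percentage of mononuclear events, granulocyte subsets as a
#' percentage of all singlet leukocyte events.
#'
#' @param events event table: one row per cell with `sample_id`,
#'   `condition`, `cell_type` and marker columns.
#' @param config a [feature_derivation_config()].
#' @return feature table (`sample_id` + one `freq|<type>|frequency` column
#'   per configured population, values in \[0, 100\]).
#' @export
cell_frequencies <- function(events, config = feature_derivation_config()) {
  check_event_table(events, config)
  unstim <- config$conditions[1L]
  ev <- events[events$condition == unstim, c("sample_id", "cell_type")]
  samples <- sort(unique(as.character(events$sample_id)))
  types <- c(config$mononuclear_types, config$granulocyte_types)
  counts <- table(factor(as.character(ev$sample_id), levels = samples),
                  factor(as.character(ev$cell_type), levels = types))
  counts <- matrix(counts, nrow = length(samples),
                   dimnames = list(samples, types))
  mono <- counts[, config$mononuclear_types, drop = FALSE]
  gran <- counts[, config$granulocyte_types, drop = FALSE]
  mono_total <- rowSums(mono)
  if (any(mono_total == 0)) {
    stop("no mononuclear events in sample(s): ",
         paste(samples[mono_total == 0], collapse = ", "), call. = FALSE)
  }
  leuk_total <- mono_total + rowSums(gran)
  out <- cbind(100 * mono / mono_total, 100 * gran / leuk_total)
  out <- out[, types, drop = FALSE]
  colnames(out) <- make_feature_id("freq", types, "frequency")
  as_feature_table(out, samples)
}

# Median raw intensity per (sample, cell type, marker, condition), wide on
# the composite key; errors when any required group has < min_cells events.
median_intensity_table <- function(events, config) {
  markers <- event_marker_columns(events)
  key <- interaction(events$sample_id, events$condition, events$cell_type,
                     drop = TRUE, sep = "\r")
  sizes <- table(key)
  meds <- lapply(markers, function(m) {
    tapply(events[[m]], key, stats::median)
  })
  info <- do.call(rbind, strsplit(names(sizes), "\r", fixed = TRUE))
  out <- data.frame(sample_id = info[, 1L], condition = info[, 2L],
                    cell_type = info[, 3L], n_cells = as.integer(sizes),
                    stringsAsFactors = FALSE)
  for (i in seq_along(markers)) out[[markers[i]]] <- as.numeric(meds[[i]])
  out
}

#' Endogenous and stimulation-response signaling features
#'
#' Endogenous features are the arcsinh-transformed median marker intensity
#' in the unstimulated aliquot per (cell type, marker); response features are
#' the difference in arcsinh-transformed medians between a stimulated and the
#' unstimulated aliquot (the arcsinh ratio of medians).
#'
#' @inheritParams cell_frequencies
#' @return feature table with `Unstim|...` endogenous columns and one
#'   response stratum per stimulation condition.
#' @export
signaling_features <- function(events, config = feature_derivation_config()) {
  check_event_table(events, config)
  markers <- event_marker_columns(events)
  if (length(markers) == 0L) stop("event table has no marker columns",
                                  call. = FALSE)
  conditions <- config$conditions
  unstim <- conditions[1L]
  med <- median_intensity_table(events, config)
  short <- med[med$n_cells < config$min_cells, , drop = FALSE]
  if (nrow(short) > 0L) {
    keys <- paste0("(", short$sample_id, ", ", short$cell_type, ", ",
                   short$condition, ": ", short$n_cells, " cells)")
    stop("fewer than ", config$min_cells, " events for ",
         paste(keys, collapse = ", "), call. = FALSE)
  }
  samples <- sort(unique(as.character(events$sample_id)))
  types <- sort(unique(as.character(med$cell_type)))
  types <- types[order(match(types, c(config$mononuclear_types,
                                      config$granulocyte_types)))]
  # require every (sample, cell type) present in every configured condition
  have <- table(paste(med$sample_id, med$cell_type),
                factor(med$condition, levels = conditions))
  missing <- rownames(have)[apply(have == 0, 1L, any)]
  if (length(missing) > 0L) {
    stop("missing condition aliquot(s) for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  arc <- function(cond, type) {
    block <- med[med$condition == cond & med$cell_type == type, , drop = FALSE]
    block <- block[match(samples, block$sample_id), markers, drop = FALSE]
    arcsinh_transform(as.matrix(block), config$cofactor)
  }
  cols <- list()
  for (type in types) {
    base <- arc(unstim, type)
    colnames(base) <- make_feature_id("Unstim", type, markers)
    cols[[paste0("U", type)]] <- base
    for (cond in setdiff(conditions, unstim)) {
      resp <- arc(cond, type) - base
      colnames(resp) <- make_feature_id(cond, type, markers)
      cols[[paste0(cond, type)]] <- resp
    }
  }
  x <- do.call(cbind, cols)
  # canonical order: strata, then cell type, then marker alphabetically
  ids <- parse_feature_id(colnames(x))
  ord <- order(match(ids$stratum, conditions), match(ids$cell_type, types),
               ids$marker)
  as_feature_table(x[, ord, drop = FALSE], samples)
}

#' Derive the full per-sample feature table from events
#'
#' Frequencies plus endogenous and stimulation-response features, columns in
#' canonical order (freq, Unstim, then each stimulation stratum), optionally
#' penalized by a prior-knowledge mask.
#'
#' @inheritParams cell_frequencies
#' @param mask optional `penalization_matrix`; when supplied, applied via
#'   [apply_penalization()].
#' @return feature table (`sample_id` first column).
#' @export
derive_features <- function(events, config = feature_derivation_config(),
                            mask = NULL) {
  freq <- cell_frequencies(events, config)
  sig <- signaling_features(events, config)
  stopifnot(identical(freq$sample_id, sig$sample_id))
  out <- cbind(freq, sig[, -1L, drop = FALSE])
  if (!is.null(mask)) out <- apply_penalization(out, mask)
  out
}

#' Apply a prior-knowledge penalization mask to a feature table
#'
#' Columns whose mask value is 0 are removed; column order is preserved.
#' Every candidate feature must be covered by the mask.
#'
#' @param table feature table (`sample_id` first column).
#' @param mask a `penalization_matrix` (see [build_penalization_mask()]).
#' @return the filtered feature table, with attribute `strata_sizes` giving
#'   per-stratum retained column counts.
#' @export
apply_penalization <- function(table, mask) {
  validate_penalization_mask(mask)
  ids <- parse_feature_id(names(table)[-1L])
  mask_key <- make_feature_id(mask$condition, mask$cell_type, mask$marker)
  hit <- match(ids$feature, mask_key)
  if (anyNA(hit)) {
    stop("penalization mask does not cover feature(s): ",
         paste(utils::head(ids$feature[is.na(hit)], 5L), collapse = ", "),
         call. = FALSE)
  }
  keep <- mask$include[hit] == 1L
  out <- table[, c(TRUE, keep), drop = FALSE]
  kept_ids <- ids[keep, , drop = FALSE]
  sizes <- base::table(factor(kept_ids$stratum,
                              levels = c("freq", "Unstim", "LPS", "IL246",
                                         "IL18")))
  attr(out, "strata_sizes") <- c(as.integer(sizes), sum(sizes))
  names(attr(out, "strata_sizes")) <- c(names(sizes), "total")
  out
}

#' Split a feature table into stimulation strata
#'
#' @param table feature table with canonical `stratum|cell_type|marker` ids.
#' @return named list of feature tables, one per stratum present, in
#'   canonical stratum order.
#' @export
split_strata <- function(table) {
  ids <- parse_feature_id(names(table)[-1L])
  strata <- c("freq", "Unstim", "LPS", "IL246", "IL18")
  present <- strata[strata %in% ids$stratum]
  out <- lapply(present, function(s) {
    table[, c(TRUE, ids$stratum == s), drop = FALSE]
  })
  names(out) <- present
  out
}

#' Read / write a feature table as wide CSV
#'
#' First column `sample_id`, remaining columns canonical feature ids.
#'
#' @param path file path.
#' @return `read_feature_table`: the feature table data.frame.
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(out)[1L], "sample_id")) {
    stop("feature CSV must start with a sample_id column", call. = FALSE)
  }
  out$sample_id <- as.character(out$sample_id)
  out
}

#' @rdname read_feature_table
#' @param table feature table to write.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
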