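# Default immune-population and functional-marker vocabulary, the canonical
# feature space, and the prior-knowledge penalization mask.

#' Default immune cell populations
#'
#' The 35 gated populations the feature space is built over: 33 mononuclear
#' subsets (monocyte, dendritic-cell, NK, NKT-like, B, CD4/CD8 T naive and
#' memory, Treg, gamma-delta T, MAIT and related subsets) plus 2 granulocyte
#' subsets. Frequencies of mononuclear subsets are expressed as a percentage
#' of mononuclear cells; granulocyte subsets as a percentage of all singlet
#' leukocytes.
#'
#' @return character vector of 35 population names.
#' @export
default_cell_types <- function() {
  c(
    # myeloid mononuclear
    "cMC", "intMC", "ncMC", "mDC", "pDC", "Basophils",
    # NK / NKT
    "NK_CD56bright", "NK_CD56dim", "NK_CD16hi", "NKT_like",
    # B lineage
    "Bcells", "Plasmablasts",
    # CD4 T
    "Tfh", "CD4T_naive", "CD4T_cm", "CD4T_em", "CD4T_emra",
    "Th1", "Th2", "Th17", "Treg_naive", "Treg_mem",
    # CD8 and unconventional T
    "CD8T_naive", "CD8T_cm", "CD8T_em", "CD8T_emra", "CD8T_CD161",
    "gdT", "MAIT", "DNT", "DPT",
    # innate lymphoid / progenitor
    "ILC", "HSPC",
    # granulocytes (frequency denominator: singlet leukocytes)
    "Neutrophils", "Eosinophils"
  )
}

#' Default granulocyte populations
#' @return character vector (subset of [default_cell_types()]).
#' @export
default_granulocyte_types <- function() c("Neutrophils", "Eosinophils")

#' Default functional / intracellular markers
#'
#' The 20 signaling, metabolic, chemotactic and activation read-outs used as
#' functional features: phospho-proteins of the JAK/STAT, MyD88/NF-kB,
#' MAPK/ERK, mTOR and TCR pathways, metabolic enzymes and transporters, and
#' chemotaxis/activation surface markers treated as functional read-outs.
#'
#' @return character vector of 20 marker names.
#' @export
default_markers <- function() {
  c("pCREB", "pERK", "pNFkB", "pPLCg1", "pp38", "pS6",
    "pSTAT1", "pSTAT3", "pSTAT5", "pSTAT6",
    "GLUT1", "HK2", "CPT1a", "VDAC1",
    "CXCR4", "CD62L", "Ki67", "PDL1", "CD63", "CD44")
}

#' Stimulation conditions
#' @return character vector: unstimulated, LPS, IL-2/IL-4/IL-6 cocktail, IL-18.
#' @export
default_conditions <- function() c("Unstim", "LPS", "IL246", "IL18")

# Marker pathway classes used by the knowledge-based mask scores.
marker_classes <- function(markers = default_markers()) {
  cls <- c(
    pCREB = "creb_myd88", pERK = "mapk", pNFkB = "myd88", pPLCg1 = "tcr",
    pp38 = "mapk", pS6 = "mtor",
    pSTAT1 = "jakstat", pSTAT3 = "jakstat", pSTAT5 = "jakstat",
    pSTAT6 = "jakstat",
    GLUT1 = "metabolic", HK2 = "metabolic", CPT1a = "metabolic",
    VDAC1 = "metabolic",
    CXCR4 = "chemotaxis", CD62L = "chemotaxis",
    Ki67 = "activation", PDL1 = "activation", CD63 = "activation",
    CD44 = "activation"
  )
  out <- cls[markers]
  out[is.na(out)] <- "activation"
  names(out) <- markers
  out
}

cell_classes <- function(cell_types = default_cell_types()) {
  myeloid <- c("cMC", "intMC", "ncMC", "mDC", "pDC", "Basophils",
               "Neutrophils", "Eosinophils")
  nk <- c("NK_CD56bright", "NK_CD56dim", "NK_CD16hi", "NKT_like")
  b <- c("Bcells", "Plasmablasts")
  out <- ifelse(cell_types %in% myeloid, "myeloid",
         ifelse(cell_types %in% nk, "nk",
         ifelse(cell_types %in% b, "b", "t")))
  names(out) <- cell_types
  out
}

# Plausibility score of a (cell type, marker) response to a stimulation:
# product of a receptor-expression weight per cell class and a
# pathway-proximity weight per marker class. Larger = more strongly supported
# by canonical receptor-to-pathway knowledge; middling scores encode
# "prior knowledge unclear" (retained when the stratum budget allows).
condition_knowledge_score <- function(cell_type, marker, condition,
                                      cell_cls = cell_classes(),
                                      mark_cls = marker_classes()) {
  cc <- cell_cls[cell_type]
  mc <- mark_cls[marker]
  cw <- switch(condition,
    # LPS engages TLR4/MyD88, essentially myeloid-restricted
    LPS   = c(myeloid = 3, nk = 1.6, b = 1.2, t = 1)[cc],
    # the IL-2/IL-4/IL-6 cocktail drives JAK/STAT broadly
    IL246 = c(myeloid = 2.6, nk = 2.4, b = 2.4, t = 3)[cc],
    # IL-18R signals via MyD88 mainly in NK/NKT and T/myeloid subsets
    IL18  = c(myeloid = 2.2, nk = 3, b = 1, t = 2.4)[cc],
    stop("unknown condition: ", condition, call. = FALSE)
  )
  mw <- switch(condition,
    LPS   = c(myd88 = 3, creb_myd88 = 3, mapk = 2.8, mtor = 2.4,
              metabolic = 2, chemotaxis = 2, activation = 1.6,
              jakstat = 1, tcr = 1)[mc],
    IL246 = c(jakstat = 3, mtor = 2.6, mapk = 2.2, creb_myd88 = 2.2,
              metabolic = 2, chemotaxis = 2, activation = 1.8,
              myd88 = 1.4, tcr = 1.2)[mc],
    IL18  = c(myd88 = 3, creb_myd88 = 3, mapk = 2.6, mtor = 2.2,
              metabolic = 2.2, chemotaxis = 2, activation = 1.6,
              jakstat = 1.2, tcr = 1)[mc]
  )
  unname(cw * mw)
}

#' Build a prior-knowledge penalization mask
#'
#' Constructs the binary include/exclude mask over
#' (cell type, marker, condition) combinations plus the frequency stratum.
#' Endogenous (unstimulated) features and frequencies are always retained.
#' For each stimulation the mask keeps the `strata_sizes` top-scoring
#' combinations under a documented receptor-to-pathway knowledge score
#' (ties broken by canonical cell-type then marker order), so the per-stratum
#' retained totals are explicit configuration mirroring the granularity of
#' expert curation.
#'
#' @param cell_types,markers character vectors defining the grid.
#' @param strata_sizes named integer vector: retained feature counts for the
#'   `LPS`, `IL246` and `IL18` strata (defaults 248, 635, 554; the `freq`
#'   and `Unstim` strata are fully retained).
#' @return data.frame with columns `cell_type`, `marker`, `condition`,
#'   `include` (0/1), of class `penalization_matrix`. Frequency rows use
#'   marker `"frequency"` and condition `"freq"`.
#' @export
build_penalization_mask <- function(cell_types = default_cell_types(),
                                    markers = default_markers(),
                                    strata_sizes = c(LPS = 248, IL246 = 635,
                                                     IL18 = 554)) {
  grid_size <- length(cell_types) * length(markers)
  for (cond in names(strata_sizes)) {
    if (strata_sizes[[cond]] > grid_size) {
      stop(sprintf("strata_sizes[%s] = %d exceeds the %d-cell grid",
                   cond, strata_sizes[[cond]], grid_size), call. = FALSE)
    }
  }
  ccls <- cell_classes(cell_types)
  mcls <- marker_classes(markers)
  rows <- list()
  # frequency stratum: always included
  rows$freq <- data.frame(
    cell_type = cell_types, marker = "frequency", condition = "freq",
    include = 1L, stringsAsFactors = FALSE
  )
  grid <- expand.grid(marker = markers, cell_type = cell_types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("cell_type", "marker")]
  rows$Unstim <- data.frame(grid, condition = "Unstim", include = 1L,
                            stringsAsFactors = FALSE)
  for (cond in c("LPS", "IL246", "IL18")) {
    sc <- mapply(condition_knowledge_score, grid$cell_type, grid$marker,
                 MoreArgs = list(condition = cond, cell_cls = ccls,
                                 mark_cls = mcls))
    keep_n <- strata_sizes[[cond]]
    ord <- order(-sc, match(grid$cell_type, cell_types),
                 match(grid$marker, markers))
    include <- integer(nrow(grid))
    include[ord[seq_len(keep_n)]] <- 1L
    rows[[cond]] <- data.frame(grid, condition = cond, include = include,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("penalization_matrix", class(out))
  out
}

#' Read / write a penalization mask as long-format CSV
#'
#' The CSV carries columns `cell_type`, `marker`, `condition`,
#' `include` (0/1); frequency rows use condition `"freq"` and marker
#' `"frequency"`.
#'
#' @param path file path.
#' @return `read_penalization_mask`: a `penalization_matrix` data.frame.
#' @export
read_penalization_mask <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_type", "marker", "condition", "include")
  if (!all(required %in% names(m))) {
    stop("mask CSV must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  validate_penalization_mask(m)
  class(m) <- c("penalization_matrix", class(m))
  m
}

#' @rdname read_penalization_mask
#' @param mask a `penalization_matrix`.
#' @export
write_penalization_mask <- function(mask, path) {
  utils::write.csv(as.data.frame(mask), path, row.names = FALSE)
  invisible(path)
}

validate_penalization_mask <- function(mask) {
  if (!all(mask$include %in% c(0L, 1L))) {
    stop("penalization mask values must be 0 or 1", call. = FALSE)
  }
  dup <- duplicated(mask[, c("cell_type", "marker", "condition")])
  if (any(dup)) stop("duplicated mask entries", call. = FALSE)
  invisible(mask)
}

# Feature ids retained by a mask, in canonical column order: strata in the
# order freq, Unstim, LPS, IL246, IL18; within a stratum, cell types in the
# configured order, then markers alphabetically.
mask_feature_ids <- function(mask, cell_types = default_cell_types()) {
  kept <- mask[mask$include == 1L, , drop = FALSE]
  strata <- c("freq", "Unstim", "LPS", "IL246", "IL18")
  kept <- kept[order(match(kept$condition, strata),
                     match(kept$cell_type, cell_types),
                     kept$marker), , drop = FALSE]
  make_feature_id(kept$condition, kept$cell_type, kept$marker)
}

#' Per-stratum retained feature counts of a mask
#'
#' @param mask a `penalization_matrix`.
#' @return named integer vector over the five strata (freq, Unstim, LPS,
#'   IL246, IL18), plus a `total`.
#' @export
mask_strata_sizes <- function(mask) {
  strata <- c("freq", "Unstim", "LPS", "IL246", "IL18")
  n <- vapply(strata, function(s) sum(mask$include[mask$condition == s]),
              integer(1))
  c(n, total = sum(n))
}
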