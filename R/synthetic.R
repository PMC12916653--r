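# Seeded synthetic-data generator: cell-level event tables and sample-level
# feature tables with the statistical structure the analysis assumes
# (case/control cohorts, stimulation-specific signaling shifts, planted
# effects, demographically realistic confounders).

default_base_proportions <- function(cell_types) {
  base <- c(
    cMC = 15, intMC = 1.5, ncMC = 2, mDC = 1, pDC = 0.5, Basophils = 0.5,
    NK_CD56bright = 1, NK_CD56dim = 8, NK_CD16hi = 1, NKT_like = 2,
    Bcells = 6, Plasmablasts = 0.5,
    Tfh = 1, CD4T_naive = 12, CD4T_cm = 8, CD4T_em = 6, CD4T_emra = 1,
    Th1 = 2, Th2 = 2, Th17 = 1, Treg_naive = 1, Treg_mem = 2,
    CD8T_naive = 6, CD8T_cm = 3, CD8T_em = 4, CD8T_emra = 2,
    CD8T_CD161 = 1, gdT = 2, MAIT = 2, DNT = 1, DPT = 0.3,
    ILC = 0.2, HSPC = 0.2
  )
  out <- base[cell_types]
  out[is.na(out)] <- 1
  names(out) <- cell_types
  out / sum(out)
}

#' Default canonical stimulation-response map
#'
#' The (condition, cell type, marker) shifts the generator plants as
#' canonical responses: LPS-driven MyD88 signaling (pCREB, pNFkB, pERK,
#' pp38, pS6) in monocyte and dendritic-cell subsets; IL-18-driven pCREB /
#' pNFkB / pp38 in NK and NKT-like cells; and IL-2/IL-4/IL-6-driven STAT
#' phosphorylation in monocytes and T-cell subsets.
#'
#' @return data.frame with columns `condition`, `cell_type`, `marker`,
#'   `log_fc` (multiplicative shift on the raw intensity scale, natural log).
#' @export
default_response_map <- function() {
  entry <- function(condition, cell_types, markers, log_fc) {
    expand.grid(condition = condition, cell_type = cell_types,
                marker = markers, log_fc = log_fc,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  rbind(
    entry("LPS", c("cMC", "intMC", "ncMC", "mDC"),
          c("pCREB", "pNFkB", "pERK", "pp38", "pS6"), log(2.5)),
    entry("IL18", c("NK_CD56bright", "NK_CD56dim", "NK_CD16hi", "NKT_like"),
          c("pCREB", "pNFkB", "pp38"), log(2)),
    entry("IL246", c("cMC", "intMC", "ncMC",
                     "CD4T_naive", "CD4T_cm", "CD4T_em", "CD8T_naive",
                     "CD8T_cm", "CD8T_em", "Treg_naive", "Treg_mem"),
          c("pSTAT1", "pSTAT3", "pSTAT5", "pSTAT6"), log(2))
  )
}

#' Planted case/control effect
#'
#' @param stratum one of freq, Unstim, LPS, IL246, IL18.
#' @param cell_type,marker target feature coordinates (marker is
#'   `"frequency"` for the freq stratum).
#' @param effect standardized mean shift (case minus control) on the derived
#'   feature scale; sign gives the direction.
#' @return one-row data.frame.
#' @export
planted_effect <- function(stratum, cell_type, marker, effect) {
  if (!is.finite(effect)) stop("effect size must be finite", call. = FALSE)
  data.frame(stratum = stratum, cell_type = cell_type, marker = marker,
             effect = effect, stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Defines the data-generating conditions for one case/control cohort:
#' population structure, marker intensity law (log-normal on the raw scale,
#' so stimulation acts multiplicatively and approximately additively on the
#' arcsinh scale), canonical stimulation responses, planted case effects and
#' the demographic confounder model. Default cohort sizes follow the three
#' study groups (AP 28/38, PP 42/37, ML 70/74).
#'
#' @param cohort one of "AP", "PP", "ML" (antepartum / postpartum / midlife).
#' @param n_cases,n_controls arm sizes (defaults: the cohort's study sizes).
#' @param cell_types,markers,conditions feature-space vocabulary; the first
#'   condition is the unstimulated reference.
#' @param granulocyte_types subset of `cell_types` simulated outside the
#'   mononuclear simplex.
#' @param cells_per_sample mononuclear events per aliquot (default 1000).
#' @param concentration Dirichlet concentration of per-sample population
#'   proportions (strictly positive; default 1000).
#' @param granulocyte_fraction expected granulocyte share of singlet
#'   leukocytes (default 0.55).
#' @param baseline_location,baseline_scale log-normal meanlog and sdlog of
#'   raw marker intensities across cells (defaults log(10), 0.6); a matrix
#'   over (cell type, marker) is accepted for `baseline_location`.
#' @param sigma_sample between-sample SD of log baseline intensity (0.25).
#' @param sigma_response between-sample SD of log stimulation shift (0.2).
#' @param sigma_freq between-sample SD of log population weight (0.3).
#' @param response_map canonical response table ([default_response_map()]);
#'   pass a zero-row data.frame for a null generator.
#' @param planted_effects data.frame of [planted_effect()] rows.
#' @param confounder_model per-variable, per-arm distribution parameters in
#'   the [hdp_cohort_summaries()] layout (defaults: this cohort's rows).
#' @param strata_sizes per-stratum feature counts for the sample-level
#'   generator (default c(freq = 35, Unstim = 700, LPS = 248, IL246 = 635,
#'   IL18 = 554)).
#' @param block_size,rho block-correlation structure of the sample-level
#'   generator: features within consecutive blocks of `block_size` share a
#'   latent factor with correlation `rho`.
#' @param seed integer seed; identical seed + config gives bitwise-identical
#'   tables.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(cohort = c("AP", "PP", "ML"),
                             n_cases = NULL, n_controls = NULL,
                             cell_types = default_cell_types(),
                             markers = default_markers(),
                             conditions = default_conditions(),
                             granulocyte_types = default_granulocyte_types(),
                             cells_per_sample = 1000L,
                             concentration = 1000,
                             granulocyte_fraction = 0.55,
                             baseline_location = log(10),
                             baseline_scale = 0.6,
                             sigma_sample = 0.25,
                             sigma_response = 0.2,
                             sigma_freq = 0.3,
                             response_map = default_response_map(),
                             planted_effects = NULL,
                             confounder_model = NULL,
                             strata_sizes = c(freq = 35, Unstim = 700,
                                              LPS = 248, IL246 = 635,
                                              IL18 = 554),
                             block_size = 10L, rho = 0.3,
                             seed = 1L) {
  cohort <- match.arg(cohort)
  study_sizes <- list(AP = c(28L, 38L), PP = c(42L, 37L), ML = c(70L, 74L))
  n_cases <- as.integer(n_cases %||% study_sizes[[cohort]][1L])
  n_controls <- as.integer(n_controls %||% study_sizes[[cohort]][2L])
  cells_per_sample <- stopifnot_scalar_count(cells_per_sample,
                                             "cells_per_sample")
  if (concentration <= 0) {
    stop("concentration (Dirichlet parameter scale) must be > 0",
         call. = FALSE)
  }
  if (!all(granulocyte_types %in% cell_types)) {
    stop("granulocyte_types must be a subset of cell_types", call. = FALSE)
  }
  mono <- setdiff(cell_types, granulocyte_types)
  if (is.null(confounder_model)) {
    cm <- hdp_cohort_summaries()
    confounder_model <- cm[cm$cohort == cohort &
                             cm$variable != "nulli_primiparous", ]
  }
  if (any(stats::na.omit(confounder_model$sd) < 0)) {
    stop("confounder SDs must be non-negative", call. = FALSE)
  }
  cfg <- structure(list(
    cohort = cohort, n_cases = n_cases, n_controls = n_controls,
    cell_types = cell_types, markers = markers, conditions = conditions,
    granulocyte_types = granulocyte_types, mononuclear_types = mono,
    cells_per_sample = cells_per_sample, concentration = concentration,
    granulocyte_fraction = granulocyte_fraction,
    base_proportions = default_base_proportions(mono),
    baseline_location = baseline_location, baseline_scale = baseline_scale,
    sigma_sample = sigma_sample, sigma_response = sigma_response,
    sigma_freq = sigma_freq,
    response_map = response_map,
    planted_effects = planted_effects,
    confounder_model = confounder_model,
    strata_sizes = strata_sizes, block_size = as.integer(block_size),
    rho = rho, seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_planted_effects(cfg)
  cfg
}

# Feature ids of the sample-level generator: frequency and endogenous strata
# truncated in canonical order, stimulation strata by knowledge-score rank
# (so the default sizes reproduce the canonical penalized feature space).
feature_space_ids <- function(config) {
  sz <- config$strata_sizes
  mask <- build_penalization_mask(
    config$cell_types, config$markers,
    strata_sizes = pmin(sz[c("LPS", "IL246", "IL18")],
                        length(config$cell_types) * length(config$markers)))
  ids <- mask_feature_ids(mask, config$cell_types)
  info <- parse_feature_id(ids)
  keep <- unlist(lapply(c("freq", "Unstim", "LPS", "IL246", "IL18"),
                        function(s) {
    utils::head(which(info$stratum == s), sz[[s]])
  }))
  ids[sort(keep)]
}

validate_planted_effects <- function(config) {
  pe <- config$planted_effects
  if (is.null(pe) || nrow(pe) == 0L) return(invisible(config))
  if (!all(is.finite(pe$effect))) stop("effect sizes must be finite",
                                       call. = FALSE)
  space <- feature_space_ids(config)
  ids <- make_feature_id(pe$stratum, pe$cell_type, pe$marker)
  missing <- setdiff(ids, space)
  if (length(missing) > 0L) {
    stop("planted effect targets feature(s) outside the configured ",
         "(penalized) feature space: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(config)
}

#' Save / load a synthetic configuration as YAML
#'
#' Serializes the scalar and tabular generator settings; the YAML round
#' trip reproduces an equivalent configuration (validated on load).
#'
#' @param config a [synthetic_config()].
#' @param path file path.
#' @export
save_synthetic_config <- function(config, path) {
  ser <- list(
    cohort = config$cohort, n_cases = config$n_cases,
    n_controls = config$n_controls,
    cell_types = config$cell_types, markers = config$markers,
    conditions = config$conditions,
    granulocyte_types = config$granulocyte_types,
    cells_per_sample = config$cells_per_sample,
    concentration = config$concentration,
    granulocyte_fraction = config$granulocyte_fraction,
    baseline_location = as.numeric(config$baseline_location),
    baseline_scale = config$baseline_scale,
    sigma_sample = config$sigma_sample,
    sigma_response = config$sigma_response,
    sigma_freq = config$sigma_freq,
    response_map = as.list(config$response_map),
    planted_effects = if (!is.null(config$planted_effects)) {
      as.list(config$planted_effects)
    },
    strata_sizes = as.list(config$strata_sizes),
    block_size = config$block_size, rho = config$rho, seed = config$seed
  )
  yaml::write_yaml(ser, path, precision = 17L)
  invisible(path)
}

#' @rdname save_synthetic_config
#' @return `load_synthetic_config`: a validated `synthetic_config`.
#' @export
load_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  synthetic_config(
    cohort = raw$cohort, n_cases = raw$n_cases,
    n_controls = raw$n_controls,
    cell_types = unlist(raw$cell_types), markers = unlist(raw$markers),
    conditions = unlist(raw$conditions),
    granulocyte_types = unlist(raw$granulocyte_types),
    cells_per_sample = raw$cells_per_sample,
    concentration = raw$concentration,
    granulocyte_fraction = raw$granulocyte_fraction,
    baseline_location = if (length(raw$baseline_location) == 1L) {
      raw$baseline_location
    } else {
      matrix(unlist(raw$baseline_location),
             nrow = length(unlist(raw$cell_types)),
             dimnames = list(unlist(raw$cell_types), unlist(raw$markers)))
    },
    baseline_scale = raw$baseline_scale,
    sigma_sample = raw$sigma_sample,
    sigma_response = raw$sigma_response, sigma_freq = raw$sigma_freq,
    response_map = as.data.frame(raw$response_map,
                                 stringsAsFactors = FALSE),
    planted_effects = if (!is.null(raw$planted_effects)) {
      as.data.frame(raw$planted_effects, stringsAsFactors = FALSE)
    },
    strata_sizes = unlist(raw$strata_sizes),
    block_size = raw$block_size, rho = raw$rho, seed = raw$seed
  )
}

# --- confounders ------------------------------------------------------------

#' Generate per-sample confounder records
#'
#' Draws the demographic confounders (BMI, maternal age, parity, gestational
#' diabetes, systolic/diastolic blood pressure, visit timing) from
#' arm-specific normal (continuous) or Bernoulli (binary) models, and HDP
#' subtype fields for cases from cohort-specific subtype proportions.
#'
#' @param config a [synthetic_config()].
#' @return metadata data.frame: `sample_id`, `cohort`, `outcome`
#'   (case/control), confounders, and subtype fields (cases only).
#' @export
generate_confounders <- function(config) {
  n <- config$n_cases + config$n_controls
  outcome <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  sample_id <- sprintf("%s_%s%03d", config$cohort,
                       ifelse(outcome == "case", "S", "C"), seq_len(n))
  out <- data.frame(sample_id = sample_id, cohort = config$cohort,
                    outcome = outcome, stringsAsFactors = FALSE)
  cm <- config$confounder_model
  with_seed(child_seed(config$seed, 101L), {
    for (v in unique(cm$variable)) {
      vals <- numeric(n)
      for (arm in c("case", "control")) {
        row <- cm[cm$variable == v & cm$arm == arm, ]
        if (nrow(row) != 1L) {
          stop("confounder model needs one ", arm, " row for ", v,
               call. = FALSE)
        }
        idx <- which(outcome == arm)
        if (row$type == "binary") {
          vals[idx] <- stats::rbinom(length(idx), 1L, row$count / row$n)
        } else if (row$sd == 0) {
          vals[idx] <- row$mean
        } else {
          vals[idx] <- stats::rnorm(length(idx), row$mean, row$sd)
        }
      }
      out[[v]] <- vals
    }
    out <- cbind(out, draw_subtypes(config, outcome))
  })
  out
}

# Cohort-specific HDP subtype frequencies (preterm onset, early vs late
# onset, gestational hypertension vs preeclampsia, severity, HELLP).
subtype_rates <- function(cohort) {
  switch(cohort,
    AP = list(preterm = 27 / 28, early = 23 / 28, gh = 4 / 28,
              mild = 6 / 24, hellp = 1 / 24),
    PP = list(preterm = 24 / 42, early = 16 / 42, gh = 8 / 42,
              mild = 10 / 34, hellp = 1 / 34),
    ML = list(preterm = 30 / 70, early = 10 / 70, gh = 9 / 70,
              mild = 27 / 61, hellp = 5 / 61))
}

draw_subtypes <- function(config, outcome) {
  n <- length(outcome)
  rates <- subtype_rates(config$cohort)
  preterm <- rep(NA, n); onset <- rep(NA_character_, n)
  subtype <- rep(NA_character_, n); severity <- rep(NA_character_, n)
  cases <- which(outcome == "case")
  preterm[cases] <- stats::rbinom(length(cases), 1L, rates$preterm) == 1L
  onset[cases] <- ifelse(stats::rbinom(length(cases), 1L, rates$early) == 1L,
                         "early", "late")
  gh <- stats::rbinom(length(cases), 1L, rates$gh) == 1L
  hellp <- !gh & stats::rbinom(length(cases), 1L, rates$hellp) == 1L
  subtype[cases] <- ifelse(gh, "GH", ifelse(hellp, "HELLP", "PE"))
  pe <- which(subtype == "PE")
  severity[pe] <- ifelse(stats::rbinom(length(pe), 1L, rates$mild) == 1L,
                         "mild", "severe")
  data.frame(preterm_onset = preterm, onset = onset, hdp_subtype = subtype,
             pe_severity = severity, stringsAsFactors = FALSE)
}

# --- event-level generator --------------------------------------------------

baseline_location_matrix <- function(config) {
  loc <- config$baseline_location
  if (is.matrix(loc)) return(loc)
  matrix(loc, nrow = length(config$cell_types),
         ncol = length(config$markers),
         dimnames = list(config$cell_types, config$markers))
}

planted_by_stratum <- function(config, stratum) {
  pe <- config$planted_effects
  if (is.null(pe)) return(pe)
  pe[pe$stratum == stratum, , drop = FALSE]
}

#' Generate a synthetic gated event table
#'
#' Simulates one aliquot per (sample, stimulation condition): mononuclear
#' cell-type counts are Dirichlet-multinomial around sample-specific
#' logistic-normal proportions, granulocytes form an extra stratum outside
#' the mononuclear simplex, and raw marker intensities are log-normal with
#' multiplicative condition shifts from the canonical response map. Planted
#' case effects are additional shifts applied to case samples only, scaled
#' so the derived-feature group difference approximates the configured
#' standardized effect.
#'
#' @param config a [synthetic_config()].
#' @return list with `events` (one row per cell: `sample_id`, `condition`,
#'   `cell_type`, marker columns) and `metadata`
#'   (see [generate_confounders()]).
#' @export
generate_events <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_planted_effects(config)
  metadata <- generate_confounders(config)
  is_case <- metadata$outcome == "case"
  mono <- config$mononuclear_types
  gran <- config$granulocyte_types
  markers <- config$markers
  loc <- baseline_location_matrix(config)
  unstim <- config$conditions[1L]
  stims <- setdiff(config$conditions, unstim)

  pe_freq <- planted_by_stratum(config, "freq")
  resp_shift <- function(cond) {
    rm <- config$response_map
    rm[rm$condition == cond, , drop = FALSE]
  }

  blocks <- vector("list", nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    blocks[[i]] <- with_seed(child_seed(config$seed, 1000L + i), {
      # sample-level population weights (logistic-normal on the simplex)
      lw <- log(config$base_proportions) +
        config$sigma_freq * stats::rnorm(length(mono))
      if (is_case[i] && !is.null(pe_freq) && nrow(pe_freq) > 0L) {
        hit <- match(pe_freq$cell_type, mono)
        lw[hit] <- lw[hit] + pe_freq$effect * config$sigma_freq
      }
      props <- exp(lw - max(lw)); props <- props / sum(props)
      alpha <- config$concentration * props
      # sample-level baseline intensity effects, shared across aliquots
      samp_eff <- matrix(config$sigma_sample *
                           stats::rnorm(length(config$cell_types) *
                                          length(markers)),
                         nrow = length(config$cell_types),
                         dimnames = list(config$cell_types, markers))
      gfrac <- stats::plogis(stats::qlogis(config$granulocyte_fraction) +
                               0.3 * stats::rnorm(1))
      rows <- list()
      for (cond in config$conditions) {
        p <- stats::rgamma(length(alpha), alpha)
        p <- p / sum(p)
        counts <- as.integer(stats::rmultinom(1L, config$cells_per_sample,
                                              p))
        n_gran_total <- round(config$cells_per_sample * gfrac / (1 - gfrac))
        gran_counts <- as.integer(stats::rmultinom(
          1L, n_gran_total, c(0.93, rep(0.07 / max(1, length(gran) - 1),
                                        length(gran) - 1))))
        all_types <- c(mono, gran)
        all_counts <- c(counts, gran_counts)
        shift <- matrix(0, nrow = length(all_types), ncol = length(markers),
                        dimnames = list(all_types, markers))
        if (cond != unstim) {
          rs <- resp_shift(cond)
          if (nrow(rs) > 0L) {
            ok <- rs$cell_type %in% all_types & rs$marker %in% markers
            rs <- rs[ok, , drop = FALSE]
            shift[cbind(rs$cell_type, rs$marker)] <-
              shift[cbind(rs$cell_type, rs$marker)] + rs$log_fc
          }
          # between-sample response variability
          shift <- shift + config$sigma_response *
            matrix(stats::rnorm(length(shift)), nrow = nrow(shift))
          pe_r <- planted_by_stratum(config, cond)
          if (is_case[i] && !is.null(pe_r) && nrow(pe_r) > 0L) {
            ok <- pe_r$cell_type %in% all_types & pe_r$marker %in% markers
            pe_r <- pe_r[ok, , drop = FALSE]
            shift[cbind(pe_r$cell_type, pe_r$marker)] <-
              shift[cbind(pe_r$cell_type, pe_r$marker)] +
              pe_r$effect * config$sigma_response
          }
        }
        pe_u <- planted_by_stratum(config, "Unstim")
        if (is_case[i] && !is.null(pe_u) && nrow(pe_u) > 0L) {
          # endogenous shifts apply to every aliquot so responses cancel
          shift[cbind(pe_u$cell_type, pe_u$marker)] <-
            shift[cbind(pe_u$cell_type, pe_u$marker)] +
            pe_u$effect * config$sigma_sample
        }
        keep <- all_counts > 0L
        for (t in which(keep)) {
          type <- all_types[t]
          nc <- all_counts[t]
          meanlog <- loc[type, ] + samp_eff[type, ] + shift[type, ]
          intens <- matrix(stats::rlnorm(nc * length(markers),
                                         meanlog = rep(meanlog, each = nc),
                                         sdlog = config$baseline_scale),
                           nrow = nc)
          colnames(intens) <- markers
          rows[[paste(cond, type)]] <- data.frame(
            sample_id = metadata$sample_id[i], condition = cond,
            cell_type = type, intens, stringsAsFactors = FALSE,
            check.names = FALSE)
        }
      }
      do.call(rbind, rows)
    })
  }
  events <- do.call(rbind, blocks)
  rownames(events) <- NULL
  list(events = events, metadata = metadata)
}

# --- sample-level generator -------------------------------------------------

#' Generate a synthetic per-sample feature table directly
#'
#' Sample-level shortcut bypassing cell simulation: non-frequency features
#' are drawn from a block-correlated Gaussian model on the arcsinh scale,
#' frequency features from a logistic-normal simplex (mononuclear subsets,
#' in percent) plus an independent granulocyte stratum. Planted case effects
#' are standardized mean shifts on the derived-feature scale.
#'
#' @param config a [synthetic_config()]; `strata_sizes` controls the
#'   feature-space dimensions (defaults 35/700/248/635/554).
#' @return list with `features` (feature table), `metadata`, and
#'   `feature_info` (parsed feature ids).
#' @export
generate_feature_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_planted_effects(config)
  metadata <- generate_confounders(config)
  n <- nrow(metadata)
  is_case <- metadata$outcome == "case"
  ids <- feature_space_ids(config)
  info <- parse_feature_id(ids)
  p <- length(ids)
  pe <- config$planted_effects
  pe_ids <- if (is.null(pe)) character(0) else
    make_feature_id(pe$stratum, pe$cell_type, pe$marker)

  x <- matrix(NA_real_, nrow = n, ncol = p,
              dimnames = list(metadata$sample_id, ids))
  with_seed(child_seed(config$seed, 202L), {
    is_freq <- info$stratum == "freq"
    # frequency stratum: logistic-normal mononuclear simplex in percent
    if (any(is_freq)) {
      ftypes <- info$cell_type[is_freq]
      fmono <- ftypes[ftypes %in% config$mononuclear_types]
      base <- default_base_proportions(fmono)
      lw <- matrix(log(base), nrow = n, ncol = length(fmono), byrow = TRUE)
      lw <- lw + config$sigma_freq * matrix(stats::rnorm(n * length(fmono)),
                                            nrow = n)
      if (length(pe_ids) > 0L) {
        for (k in which(pe$stratum == "freq")) {
          j <- match(pe$cell_type[k], fmono)
          lw[is_case, j] <- lw[is_case, j] + pe$effect[k] * config$sigma_freq
        }
      }
      w <- exp(lw)
      pr <- 100 * w / rowSums(w)
      for (j in seq_along(fmono)) {
        x[, make_feature_id("freq", fmono[j], "frequency")] <- pr[, j]
      }
      fgran <- ftypes[ftypes %in% config$granulocyte_types]
      if (length(fgran) > 0L) {
        gbase <- 100 * config$granulocyte_fraction *
          c(0.93, rep(0.07 / max(1, length(fgran) - 1),
                      length(fgran) - 1))[seq_along(fgran)]
        for (j in seq_along(fgran)) {
          vals <- gbase[j] * exp(config$sigma_freq * stats::rnorm(n))
          x[, make_feature_id("freq", fgran[j], "frequency")] <-
            pmin(vals, 100)
        }
      }
    }
    # signaling strata: block-correlated Gaussian on the arcsinh scale
    for (s in c("Unstim", "LPS", "IL246", "IL18")) {
      jj <- which(info$stratum == s)
      if (length(jj) == 0L) next
      mu <- if (s == "Unstim") 1.5 else 0.3
      sd_j <- 0.5
      nb <- ceiling(length(jj) / config$block_size)
      bfac <- matrix(stats::rnorm(n * nb), nrow = n)
      block_of <- rep(seq_len(nb), each = config$block_size,
                      length.out = length(jj))
      eps <- matrix(stats::rnorm(n * length(jj)), nrow = n)
      z <- sqrt(config$rho) * bfac[, block_of, drop = FALSE] +
        sqrt(1 - config$rho) * eps
      xm <- mu + sd_j * z
      if (length(pe_ids) > 0L) {
        for (k in which(pe$stratum == s)) {
          col <- match(pe_ids[k], ids[jj])
          xm[is_case, col] <- xm[is_case, col] + pe$effect[k] * sd_j
        }
      }
      x[, jj] <- xm
    }
  })
  list(features = as_feature_table(x, metadata$sample_id),
       metadata = metadata, feature_info = info)
}
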