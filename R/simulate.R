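#' Ground-truth effect specification
#'
#' Each entry shifts the arcsinh-scale mean of one functional marker in one
#' subset along one design axis: `"stimulation"` (added in every stimulated
#' sample), `"gravity"` (added in every simulated-microgravity sample,
#' stimulated or not), or `"gravity_x_stimulation"` (added only in
#' stimulated microgravity samples, i.e. a pure response-feature shift).
#' The spec doubles as the recovery ground truth for model benchmarking.
#'
#' @param subset,marker,axis,shift equal-length vectors.
#' @return data.frame of class `effect_spec`.
#' @export
effect_spec <- function(subset = character(), marker = character(),
                        axis = character(), shift = numeric()) {
  ax <- c("stimulation", "gravity", "gravity_x_stimulation")
  stopifnot(all(axis %in% ax))
  structure(data.frame(subset = subset, marker = marker, axis = axis,
                       shift = shift, stringsAsFactors = FALSE),
            class = c("effect_spec", "data.frame"))
}

#' Default microgravity effect specification
#'
#' The qualitative single-cell findings used as simulation ground truth:
#' simulated microgravity dampens CD25, CD69 and JAK/STAT (pSTAT1, pSTAT5)
#' responses in CD8 T cell subsets, CD25/CD69 responses in CD56dim CD16+ NK
#' cells and CD69 responses in CD4 T cell subsets, while *increasing* the
#' pSTAT5 response of naive and memory Tregs. All shifts are on the arcsinh
#' scale and act on the gravity-by-stimulation axis.
#'
#' @param magnitude absolute shift size in arcsinh units (default 1).
#' @return An `effect_spec` with 14 entries.
#' @export
default_effect_spec <- function(magnitude = 1.0) {
  dn <- -abs(magnitude); up <- abs(magnitude)
  effect_spec(
    subset = c("Treg naive", "Treg memory",
               "CD8 T naive", "CD8 T naive", "CD8 T naive", "CD8 T naive",
               "CD8 T memory", "CD8 T memory", "CD8 T memory",
               "CD8 T memory",
               "NK CD56dim CD16+", "NK CD56dim CD16+",
               "CD4 T naive", "CD4 T memory"),
    marker = c("pSTAT5", "pSTAT5",
               "CD25", "CD69", "pSTAT1", "pSTAT5",
               "CD25", "CD69", "pSTAT1", "pSTAT5",
               "CD25", "CD69",
               "CD69", "CD69"),
    axis = rep("gravity_x_stimulation", 14),
    shift = c(up, up, dn, dn, dn, dn, dn, dn, dn, dn, dn, dn, dn, dn)
  )
}

#' Default PBMC subset composition
#'
#' Leaf proportions loosely matching healthy adult peripheral blood
#' mononuclear cells; sums to 1 over the default 18-leaf hierarchy.
#'
#' @return Named numeric simplex vector over the 18 default leaves.
#' @export
default_subset_proportions <- function() {
  c("classical MC" = 0.120, "intermediate MC" = 0.030,
    "non-classical MC" = 0.040, "mDC" = 0.015, "pDC" = 0.010,
    "B naive" = 0.060, "B memory" = 0.040,
    "NK CD56dim CD16+" = 0.100, "NK CD56bright CD16-" = 0.020,
    "NKT" = 0.030, "gd T" = 0.030,
    "CD4 T naive" = 0.170, "CD4 T memory" = 0.150,
    "CD8 T naive" = 0.080, "CD8 T memory" = 0.070,
    "Treg naive" = 0.010, "Treg memory" = 0.020,
    "basophil-like Lin-" = 0.005)
}

#' Simulation configuration
#'
#' Defines a complete synthetic CyTOF experiment: donors, cells per sample,
#' subset composition, arcsinh-scale baselines, stimulation responses,
#' injected condition effects, donor random intercepts and barcode bands.
#' Defaults mirror the study design: 8 donors, two gravity conditions,
#' unstimulated (0 h) and ConA/anti-CD28-stimulated (4 h) samples, 5000
#' cells per sample.
#'
#' @param n_donors number of donors (>= 2).
#' @param cells_per_sample events per sample.
#' @param subset_proportions named simplex vector over hierarchy leaves.
#' @param baseline_mean,baseline_sd arcsinh-scale unstimulated functional
#'   marker distribution (scalar, or matrix subset x marker).
#' @param stim_shift arcsinh-scale mean shift added under stimulation
#'   (scalar or subset x marker matrix).
#' @param effects an [effect_spec()]; injected condition effects.
#' @param donor_sd SD of the per-(donor, marker) Gaussian random intercept
#'   shared across a donor's samples.
#' @param donor_response_sd SD of the per-(donor, marker) random slope on
#'   the stimulation response. Unlike the intercept it does not cancel in
#'   the stimulated-minus-unstimulated difference, so it couples the
#'   response features of one marker across subsets within a donor -- the
#'   donor-level responsiveness variation that gives rise to the
#'   marker-dominated communities of the feature correlation network.
#' @param stim_timepoint_h stimulated sampling time (1.5 or 4).
#' @param barcode_pos_meanlog,barcode_neg_meanlog,barcode_sdlog lognormal
#'   raw-intensity bands of positive/negative barcode channels.
#' @param seed integer random seed (mandatory).
#' @param hierarchy,panel gating hierarchy and panel the data are simulated
#'   against.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_donors = 8, cells_per_sample = 5000,
                       subset_proportions = default_subset_proportions(),
                       baseline_mean = 0.5, baseline_sd = 0.3,
                       stim_shift = 1.0,
                       effects = default_effect_spec(),
                       donor_sd = 0.2,
                       donor_response_sd = 0.3,
                       stim_timepoint_h = 4,
                       barcode_pos_meanlog = log(500),
                       barcode_neg_meanlog = 0,
                       barcode_sdlog = 0.3,
                       seed = 1L,
                       hierarchy = build_default_hierarchy(panel),
                       panel = default_panel()) {
  if (n_donors < 2) stop("need n_donors >= 2", call. = FALSE)
  if (abs(sum(subset_proportions) - 1) > 1e-9) {
    stop("subset_proportions must sum to 1", call. = FALSE)
  }
  if (!setequal(names(subset_proportions), hierarchy$leaves)) {
    stop("subset_proportions must be named by the hierarchy leaves",
         call. = FALSE)
  }
  fn <- panel_markers(panel, "functional")
  bad <- !(effects$subset %in% hierarchy$leaves &
           effects$marker %in% fn)
  if (any(bad)) {
    stop("effect entries reference unknown subset/marker: ",
         paste(effects$subset[bad], effects$marker[bad], collapse = "; "),
         call. = FALSE)
  }
  structure(list(
    n_donors = as.integer(n_donors),
    cells_per_sample = as.integer(cells_per_sample),
    subset_proportions = subset_proportions[hierarchy$leaves],
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    stim_shift = stim_shift, effects = effects, donor_sd = donor_sd,
    donor_response_sd = donor_response_sd,
    stim_timepoint_h = stim_timepoint_h,
    barcode_pos_meanlog = barcode_pos_meanlog,
    barcode_neg_meanlog = barcode_neg_meanlog,
    barcode_sdlog = barcode_sdlog,
    seed = as.integer(seed), hierarchy = hierarchy, panel = panel
  ), class = "sim_config")
}

# subset x surface-marker positivity used to draw phenotyping channels;
# must be consistent with the default hierarchy's gate paths
subset_phenotypes <- function(panel, hierarchy) {
  surf <- panel_markers(panel, "surface")
  pheno <- matrix(0L, length(hierarchy$leaves), length(surf),
                  dimnames = list(hierarchy$leaves, surf))
  set_pos <- function(subset, markers) pheno[subset, markers] <<- 1L
  set_pos("gd T", c("CD45", "CD3", "TCRgd", "CD7"))
  set_pos("NKT", c("CD45", "CD3", "CD56", "CD7"))
  set_pos("Treg naive", c("CD45", "CD3", "CD4", "FoxP3", "CD45RA", "CCR7"))
  set_pos("Treg memory", c("CD45", "CD3", "CD4", "FoxP3"))
  set_pos("CD4 T naive",
          c("CD45", "CD3", "CD4", "CD45RA", "CCR7", "CD127", "CD7"))
  set_pos("CD4 T memory", c("CD45", "CD3", "CD4", "CD127", "CD7"))
  set_pos("CD8 T naive", c("CD45", "CD3", "CD8", "CD45RA", "CCR7", "CD7"))
  set_pos("CD8 T memory", c("CD45", "CD3", "CD8", "CD7"))
  set_pos("B naive", c("CD45", "CD19", "CD20", "HLA-DR"))
  set_pos("B memory", c("CD45", "CD19", "CD20", "CD27", "HLA-DR"))
  set_pos("NK CD56dim CD16+", c("CD45", "CD56", "CD16", "CD7"))
  set_pos("NK CD56bright CD16-", c("CD45", "CD56", "CD7"))
  set_pos("classical MC", c("CD45", "CD14", "HLA-DR", "CD11c"))
  set_pos("intermediate MC", c("CD45", "CD14", "CD16", "HLA-DR", "CD11c"))
  set_pos("non-classical MC", c("CD45", "CD16", "HLA-DR", "CD11c"))
  set_pos("mDC", c("CD45", "HLA-DR", "CD11c"))
  set_pos("pDC", c("CD45", "HLA-DR", "CD123"))
  set_pos("basophil-like Lin-", c("CD45", "CD123", "CD38"))
  pheno
}

as_subset_marker_matrix <- function(x, leaves, markers) {
  if (is.matrix(x)) {
    stopifnot(identical(rownames(x), leaves),
              identical(colnames(x), markers))
    return(x)
  }
  matrix(x, length(leaves), length(markers),
         dimnames = list(leaves, markers))
}

#' Simulate a complete synthetic CyTOF experiment
#'
#' For every donor, generates event tables for the four core samples
#' (1G/microgravity x unstimulated/stimulated). Cells are drawn from the
#' configured subset composition; surface markers from well-separated
#' positive/negative arcsinh bands matching each subset's phenotype (so the
#' gating tree recovers membership); functional markers as Gaussians on the
#' arcsinh scale with stimulation shifts, injected condition effects and a
#' donor random intercept, inverse-transformed to nonnegative raw counts.
#' Barcode channels carry the sample's 3-of-6 palladium key as two
#' well-separated lognormal intensity bands.
#'
#' @param config a [sim_config()].
#' @return List with `tables` (list of `event_table`, each carrying
#'   generative truth labels), `effects` (the ground-truth `effect_spec`)
#'   and `scheme` (the barcode scheme used for key assignment).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- config$panel
  hierarchy <- config$hierarchy
  leaves <- hierarchy$leaves
  surf <- panel_markers(panel, "surface")
  fn <- panel_markers(panel, "functional")
  bc <- panel_markers(panel, "barcode")
  cofactor <- panel$cofactor
  bands <- surface_band_defaults()
  pheno <- subset_phenotypes(panel, hierarchy)
  base_mu <- as_subset_marker_matrix(config$baseline_mean, leaves, fn)
  base_sd <- as_subset_marker_matrix(config$baseline_sd, leaves, fn)
  stim_mu <- as_subset_marker_matrix(config$stim_shift, leaves, fn)

  # injected effects as subset x marker matrices per axis
  eff <- list(stimulation = 0 * base_mu, gravity = 0 * base_mu,
              gravity_x_stimulation = 0 * base_mu)
  for (i in seq_len(nrow(config$effects))) {
    e <- config$effects[i, ]
    eff[[e$axis]][e$subset, e$marker] <-
      eff[[e$axis]][e$subset, e$marker] + e$shift
  }

  scheme <- make_barcode_scheme(6, 3)
  donors <- sprintf("D%02d", seq_len(config$n_donors))
  conditions <- expand.grid(stimulation = c("unstim", "ConA/anti-CD28"),
                            gravity = c("1G", "uG"),
                            stringsAsFactors = FALSE)
  tables <- list()
  key_idx <- 0L
  for (d in seq_along(donors)) {
    donor_icpt <- stats::rnorm(length(fn), 0, config$donor_sd)
    names(donor_icpt) <- fn
    donor_slope <- stats::rnorm(length(fn), 0, config$donor_response_sd)
    names(donor_slope) <- fn
    for (ci in seq_len(nrow(conditions))) {
      stim <- conditions$stimulation[ci]
      grav <- conditions$gravity[ci]
      key_idx <- key_idx %% nrow(scheme$keys) + 1L
      n <- config$cells_per_sample
      membership <- sample(leaves, n, replace = TRUE,
                           prob = config$subset_proportions)
      mi <- match(membership, leaves)

      values <- matrix(0, n, nrow(panel$markers),
                       dimnames = list(NULL, panel$markers$name))
      # surface: positive/negative bands per phenotype
      ispos <- pheno[mi, , drop = FALSE] == 1L
      mu_s <- ifelse(ispos, bands$pos_mean, bands$neg_mean)
      sd_s <- ifelse(ispos, bands$pos_sd, bands$neg_sd)
      values[, surf] <- stats::rnorm(n * length(surf), mu_s, sd_s)
      # functional: baseline + axis shifts + donor intercept
      s <- as.numeric(stim != "unstim")
      g <- as.numeric(grav == "uG")
      mu_f <- base_mu[mi, , drop = FALSE] +
        s * (stim_mu[mi, , drop = FALSE] +
               eff$stimulation[mi, , drop = FALSE]) +
        g * eff$gravity[mi, , drop = FALSE] +
        s * g * eff$gravity_x_stimulation[mi, , drop = FALSE]
      mu_f <- sweep(mu_f, 2, donor_icpt[fn] + s * donor_slope[fn], "+")
      values[, fn] <- stats::rnorm(n * length(fn), mu_f,
                                   base_sd[mi, , drop = FALSE])
      # inverse arcsinh to raw scale, floored at zero (ion counts)
      values[, c(surf, fn)] <-
        pmax(sinh(values[, c(surf, fn)]) * cofactor, 0)
      # barcode: lognormal bands per the sample's key
      key <- scheme$keys[key_idx, ]
      meanlog <- ifelse(key == 1, config$barcode_pos_meanlog,
                        config$barcode_neg_meanlog)
      values[, bc] <- matrix(
        stats::rlnorm(n * length(bc),
                      rep(meanlog, each = n), config$barcode_sdlog),
        n, length(bc))

      meta <- list(donor_id = donors[d], gravity = grav,
                   stimulation = stim,
                   timepoint_h = if (stim == "unstim") 0
                                 else config$stim_timepoint_h,
                   barcode_key_index = key_idx)
      tables[[length(tables) + 1L]] <-
        event_table(values, meta, panel, truth_labels = membership)
    }
  }
  list(tables = tables, effects = config$effects, scheme = scheme)
}

#' Pool samples into one barcoded event table
#'
#' Concatenates per-sample tables (each already carrying its barcode key in
#' the barcode channels) into a single pooled table, as in palladium
#' multiplexed acquisition. Ground-truth origins are kept in the
#' `origin_key` attribute.
#'
#' @param tables list of `event_table`s from [simulate_experiment()].
#' @return A pooled `event_table` with attribute `origin_key` (integer per
#'   event).
#' @export
pool_samples <- function(tables) {
  stopifnot(length(tables) >= 1)
  panel <- attr(tables[[1]], "panel")
  values <- do.call(rbind, lapply(tables, event_values))
  origin <- unlist(lapply(tables, function(t) {
    rep(attr(t, "meta")$barcode_key_index %||% NA_integer_, nrow(t))
  }))
  pooled <- event_table(values,
                        list(donor_id = "pool", gravity = "1G",
                             stimulation = "unstim", timepoint_h = 0),
                        panel)
  attr(pooled, "origin_key") <- origin
  pooled
}
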