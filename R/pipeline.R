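#' Pipeline run configuration
#'
#' Bundles every setting of an end-to-end run: the simulation (or a
#' directory of per-sample CSV event tables), the gating hierarchy and
#' panel, elastic-net and screening settings, network settings, the output
#' directory and the mandatory global seed. Randomized stages derive their
#' own seeds from the global one with fixed offsets, so single stages can
#' be re-run reproducibly.
#'
#' @param outdir output directory (created if absent).
#' @param seed global integer seed (mandatory).
#' @param sim a [sim_config()], or `NULL` when `input_dir` is given.
#' @param input_dir directory of `<sample>.csv` + `<sample>.json` event
#'   tables for real-data runs.
#' @param panel,hierarchy panel and gating tree (defaults from the sim
#'   config when present).
#' @param fdr_q FDR level of the univariate screens.
#' @param en_mixing,en_n_lambda elastic-net mixing fraction and lambda-grid
#'   size.
#' @param min_cells per-(sample, subset) floor for feature computation.
#' @param network_alpha Bonferroni familywise level of the edge criterion.
#' @return A `run_config`.
#' @export
run_config <- function(outdir, seed, sim = NULL, input_dir = NULL,
                       panel = NULL, hierarchy = NULL,
                       fdr_q = 0.01, en_mixing = 0.5, en_n_lambda = 50,
                       min_cells = 20, network_alpha = 0.05) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory",
                                           call. = FALSE)
  if (is.null(sim) && is.null(input_dir)) {
    stop("provide a sim config or an input_dir of event tables",
         call. = FALSE)
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  if (is.null(panel)) panel <- if (!is.null(sim)) sim$panel
                               else default_panel()
  if (is.null(hierarchy)) hierarchy <- if (!is.null(sim)) sim$hierarchy
                                       else build_default_hierarchy(panel)
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 input_dir = input_dir, panel = panel,
                 hierarchy = hierarchy, fdr_q = fdr_q,
                 en_mixing = en_mixing, en_n_lambda = en_n_lambda,
                 min_cells = min_cells, network_alpha = network_alpha),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Diagnostic-only consistency checks: panel/hierarchy marker coverage,
#' subset-proportion support, and (for loaded data) sample pairing
#' completeness. Returns messages rather than erroring so problems can be
#' reported together.
#'
#' @param config a `run_config`.
#' @param tables optional list of loaded `event_table`s to check pairing
#'   on.
#' @return Character vector of diagnostics; empty when consistent.
#' @export
validate_inputs <- function(config, tables = NULL) {
  diags <- character()
  surf <- panel_markers(config$panel, "surface")
  used <- tryCatch(gate_markers(config$hierarchy$root), error = function(e) NULL)
  if (is.null(used)) {
    diags <- c(diags, "hierarchy is malformed")
  } else if (length(setdiff(used, surf))) {
    diags <- c(diags, paste0("hierarchy references non-surface marker(s): ",
                             paste(setdiff(used, surf), collapse = ", ")))
  }
  if (!is.null(config$sim)) {
    miss <- setdiff(config$hierarchy$leaves,
                    names(config$sim$subset_proportions))
    if (length(miss)) {
      diags <- c(diags, paste0("subset proportions missing leaves: ",
                               paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(tables)) {
    meta <- lapply(tables, attr, "meta")
    donor <- vapply(meta, `[[`, "", "donor_id")
    gravity <- vapply(meta, `[[`, "", "gravity")
    stim <- vapply(meta, `[[`, "", "stimulation")
    for (d in unique(donor)) for (g in c("1G", "uG")) {
      here <- donor == d & gravity == g
      if (!any(here & stim == "unstim")) {
        diags <- c(diags, paste0("donor ", d, " (", g,
                                 ") lacks an unstimulated sample"))
      }
      if (!any(here & stim != "unstim")) {
        diags <- c(diags, paste0("donor ", d, " (", g,
                                 ") lacks a stimulated sample"))
      }
    }
  }
  diags
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> gate -> feature matrices (response, basal,
#' abundance) -> univariate BKY screens -> elastic-net fits with
#' leave-one-donor-out cross-validation and paired model significance
#' (response and basal modes) -> Bonferroni Spearman correlation network
#' with communities and t-SNE layout. All tables and network files are
#' written under `config$outdir`; the returned report indexes them. With
#' identical config and seed the run is fully reproducible.
#'
#' @param config a [run_config()].
#' @return A `run_report` list: feature matrices, screen tables, `cv`
#'   results, `significance`, `components`, network objects, ground-truth
#'   `recovery` (synthetic runs), `files`, and a config/seed `fingerprint`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  out <- function(...) file.path(config$outdir, paste0(...))

  # stage 1: events
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    sim_out <- simulate_experiment(sim)
    tables <- sim_out$tables
    stage_log("simulate", length(tables), " samples x ",
              sim$cells_per_sample, " cells")
  } else {
    stems <- sub("\\.csv$", "",
                 list.files(config$input_dir, pattern = "\\.csv$",
                            full.names = TRUE))
    tables <- lapply(stems, read_event_table, panel = config$panel)
    sim_out <- NULL
    stage_log("load", length(tables), " event tables from ",
              config$input_dir)
  }
  diags <- validate_inputs(config, tables)
  if (length(diags)) {
    stop("pipeline aborted at stage 'validate': ",
         paste(diags, collapse = "; "), call. = FALSE)
  }

  # stage 2: gating
  labels <- lapply(tables, apply_gating, hierarchy = config$hierarchy)
  assigned <- vapply(labels, function(l) mean(l != "unassigned"), 0)
  stage_log("gate", "median assigned fraction ",
            format(stats::median(assigned), digits = 3))

  # stage 3: features
  fm_args <- list(tables = tables, labels_list = labels,
                  hierarchy = config$hierarchy, panel = config$panel,
                  min_cells = config$min_cells)
  response <- impute_features(do.call(build_feature_matrix,
                                      c(fm_args, mode = "response")))
  basal <- impute_features(do.call(build_feature_matrix,
                                   c(fm_args, mode = "basal")))
  abundance <- do.call(build_feature_matrix, c(fm_args, mode = "abundance"))
  for (nm in c("response", "basal", "abundance")) {
    f <- out("features_", nm, ".csv")
    write_feature_matrix(get(nm), f)
    files <- c(files, f)
  }
  stage_log("features", ncol(response), " response / ", ncol(basal),
            " basal / ", ncol(abundance), " abundance features")

  # stage 4: univariate screens
  screen_response <- univariate_screen(response, q = config$fdr_q)
  screen_abundance <- univariate_screen(abundance, q = config$fdr_q)
  for (nm in c("response", "abundance")) {
    f <- out("screen_", nm, ".tsv")
    utils::write.table(get(paste0("screen_", nm)), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  stage_log("screen", sum(screen_response$discovery), " response and ",
            sum(screen_abundance$discovery),
            " abundance discoveries at q = ", config$fdr_q)

  # stage 5: elastic net (response and basal modes)
  en_one <- function(fm, tag) {
    rm_ <- attr(fm, "row_meta")
    Y <- ifelse(rm_$gravity == "uG", 1, -1)
    cv <- cv_lambda_path(fm, Y, rm_$donor, mixing = config$en_mixing,
                         n_lambda = config$en_n_lambda,
                         seed = config$seed + 1000L)
    sig <- tryCatch(model_significance(cv),
                    error = function(e) structure(
                      list(scores = NULL, test = NULL, which = "1se",
                           degenerate = conditionMessage(e)),
                      class = "model_significance"))
    list(cv = cv, significance = sig, tag = tag)
  }
  en_response <- en_one(response, "response")
  en_basal <- en_one(basal, "basal")
  p_resp <- en_response$significance$test$p_two_sided %||% NA_real_
  stage_log("fit-en", "response model p = ", format(p_resp, digits = 4),
            ", ", en_response$cv$fit_1se$n_nonzero,
            " nonzero coefficients at lambda_1se")

  # stage 6: network on response features
  net <- build_network(response, alpha = config$network_alpha)
  communities <- detect_communities(net, seed = config$seed + 3000L)
  community_table <- annotate_communities(communities)
  layout <- layout_2d(net, seed = config$seed + 2000L)
  files <- c(files, export_network(net, out("network"), communities,
                                   layout))
  stage_log("network", length(net$nodes), " nodes, ",
            sum(net$adjacency) / 2, " edges, ",
            length(unique(communities)), " communities")

  components <- component_report(en_response$cv$fit_1se, screen_response,
                                 communities)
  components_min <- component_report(en_response$cv$fit_min,
                                     screen_response, communities)
  for (cmp in c("components_response", "components_response_min")) {
    f <- out(cmp, ".tsv")
    utils::write.table(if (cmp == "components_response") components
                       else components_min,
                       f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }

  # recovery is judged on the denser lambda_min model, the discovery-
  # oriented end of the bracket; lambda_1se is the parsimonious report
  recovery <- if (!is.null(sim_out)) {
    recovery_summary(components_min, sim_out$effects)
  } else NULL

  model_json <- list(
    seed = config$seed,
    response = en_model_record(en_response),
    basal = en_model_record(en_basal)
  )
  f <- out("models.json")
  jsonlite::write_json(model_json, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)

  fingerprint <- config_fingerprint(config)
  report <- structure(list(
    response = response, basal = basal, abundance = abundance,
    screen_response = screen_response,
    screen_abundance = screen_abundance,
    en_response = en_response, en_basal = en_basal,
    network = net, communities = communities,
    community_table = community_table, layout = layout,
    components = components, components_min = components_min,
    recovery = recovery,
    effects = if (!is.null(sim_out)) sim_out$effects else NULL,
    files = files, fingerprint = fingerprint, seed = config$seed
  ), class = "run_report")
  f <- out("report.json")
  jsonlite::write_json(report_summary(report), f, auto_unbox = TRUE,
                       digits = NA)
  report$files <- c(files, f)
  report
}

en_model_record <- function(en) {
  fit <- en$cv$fit_1se
  list(tag = en$tag,
       lambda_min = en$cv$lambda_min, lambda_1se = en$cv$lambda_1se,
       cv_error_min = en$cv$cv_mean[en$cv$i_min],
       cv_error_1se = en$cv$cv_mean[en$cv$i_1se],
       n_nonzero = fit$n_nonzero,
       p_model = en$significance$test$p_two_sided %||% NA_real_,
       beta = as.list(stats::setNames(fit$beta_raw[fit$beta != 0],
                                      fit$features[fit$beta != 0])))
}

#' Ground-truth recovery of injected effects
#'
#' Fraction of injected response-scale effects (gravity or
#' gravity-by-stimulation axis) that the component report recovers with
#' the correct microgravity direction.
#'
#' @param components a [component_report()] table.
#' @param effects the generating `effect_spec`.
#' @return List: `n_injected`, `n_recovered`, `sensitivity`, per-effect
#'   `detail` data.frame.
#' @export
recovery_summary <- function(components, effects) {
  inj <- effects[effects$axis %in% c("gravity", "gravity_x_stimulation"), ,
                 drop = FALSE]
  hit <- logical(nrow(inj))
  for (i in seq_len(nrow(inj))) {
    row <- components[components$subset == inj$subset[i] &
                        components$marker == inj$marker[i], , drop = FALSE]
    hit[i] <- nrow(row) > 0 &&
      sign(row$beta[1]) == sign(inj$shift[i])
  }
  list(n_injected = nrow(inj), n_recovered = sum(hit),
       sensitivity = if (nrow(inj)) sum(hit) / nrow(inj) else NA_real_,
       detail = cbind(inj, recovered = hit))
}

report_summary <- function(report) {
  list(
    seed = report$seed,
    fingerprint = report$fingerprint,
    n_response_features = ncol(report$response),
    n_basal_features = ncol(report$basal),
    n_subsets = ncol(report$abundance),
    n_response_discoveries = sum(report$screen_response$discovery),
    n_abundance_discoveries = sum(report$screen_abundance$discovery),
    p_model_response =
      report$en_response$significance$test$p_two_sided %||% NA_real_,
    p_model_basal =
      report$en_basal$significance$test$p_two_sided %||% NA_real_,
    n_network_edges = sum(report$network$adjacency) / 2,
    n_communities = length(unique(report$communities)),
    recovery_sensitivity = report$recovery$sensitivity %||% NA_real_,
    files = report$files
  )
}

#' @export
print.run_report <- function(x, ...) {
  s <- report_summary(x)
  cat("<run_report> seed ", s$seed, "\n",
      "  features: ", s$n_response_features, " response, ",
      s$n_basal_features, " basal, ", s$n_subsets, " abundance\n",
      "  screens: ", s$n_response_discoveries, " response / ",
      s$n_abundance_discoveries, " abundance discoveries\n",
      "  EN: response p = ", format(s$p_model_response, digits = 4),
      ", basal p = ", format(s$p_model_basal, digits = 4), "\n",
      "  network: ", s$n_network_edges, " edges, ", s$n_communities,
      " communities\n", sep = "")
  if (!is.null(x$recovery)) {
    cat("  recovery: ", x$recovery$n_recovered, "/",
        x$recovery$n_injected, " injected effects\n", sep = "")
  }
  invisible(x)
}

config_fingerprint <- function(config) {
  payload <- list(seed = config$seed,
                  fdr_q = config$fdr_q, en_mixing = config$en_mixing,
                  en_n_lambda = config$en_n_lambda,
                  min_cells = config$min_cells,
                  network_alpha = config$network_alpha,
                  sim = if (!is.null(config$sim)) {
                    s <- config$sim
                    list(n_donors = s$n_donors,
                         cells_per_sample = s$cells_per_sample,
                         proportions = unname(s$subset_proportions),
                         donor_sd = s$donor_sd,
                         effects = as.list(as.data.frame(s$effects)))
                  })
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
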