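#' Build a validated pipeline run configuration
#'
#' Collects everything a reporting run needs: input manifests, analysis
#' switches and thresholds, output directory and seed. Unknown fields are
#' rejected so that configuration typos fail loudly.
#'
#' @param titrations data frame manifest for equilibrium fitting: columns
#'   `file`, `protein`, `template`, `modifications`, `assay`, `model`
#'   (`"hill"`, `"two_site"` or `"both"`).
#' @param kinetics data frame manifest for sensogram fitting: columns
#'   `file`, `protein`, `template`, `phase`, `conc_uM`, `i`.
#' @param states data frame of binding states for the occupancy report:
#'   columns `label`, `K_D_uM`, `hill_n`; default the packaged three-state
#'   system ([default_binding_states()]).
#' @param conc_range concentration interval for selectivity reporting,
#'   micromolar; default `c(0.4, 0.8)`, the estimated intranuclear Sir3
#'   range.
#' @param ensemble list for the ChIP ensemble stage: `signal` and
#'   `control` bedGraph paths, `anchors` anchor-table path, `sizes`
#'   chrom-sizes path, optional `window` (default 14000) and `kind`.
#' @param qpcr list for the qPCR stage: `file` (CT table path), optional
#'   `reference_gene`, `control_sample`.
#' @param alpha_f,alpha_runs kinetic model-selection thresholds
#'   (see [select_model_order()]).
#' @param out_dir output directory for delimited reports (`NULL` = return
#'   tables only).
#' @param seed integer seed recorded with the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(titrations = NULL, kinetics = NULL, states = NULL,
                       conc_range = c(0.4, 0.8), ensemble = NULL,
                       qpcr = NULL, alpha_f = 0.01, alpha_runs = 0.05,
                       out_dir = NULL, seed = 1L) {
  stopifnot(length(conc_range) == 2, conc_range[1] > 0,
            conc_range[2] > conc_range[1])
  if (!is.null(titrations)) {
    req <- c("file", "protein", "template", "modifications", "assay", "model")
    if (!all(req %in% names(titrations)))
      stop("titration manifest needs columns: ", paste(req, collapse = ", "))
  }
  if (!is.null(kinetics)) {
    req <- c("file", "protein", "template", "phase", "conc_uM", "i")
    if (!all(req %in% names(kinetics)))
      stop("kinetics manifest needs columns: ", paste(req, collapse = ", "))
  }
  if (!is.null(states)) {
    req <- c("label", "K_D_uM", "hill_n")
    if (!all(req %in% names(states)))
      stop("state table needs columns: ", paste(req, collapse = ", "))
  }
  if (!is.null(ensemble)) {
    req <- c("signal", "control", "anchors", "sizes")
    if (!all(req %in% names(ensemble)))
      stop("ensemble config needs fields: ", paste(req, collapse = ", "))
  }
  structure(list(titrations = titrations, kinetics = kinetics,
                 states = states, conc_range = conc_range,
                 ensemble = ensemble, qpcr = qpcr, alpha_f = alpha_f,
                 alpha_runs = alpha_runs, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror the arguments of [run_config()]; manifest fields
#' (`titrations`, `kinetics`, `states`) may be inline lists of records or
#' paths to delimited files. Unknown top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  as_manifest <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1)
      return(read.table(x, header = TRUE, sep = "\t"))
    do.call(rbind, lapply(x, as.data.frame))
  }
  y$titrations <- as_manifest(y$titrations)
  y$kinetics <- as_manifest(y$kinetics)
  y$states <- as_manifest(y$states)
  if (!is.null(y$conc_range)) y$conc_range <- as.numeric(y$conc_range)
  do.call(run_config, y)
}

## 32-bit FNV-1a hash of the deparsed configuration, for provenance logging
.config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

.write_report <- function(df, config, name) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(df, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  df
}

#' Fit all titrations in a manifest
#'
#' Runs [fit_hill()] (and/or [fit_two_site()]) over every titration file
#' in the configuration manifest and assembles a thermodynamic parameter
#' table (one row per curve and model). Per-curve fit failures are
#' recorded as `NA` rows with the diagnostic in `note`; the run continues.
#'
#' @param config a [run_config()] with a `titrations` manifest.
#' @return Data frame with columns `protein`, `template`, `modifications`,
#'   `assay`, `model`, `K_D_uM`, `sd_K_D`, `hill_n`, `sd_n`, `rss`,
#'   `n_confidence`, `note` (also written to
#'   `<out_dir>/equilibrium_fits.tsv` when an output directory is set).
#' @export
run_equilibrium <- function(config) {
  stopifnot(inherits(config, "run_config"))
  man <- config$titrations
  if (is.null(man) || nrow(man) == 0)
    stop("no titrations in configuration")
  rows <- list()
  for (r in seq_len(nrow(man))) {
    m <- man[r, ]
    mods <- if (is.na(m$modifications) || m$modifications == "") character()
            else strsplit(m$modifications, "\\+")[[1]]
    curve <- tryCatch(
      suppressWarnings(
        read_titration(m$file, assay = m$assay, protein_label = m$protein,
                       template_label = m$template, modifications = mods)),
      error = function(e) e)
    models <- if (m$model == "both") c("hill", "two_site") else m$model
    for (mod in models) {
      row <- data.frame(protein = m$protein, template = m$template,
                        modifications = m$modifications, assay = m$assay,
                        model = mod, K_D_uM = NA_real_, sd_K_D = NA_real_,
                        hill_n = NA_real_, sd_n = NA_real_, rss = NA_real_,
                        n_confidence = NA_character_, note = "")
      res <- if (inherits(curve, "error")) curve else tryCatch(
        if (mod == "hill") fit_hill(curve) else fit_two_site(curve),
        error = function(e) e)
      if (inherits(res, "error")) {
        row$note <- conditionMessage(res)
      } else if (mod == "hill") {
        row$K_D_uM <- res$K_D; row$sd_K_D <- res$sd_K_D
        row$hill_n <- res$n; row$sd_n <- res$sd_n
        row$rss <- res$rss; row$n_confidence <- res$n_confidence
      } else {
        row$K_D_uM <- res$K_D_macro; row$sd_K_D <- res$sd_K_D_macro
        row$rss <- res$rss
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .write_report(out, config, "equilibrium_fits.tsv")
}

#' Fit all sensograms in a manifest
#'
#' For every trace: fit mono- and bi-exponential models, select the order
#' by F-test plus runs test, and report amplitude fractions, rates and
#' time constants. Association rates are converted to `k_on` by pairing
#' each association trace with the selected dissociation fit of the same
#' protein/template (phase-by-phase pairing).
#'
#' @param config a [run_config()] with a `kinetics` manifest.
#' @return Data frame with one row per trace: `protein`, `template`,
#'   `phase`, `conc_uM`, `model_order`, `A1_pct`, `k1_s`, `tau1_s`,
#'   `A2_pct`, `k2_s`, `tau2_s`, `i`, `kon1`, `kon2`, `f_test_p`,
#'   `runs_test_p`, `note` (written to `<out_dir>/kinetic_fits.tsv`).
#' @export
run_kinetics <- function(config) {
  stopifnot(inherits(config, "run_config"))
  man <- config$kinetics
  if (is.null(man) || nrow(man) == 0)
    stop("no kinetic traces in configuration")
  fits <- vector("list", nrow(man))
  rows <- list()
  for (r in seq_len(nrow(man))) {
    m <- man[r, ]
    row <- data.frame(protein = m$protein, template = m$template,
                      phase = m$phase, conc_uM = m$conc_uM,
                      model_order = NA_integer_,
                      A1_pct = NA_real_, k1_s = NA_real_, tau1_s = NA_real_,
                      A2_pct = NA_real_, k2_s = NA_real_, tau2_s = NA_real_,
                      i = m$i, kon1 = NA_real_, kon2 = NA_real_,
                      f_test_p = NA_real_, runs_test_p = NA_real_,
                      note = "")
    res <- tryCatch({
      tr <- read_sensogram(m$file, phase = m$phase,
                           protein_conc_uM = m$conc_uM,
                           template_label = m$template)
      f1 <- fit_exponential(tr, order = 1)
      f2 <- fit_exponential(tr, order = 2)
      sel <- select_model_order(f1, f2, alpha_f = config$alpha_f,
                                alpha_runs = config$alpha_runs)
      list(fit = if (sel$chosen_order == 2) f2 else f1, sel = sel)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$note <- conditionMessage(res)
    } else {
      f <- res$fit
      fits[[r]] <- f
      row$model_order <- f$order
      row$A1_pct <- f$amplitude_fractions[1]
      row$k1_s <- f$k[1]; row$tau1_s <- f$tau[1]
      if (f$order == 2) {
        row$A2_pct <- f$amplitude_fractions[2]
        row$k2_s <- f$k[2]; row$tau2_s <- f$tau[2]
      }
      row$f_test_p <- res$sel$f_test_p
      row$runs_test_p <- res$sel$runs_test_p
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, rows)
  ## pair association k_obs with the matching dissociation k_off for k_on
  for (r in which(out$phase == "association" & !is.na(out$model_order))) {
    mate <- which(out$phase == "dissociation" &
                    out$protein == out$protein[r] &
                    out$template == out$template[r] &
                    !is.na(out$model_order))
    if (!length(mate)) next
    mate <- mate[1]
    koff <- c(out$k1_s[mate], out$k2_s[mate])
    kobs <- c(out$k1_s[r], out$k2_s[r])
    for (ph in 1:2) {
      if (is.na(kobs[ph]) || is.na(koff[ph])) next
      kc <- suppressWarnings(
        derive_kon(kobs[ph], koff[ph], i = out$i[r], S_uM = out$conc_uM[r]))
      out[[paste0("kon", ph)]][r] <- kc$k_on
    }
  }
  rownames(out) <- NULL
  .write_report(out, config, "kinetic_fits.tsv")
}

#' Boltzmann occupancy and selectivity report
#'
#' Evaluates the multi-state occupancy system over the configured
#' concentration range: state probabilities at both endpoints, all
#' pairwise selectivities, and the non-cooperative counterfactual in which
#' every Hill coefficient is set to 1 (isolating the contribution of
#' cooperativity to selectivity, which is then concentration-independent).
#'
#' @param config a [run_config()]; uses `states` (default
#'   [default_binding_states()]) and `conc_range`.
#' @return List of class `occupancy_report` with data frames
#'   `probabilities`, `selectivity` (columns `state_a`, `state_b`,
#'   `fold_low`, `fold_high`, `fold_low_n1`, `fold_high_n1`) and the state
#'   table; written to `<out_dir>/occupancy_report.tsv` when set.
#' @export
run_occupancy_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  states <- if (is.null(config$states)) default_binding_states()
  else {
    st <- lapply(seq_len(nrow(config$states)), function(i)
      binding_state(config$states$label[i], config$states$K_D_uM[i],
                    config$states$hill_n[i]))
    setNames(st, config$states$label)
  }
  S <- config$conc_range
  prob <- do.call(rbind, lapply(S, function(s) {
    occ <- occupancy_probabilities(states, s)
    data.frame(S_uM = s, state = names(occ$probabilities),
               probability = unname(occ$probabilities),
               dG_over_RT = unname(occ$dG_over_RT))
  }))
  cf <- lapply(states, function(st) binding_state(st$label, st$K_D, n = 1))
  pairs <- if (length(states) > 1) utils::combn(names(states), 2) else NULL
  sel <- if (!is.null(pairs)) do.call(rbind, lapply(
    seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      r <- selectivity_range(states[[a]], states[[b]], S[1], S[2])
      r1 <- selectivity_range(cf[[a]], cf[[b]], S[1], S[2])
      data.frame(state_a = a, state_b = b,
                 fold_low = r[["low"]], fold_high = r[["high"]],
                 fold_low_n1 = r1[["low"]], fold_high_n1 = r1[["high"]])
    })) else data.frame()
  state_tab <- data.frame(
    label = names(states),
    K_D_uM = vapply(states, `[[`, numeric(1), "K_D"),
    hill_n = vapply(states, `[[`, numeric(1), "n"))
  rownames(state_tab) <- NULL
  .write_report(prob, config, "occupancy_probabilities.tsv")
  .write_report(sel, config, "occupancy_selectivity.tsv")
  structure(list(states = state_tab, probabilities = prob,
                 selectivity = sel, conc_range = S),
            class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat(sprintf("Occupancy report over [S] = %.3g-%.3g uM, %d states\n",
              x$conc_range[1], x$conc_range[2], nrow(x$states)))
  if (nrow(x$selectivity)) {
    for (j in seq_len(nrow(x$selectivity))) {
      s <- x$selectivity[j, ]
      cat(sprintf("  %s vs %s: %.3g-%.3g fold (n=1 counterfactual: %.3g)\n",
                  s$state_a, s$state_b, s$fold_low, s$fold_high,
                  s$fold_low_n1))
    }
  }
  invisible(x)
}

#' Subtelomeric ensemble stage
#'
#' Reads signal and control bedGraph tracks plus the anchor table, RPM
#' normalizes both tracks, aggregates them at the anchors and normalizes
#' the signal meta-profile to the control per base.
#'
#' @param config a [run_config()] with an `ensemble` block.
#' @return The control-normalized [aggregate_at_anchors()] profile
#'   (written to `<out_dir>/ensemble_profile.tsv` when set).
#' @export
run_ensemble <- function(config) {
  stopifnot(inherits(config, "run_config"))
  e <- config$ensemble
  if (is.null(e)) stop("no ensemble block in configuration")
  window <- if (is.null(e$window)) 14000 else e$window
  kind <- if (is.null(e$kind)) "C_ACS" else e$kind
  anchors <- read_anchor_table(e$anchors, kind = kind)
  sig <- rpm_normalize(read_bedgraph_track(e$signal, e$sizes))
  ctl <- rpm_normalize(read_bedgraph_track(e$control, e$sizes))
  prof <- normalize_to_control(
    aggregate_at_anchors(sig, anchors, window = window),
    aggregate_at_anchors(ctl, anchors, window = window))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ensemble_profile(prof,
                           file.path(config$out_dir, "ensemble_profile.tsv"))
  }
  prof
}

#' qPCR stage
#'
#' Reads a CT table and computes delta-CT fold enrichments
#' ([qpcr_fold_enrichment()]).
#'
#' @param config a [run_config()] with a `qpcr` block (`file`, optional
#'   `reference_gene`, `control_sample`).
#' @return Fold-enrichment table (written to `<out_dir>/qpcr_report.tsv`).
#' @export
run_qpcr <- function(config) {
  stopifnot(inherits(config, "run_config"))
  q <- config$qpcr
  if (is.null(q)) stop("no qpcr block in configuration")
  ct <- read.table(q$file, header = TRUE, sep = "\t")
  out <- qpcr_fold_enrichment(
    ct,
    reference_gene = if (is.null(q$reference_gene)) "cup1"
                     else q$reference_gene,
    control_sample = if (is.null(q$control_sample)) "sir3d"
                     else q$control_sample)
  .write_report(out, config, "qpcr_report.tsv")
}

#' Run all configured stages
#'
#' Executes every stage present in the configuration (equilibrium,
#' kinetics, occupancy, ensemble, qPCR) and writes a JSON run summary with
#' package version, configuration hash, seed, and per-stage timing.
#'
#' @param config a [run_config()].
#' @return Named list of stage results, invisibly; summary at
#'   `<out_dir>/run_summary.json` when an output directory is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- list(
    equilibrium = function() run_equilibrium(config),
    kinetics = function() run_kinetics(config),
    occupancy = function() run_occupancy_report(config),
    ensemble = function() run_ensemble(config),
    qpcr = function() run_qpcr(config)
  )
  enabled <- c(equilibrium = !is.null(config$titrations),
               kinetics = !is.null(config$kinetics),
               occupancy = TRUE,
               ensemble = !is.null(config$ensemble),
               qpcr = !is.null(config$qpcr))
  results <- list()
  timing <- list()
  for (s in names(stages)[enabled]) {
    t0 <- proc.time()[["elapsed"]]
    results[[s]] <- stages[[s]]()
    timing[[s]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  summary <- list(
    package = "sir3coop",
    version = as.character(utils::packageVersion("sir3coop")),
    config_hash = .config_hash(config),
    seed = config$seed,
    stages = names(results),
    timing_s = timing
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}
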