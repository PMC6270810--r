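# End-to-end orchestration and validation of the packaged tables.

#' Pipeline configuration
#'
#' Stage toggles and per-stage settings for [run_pipeline()]. The default
#' stage order is charges, minimize, anneal, minimize, align, fields, PLS,
#' contours; each preparation stage can be switched off (for example when
#' the input conformers are already relaxed and aligned).
#'
#' @param charges Assign PEOE partial charges (default `FALSE`: trusts the
#'   charges carried by the input molecules).
#' @param minimize_pre,anneal,minimize_post Geometry stages (default
#'   `TRUE`).
#' @param align Superimpose onto the template via the scaffold map
#'   (default `TRUE`).
#' @param spacing,margin,cap,filter_sigma Field lattice settings
#'   (defaults 2, 4, 30, 2).
#' @param probe A [probe_spec()].
#' @param block_scaling `"inverse_stdev"` or `"none"`.
#' @param n_components Fixed component count; `NULL` (default) scans and
#'   applies `selection_rule`.
#' @param n_max Scan limit (default 15).
#' @param selection_rule Passed to [select_components()].
#' @param contour_levels Favored/disfavored quantiles (default
#'   `c(0.8, 0.2)`).
#' @param anneal_cfg,minimize_cfg,charge_cfg Stage configurations.
#' @param seed Integer seed; per-molecule annealing seeds are derived from
#'   it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(charges = FALSE, minimize_pre = TRUE,
                            anneal = TRUE, minimize_post = TRUE,
                            align = TRUE, spacing = 2, margin = 4, cap = 30,
                            filter_sigma = 2, probe = probe_spec(),
                            block_scaling = "inverse_stdev",
                            n_components = NULL, n_max = 15L,
                            selection_rule = "max_q2",
                            contour_levels = c(0.8, 0.2),
                            anneal_cfg = anneal_config(),
                            minimize_cfg = minimize_config(),
                            charge_cfg = charge_config(), seed = 1L) {
  structure(list(charges = charges, minimize_pre = minimize_pre,
                 anneal = anneal, minimize_post = minimize_post,
                 align = align, spacing = spacing, margin = margin,
                 cap = cap, filter_sigma = filter_sigma, probe = probe,
                 block_scaling = block_scaling, n_components = n_components,
                 n_max = n_max, selection_rule = selection_rule,
                 contour_levels = contour_levels, anneal_cfg = anneal_cfg,
                 minimize_cfg = minimize_cfg, charge_cfg = charge_cfg,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full 3D-QSAR pipeline
#'
#' Prepares the conformers (charges, minimization, torsional annealing,
#' re-minimization), superimposes them onto the template scaffold, builds
#' the steric/electrostatic field block, selects and fits the PLS model
#' with leave-one-out cross-validation, and computes fit statistics, field
#' contributions, external-validation statistics (when the activity table
#' carries a test split), and StDev*Coeff contour maps. Fully reproducible
#' per seed.
#'
#' @param mols List of [molecule] objects.
#' @param activities An [affinity_table] or data frame with `molecule_id`,
#'   `pki` and optionally `split`; ids must match the molecule ids (the
#'   generator uses integer positions as ids).
#' @param template Template [molecule] for alignment (ignored when
#'   `config$align` is `FALSE`).
#' @param scaffold_map Atom correspondence for [atom_fit()] (template,
#'   molecule).
#' @param config A [pipeline_config()].
#' @return Report list: `summary` (N, q2, sep, r2, see, f_stat,
#'   contributions, and press/sd/r2_pred when a test split is present),
#'   `scan`, `predictions` (per-molecule actual/predicted/residual),
#'   `maps` (steric and electrostatic contour maps), `field_matrix`,
#'   `model`, `config`.
#' @export
run_pipeline <- function(mols, activities, template = NULL,
                         scaffold_map = NULL, config = pipeline_config()) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  if (!length(mols)) stop("pipeline stage 'input': no molecules")
  mols <- lapply(mols, assign_vdw_params)
  if (isTRUE(config$charges))
    mols <- lapply(mols, gasteiger_charges, cfg = config$charge_cfg)
  if (isTRUE(config$minimize_pre))
    mols <- lapply(mols, function(m) minimize(m, config$minimize_cfg)$molecule)
  if (isTRUE(config$anneal)) {
    mols <- lapply(seq_along(mols), function(k) {
      acfg <- config$anneal_cfg
      acfg$seed <- config$seed + k
      simulated_anneal(mols[[k]], acfg)$molecule
    })
  }
  if (isTRUE(config$minimize_post))
    mols <- lapply(mols, function(m) minimize(m, config$minimize_cfg)$molecule)
  if (isTRUE(config$align)) {
    if (is.null(template) || is.null(scaffold_map))
      stop("pipeline stage 'align': template and scaffold_map are required")
    mols <- lapply(mols, function(m) atom_fit(m, template, scaffold_map)$molecule)
  }
  grid <- make_grid(mols, spacing = config$spacing, margin = config$margin)
  fm <- build_field_matrix(mols, grid, probe = config$probe,
                           cap = config$cap,
                           filter_sigma = config$filter_sigma)
  X <- descriptor_matrix(fm, block_scaling = config$block_scaling)
  act <- as.data.frame(activities)
  if (is.null(act$split)) act$split <- "train"
  mol_ids <- vapply(mols, function(m) m$id, character(1))
  row_of <- match(as.character(act$molecule_id), mol_ids)
  if (anyNA(row_of)) {
    # generator-style integer ids map to molecule positions
    row_of <- match(act$molecule_id, seq_along(mols))
    if (anyNA(row_of))
      stop("pipeline stage 'pls': activity ids do not match molecule ids")
  }
  train <- act$split == "train"
  X_train <- X[row_of[train], , drop = FALSE]
  attr(X_train, "block") <- attr(X, "block")
  attr(X_train, "point") <- attr(X, "point")
  y_train <- act$pki[train]
  scan <- NULL
  if (is.null(config$n_components)) {
    scan <- scan_components(X_train, y_train, n_max = config$n_max,
                            rule = config$selection_rule)
    n_comp <- attr(scan, "selected")
    cv <- list(q2 = scan$q2[scan$N == n_comp],
               sep = scan$sep[scan$N == n_comp])
  } else {
    n_comp <- config$n_components
    cv <- loo_cv(X_train, y_train, n_comp)
  }
  model <- fit_pls(X_train, y_train, n_comp)
  stats <- final_stats(model, X_train, y_train)
  contrib <- field_contributions(model)
  predicted <- predict(model, X[row_of, , drop = FALSE])
  predictions <- data.frame(molecule_id = act$molecule_id,
                            pki = act$pki, predicted_pki = predicted,
                            residual = act$pki - predicted,
                            split = act$split)
  summary <- list(n_components = n_comp, q2 = cv$q2, sep = cv$sep,
                  r2 = stats$r2, see = stats$see, f_stat = stats$f_stat,
                  contribution_steric = contrib[["steric"]],
                  contribution_electrostatic = contrib[["electrostatic"]])
  if (any(!train)) {
    val_tab <- affinity_table(data.frame(
      receptor = "RUN", molecule_id = act$molecule_id,
      ki_nM = 10^(9 - act$pki), pki = act$pki,
      predicted_pki = predicted, residual = act$pki - predicted,
      split = act$split, stringsAsFactors = FALSE), validate = FALSE)
    ps <- predictive_stats(val_tab)
    summary$press <- ps$press
    summary$sd <- ps$sd
    summary$r2_pred <- ps$r2_pred
  }
  maps <- list(steric = stdev_coeff_map(model, fm, "steric",
                                        config$contour_levels),
               electrostatic = stdev_coeff_map(model, fm, "electrostatic",
                                               config$contour_levels))
  list(summary = summary, scan = scan, predictions = predictions,
       maps = maps, field_matrix = fm, model = model, molecules = mols,
       config = config)
}

# Reference values as printed in the source tables; used only to check the
# packaged transcription against itself.
printed_reference_stats <- function() {
  list(CB1 = list(press = 5.46, sd = 15.22, r2_pred = 0.641),
       CB2 = list(press = 2.56, sd = 10.16, r2_pred = 0.748))
}

#' Validate the packaged affinity tables against their printed statistics
#'
#' Recomputes, for both receptors: per-row pKi from Ki, per-row residuals
#' from actual and predicted pKi, and the external-validation sums (PRESS,
#' SD, predictive r-squared), and compares them with the printed values at
#' printed precision.
#'
#' @param pki_tol Per-row tolerance on pKi and residual agreement
#'   (default 0.01).
#' @return Object of class `table_validation`: data frame of checks with a
#'   `pass` flag; attribute `passed` is `TRUE` when every check passes.
#' @export
validate_tables <- function(pki_tol = 0.01) {
  ref <- printed_reference_stats()
  checks <- list()
  for (receptor in c("CB1", "CB2")) {
    tab <- load_affinity_table(receptor)
    # per-row allowance: pKi rounding plus the printed Ki's half-ulp on
    # the log scale (see check_affinity_consistency)
    row_tol <- pmax(pki_tol,
                    log10(tab$ki_nM /
                          pmax(tab$ki_nM - printed_half_ulp(tab$ki_nM),
                               1e-12)))
    pki_dev <- max(abs(tab$pki - ki_to_pki(tab$ki_nM)) - row_tol)
    res_dev <- max(abs(tab$residual - (tab$pki - tab$predicted_pki)))
    ps <- predictive_stats(tab)
    r <- ref[[receptor]]
    checks[[length(checks) + 1L]] <- data.frame(
      receptor = receptor,
      check = c("pki_consistency", "residual_consistency",
                "press", "sd", "r2_pred"),
      value = c(pki_dev, res_dev, ps$press, ps$sd, ps$r2_pred),
      reference = c(0, pki_tol, r$press, r$sd, r$r2_pred),
      pass = c(pki_dev <= 1e-9, res_dev <= pki_tol + 1e-9,
               abs(round(ps$press, 2) - r$press) < 1e-9,
               abs(round(ps$sd, 2) - r$sd) < 1e-9,
               abs(round(ps$r2_pred, 3) - r$r2_pred) < 1e-9))
  }
  out <- do.call(rbind, checks)
  class(out) <- c("table_validation", "data.frame")
  attr(out, "passed") <- all(out$pass)
  out
}

#' @export
print.table_validation <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(if (attr(x, "passed")) "\nAll checks passed.\n"
      else "\nSome checks FAILED.\n")
  invisible(x)
}
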