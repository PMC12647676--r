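#' Configuration of the full evaluation protocol
#'
#' Every convention decision (percentile type, outlier fence, NRMSE
#' normalizer, Levene center) is an explicit field so reports never rely
#' on silent defaults.
#'
#' @param seed master seed for fold assignment.
#' @param k_folds participant cross-validation folds.
#' @param e_target target peak E-field for dosing comparisons (V/m).
#' @param max_current safety cap in mA for the dosing comparison
#'   (`Inf` reproduces the uncapped comparison).
#' @param fence_k,fence_method per-montage outlier fence
#'   ([reject_outliers()]).
#' @param nrmse_normalizer `"mean"` or `"range"` ([nrmse()]).
#' @param levene_center `"median"` or `"mean"` ([levene_test()]).
#' @param robust a [robust_config()].
#' @param vif_threshold multicollinearity acceptability threshold.
#' @return list of class `tes_run_config`.
#' @export
run_config <- function(seed = 1L, k_folds = 5L, e_target = 0.1,
                       max_current = Inf, fence_k = 3,
                       fence_method = "tukey", nrmse_normalizer = "mean",
                       levene_center = "median",
                       robust = robust_config(), vif_threshold = 2.5) {
  structure(list(seed = seed, k_folds = as.integer(k_folds),
                 e_target = e_target, max_current = max_current,
                 fence_k = fence_k, fence_method = fence_method,
                 nrmse_normalizer = nrmse_normalizer,
                 levene_center = levene_center, robust = robust,
                 vif_threshold = vif_threshold,
                 percentile_convention = "type7-linear-interpolation"),
            class = "tes_run_config")
}

#' Run the full dose-standardization study protocol
#'
#' Executes, on a dataset of cohort features plus per-montage peak
#' E-field strengths: per-montage IQR-fence QC; participant k-fold
#' cross-validation with training-fold-only standardization; robust
#' montage-specific model fits and out-of-fold prediction; montage-
#' agnostic fits (linear and quadratic distance-scaling variants) with
#' leave-one-montage-out validation inside each montage class; adjusted
#' R-squared and NRMSE per fold; and the dosing comparison (standardized
#' versus fixed dosing) with Brown-Forsythe/Levene tests and Bonferroni
#' correction across montages.
#'
#' @param dataset list with `cohort`, `efields`, `registry` (e.g. from
#'   [synthetic_dataset()]).
#' @param config a [run_config()].
#' @return report list of class `tes_report`: QC counts, per-fold metric
#'   tables for all model families, dosing table, summary means and the
#'   config snapshot.
#' @export
run_protocol <- function(dataset, config = run_config()) {
  stopifnot(inherits(config, "tes_run_config"))
  cohort <- dataset$cohort
  registry <- dataset$registry
  efields <- qc_efield_table(dataset$efields, k = config$fence_k,
                             method = config$fence_method)
  counts <- list(pairs_total = nrow(efields),
                 pairs_rejected = sum(!efields$qc_keep),
                 pairs_retained = sum(efields$qc_keep))
  efields <- efields[efields$qc_keep, , drop = FALSE]

  montage_ids <- names(registry)
  classes <- vapply(registry, function(m) m$class, character(1))
  ed_matrix <- dataset$distances
  if (is.null(ed_matrix)) {
    ed_matrix <- montage_distances(registry, cohort$head_circumference)
    rownames(ed_matrix) <- cohort$participant_id
  }

  plan <- kfold_split(cohort$participant_id, k = config$k_folds,
                      seed = config$seed)
  ms_rows <- list()
  ag_rows <- list()
  preds <- list()   # out-of-fold V/m predictions, montage-specific models

  for (f in seq_len(plan$k)) {
    test_ids <- names(plan$assignments)[plan$assignments == f]
    train_ids <- setdiff(cohort$participant_id, test_ids)
    tr <- cohort[cohort$participant_id %in% train_ids, , drop = FALSE]
    te <- cohort[cohort$participant_id %in% test_ids, , drop = FALSE]
    bmi_ref <- stats::median(tr$bmi, na.rm = TRUE)
    tr$bmi <- impute_bmi(tr$bmi, bmi_ref)
    te$bmi <- impute_bmi(te$bmi, bmi_ref)
    ef_tr <- efields[efields$participant_id %in% train_ids, , drop = FALSE]
    ef_te <- efields[efields$participant_id %in% test_ids, , drop = FALSE]
    params <- fit_standardizer(
      tr, efields = ef_tr,
      ed = as.vector(ed_matrix[tr$participant_id, montage_ids]),
      fitted_on = paste0("fold", f))

    feats <- function(coh, m)
      standardize_features(coh, params, ed = ed_matrix[coh$participant_id, m])

    # montage-specific models
    for (m in montage_ids) {
      ytr <- ef_tr[ef_tr$montage_id == m, ]
      yte <- ef_te[ef_te$montage_id == m, ]
      xtr <- feats(tr[match(ytr$participant_id, tr$participant_id), ], m)
      xte <- feats(te[match(yte$participant_id, te$participant_id), ], m)
      model <- fit_montage_specific(
        xtr, standardize_outcome(ytr$peak_e, params, m),
        standardizer = params, montage_id = m, cfg = config$robust)
      pred_vm <- predict_montage_specific(model, xte, units = "vm")
      ms_rows[[length(ms_rows) + 1L]] <- data.frame(
        montage_id = m, class = classes[[m]], fold = f,
        adj_r2 = adjusted_r2(yte$peak_e, pred_vm, p = 5L),
        nrmse = nrmse(yte$peak_e, pred_vm,
                      normalizer = config$nrmse_normalizer),
        vif_ok = model$vif$acceptable, stringsAsFactors = FALSE)
      preds[[length(preds) + 1L]] <- data.frame(
        participant_id = yte$participant_id, montage_id = m,
        true_e = yte$peak_e, pred_e = pred_vm, stringsAsFactors = FALSE)
    }

    # montage-agnostic models: LOMO inside each montage class
    for (cls in unique(classes)) {
      fam <- montage_ids[classes == cls]
      for (mo in fam) {
        train_m <- setdiff(fam, mo)
        pooled <- do.call(rbind, lapply(train_m, function(m) {
          ytr <- ef_tr[ef_tr$montage_id == m, ]
          x <- feats(tr[match(ytr$participant_id, tr$participant_id), ], m)
          x$montage_id <- m
          x$y <- standardize_outcome(ytr$peak_e, params, m)
          x
        }))
        yte <- ef_te[ef_te$montage_id == mo, ]
        xte <- feats(te[match(yte$participant_id, te$participant_id), ], mo)
        for (variant in c("linear", "quadratic")) {
          ag <- fit_montage_agnostic(pooled, variant = variant,
                                     cfg = config$robust,
                                     standardizer = params)
          pred_vm <- predict_agnostic(ag, xte, units = "vm",
                                      montage_id = mo)
          ag_rows[[length(ag_rows) + 1L]] <- data.frame(
            variant = variant, class = cls, held_out = mo, fold = f,
            adj_r2 = adjusted_r2(yte$peak_e, pred_vm, p = 6L),
            nrmse = nrmse(yte$peak_e, pred_vm,
                          normalizer = config$nrmse_normalizer),
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  ms_metrics <- do.call(rbind, ms_rows)
  ag_metrics <- do.call(rbind, ag_rows)
  oof <- do.call(rbind, preds)

  # dosing comparison per montage from the out-of-fold predictions
  dose_rows <- lapply(montage_ids, function(m) {
    d <- oof[oof$montage_id == m, ]
    std <- standardized_distribution(d$true_e, d$pred_e,
                                     e_target = config$e_target,
                                     max_current = config$max_current)
    fx <- fixed_dose_distribution(d$true_e, e_target = config$e_target)
    lv <- levene_test(list(standardized = std, fixed = fx),
                      center = config$levene_center)
    data.frame(montage_id = m, class = classes[[m]],
               sd_fixed = stats::sd(fx), sd_standardized = stats::sd(std),
               sd_reduction_pct = 100 * (1 - stats::sd(std) / stats::sd(fx)),
               levene_f = lv$statistic, levene_p = lv$p_value,
               stringsAsFactors = FALSE)
  })
  dosing <- do.call(rbind, dose_rows)
  dosing$levene_p_adjusted <- bonferroni(dosing$levene_p, m = nrow(dosing))

  summarize <- function(df, what) {
    agg <- stats::aggregate(df[[what]],
                            by = list(class = df$class), FUN = mean)
    stats::setNames(agg$x, agg$class)
  }
  summary <- list(
    ms_mean_adj_r2 = summarize(ms_metrics, "adj_r2"),
    ms_mean_nrmse = summarize(ms_metrics, "nrmse"),
    agnostic_mean_adj_r2 = lapply(split(ag_metrics, ag_metrics$variant),
                                  summarize, what = "adj_r2"),
    sd_reduction_pct = summarize(dosing, "sd_reduction_pct")
  )

  structure(list(counts = counts, ms_metrics = ms_metrics,
                 agnostic_metrics = ag_metrics, dosing = dosing,
                 predictions = oof, summary = summary,
                 config = unclass(config), seed = config$seed,
                 schema_version = "1"),
            class = "tes_report")
}

#' Serialize a protocol report to JSON
#'
#' @param report a `tes_report`.
#' @param path output path.
#' @export
save_report_json <- function(report, path) {
  # named atomic vectors become JSON objects so names survive round trips
  namify <- function(x) {
    if (is.data.frame(x)) x
    else if (is.list(x)) lapply(x, namify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(namify(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", null = "null",
                       force = TRUE)
  invisible(path)
}
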