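#' Kruskal-Wallis condition contrasts
#'
#' Runs the protocol's standard stance contrasts on an NPL table: each
#' eyes-open condition against its eyes-closed pair (1 vs 2, 3 vs 4, 5 vs 6),
#' and the reference stance (firm surface, feet together, eyes open) against
#' the foam-surface and tandem eyes-open stances (1 vs 3, 1 vs 5). Contrasts
#' with an empty side are skipped with a message.
#'
#' @param npl NPL results table for one device (retained trials).
#' @param metric `"npl_ap"` (default) or `"npl_total"`.
#' @return Data frame with `contrast`, `cond_a`, `cond_b`, `n_a`, `n_b`,
#'   `H`, `p_value` (skipped contrasts omitted).
#' @export
report_condition_effects <- function(npl, metric = "npl_ap") {
  pairs <- rbind(
    data.frame(contrast = c("eyes open vs closed (firm, feet together)",
                            "eyes open vs closed (foam, feet together)",
                            "eyes open vs closed (firm, tandem)"),
               cond_a = c(1L, 3L, 5L), cond_b = c(2L, 4L, 6L)),
    data.frame(contrast = c("firm feet-together vs foam",
                            "firm feet-together vs tandem"),
               cond_a = c(1L, 1L), cond_b = c(3L, 5L)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- npl[[metric]][npl$condition == pairs$cond_a[i]]
    b <- npl[[metric]][npl$condition == pairs$cond_b[i]]
    if (length(a) < 2 || length(b) < 2) {
      message("skipping contrast '", pairs$contrast[i],
              "': a condition has < 2 retained trials")
      return(NULL)
    }
    kw <- kruskal_wallis(list(a, b))
    data.frame(contrast = pairs$contrast[i], cond_a = pairs$cond_a[i],
               cond_b = pairs$cond_b[i], n_a = length(a), n_b = length(b),
               H = kw$H, p_value = kw$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# ICC matrices for one device/metric: per condition, rows are subjects with
# both attempts retained; the joint matrix stacks subject-condition rows.
.icc_matrices <- function(npl, metric) {
  per_cond <- list()
  joint <- NULL
  for (cc in sort(unique(npl$condition))) {
    sub <- npl[npl$condition == cc, ]
    wide <- stats::reshape(sub[, c("subject_id", "attempt", metric)],
                           idvar = "subject_id", timevar = "attempt",
                           direction = "wide")
    mat <- as.matrix(wide[, -1, drop = FALSE])
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    if (nrow(mat) >= 2 && ncol(mat) >= 2) {
      per_cond[[as.character(cc)]] <- mat
      joint <- rbind(joint, mat)
    }
  }
  list(per_condition = per_cond, joint = joint)
}

#' Analyze an NPL results table into the study's result surface
#'
#' Computes the full validation summary from per-trial NPL values and the
#' study manifest: failure exclusion and pass tallies; per-condition
#' geometric-mean summaries; pooled head-waist Spearman correlations (one
#' point per retained trial, all conditions pooled) for AP and total NPL with
#' their Fisher-z comparison; test-retest ICC(2,1) per device and metric
#' (jointly over subject-condition rows, and per condition); Kruskal-Wallis
#' stance contrasts; Anderson-Darling normality checks within conditions;
#' and composite scores.
#'
#' @param npl NPL results (all computed trials; failures are excluded here
#'   against the manifest).
#' @param manifest The study manifest.
#' @param ref Optional [normative_reference()] for the composite; when
#'   `NULL`, a reference is built from the analyzed waist data itself
#'   (internal standardization, flagged in the report).
#' @param alpha Two-sided error rate for CIs (default 0.05).
#' @return An object of class `study_report`.
#' @export
analyze_npl <- function(npl, manifest, ref = NULL, alpha = 0.05) {
  ex <- exclude_failures(npl, manifest)
  retained <- ex$retained
  if (nrow(retained) == 0) stop("analysis stage: no retained trials")

  # per-condition geometric-mean summaries
  summ <- list()
  for (device in unique(retained$device)) {
    for (metric in c("npl_ap", "npl_total")) {
      for (cc in sort(unique(retained$condition))) {
        v <- retained[[metric]][retained$device == device &
                                retained$condition == cc]
        if (!length(v)) next
        g <- geometric_mean_ci(v, alpha)
        summ[[length(summ) + 1]] <- data.frame(
          device = device, metric = metric, condition = cc, gm = g$gm,
          ci_low = g$ci_low, ci_high = g$ci_high, n = g$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  condition_summaries <- do.call(rbind, summ)

  # pooled inter-device correlation: one point per retained trial
  key <- function(d) paste(d$subject_id, d$condition, d$attempt, sep = "\r")
  head_t <- retained[retained$device == "head", ]
  waist_t <- retained[retained$device == "waist", ]
  idx <- match(key(head_t), key(waist_t))
  paired <- !is.na(idx)
  correlation <- NULL
  if (sum(paired) >= 4) {
    h <- head_t[paired, ]; w <- waist_t[idx[paired], ]
    rho_ap <- spearman_rho(h$npl_ap, w$npl_ap)
    rho_total <- spearman_rho(h$npl_total, w$npl_total)
    correlation <- list(
      rho_ap = rho_ap, rho_total = rho_total, n = nrow(h),
      fisher = if (!is.na(rho_ap) && !is.na(rho_total) &&
                   abs(rho_ap) < 1 && abs(rho_total) < 1)
        compare_correlations_fisher(rho_total, nrow(h), rho_ap, nrow(h))
      else NULL)
  }

  # test-retest reliability
  icc <- list()
  for (device in unique(retained$device)) {
    for (metric in c("npl_ap", "npl_total")) {
      mats <- .icc_matrices(retained[retained$device == device, ], metric)
      if (is.null(mats$joint) || nrow(mats$joint) < 2) next
      icc[[paste(device, metric, sep = ".")]] <- list(
        joint = icc_2_1(mats$joint, alpha),
        per_condition = lapply(mats$per_condition, icc_2_1, alpha = alpha))
    }
  }

  # stance contrasts and within-condition normality, per device (AP NPL)
  contrasts <- list(); normality <- list()
  for (device in unique(retained$device)) {
    sub <- retained[retained$device == device, ]
    contrasts[[device]] <- report_condition_effects(sub, "npl_ap")
    nr <- lapply(sort(unique(sub$condition)), function(cc) {
      v <- sub$npl_ap[sub$condition == cc]
      if (length(v) < 8) return(NULL)
      ad <- anderson_darling_normal(v, alpha)
      data.frame(device = device, condition = cc, A2 = ad$A2,
                 p_value = ad$p_value, reject_normality = ad$reject,
                 n = ad$n, stringsAsFactors = FALSE)
    })
    normality[[device]] <- do.call(rbind, nr[!vapply(nr, is.null, logical(1))])
  }

  # composite scores (per device, AP NPL)
  internal_ref <- is.null(ref)
  if (internal_ref) {
    wsrc <- if (nrow(waist_t)) waist_t else retained
    ref <- build_reference_from_npl(wsrc, "npl_ap")
  }
  composites <- list()
  for (device in unique(retained$device)) {
    cs <- composite_scores(retained[retained$device == device, ], ref)
    ok <- !is.na(cs$composite)
    composites[[device]] <- list(
      scores = cs, mean = if (any(ok)) mean(cs$composite[ok]) else NA_real_,
      sd = if (sum(ok) > 1) stats::sd(cs$composite[ok]) else NA_real_,
      n = sum(ok))
  }

  structure(list(
    n_trials_input = nrow(npl), n_trials_retained = nrow(retained),
    tally = ex$tally, condition_summaries = condition_summaries,
    correlation = correlation, icc = icc, contrasts = contrasts,
    normality = do.call(rbind, normality), composites = composites,
    reference = ref, internal_reference = internal_ref,
    retained = retained, alpha = alpha
  ), class = "study_report")
}

#' Run the full analysis pipeline from a manifest of trial files
#'
#' Reads every manifest entry, computes NPL for each non-failed trial
#' (failed trials are excluded up front, as recorded by the facilitator),
#' and assembles the study's result surface via [analyze_npl()]. Optionally
#' writes tidy CSVs and a markdown report; re-running on identical inputs
#' and configuration yields byte-identical outputs.
#'
#' @param manifest_path Path to the study manifest (trial paths resolved
#'   relative to it).
#' @param out_dir Optional output directory for `npl.csv`,
#'   `condition_summaries.csv`, `statistics.csv` and `report.md`.
#' @param conventions Axis conventions per device.
#' @param trim,filt,total_variant Preprocessing and metric settings.
#' @param ref Optional [normative_reference()] for composites.
#' @param alpha CI error rate.
#' @param verbose Log per-trial exclusions (default `TRUE`).
#' @return A `study_report` (invisibly when `out_dir` is given).
#' @export
run_pipeline <- function(manifest_path, out_dir = NULL,
                         conventions = default_conventions(),
                         trim = trim_spec(), filt = filter_spec(),
                         total_variant = "path3d", ref = NULL, alpha = 0.05,
                         verbose = TRUE) {
  manifest <- tryCatch(read_manifest(manifest_path),
                       error = function(e) stop("manifest stage: ",
                                                conditionMessage(e)))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    entry <- manifest[i, ]
    if (entry$failed) {
      if (verbose)
        message(sprintf("excluding failed trial %s/%s c%d a%d (%s)",
                        entry$subject_id, entry$device, entry$condition,
                        entry$attempt,
                        if (is.na(entry$failure_reason)) "unspecified"
                        else entry$failure_reason))
      next
    }
    tr <- tryCatch(
      read_trial_csv(entry$file, entry, conventions[[entry$device]]),
      error = function(e) stop("read stage (", entry$file, "): ",
                               conditionMessage(e)))
    rows[[i]] <- tryCatch(
      trial_npl(tr, conventions[[entry$device]], trim, filt, total_variant),
      error = function(e) stop("metric stage (", entry$file, "): ",
                               conditionMessage(e)))
  }
  npl <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  report <- analyze_npl(npl, manifest, ref = ref, alpha = alpha)
  if (!is.null(out_dir)) {
    write_report_files(report, out_dir)
    return(invisible(report))
  }
  report
}

#' Write a study report's tidy CSVs and markdown summary
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_report_files <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE, quote = FALSE)
  wcsv(report$retained, "npl.csv")
  wcsv(report$condition_summaries, "condition_summaries.csv")

  stat_rows <- list()
  add <- function(name, value, n) stat_rows[[length(stat_rows) + 1]] <<-
    data.frame(statistic = name, value = value, n = n,
               stringsAsFactors = FALSE)
  if (!is.null(report$correlation)) {
    add("pooled_spearman_ap", report$correlation$rho_ap, report$correlation$n)
    add("pooled_spearman_total", report$correlation$rho_total,
        report$correlation$n)
    if (!is.null(report$correlation$fisher)) {
      add("fisher_z_total_vs_ap", report$correlation$fisher$z_statistic,
          report$correlation$n)
      add("fisher_p_total_vs_ap", report$correlation$fisher$p_value,
          report$correlation$n)
    }
  }
  for (nm in names(report$icc)) {
    est <- report$icc[[nm]]$joint
    add(paste0("icc_", gsub(".", "_", nm, fixed = TRUE)), est$icc,
        est$n_subjects)
    add(paste0("icc_", gsub(".", "_", nm, fixed = TRUE), "_ci_low"),
        est$ci_low, est$n_subjects)
    add(paste0("icc_", gsub(".", "_", nm, fixed = TRUE), "_ci_high"),
        est$ci_high, est$n_subjects)
  }
  for (dev in names(report$composites)) {
    add(paste0("composite_mean_", dev), report$composites[[dev]]$mean,
        report$composites[[dev]]$n)
    add(paste0("composite_sd_", dev), report$composites[[dev]]$sd,
        report$composites[[dev]]$n)
  }
  wcsv(do.call(rbind, stat_rows), "statistics.csv")

  md <- utils::capture.output(print(report))
  writeLines(c("# Standing-balance study report", "", "```", md, "```"),
             file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Standing-balance study report\n")
  cat(sprintf("  trials: %d analyzed of %d computed (failures excluded)\n",
              x$n_trials_retained, x$n_trials_input))
  print(x$tally)
  if (!is.null(x$correlation)) {
    cat(sprintf(
      "  pooled head-waist Spearman rho: AP = %.3f, total = %.3f (n = %d)\n",
      x$correlation$rho_ap, x$correlation$rho_total, x$correlation$n))
    if (!is.null(x$correlation$fisher))
      cat(sprintf("    total vs AP (Fisher z): z = %.2f, p = %.4g\n",
                  x$correlation$fisher$z_statistic,
                  x$correlation$fisher$p_value))
  }
  for (nm in names(x$icc)) {
    est <- x$icc[[nm]]$joint
    cat(sprintf("  ICC(2,1) %-16s = %.3f (%.3f-%.3f), n = %d\n",
                nm, est$icc, est$ci_low, est$ci_high, est$n_subjects))
  }
  for (dev in names(x$composites)) {
    cm <- x$composites[[dev]]
    cat(sprintf("  composite score [%s]: mean %.2f (SD %.2f), n = %d%s\n",
                dev, cm$mean, cm$sd, cm$n,
                if (x$internal_reference) "  [internally standardized]" else ""))
  }
  if (!is.null(x$contrasts)) {
    for (dev in names(x$contrasts)) {
      ct <- x$contrasts[[dev]]
      if (is.null(ct)) next
      cat(sprintf("  stance contrasts [%s, AP NPL]:\n", dev))
      for (i in seq_len(nrow(ct)))
        cat(sprintf("    %-45s H = %6.2f, p = %.3g\n",
                    ct$contrast[i], ct$H[i], ct$p_value[i]))
    }
  }
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  print(object)
  cat("\nPer-condition geometric means:\n")
  print(object$condition_summaries, row.names = FALSE)
  invisible(object)
}
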