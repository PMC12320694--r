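# End-to-end study pipeline: ingest cohort CSVs, score limbs, compute
# volumetric outcomes, run the nonparametric association battery, and emit a
# structured report. Every analysis block records its own n; blocks that
# cannot be computed (insufficient or degenerate data) are marked
# "not computed" with a reason and the run continues.

tp_levels <- c("pre", "1m", "3m", "6m")
post_tp <- c("1m", "3m", "6m")

#' Load a cohort from CSV files
#'
#' Reads `reads.csv` (one row per limb: patient_id, side, K, D, node_time_min
#' — empty when nodes were never visualized — N, V, collateral 0/1, optional
#' `reading` pass number), `volumetry.csv` (patient_id, side, timepoint in
#' pre/1m/3m/6m, c1..c5 in cm, bmi) and `patients.csv` (patient_id, age,
#' stage, duration_years, bmi, affected_side, optional `bilateral` flag).
#' Schema violations raise errors with row-level diagnostics naming the field;
#' orphan limb rows and duplicate (patient, side, timepoint) rows are
#' rejected. Limbs with missing post-operative timepoints are retained; the
#' affected analyses simply exclude them from those timepoints.
#'
#' @param reads_path,volumetry_path,patients_path CSV file paths.
#' @return A `lymph_cohort`.
#' @export
load_cohort <- function(reads_path, volumetry_path, patients_path) {
  for (p in c(reads_path, volumetry_path, patients_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  reads <- readr::read_csv(reads_path, na = c("", "NA"), show_col_types = FALSE)
  volumetry <- readr::read_csv(volumetry_path, na = c("", "NA"), show_col_types = FALSE)
  patients <- readr::read_csv(patients_path, na = c("", "NA"), show_col_types = FALSE)

  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop(file, " is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  need(reads, c("patient_id", "side", read_cols), "reads.csv")
  need(volumetry, c("patient_id", "side", "timepoint", paste0("c", 1:5), "bmi"),
       "volumetry.csv")
  need(patients, c("patient_id", "age", "stage", "duration_years", "bmi",
                   "affected_side"), "patients.csv")

  bad_side <- !reads$side %in% c("affected", "contralateral")
  if (any(bad_side)) {
    stop("reads.csv: side must be 'affected' or 'contralateral', row(s): ",
         paste(which(bad_side), collapse = ", "), call. = FALSE)
  }
  reads$collateral <- as.logical(reads$collateral)
  validate_reads(reads)
  if (!"reading" %in% names(reads)) reads$reading <- 1L
  dup <- duplicated(reads[c("patient_id", "side", "reading")])
  if (any(dup)) {
    stop("reads.csv: duplicate (patient_id, side, reading) row(s): ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }

  bad_tp <- !volumetry$timepoint %in% tp_levels
  if (any(bad_tp)) {
    stop("volumetry.csv: timepoint must be one of ", paste(tp_levels, collapse = "/"),
         ", row(s): ", paste(which(bad_tp), collapse = ", "), call. = FALSE)
  }
  circ <- as.matrix(volumetry[paste0("c", 1:5)])
  bad_c <- rowSums(!is.finite(circ) | circ <= 0) > 0
  if (any(bad_c)) {
    stop("volumetry.csv: non-positive or missing circumference (c1..c5) in row(s): ",
         paste(which(bad_c), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(volumetry$bmi) | volumetry$bmi <= 0)) {
    stop("volumetry.csv: bmi must be positive", call. = FALSE)
  }
  dupv <- duplicated(volumetry[c("patient_id", "side", "timepoint")])
  if (any(dupv)) {
    stop("volumetry.csv: duplicate (patient_id, side, timepoint) row(s): ",
         paste(which(dupv), collapse = ", "), call. = FALSE)
  }

  orphan_r <- !reads$patient_id %in% patients$patient_id
  if (any(orphan_r)) {
    stop("reads.csv: patient_id not in patients.csv, row(s): ",
         paste(which(orphan_r), collapse = ", "), call. = FALSE)
  }
  orphan_v <- !volumetry$patient_id %in% patients$patient_id
  if (any(orphan_v)) {
    stop("volumetry.csv: patient_id not in patients.csv, row(s): ",
         paste(which(orphan_v), collapse = ", "), call. = FALSE)
  }
  has_pre <- patients$patient_id %in%
    volumetry$patient_id[volumetry$side == "affected" & volumetry$timepoint == "pre"]
  if (any(!has_pre)) {
    stop("patients.csv: missing pre-operative affected-limb volumetry for: ",
         paste(patients$patient_id[!has_pre], collapse = ", "), call. = FALSE)
  }
  structure(list(patients = patients, reads = reads, volumetry = volumetry,
                 config = NULL, seed = NA_integer_),
            class = "lymph_cohort")
}

# wrap an analysis block: failures become "not computed" entries
compute_block <- function(expr) {
  tryCatch(c(list(computed = TRUE), expr),
           error = function(e) list(computed = FALSE, reason = conditionMessage(e)))
}

summ <- function(x) {
  x <- x[!is.na(x)]
  list(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x), n = length(x))
}

corr_entry <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  ct <- spearman_test(x[keep], y[keep])
  list(rho = ct$estimate, p = ct$p_value, n = ct$n)
}

#' Run the full study analysis
#'
#' Executes, on a loaded or generated cohort: per-limb TI at the 240- and
#' 120-minute windows; counts of limbs with identical versus higher TI_120 and
#' the distribution of positive differences; LELI and %LELI change per
#' post-operative timepoint; stage-wise TI comparison (Kruskal-Wallis);
#' Spearman correlation of TI with the pre-operative affected-contralateral
#' LELI excess; Mann-Whitney association of each binary lymphoscintigraphy
#' criterion with %LELI change per timepoint; Spearman correlation of TI
#' (both windows) with %LELI change per timepoint; inter-timepoint %LELI
#' correlations; the affected-versus-contralateral pre-operative Wilcoxon
#' comparison; intra-rater ICC when two reading passes are present; and an
#' optional stage-3 subgroup rerun of the TI-outcome correlations.
#'
#' When a second reading pass exists, analyses use pass 1 (the consensus is
#' expected to be recorded as pass 1); the ICC compares passes 1 and 2.
#'
#' @param cohort A `lymph_cohort`.
#' @param subgroup_stage3 Rerun the TI-outcome correlations on stage-3
#'   patients only.
#' @param p_adjust `"none"` (default, matching the study) or `"holm"` to
#'   adjust the binary-criterion p-values within each timepoint.
#' @param include_bilateral Keep patients flagged `bilateral` in outcome
#'   analyses (sensitivity analysis); by default they are dropped.
#' @return A `lymph_report` (nested list of blocks, each with its own n).
#' @export
run_study <- function(cohort, subgroup_stage3 = FALSE,
                      p_adjust = c("none", "holm"), include_bilateral = FALSE) {
  p_adjust <- match.arg(p_adjust)
  patients <- cohort$patients
  reads <- cohort$reads
  if (!"reading" %in% names(reads)) reads$reading <- 1L
  volumetry <- cohort$volumetry
  if (nrow(patients) < 3) stop("need at least 3 patients", call. = FALSE)

  excluded <- character(0)
  if (!include_bilateral && "bilateral" %in% names(patients)) {
    excluded <- patients$patient_id[patients$bilateral %in% TRUE]
  }

  reads1 <- reads[reads$reading == 1L, ]
  scored <- score_reads(reads1, window = 240)
  limb_ti <- tibble::tibble(
    patient_id = scored$patient_id, side = scored$side,
    ti_240 = scored$ti, ti_120 = score_reads(reads1, window = 120)$ti
  )

  vol <- volumetry
  vol$leli <- leli(vol[paste0("c", 1:5)], vol$bmi)
  leli_wide <- tidyr::pivot_wider(vol[c("patient_id", "side", "timepoint", "leli")],
                                  names_from = "timepoint", values_from = "leli")
  for (tp in setdiff(tp_levels, names(leli_wide))) leli_wide[[tp]] <- NA_real_
  aff <- leli_wide[leli_wide$side == "affected", ]
  con <- leli_wide[leli_wide$side == "contralateral", ]

  df <- dplyr::left_join(patients, limb_ti[limb_ti$side == "affected", ],
                         by = "patient_id")
  df <- dplyr::left_join(df, stats::setNames(aff[c("patient_id", tp_levels)],
                                             c("patient_id", paste0("leli_", tp_levels))),
                         by = "patient_id")
  df <- dplyr::left_join(df, stats::setNames(con[c("patient_id", "pre")],
                                             c("patient_id", "leli_pre_contra")),
                         by = "patient_id")
  df$excess <- df$leli_pre - df$leli_pre_contra
  for (tp in post_tp) {
    post <- df[[paste0("leli_", tp)]]
    df[[paste0("pct_", tp)]] <- ifelse(
      is.na(post), NA_real_, 100 * (df$leli_pre - post) / df$leli_pre)
  }
  flags <- binarize_reads(reads1[reads1$side == "affected", ])
  df <- dplyr::left_join(df, flags, by = "patient_id")
  outcome_df <- df[!df$patient_id %in% excluded, ]

  descriptives <- compute_block(list(
    n = nrow(patients),
    age = summ(df$age), bmi = summ(df$bmi), duration_years = summ(df$duration_years),
    stage_counts = as.list(table(df$stage)),
    leli_affected_pre = summ(df$leli_pre),
    leli_contralateral_pre = summ(df$leli_pre_contra)
  ))

  component_counts <- compute_block({
    ar <- reads1[reads1$side == "affected", ]
    count_scores <- function(x) {
      sapply(as.character(ti_score_levels), function(s) sum(x == as.integer(s)))
    }
    list(
      scores = tibble::tibble(
        component = c("K", "D", "N", "V"),
        score_0 = c(count_scores(ar$K)[1], count_scores(ar$D)[1],
                    count_scores(ar$N)[1], count_scores(ar$V)[1]),
        score_3 = c(count_scores(ar$K)[2], count_scores(ar$D)[2],
                    count_scores(ar$N)[2], count_scores(ar$V)[2]),
        score_5 = c(count_scores(ar$K)[3], count_scores(ar$D)[3],
                    count_scores(ar$N)[3], count_scores(ar$V)[3]),
        score_9 = c(count_scores(ar$K)[4], count_scores(ar$D)[4],
                    count_scores(ar$N)[4], count_scores(ar$V)[4])
      ),
      node_time_counts = as.list(table(ar$node_time_min, useNA = "always")),
      collateral_present = sum(ar$collateral), n = nrow(ar)
    )
  })

  ti_summary <- compute_block({
    contra <- limb_ti$ti_240[limb_ti$side == "contralateral"]
    list(
      ti_240_affected = summ(df$ti_240), ti_120_affected = summ(df$ti_120),
      # contralateral TIs above 2 cannot arise from an all-normal read
      # (max 0 + 0 + 0.04*30 + 0 + 0 = 1.2) and are reported descriptively
      contralateral_elevated = sort(contra[contra > 2]),
      contralateral_n = length(contra)
    )
  })

  ti_windows <- compute_block({
    d <- df$ti_120 - df$ti_240
    pos <- d[d > 1e-9]
    list(n = length(d), n_identical = sum(abs(d) < 1e-9), n_higher_120 = length(pos),
         diff = if (length(pos) > 0) summ(pos) else NULL)
  })

  stage_ti <- compute_block({
    by_stage <- function(v) lapply(split(v, df$stage), summ)
    kt240 <- kruskal_wallis_test(split(df$ti_240, df$stage))
    kt120 <- kruskal_wallis_test(split(df$ti_120, df$stage))
    list(ti_240 = list(by_stage = by_stage(df$ti_240), p = kt240$p_value),
         ti_120 = list(by_stage = by_stage(df$ti_120), p = kt120$p_value),
         n = nrow(df))
  })

  ti_excess_corr <- compute_block(list(
    ti_240 = corr_entry(df$ti_240, df$excess),
    ti_120 = corr_entry(df$ti_120, df$excess)
  ))

  pct_leli <- compute_block({
    out <- lapply(post_tp, function(tp) summ(outcome_df[[paste0("pct_", tp)]]))
    names(out) <- post_tp
    out
  })

  binary_assoc <- compute_block({
    flag_cols <- c("kinetics_delayed", "dbf_present", "node_time_late",
                   "nodes_not_visualized", "vessel_not_visualized",
                   "collateral_present")
    tab <- lapply(post_tp, function(tp) {
      y <- outcome_df[[paste0("pct_", tp)]]
      vapply(flag_cols, function(fc) {
        g <- outcome_df[[fc]]
        keep <- !is.na(y) & !is.na(g)
        if (sum(keep & g) == 0 || sum(keep & !g) == 0) return(NA_real_)
        tryCatch(mann_whitney_test(y[keep & g], y[keep & !g])$p_value,
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    names(tab) <- post_tp
    if (p_adjust == "holm") {
      tab <- lapply(tab, function(p) stats::p.adjust(p, method = "holm"))
    }
    list(p_values = tibble::tibble(
      parameter = flag_cols,
      at_1m = tab[["1m"]], at_3m = tab[["3m"]], at_6m = tab[["6m"]]
    ), p_adjust = p_adjust, n = nrow(outcome_df))
  })

  ti_outcome_corr <- compute_block({
    grid <- expand.grid(window = c(240L, 120L), timepoint = post_tp,
                        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      ti <- outcome_df[[if (grid$window[i] == 240) "ti_240" else "ti_120"]]
      y <- outcome_df[[paste0("pct_", grid$timepoint[i])]]
      e <- tryCatch(corr_entry(ti, y),
                    error = function(err) list(rho = NA_real_, p = NA_real_,
                                               n = sum(stats::complete.cases(ti, y))))
      tibble::tibble(window = grid$window[i], timepoint = grid$timepoint[i],
                     rho = e$rho, p = e$p, n = e$n)
    })
    list(correlations = dplyr::bind_rows(rows))
  })

  intertime_corr <- compute_block({
    pairs <- list(c("1m", "3m"), c("3m", "6m"), c("1m", "6m"))
    rows <- lapply(pairs, function(pr) {
      e <- tryCatch(corr_entry(outcome_df[[paste0("pct_", pr[1])]],
                               outcome_df[[paste0("pct_", pr[2])]]),
                    error = function(err) list(rho = NA_real_, p = NA_real_, n = NA_integer_))
      tibble::tibble(from = pr[1], to = pr[2], rho = e$rho, p = e$p, n = e$n)
    })
    list(correlations = dplyr::bind_rows(rows))
  })

  leli_side_test <- compute_block({
    keep <- stats::complete.cases(df$leli_pre, df$leli_pre_contra)
    wt <- wilcoxon_signed_rank_test(df$leli_pre[keep], df$leli_pre_contra[keep])
    list(statistic = wt$statistic, p = wt$p_value, n = sum(keep))
  })

  icc <- compute_block({
    r2 <- reads[reads$reading == 2L & reads$side == "affected", ]
    if (nrow(r2) == 0) stop("single reading pass: ICC not applicable")
    t1 <- score_reads(reads1[reads1$side == "affected" &
                               reads1$patient_id %in% r2$patient_id, ], 240)
    t2 <- score_reads(r2, 240)
    m <- dplyr::inner_join(t1[c("patient_id", "ti")], t2[c("patient_id", "ti")],
                           by = "patient_id", suffix = c("_1", "_2"))
    list(icc = icc_intrarater(m$ti_1, m$ti_2), n = nrow(m))
  })

  stage3 <- if (subgroup_stage3) {
    compute_block({
      sub <- outcome_df[outcome_df$stage == 3, ]
      grid <- expand.grid(window = c(240L, 120L), timepoint = post_tp,
                          stringsAsFactors = FALSE)
      rows <- lapply(seq_len(nrow(grid)), function(i) {
        ti <- sub[[if (grid$window[i] == 240) "ti_240" else "ti_120"]]
        y <- sub[[paste0("pct_", grid$timepoint[i])]]
        e <- tryCatch(corr_entry(ti, y),
                      error = function(err) list(rho = NA_real_, p = NA_real_,
                                                 n = sum(stats::complete.cases(ti, y))))
        tibble::tibble(window = grid$window[i], timepoint = grid$timepoint[i],
                       rho = e$rho, p = e$p, n = e$n)
      })
      list(correlations = dplyr::bind_rows(rows), n = nrow(sub))
    })
  } else {
    list(computed = FALSE, reason = "subgroup not requested")
  }

  limb_table <- limb_ti
  outcome_table <- outcome_df[c("patient_id", "stage", "ti_240", "ti_120",
                                "leli_pre", "excess",
                                paste0("pct_", post_tp))]

  structure(list(
    descriptives = descriptives,
    component_counts = component_counts,
    ti_summary = ti_summary,
    ti_windows = ti_windows,
    stage_ti = stage_ti,
    ti_excess_corr = ti_excess_corr,
    pct_leli = pct_leli,
    binary_assoc = binary_assoc,
    ti_outcome_corr = ti_outcome_corr,
    intertime_corr = intertime_corr,
    leli_side_test = leli_side_test,
    icc = icc,
    stage3_subgroup = stage3,
    limb_ti = limb_table,
    outcomes = outcome_table,
    n_excluded = length(excluded)
  ), class = "lymph_report")
}

#' @export
print.lymph_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
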