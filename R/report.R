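# Report serialization: machine-readable JSON and per-table CSVs at full
# precision, plus a rendered text summary with display rounding (TI to 1
# decimal, rho to 3, p to 3).

fmt_ms <- function(s, digits = 1) {
  if (is.null(s)) return("not computed")
  sprintf("%.*f +/- %.*f (range, %.*f-%.*f; n = %d)",
          digits, s$mean, digits, s$sd, digits, s$min, digits, s$max, s$n)
}

fmt_corr <- function(e) {
  sprintf("r = %.3f, p = %.3f (n = %d)", e$rho, e$p, e$n)
}

#' Render a report as human-readable text
#'
#' Display rounding only; the JSON and CSV outputs of [write_report()] keep
#' full precision.
#'
#' @param report A `lymph_report`.
#' @return Character vector of lines.
#' @export
render_report <- function(report) {
  out <- character(0)
  add <- function(...) out <<- c(out, paste0(...))
  add("Lymphoscintigraphy TI / LVA outcome study report")
  add("================================================")
  if (report$descriptives$computed) {
    d <- report$descriptives
    add("Patients: ", d$n,
        " | age ", fmt_ms(d$age, 0),
        " | BMI ", fmt_ms(d$bmi, 1))
    add("Stage counts: ",
        paste(names(d$stage_counts), unlist(d$stage_counts), sep = ":", collapse = ", "))
    add("Pre-op LELI affected: ", fmt_ms(d$leli_affected_pre),
        " | contralateral: ", fmt_ms(d$leli_contralateral_pre))
  }
  if (report$ti_summary$computed) {
    s <- report$ti_summary
    add("TI_240 affected: ", fmt_ms(s$ti_240_affected),
        " | TI_120 affected: ", fmt_ms(s$ti_120_affected))
    add("Contralateral limbs with elevated TI (> 2): ",
        if (length(s$contralateral_elevated) > 0) {
          paste(sprintf("%.1f", s$contralateral_elevated), collapse = ", ")
        } else "none")
  }
  if (report$ti_windows$computed) {
    w <- report$ti_windows
    add("TI_120 vs TI_240: identical in ", w$n_identical, "/", w$n,
        ", higher in ", w$n_higher_120,
        if (!is.null(w$diff)) paste0(" (difference ", fmt_ms(w$diff), ")") else "")
  }
  if (report$stage_ti$computed) {
    add("Stage-wise TI_240 Kruskal-Wallis p = ",
        sprintf("%.3f", report$stage_ti$ti_240$p),
        "; TI_120 p = ", sprintf("%.3f", report$stage_ti$ti_120$p))
  }
  if (report$ti_excess_corr$computed) {
    add("TI vs pre-op excess: TI_240 ", fmt_corr(report$ti_excess_corr$ti_240),
        "; TI_120 ", fmt_corr(report$ti_excess_corr$ti_120))
  }
  if (report$pct_leli$computed) {
    p <- report$pct_leli
    add("%dLELI: 1m ", fmt_ms(p[["1m"]]), " | 3m ", fmt_ms(p[["3m"]]),
        " | 6m ", fmt_ms(p[["6m"]]))
  }
  if (report$ti_outcome_corr$computed) {
    add("TI vs %dLELI (Spearman):")
    tab <- report$ti_outcome_corr$correlations
    for (i in seq_len(nrow(tab))) {
      add(sprintf("  TI_%d vs %s: r = %.3f, p = %.3f (n = %d)",
                  tab$window[i], tab$timepoint[i], tab$rho[i], tab$p[i], tab$n[i]))
    }
  }
  if (report$binary_assoc$computed) {
    add("Binary criteria vs %dLELI (Mann-Whitney p): ")
    tab <- report$binary_assoc$p_values
    for (i in seq_len(nrow(tab))) {
      add(sprintf("  %-22s 1m %.3f | 3m %.3f | 6m %.3f", tab$parameter[i],
                  tab$at_1m[i], tab$at_3m[i], tab$at_6m[i]))
    }
  }
  if (report$leli_side_test$computed) {
    add("Affected vs contralateral pre-op LELI (Wilcoxon): p = ",
        sprintf("%.3g", report$leli_side_test$p), " (n = ", report$leli_side_test$n, ")")
  }
  if (report$icc$computed) {
    add("Intra-rater ICC (TI_240, two passes): ",
        sprintf("%.3f", report$icc$icc), " (n = ", report$icc$n, ")")
  }
  if (report$stage3_subgroup$computed) {
    add("Stage-3 subgroup TI vs %dLELI:")
    tab <- report$stage3_subgroup$correlations
    for (i in seq_len(nrow(tab))) {
      add(sprintf("  TI_%d vs %s: r = %.3f, p = %.3f (n = %d)",
                  tab$window[i], tab$timepoint[i], tab$rho[i], tab$p[i], tab$n[i]))
    }
  }
  out
}

#' Write a study report to disk
#'
#' Emits `report.json` (full precision, machine-readable), per-table CSVs
#' (`limb_ti.csv`, `outcomes.csv`, `binary_assoc.csv`, `ti_outcome_corr.csv`)
#' and a rounded `summary.txt`. Output is deterministic: identical reports
#' produce byte-identical files.
#'
#' @param report A `lymph_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, dataframe = "columns")
  readr::write_csv(report$limb_ti, file.path(out_dir, "limb_ti.csv"), na = "")
  readr::write_csv(report$outcomes, file.path(out_dir, "outcomes.csv"), na = "")
  if (report$binary_assoc$computed) {
    readr::write_csv(report$binary_assoc$p_values,
                     file.path(out_dir, "binary_assoc.csv"), na = "")
  }
  if (report$ti_outcome_corr$computed) {
    readr::write_csv(report$ti_outcome_corr$correlations,
                     file.path(out_dir, "ti_outcome_corr.csv"), na = "")
  }
  writeLines(render_report(report), file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' Read back a report written by [write_report()]
#'
#' @param out_dir Directory containing `report.json`.
#' @return The report as a plain nested list (tables as data frames).
#' @export
read_report <- function(out_dir) {
  path <- if (dir.exists(out_dir)) file.path(out_dir, "report.json") else out_dir
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
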