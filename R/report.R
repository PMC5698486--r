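#' Write a prediction report to disk
#'
#' Emits three CSV tables: (i) the per-signal shift table (multiplicity,
#' both route predictions, combined estimate, uncertainties, route used),
#' (ii) the ions/albumin/pH/T table with clinical-range flags where
#' configured, and (iii) the active-metabolite concentration table;
#' optionally an annotated-spectrum figure (PNG) when the source spectrum
#' is supplied.
#'
#' @param report A `prediction_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @param spectrum Optional `nmr_spectrum` for the annotated figure.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, out_dir, spectrum = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_report: cannot create directory ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) {
    stop("write_report: directory not writable: ", out_dir)
  }
  files <- character(0)

  f1 <- file.path(out_dir, "signals.csv")
  sig <- report$signals
  num <- vapply(sig, is.numeric, logical(1))
  sig[num] <- lapply(sig[num], function(x) sprintf("%.6f", x))
  utils::write.csv(sig, f1, row.names = FALSE, quote = FALSE)
  files <- c(files, f1)

  comp <- report$components
  roles <- report_component_roles(report)
  ion_rows <- roles %in% c("inorganic_ion", "protein")
  f2 <- file.path(out_dir, "ions_albumin_ph_t.csv")
  ions <- comp[ion_rows, , drop = FALSE]
  ions_extra <- data.frame(component = c("pH", "T"),
                           concentration = c(report$pH, report$T),
                           uncertainty = NA_real_, clipped = FALSE, flag = "",
                           stringsAsFactors = FALSE)
  utils::write.csv(format_conc(rbind(ions, ions_extra)), f2,
                   row.names = FALSE, quote = FALSE)
  files <- c(files, f2)

  f3 <- file.path(out_dir, "metabolite_concentrations.csv")
  utils::write.csv(format_conc(comp[roles == "active_metabolite", ,
                                    drop = FALSE]),
                   f3, row.names = FALSE, quote = FALSE)
  files <- c(files, f3)

  if (!is.null(spectrum)) {
    f4 <- file.path(out_dir, "annotated_spectrum.png")
    grDevices::png(f4, width = 1600, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_annotated_spectrum(spectrum, report)
    files <- c(files, f4)
  }
  invisible(files)
}

report_component_roles <- function(report) {
  # roles looked up in the report's panel are not stored in the report;
  # fall back on naming conventions when absent
  comp <- report$components$component
  panel <- attr(report, "panel")
  if (!is.null(panel)) {
    return(panel$components$role[match(comp, panel$components$name)])
  }
  ifelse(grepl("[+-]$|^phosphate$|^sulfate$", comp), "inorganic_ion",
         ifelse(comp == "albumin", "protein", "active_metabolite"))
}

format_conc <- function(df) {
  df$concentration <- sprintf("%.4f", df$concentration)
  df$uncertainty <- ifelse(is.na(df$uncertainty), "",
                           sprintf("%.4f", as.numeric(df$uncertainty)))
  df
}

#' Plot a spectrum with predicted signal positions annotated
#'
#' @param spectrum An `nmr_spectrum`.
#' @param report A `prediction_report`.
#' @param xlim ppm limits (default: span of the annotated signals).
#' @export
plot_annotated_spectrum <- function(spectrum, report, xlim = NULL) {
  sig <- report$signals
  if (is.null(xlim)) {
    xlim <- rev(range(sig$delta_best) + c(-0.3, 0.3))
  }
  sel <- spectrum$ppm <= max(xlim) & spectrum$ppm >= min(xlim)
  graphics::plot(spectrum$ppm[sel], spectrum$intensity[sel], type = "l",
                 xlim = xlim, xlab = "ppm", ylab = "intensity",
                 main = "Predicted signal positions")
  ymax <- max(spectrum$intensity[sel])
  graphics::abline(v = sig$delta_best, col = "#D55E00", lty = 3)
  graphics::text(sig$delta_best, ymax * 0.95,
                 paste0(sig$spin_system_id, " (", sig$multiplicity, ")"),
                 srt = 90, adj = c(1, 0.5), cex = 0.8, col = "#D55E00")
  invisible(NULL)
}
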