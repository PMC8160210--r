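#' Read a titration CSV
#'
#' Expects RFC-4180 CSV (UTF-8, dot decimal) with columns `l_total_uM` and
#' `signal`, optionally preceded by a comment line `# units: uM` (or `mM`,
#' `nM`) declaring the ligand unit; values are converted to uM internally.
#' Malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @param modality Curve modality (see [titration_curve()]).
#' @param p_total Binding-unit protein concentration, uM.
#' @return A [titration_curve()].
#' @examples
#' f <- system.file("extdata", "example_titration.csv", package = "hexabind")
#' read_titration_csv(f, "fluorescence", p_total = 0.5)
#' @export
read_titration_csv <- function(path, modality, p_total) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  unit <- "uM"
  header_at <- 1L
  if (length(lines) && grepl("^#", lines[1])) {
    m <- regmatches(lines[1], regexec("#\\s*units:\\s*(\\S+)", lines[1]))[[1]]
    if (length(m) == 2) unit <- m[2]
    header_at <- 2L
  }
  d <- utils::read.csv(text = paste(lines[header_at:length(lines)],
                                    collapse = "\n"),
                       stringsAsFactors = FALSE)
  lcol <- intersect(c("l_total_uM", "l_total"), names(d))[1]
  if (is.na(lcol) || !("signal" %in% names(d)))
    stop("missing column(s); need l_total_uM (or l_total) and signal")
  l <- suppressWarnings(as.numeric(d[[lcol]]))
  s <- suppressWarnings(as.numeric(d$signal))
  bad <- which(!is.finite(l) | !is.finite(s))
  if (length(bad))
    stop("malformed value(s) at data row(s): ", paste(bad, collapse = ", "))
  neg <- which(l < 0)
  if (length(neg))
    stop("negative ligand concentration at data row(s): ",
         paste(neg, collapse = ", "))
  fac <- switch(unit, uM = 1, "µM" = 1, mM = 1e3, nM = 1e-3,
                stop("unknown ligand unit: ", unit))
  titration_curve(l * fac, s, modality, p_total)
}

#' Write a titration curve as CSV
#'
#' @param curve A [titration_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: uM", con)
  utils::write.csv(data.frame(l_total_uM = curve$l_total,
                              signal = curve$signal),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an initial-rate kinetics CSV
#'
#' Columns `c0_uM`, `v0_U_per_mg` and optionally `ci_uM`.
#'
#' @param path File path.
#' @return A [kinetic_dataset()].
#' @export
read_kinetics_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("c0_uM", "v0_U_per_mg") %in% names(d)))
    stop("missing column(s); need c0_uM and v0_U_per_mg")
  kinetic_dataset(d$c0_uM, d$v0_U_per_mg,
                  ci = if ("ci_uM" %in% names(d)) d$ci_uM else NULL)
}

#' Oligomer mass from monomer mass
#'
#' @param monomer_kda Monomer molecular mass, kDa.
#' @param n_subunits Number of subunits (positive integer).
#' @return Assembly mass, kDa, rounded to 1 decimal for display.
#' @examples
#' molecular_mass_kda(25.970, 6)  # 155.8 kDa, the hexamer
#' @export
molecular_mass_kda <- function(monomer_kda, n_subunits) {
  if (n_subunits < 1 || n_subunits != round(n_subunits))
    stop("n_subunits must be a positive integer")
  if (monomer_kda <= 0) stop("monomer_kda must be > 0")
  round(monomer_kda * n_subunits, 1)
}

format_interval <- function(lower, upper, open_lower = FALSE,
                            open_upper = FALSE, digits = 3) {
  lo <- signif(lower, digits); up <- signif(upper, digits)
  lo_s <- if (open_lower) paste0("< ", lo) else as.character(lo)
  up_s <- if (open_upper) paste0("> ", up) else as.character(up)
  if (open_upper && !is.finite(upper)) up_s <- "open"
  paste0("(", lo_s, "–", up_s, ")", if (open_lower || open_upper) "*" else "")
}

#' Render a binding-fit report
#'
#' A per-constant table in the conventional layout -- K_d with SD and the
#' 3-sigma interval, open bounds marked with a `<` prefix and an asterisk --
#' plus a JSON twin for machine consumption.
#'
#' @param fit A `binding_fit`.
#' @param profiles Optional list of [profile_ci_3sigma()] results (one per
#'   constant); if omitted, Wald +/- 3 SD intervals in log10 space are used.
#' @param json_path Optional path; when given, the JSON twin is written there.
#' @return Character vector of report lines (invisibly returns the report
#'   list when `json_path` is set).
#' @export
write_report <- function(fit, profiles = NULL, json_path = NULL) {
  idx <- grep("^log10_kd", names(fit$params))
  rows <- lapply(seq_along(idx), function(j) {
    est <- 10^fit$params[idx[j]]
    sd_lin <- abs(est * log(10) * fit$sd[idx[j]])
    if (!is.null(profiles)) {
      pr <- profiles[[j]]
      interval <- format_interval(pr$lower, pr$upper, pr$open_lower,
                                  pr$open_upper)
      ivals <- list(lower = pr$lower, upper = pr$upper,
                    open_lower = pr$open_lower, open_upper = pr$open_upper)
    } else {
      lo <- 10^fit$ci3[idx[j], "lower"]; up <- 10^fit$ci3[idx[j], "upper"]
      interval <- format_interval(lo, up, fit$ci3_open[idx[j], "lower"],
                                  fit$ci3_open[idx[j], "upper"])
      ivals <- list(lower = lo, upper = up,
                    open_lower = unname(fit$ci3_open[idx[j], "lower"]),
                    open_upper = unname(fit$ci3_open[idx[j], "upper"]))
    }
    list(name = paste0("Kd", j), estimate_uM = unname(est),
         sd_uM = unname(sd_lin), interval = interval, bounds = ivals)
  })
  lines <- c(sprintf("Model: %s   SSR = %.6g   n = %d   AICc = %.4g",
                     fit$model_label, fit$ssr, fit$n_obs, fit$aic),
             sprintf("%-6s %14s %14s   %s", "const", "Kd [uM]", "SD [uM]",
                     "3-sigma interval [uM]"),
             vapply(rows, function(r)
               sprintf("%-6s %14.5g %14.3g   %s", r$name, r$estimate_uM,
                       r$sd_uM, r$interval), character(1)))
  if (!is.null(json_path)) {
    payload <- list(model = fit$model_label, ssr = fit$ssr, n = fit$n_obs,
                    aicc = fit$aic,
                    constants = lapply(rows, function(r)
                      r[c("name", "estimate_uM", "sd_uM", "bounds")]))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
    return(invisible(list(lines = lines, payload = payload)))
  }
  lines
}
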