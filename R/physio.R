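#' Load the packaged per-run physiology table
#'
#' Per-run isoflurane concentration, burst-suppression ratio, heart rate,
#' end-tidal CO2 and temperature for the two animals of the study cohort
#' (27 BS runs, 11 SW runs), shipped as a plain TSV fixture.
#'
#' @param path optional path to an alternative table with the same columns.
#' @return data.frame with columns `subject`, `session`, `run`, `group`,
#'   `iso_pct`, `bsr_pct`, `heart_rate_bpm`, `etco2_mmhg`, `temperature_c`.
#' @export
load_physio_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_physio.tsv", package = "bsfc",
                        mustWork = TRUE)
  }
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_physio_table(tb)
  tb
}

validate_physio_table <- function(tb) {
  need <- c("subject", "session", "run", "group", "iso_pct", "bsr_pct",
            "heart_rate_bpm", "etco2_mmhg", "temperature_c")
  if (!all(need %in% names(tb))) {
    stop("physiology table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(tb$group %in% c("BS", "SW"))) stop("group must be BS or SW")
  if (any(tb$bsr_pct[tb$group == "SW"] != 0)) stop("SW rows must have BSR 0")
  num <- tb[c("bsr_pct", "heart_rate_bpm", "etco2_mmhg", "temperature_c")]
  if (!all(vapply(num, is.numeric, logical(1))) || !all(is.finite(as.matrix(num)))) {
    stop("physiological measures must be finite numerics")
  }
  invisible(tb)
}

#' Per-group mean of a physiological variable
#'
#' @param table a physiology table (see [load_physio_table()]).
#' @param subject subject ID to restrict to.
#' @param variable one of `bsr_pct`, `heart_rate_bpm`, `etco2_mmhg`,
#'   `temperature_c`.
#' @return Named numeric vector of per-group arithmetic means
#'   (`BS` and/or `SW`).
#' @export
group_summary <- function(table, subject, variable) {
  validate_physio_table(table)
  if (!variable %in% names(table) ||
      variable %in% c("subject", "session", "run", "group")) {
    stop("unknown variable: ", variable)
  }
  sub <- table[table$subject == subject, ]
  if (nrow(sub) == 0) stop("unknown subject: ", subject)
  tapply(sub[[variable]], sub$group, mean)
}

#' Pooled two-sample Student's t-test
#'
#' Classical equal-variance two-sample t:
#' `t = (mean(x) - mean(y)) / (s_p * sqrt(1/n_x + 1/n_y))`,
#' `df = n_x + n_y - 2`, two-tailed p. When both samples are constant and
#' equal, `t = 0, p = 1` by convention.
#'
#' @param x,y numeric samples (length >= 2 each).
#' @return List with `t`, `df`, `p`.
#' @export
pooled_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need at least 2 observations per group")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  d <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (d == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
    stop("degenerate variance: zero pooled variance with unequal means")
  }
  tt <- d / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

# round half away from zero (the convention of the printed table; base R
# round() is round-half-even and would print 15.865 as 15.86)
round_half_away <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

format_p <- function(p) {
  if (p < 5e-4) "<0.000" else sprintf("%.3f", round_half_away(p, 3))
}

#' Group summary and significance report for the physiology table
#'
#' Mirrors the summary layout of the cohort's physiology table: per subject,
#' BS-group means, SW-group means, and pooled two-sample t-test p-values for
#' heart rate, end-tidal CO2 and temperature. P-values are printed at three
#' decimals (round half away from zero); values below 0.0005 render as
#' `"<0.000"`.
#'
#' @param table a physiology table.
#' @return Named list per subject, each with `bs_means`, `sw_means`
#'   (named vectors over bsr/heart rate/EtCO2/temperature) and `p` (named
#'   character vector over heart rate/EtCO2/temperature).
#' @export
physio_report <- function(table) {
  validate_physio_table(table)
  vars <- c("bsr_pct", "heart_rate_bpm", "etco2_mmhg", "temperature_c")
  tested <- c("heart_rate_bpm", "etco2_mmhg", "temperature_c")
  out <- list()
  for (s in unique(table$subject)) {
    sub <- table[table$subject == s, ]
    if (!all(c("BS", "SW") %in% sub$group)) {
      stop("subject ", s, " is missing a group")
    }
    bs <- sub[sub$group == "BS", ]; sw <- sub[sub$group == "SW", ]
    out[[s]] <- list(
      bs_means = vapply(vars, function(v) mean(bs[[v]]), numeric(1)),
      sw_means = vapply(vars, function(v) mean(sw[[v]]), numeric(1)),
      p = vapply(tested, function(v) {
        format_p(pooled_t_test(bs[[v]], sw[[v]])$p)
      }, character(1))
    )
  }
  out
}
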