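#' Write a sprint trace to delimited text
#'
#' Canonical per-revolution format: comma-separated, '.' decimal, UTF-8, with
#' '#'-prefixed metadata header lines (protocol, target cadence, crank length,
#' seed if recorded) followed by a header row
#' `rev_index,t_s,cadence_rpm,force_N,power_W`.
#'
#' @param trace A [sprint_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sprint_trace"))
  meta <- c(
    sprintf("# protocol: %s", trace$protocol),
    sprintf("# target_cadence_rpm: %.6g", trace$target_cadence_rpm),
    sprintf("# crank_length_m: %.6g", trace$geometry$crank_length_m)
  )
  if (!is.null(trace$meta$seed)) {
    meta <- c(meta, sprintf("# seed: %d", trace$meta$seed))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  r <- trace$revolutions
  out <- data.frame(rev_index = r$index_n,
                    t_s = formatC(r$t_s, digits = 10, format = "g"),
                    cadence_rpm = formatC(r$cadence_rpm, digits = 10, format = "g"),
                    force_N = formatC(r$force_N, digits = 10, format = "g"),
                    power_W = formatC(r$power_W, digits = 10, format = "g"))
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sprint trace from delimited text
#'
#' Inverse of [write_trace()]. Unknown extra columns are ignored (or kept in
#' the revolutions data frame with `keep_extra = TRUE`); missing required
#' columns or unsorted times are errors.
#'
#' @param path File path.
#' @param keep_extra Keep unrecognised columns.
#' @return A [sprint_trace()].
#' @export
read_trace <- function(path, keep_extra = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, ":"), meta_lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  req <- c("rev_index", "t_s", "cadence_rpm", "force_N", "power_W")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("trace file missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!keep_extra) df <- df[req]
  names(df)[names(df) == "rev_index"] <- "index_n"
  protocol <- get_meta("protocol")
  target <- as.numeric(get_meta("target_cadence_rpm"))
  crank <- as.numeric(get_meta("crank_length_m"))
  seed <- get_meta("seed")
  sprint_trace(df,
               target_cadence_rpm = if (length(target)) target else max(df$cadence_rpm),
               geometry = crank_geometry(if (length(crank)) crank else 0.17),
               protocol = if (!is.null(protocol)) protocol else "isokinetic_45s",
               meta = if (!is.null(seed)) list(seed = as.integer(seed)) else list())
}

#' Aggregate raw crank samples into per-revolution values
#'
#' Integrates angular velocity to cumulative crank angle, cuts revolutions at
#' each multiple of 2*pi, and computes per-revolution cadence (1/duration),
#' mean power (mean of torque times angular velocity) and mean pedal force
#' (power / tangential pedal speed). Emulates per-revolution averaging of
#' 200 Hz ergometer data.
#'
#' @param raw Data frame with columns `time_s` (uniform), `torque_Nm`,
#'   `angular_velocity_rad_s` (>= 0).
#' @param geometry A [crank_geometry()].
#' @param target_cadence_rpm Target cadence metadata for the resulting trace;
#'   default the maximum observed per-revolution cadence.
#' @param protocol Protocol tag for the resulting trace.
#' @return A [sprint_trace()].
#' @export
aggregate_revolutions <- function(raw, geometry = crank_geometry(),
                                  target_cadence_rpm = NULL,
                                  protocol = "isokinetic_45s") {
  req <- c("time_s", "torque_Nm", "angular_velocity_rad_s")
  stopifnot(all(req %in% names(raw)))
  w <- raw$angular_velocity_rad_s
  if (any(w < 0)) stop("angular velocity must be >= 0", call. = FALSE)
  dt <- diff(raw$time_s)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  # cumulative angle by trapezoid
  ang <- c(0, cumsum(dt * (utils::head(w, -1) + utils::tail(w, -1)) / 2))
  n_rev <- floor(ang[length(ang)] / (2 * pi))
  if (n_rev < 1) stop("samples span less than one revolution", call. = FALSE)
  power_inst <- raw$torque_Nm * w
  bounds <- vapply(seq_len(n_rev) * 2 * pi, function(a) {
    i <- which(ang >= a)[1]
    # linear interpolation of the crossing time
    if (ang[i] == a || i == 1L) return(raw$time_s[i])
    f <- (a - ang[i - 1]) / (ang[i] - ang[i - 1])
    raw$time_s[i - 1] + f * (raw$time_s[i] - raw$time_s[i - 1])
  }, numeric(1))
  t0 <- c(raw$time_s[1], bounds[-n_rev])
  dur <- bounds - t0
  cad <- 60 / dur
  pw <- vapply(seq_len(n_rev), function(i) {
    sel <- raw$time_s >= t0[i] & raw$time_s <= bounds[i]
    mean(power_inst[sel])
  }, numeric(1))
  force <- pw / (2 * pi * geometry$crank_length_m * cad / 60)
  revs <- data.frame(index_n = seq_len(n_rev), t_s = bounds, cadence_rpm = cad,
                     force_N = force, power_W = pw)
  sprint_trace(revs,
               target_cadence_rpm = if (is.null(target_cadence_rpm))
                 max(cad) else target_cadence_rpm,
               geometry = geometry, protocol = protocol)
}

#' Emit constant-within-revolution raw samples from a trace
#'
#' Synthesises a 200 Hz torque / angular-velocity record in which each
#' revolution has constant angular velocity and torque matching its
#' per-revolution cadence and power; exists solely to exercise
#' [aggregate_revolutions()] round trips.
#'
#' @param trace A [sprint_trace()].
#' @param hz Sampling rate, default 200.
#' @return Data frame with `time_s`, `torque_Nm`, `angular_velocity_rad_s`.
#' @export
emit_raw_samples <- function(trace, hz = 200) {
  r <- trace$revolutions
  t0 <- c(0, utils::head(r$t_s, -1))
  tt <- seq(0, max(r$t_s), by = 1 / hz)
  i <- findInterval(tt, c(t0[1], r$t_s), rightmost.closed = TRUE)
  i[i < 1] <- 1L; i[i > nrow(r)] <- nrow(r)
  w <- 2 * pi * r$cadence_rpm[i] / 60
  torque <- ifelse(w > 0, r$power_W[i] / w, 0)
  data.frame(time_s = tt, torque_Nm = torque, angular_velocity_rad_s = w)
}

#' Calibrate a whole synthetic cohort
#'
#' Runs [calibrate_athlete()] on every athlete of a [generate_cohort()]
#' result and stacks the per-athlete parameter rows.
#'
#' @param cohort Result of [generate_cohort()].
#' @return List with `fits` (per-athlete calibration lists) and `table`
#'   (data frame of parameter rows, one per athlete, plus `sex`).
#' @export
calibrate_cohort <- function(cohort) {
  fits <- lapply(cohort, function(a) calibrate_athlete(a$iso, a$motoric))
  tab <- as.data.frame(do.call(rbind, lapply(fits, `[[`, "row")))
  tab$sex <- vapply(cohort, function(a) a$athlete$sex, character(1))
  list(fits = fits, table = tab)
}

#' Cohort summary table (mean, 95% CI, SD)
#'
#' Summarises each numeric column of a cohort parameter table as mean, 95%
#' confidence bounds (`mean +/- t[0.975, n-1] * SD / sqrt(n)`) and SD — the
#' presentation of the calibrated-parameter table.
#'
#' @param table Data frame of per-athlete parameter rows
#'   (from [calibrate_cohort()]).
#' @return Data frame with `parameter`, `mean`, `ci_lower`, `ci_upper`, `sd`.
#' @export
report_table <- function(table) {
  num <- table[vapply(table, is.numeric, logical(1))]
  n <- nrow(num)
  tq <- stats::qt(0.975, n - 1)
  out <- do.call(rbind, lapply(names(num), function(p) {
    m <- mean(num[[p]]); s <- stats::sd(num[[p]])
    data.frame(parameter = p, mean = m,
               ci_lower = m - tq * s / sqrt(n), ci_upper = m + tq * s / sqrt(n),
               sd = s, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Model-accuracy comparison statistics across a cohort
#'
#' The model-comparison battery on a cohort's fit table: one-way
#' repeated-measures ANOVA (GG-corrected) of RMSE across PASA, PESA15 and
#' PESA45, Bonferroni-corrected paired post hocs with Cohen's d, the
#' PASA-vs-optimised-decrement contrast, the paired comparison and
#' Pitman-Morgan variance test of the short- vs full-window decrement, and
#' (when both sexes are present) summary-based sex contrasts with Hedges' g.
#'
#' @param table Cohort parameter table from [calibrate_cohort()].
#' @return List with `rmse_anova`, `posthoc` (data frame), `delta_paired`,
#'   `delta_variance`, and `sex_contrasts` (data frame or NULL).
#' @export
compare_models <- function(table) {
  rmse <- as.matrix(table[, c("RMSE", "RMSE_PESA15", "RMSE_PESA45")])
  colnames(rmse) <- c("PASA", "PESA15", "PESA45")
  anova_res <- rm_anova_gg(rmse)

  pairs <- list(c("PASA", "PESA15"), c("PASA", "PESA45"), c("PESA15", "PESA45"))
  ph <- do.call(rbind, lapply(pairs, function(pr) {
    tr <- paired_t(rmse[, pr[1]], rmse[, pr[2]])
    data.frame(contrast = paste(pr, collapse = " vs "),
               t = tr$statistic, df = tr$df, p = tr$p_value,
               cohens_d = tr$effect_size, stringsAsFactors = FALSE)
  }))
  ph$p_adj <- bonferroni(ph$p, m = nrow(ph))
  opt_vs_pasa <- paired_t(table$RMSE, table$RMSE_PESAopt)

  delta_paired <- paired_t(table$Delta15, table$Delta45)
  delta_variance <- pitman_morgan(table$Delta15, table$Delta45)

  sex_contrasts <- NULL
  if (all(c("female", "male") %in% table$sex)) {
    gsum <- function(x) group_summary(length(x), mean(x), stats::sd(x))
    sex_contrasts <- do.call(rbind, lapply(
      c("Pmax", "Fmax", "PRopt", "a", "AF", "tauF", "CF", "Delta15", "Delta45"),
      function(p) {
        m <- table[[p]][table$sex == "male"]
        f <- table[[p]][table$sex == "female"]
        tr <- independent_t(gsum(m), gsum(f))
        data.frame(parameter = p, t = tr$statistic, df = tr$df, p = tr$p_value,
                   hedges_g = tr$effect_size, stringsAsFactors = FALSE)
      }))
  }
  list(rmse_anova = anova_res, posthoc = ph, opt_vs_pasa = opt_vs_pasa,
       delta_paired = delta_paired, delta_variance = delta_variance,
       sex_contrasts = sex_contrasts)
}
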